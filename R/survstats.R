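# Censored-survival statistics implemented from first principles:
# Kaplan-Meier product-limit, two-group log-rank, Cox partial likelihood
# (Efron/Breslow ties, Newton-Raphson with step-halving), Harrell's C.

#' @keywords internal
check_surv <- function(times, events) {
  stopifnot(is.numeric(times), length(times) == length(events))
  events <- as.integer(as.logical(events))
  if (length(times) == 0L) stop("empty survival sample", call. = FALSE)
  if (any(is.na(times)) || any(is.na(events))) {
    stop("missing values in survival sample", call. = FALSE)
  }
  if (any(times <= 0)) stop("survival times must be positive", call. = FALSE)
  events
}

#' Kaplan-Meier product-limit curve
#'
#' @param times event/censoring times in months.
#' @param events event indicators (1 = event observed, 0 = censored).
#' @return An object of class `km_curve` with the distinct event times,
#'   the product-limit survival estimate after each, the number at risk
#'   and the number of events at each time.
#' @examples
#' km <- km_curve(c(5, 10, 12, 30), c(1, 0, 1, 0))
#' survival_at(km, 36)
#' @export
km_curve <- function(times, events) {
  events <- check_surv(times, events)
  et <- sort(unique(times[events == 1L]))
  n_risk <- d <- integer(length(et))
  surv <- numeric(length(et))
  s <- 1
  for (i in seq_along(et)) {
    n_risk[i] <- sum(times >= et[i])
    d[i] <- sum(times == et[i] & events == 1L)
    s <- s * (1 - d[i] / n_risk[i])
    surv[i] <- s
  }
  structure(list(event_times = et, survival = surv, at_risk = n_risk,
                 n_events = d, n = length(times), max_time = max(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event time(s)\n",
              x$n, length(x$event_times)))
  if (length(x$event_times) > 0L) {
    print(data.frame(time = x$event_times, n_risk = x$at_risk,
                     n_events = x$n_events, survival = round(x$survival, 4)))
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "Months", ylab = "Survival probability",
                          ...) {
  tt <- c(0, x$event_times, x$max_time)
  ss <- c(1, x$survival, if (length(x$survival)) x$survival[length(x$survival)] else 1)
  graphics::plot(tt, ss, type = "s", ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation: at an event time the
#' post-drop value is returned; beyond the last event time the last
#' survival value extends.
#'
#' @param curve a [km_curve()].
#' @param t time in months (vectorized), `t >= 0`.
#' @return Survival probabilities.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  if (length(curve$event_times) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, curve$event_times)
  c(1, curve$survival)[idx + 1L]
}

#' Three-year survival rate
#'
#' Kaplan-Meier survival probability at 36 months, the primary outcome
#' scale used for recurrence-free and overall survival comparisons.
#'
#' @inheritParams km_curve
#' @return Probability in \[0, 1\].
#' @export
three_year_rate <- function(times, events) {
  survival_at(km_curve(times, events), 36)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) two-group log-rank: at each distinct event time
#' the observed minus expected events in group B are accumulated with the
#' hypergeometric variance; the statistic is `(O-E)^2/V` on 1 degree of
#' freedom. With zero events overall the result is degenerate and returned
#' as chi-square 0, p 1 with `degenerate = TRUE`.
#'
#' @param times_a,events_a survival data for group A.
#' @param times_b,events_b survival data for group B.
#' @return A list of class `logrank_result` with `chi_square`, `df`,
#'   `p_value`, `observed`, `expected` (group B), and `degenerate`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  ea <- check_surv(times_a, events_a)
  eb <- check_surv(times_b, events_b)
  times <- c(times_a, times_b)
  events <- c(ea, eb)
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  et <- sort(unique(times[events == 1L]))
  if (length(et) == 0L) {
    return(structure(list(chi_square = 0, df = 1L, p_value = 1,
                          observed = 0, expected = 0, variance = 0,
                          degenerate = TRUE), class = "logrank_result"))
  }
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(times == t & events == 1L)
    d1 <- sum(times == t & events == 1L & grp == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  structure(list(chi_square = chi, df = 1L,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = O, expected = E, variance = V,
                 degenerate = V <= 0), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f (df = %d), p = %.4g%s\n",
              x$chi_square, x$df, x$p_value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# Partial log-likelihood, score and observed information for the Cox model.
# Subjects must be sorted by increasing time.
#' @keywords internal
cox_loglik <- function(beta, tt, ee, xx, ties) {
  n <- nrow(xx)
  p <- ncol(xx)
  eta <- drop(xx %*% beta)
  w <- exp(eta)
  wx <- xx * w
  # reverse cumulative sums over the (ascending-time) risk sets
  rc <- function(m) {
    m <- apply(m, 2L, function(col) rev(cumsum(rev(col))))
    matrix(m, nrow = n)
  }
  cw <- rev(cumsum(rev(w)))
  cwx <- rc(wx)
  # upper-triangle cross products w * x_j * x_k
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  wxx <- matrix(0, n, nrow(ut))
  for (q in seq_len(nrow(ut))) {
    wxx[, q] <- w * xx[, ut[q, 1L]] * xx[, ut[q, 2L]]
  }
  cwxx <- rc(wxx)
  unpack <- function(v) {
    m <- matrix(0, p, p)
    for (q in seq_len(nrow(ut))) {
      m[ut[q, 1L], ut[q, 2L]] <- v[q]
      m[ut[q, 2L], ut[q, 1L]] <- v[q]
    }
    m
  }
  ll <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    t_i <- tt[i]
    first <- i
    while (i <= n && tt[i] == t_i) i <- i + 1L
    dset <- first:(i - 1L)
    dset <- dset[ee[dset] == 1L]
    d <- length(dset)
    if (d == 0L) next
    S_R <- cw[first]
    S_Rx <- cwx[first, ]
    S_Rxx <- unpack(cwxx[first, ])
    if (ties == "efron" && d > 1L) {
      S_D <- sum(w[dset])
      S_Dx <- colSums(wx[dset, , drop = FALSE])
      S_Dxx <- unpack(colSums(wxx[dset, , drop = FALSE]))
    } else {
      S_D <- 0
      S_Dx <- numeric(p)
      S_Dxx <- matrix(0, p, p)
    }
    ll <- ll + sum(eta[dset])
    score <- score + colSums(xx[dset, , drop = FALSE])
    for (l in seq_len(d) - 1L) {
      frac <- if (ties == "efron") l / d else 0
      phi <- S_R - frac * S_D
      Z <- S_Rx - frac * S_Dx
      V <- S_Rxx - frac * S_Dxx
      ll <- ll - log(phi)
      score <- score - Z / phi
      info <- info + V / phi - tcrossprod(Z / phi)
    }
  }
  list(ll = ll, score = score, info = info)
}

#' Cox proportional hazards fit by partial likelihood
#'
#' Newton-Raphson maximization of the Cox partial likelihood with the
#' Efron (default) or Breslow correction for tied event times. Iteration
#' starts at zero, uses step-halving whenever a step would decrease the
#' partial log-likelihood, and stops when the largest component of the
#' score vector falls below `tol`. Standard errors come from the inverse
#' observed information; confidence intervals and p-values are Wald,
#' two-sided.
#'
#' Monotone likelihood (separation, e.g. a comparison group with no
#' events) cannot be maximized at a finite coefficient: the fit is then
#' flagged `degenerate` and the diverging coefficient is reported capped
#' at +/-`cap` rather than presented as a trustworthy finite estimate.
#'
#' @param times,events survival data (months; 1 = event).
#' @param x covariate matrix (or vector) aligned to subjects.
#' @param ties `"efron"` or `"breslow"`; both agree exactly when no event
#'   times are tied.
#' @param tol convergence tolerance on the score max-norm.
#' @param max_iter maximum Newton iterations.
#' @param cap absolute bound at which a coefficient is declared diverging.
#' @param conf confidence level for the Wald intervals.
#' @return An object of class `cox_pl` with elements `coef`, `hr`, `se`,
#'   `ci_low`, `ci_high`, `p_values`, `loglik` (null and maximized),
#'   `iterations`, `converged`, `degenerate`, `n`, `n_events`.
#' @examples
#' set.seed(1)
#' tm <- rexp(60); ev <- rbinom(60, 1, 0.8); z <- rbinom(60, 1, 0.5)
#' fit <- cox_fit(tm, ev, z)
#' coef(fit)
#' @export
cox_fit <- function(times, events, x, ties = c("efron", "breslow"),
                    tol = 1e-9, max_iter = 50L, cap = 15, conf = 0.95) {
  ties <- match.arg(ties)
  events <- check_surv(times, events)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stopifnot(nrow(x) == length(times))
  if (sum(events) == 0L) stop("no events in sample", call. = FALSE)
  constant <- apply(x, 2L, function(col) length(unique(col)) == 1L)
  if (any(constant)) {
    stop("constant covariate column(s): ",
         paste(colnames(x)[constant], collapse = ", "), call. = FALSE)
  }
  ord <- order(times)
  tt <- times[ord]
  ee <- events[ord]
  xx <- x[ord, , drop = FALSE]
  p <- ncol(xx)
  beta <- numeric(p)
  state <- cox_loglik(beta, tt, ee, xx, ties)
  ll_null <- state$ll
  converged <- FALSE
  degenerate <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(state$score)) < tol) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(state$info, state$score), error = function(e) NULL)
    if (is.null(delta)) {
      degenerate <- TRUE
      break
    }
    step <- 1
    repeat {
      cand <- beta + step * delta
      cand_state <- cox_loglik(cand, tt, ee, xx, ties)
      if (is.finite(cand_state$ll) && cand_state$ll >= state$ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- pmin(pmax(cand, -cap), cap)
    if (any(abs(cand) >= cap)) {
      degenerate <- TRUE
      state <- cox_loglik(beta, tt, ee, xx, ties)
      break
    }
    state <- cand_state
  }
  if (!degenerate && !converged && max(abs(state$score)) < tol) {
    converged <- TRUE
  }
  vcov <- tryCatch(solve(state$info), error = function(e) matrix(NA_real_, p, p))
  if (anyNA(vcov) || any(diag(vcov) < 0)) degenerate <- TRUE
  se <- sqrt(pmax(diag(vcov), 0))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  names(beta) <- names(se) <- colnames(xx)
  structure(list(
    coef = beta, hr = exp(beta), se = se,
    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    p_values = 2 * stats::pnorm(-abs(beta / se)),
    loglik = c(null = ll_null, final = state$ll),
    score = state$score, vcov = vcov, iterations = iter,
    converged = converged, degenerate = degenerate,
    ties = ties, n = length(tt), n_events = sum(ee)
  ), class = "cox_pl")
}

#' @export
print.cox_pl <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  if (x$degenerate) cat("  NOTE: degenerate fit (monotone likelihood or singular information)\n")
  if (!x$converged) cat("  NOTE: did not converge\n")
  print(summary(x)$table)
  invisible(x)
}

#' @export
summary.cox_pl <- function(object, ...) {
  tab <- data.frame(
    coef = object$coef, HR = object$hr, se = object$se,
    ci_low = object$ci_low, ci_high = object$ci_high,
    p = object$p_values, row.names = names(object$coef))
  out <- list(table = tab, loglik = object$loglik,
              iterations = object$iterations, converged = object$converged,
              degenerate = object$degenerate)
  class(out) <- "summary.cox_pl"
  out
}

#' @export
print.summary.cox_pl <- function(x, ...) {
  print(x$table)
  cat(sprintf("partial log-likelihood: %.4f (null %.4f); %d iteration(s)\n",
              x$loglik[["final"]], x$loglik[["null"]], x$iterations))
  invisible(x)
}

#' @export
coef.cox_pl <- function(object, ...) object$coef

#' @export
vcov.cox_pl <- function(object, ...) object$vcov

#' @export
logLik.cox_pl <- function(object, ...) {
  structure(object$loglik[["final"]], df = length(object$coef),
            class = "logLik")
}

# Concordance statistic over comparable pairs: a pair is usable when the
# two times differ and the subject with the smaller time had the event.
#' @keywords internal
c_stat <- function(scores, times, events) {
  conc <- tied <- comp <- 0
  for (i in which(events == 1L)) {
    later <- times > times[i]
    comp <- comp + sum(later)
    conc <- conc + sum(later & scores[i] > scores)
    tied <- tied + sum(later & scores[i] == scores)
  }
  list(c_index = if (comp > 0) (conc + 0.5 * tied) / comp else NA_real_,
       n_comparable = comp, n_tied_score = tied)
}

#' Harrell's concordance index
#'
#' Probability, over pairs comparable under right censoring (the smaller
#' time carries an event and the times differ), that the higher-scored
#' subject fails first; score ties count one half. The confidence interval
#' is a seeded percentile bootstrap over subjects.
#'
#' @param scores risk scores (higher = higher risk), aligned to subjects.
#' @param times,events survival data.
#' @param n_boot bootstrap replicates for the confidence interval; 0
#'   disables the interval.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return An object of class `concordance_result` with `c_index`,
#'   `ci_low`, `ci_high`, `n_comparable`, `n_tied_score`.
#' @export
harrell_c <- function(scores, times, events, n_boot = 1000L, seed = NULL,
                      conf = 0.95) {
  events <- check_surv(times, events)
  scores <- as.numeric(scores)
  stopifnot(length(scores) == length(times))
  base <- c_stat(scores, times, events)
  if (base$n_comparable == 0) {
    stop("no comparable pairs under censoring", call. = FALSE)
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit({
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      }, add = TRUE)
      set.seed(seed)
    }
    n <- length(times)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      c_stat(scores[idx], times[idx], events[idx])$c_index
    }, numeric(1))
    reps <- reps[!is.na(reps)]
    if (length(reps) > 0L) {
      alpha <- 1 - conf
      ci <- unname(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                   type = 7))
    }
  }
  structure(list(c_index = base$c_index, ci_low = ci[1], ci_high = ci[2],
                 n_comparable = base$n_comparable,
                 n_tied_score = base$n_tied_score, n_boot = n_boot),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f", x$c_index))
  if (!is.na(x$ci_low)) cat(sprintf(" (95%% CI %.4f-%.4f)", x$ci_low, x$ci_high))
  cat(sprintf("; %d comparable pair(s), %d score tie(s)\n",
              x$n_comparable, x$n_tied_score))
  invisible(x)
}
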