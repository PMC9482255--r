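# Full analysis pipeline: variable screening, rule-model evaluation
# against the Sedlis criteria, ranking and best-model drill-down.

#' Analysis configuration
#'
#' @param seed seed for every stochastic component (bootstrap intervals).
#' @param alpha two-sided significance level for the univariate screen.
#' @param endpoint screening/evaluation endpoint, `"rfs"` or `"os"`;
#'   selection always uses recurrence-free survival in the reference
#'   workflow.
#' @param force_include variable names retained regardless of their
#'   screening p-value (default Silva B + C, kept for its prognostic
#'   value despite a borderline p).
#' @param n_boot bootstrap replicates for concordance intervals.
#' @param cutoffs a [cutoff_config()].
#' @param models a [model_config()].
#' @param evaluate_full_cohort evaluate on the full cohort instead of the
#'   intermediate-risk subset (sensitivity analysis only).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, alpha = 0.05, endpoint = "rfs",
                            force_include = "silva_BC", n_boot = 200L,
                            cutoffs = cutoff_config(),
                            models = model_config(),
                            evaluate_full_cohort = FALSE) {
  stopifnot(alpha > 0, alpha < 1, endpoint %in% c("rfs", "os"))
  structure(list(seed = as.integer(seed), alpha = alpha,
                 endpoint = endpoint, force_include = force_include,
                 n_boot = as.integer(n_boot), cutoffs = cutoffs,
                 models = models,
                 evaluate_full_cohort = isTRUE(evaluate_full_cohort)),
            class = "analysis_config")
}

#' @keywords internal
endpoint_cols <- function(cohort, endpoint) {
  if (endpoint == "rfs") {
    list(times = cohort$rfs_months, events = as.integer(cohort$rfs_event))
  } else {
    list(times = cohort$os_months, events = as.integer(cohort$os_event))
  }
}

#' Univariate screening of candidate variables
#'
#' Fits a univariate Cox model per candidate indicator and retains those
#' with two-sided Wald p below `alpha`, plus any `force_include`
#' variables. Indicators constant over the cohort (all-true or all-false)
#' cannot be screened and are excluded with a warning.
#'
#' @param cohort a `silva_cohort` (normally the intermediate-risk subset).
#' @param variables candidate table from [make_cutoff_variables()].
#' @param endpoint `"rfs"` or `"os"`.
#' @param alpha significance level.
#' @param force_include variable names always retained.
#' @return Data frame of class `screen_result`: one row per screenable
#'   variable with `hr`, `ci_low`, `ci_high`, `p`, `n_positive`,
#'   `selected`, `forced`, `degenerate`.
#' @export
univariate_screen <- function(cohort, variables, endpoint = "rfs",
                              alpha = 0.05, force_include = character()) {
  stopifnot(inherits(cohort, "silva_cohort"), nrow(cohort) > 0L)
  ep <- endpoint_cols(cohort, endpoint)
  rows <- list()
  for (i in seq_len(nrow(variables))) {
    v <- variables[i, , drop = FALSE]
    ind <- as.numeric(factor_value(cohort, v))
    if (length(unique(ind)) == 1L) {
      warning("variable '", v$name, "' is constant over the cohort; excluded",
              call. = FALSE)
      next
    }
    fit <- cox_fit(ep$times, ep$events, matrix(ind, ncol = 1))
    rows[[length(rows) + 1L]] <- data.frame(
      name = v$name, label = v$label,
      hr = unname(fit$hr), ci_low = unname(fit$ci_low),
      ci_high = unname(fit$ci_high), p = unname(fit$p_values),
      n_positive = sum(ind), degenerate = fit$degenerate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$forced <- out$name %in% force_include
  out$selected <- (out$p < alpha & !out$degenerate) | out$forced
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Multivariate Cox fit on a set of cutoff variables
#'
#' Joint Cox model over the indicator columns of the given variables.
#' Exactly duplicated indicator columns raise a collinearity error naming
#' the columns; overlapping (nested) indicators such as Silva B + C with
#' Silva C are permitted but flagged in the returned object.
#'
#' @param cohort a `silva_cohort`.
#' @param variables variable table (rows of [make_cutoff_variables()]) or
#'   character vector of variable names.
#' @param endpoint `"rfs"` or `"os"`.
#' @return A [cox_fit()] object with extra fields `condition_number` and
#'   `overlapping` (character vector of nested indicator pairs).
#' @export
multivariate_fit <- function(cohort, variables, endpoint = "rfs") {
  stopifnot(inherits(cohort, "silva_cohort"))
  if (is.character(variables)) {
    tab <- make_cutoff_variables()
    variables <- tab[match(variables, tab$name), , drop = FALSE]
  }
  if (nrow(variables) < 1L) stop("need at least one variable", call. = FALSE)
  X <- sapply(seq_len(nrow(variables)), function(i) {
    as.numeric(factor_value(cohort, variables[i, , drop = FALSE]))
  })
  X <- matrix(X, nrow = nrow(cohort))
  colnames(X) <- variables$name
  dup <- duplicated(t(X))
  if (any(dup)) {
    for (j in which(dup)) {
      twin <- which(apply(X, 2L, identical, X[, j]))[1L]
      stop("collinear indicator columns: ", colnames(X)[twin], " and ",
           colnames(X)[j], call. = FALSE)
    }
  }
  overlapping <- character(0)
  for (a in seq_len(ncol(X) - 1L)) for (b in (a + 1L):ncol(X)) {
    if (all(X[, b] <= X[, a]) || all(X[, a] <= X[, b])) {
      overlapping <- c(overlapping,
                       paste(colnames(X)[a], colnames(X)[b], sep = " ~ "))
    }
  }
  ep <- endpoint_cols(cohort, endpoint)
  fit <- cox_fit(ep$times, ep$events, X)
  fit$condition_number <- kappa(fit$vcov, exact = TRUE)
  fit$overlapping <- overlapping
  fit
}

#' @keywords internal
evaluate_indicator <- function(cohort, indicator, model_id, label,
                               endpoint = "rfs", n_boot = 200L,
                               seed = NULL) {
  ep <- endpoint_cols(cohort, endpoint)
  ind <- as.integer(indicator)
  n_pos <- sum(ind == 1L)
  n_neg <- sum(ind == 0L)
  ev_pos <- sum(ep$events[ind == 1L])
  ev_neg <- sum(ep$events[ind == 0L])
  degenerate <- n_pos == 0L || n_neg == 0L || ev_pos == 0L || ev_neg == 0L
  hr <- ci_low <- ci_high <- cox_p <- chi_sq <- lr_p <- NA_real_
  c_index <- c_lo <- c_hi <- NA_real_
  if (n_pos > 0L && n_neg > 0L && sum(ep$events) > 0L) {
    fit <- cox_fit(ep$times, ep$events, matrix(ind, ncol = 1))
    hr <- unname(fit$hr); ci_low <- unname(fit$ci_low)
    ci_high <- unname(fit$ci_high); cox_p <- unname(fit$p_values)
    degenerate <- degenerate || fit$degenerate
    lr <- logrank(ep$times[ind == 0L], ep$events[ind == 0L],
                  ep$times[ind == 1L], ep$events[ind == 1L])
    chi_sq <- lr$chi_square; lr_p <- lr$p_value
    degenerate <- degenerate || lr$degenerate
  }
  if (sum(ep$events) > 0L) {
    hc <- harrell_c(ind, ep$times, ep$events, n_boot = n_boot, seed = seed)
    c_index <- hc$c_index; c_lo <- hc$ci_low; c_hi <- hc$ci_high
  }
  out <- data.frame(
    model_id = model_id, label = label,
    hr = hr, ci_low = ci_low, ci_high = ci_high, cox_p = cox_p,
    chi_square = chi_sq, logrank_p = lr_p,
    c_index = c_index, c_ci_low = c_lo, c_ci_high = c_hi,
    n_positive = n_pos, n_negative = n_neg,
    events_positive = ev_pos, events_negative = ev_neg,
    degenerate = degenerate, stringsAsFactors = FALSE)
  class(out) <- c("model_evaluation", "data.frame")
  out
}

#' Evaluate a rule model on a cohort
#'
#' Applies the rule to every record and evaluates the resulting binary
#' indicator against the chosen endpoint: univariate Cox hazard ratio
#' with Wald interval and p-value, two-group log-rank chi-square, and
#' Harrell's concordance index using the indicator as the risk score,
#' with group sizes and event counts. When one group is empty or
#' event-free the evaluation is flagged degenerate and the statistics
#' that remain well-defined are still reported.
#'
#' @param cohort a `silva_cohort`.
#' @param model a [rule_model()].
#' @param endpoint `"rfs"` (default) or `"os"`.
#' @param n_boot bootstrap replicates for the concordance interval.
#' @param seed seed for the bootstrap.
#' @return One-row data frame of class `model_evaluation`.
#' @export
evaluate_model <- function(cohort, model, endpoint = "rfs", n_boot = 200L,
                           seed = NULL) {
  stopifnot(inherits(cohort, "silva_cohort"), nrow(cohort) > 0L)
  evaluate_indicator(cohort, apply_rule(model, cohort), model$model_id,
                     model_label(model), endpoint, n_boot, seed)
}

#' Evaluate the Sedlis criteria on a cohort
#'
#' @inheritParams evaluate_model
#' @return One-row `model_evaluation` with model id `"sedlis"`.
#' @export
evaluate_sedlis <- function(cohort, endpoint = "rfs", n_boot = 200L,
                            seed = NULL) {
  stopifnot(inherits(cohort, "silva_cohort"), nrow(cohort) > 0L)
  evaluate_indicator(cohort, sedlis_indicator(cohort), "sedlis",
                     "Sedlis criteria", endpoint, n_boot, seed)
}

#' Rank model evaluations
#'
#' Orders evaluations by descending concordance index, breaking ties by
#' descending log-rank chi-square and then by model id; degenerate
#' evaluations rank last (in the same key order among themselves).
#'
#' @param evaluations a data frame of stacked `model_evaluation` rows (or
#'   a list of them).
#' @return The rows in rank order, with a `rank` column prepended.
#' @export
rank_models <- function(evaluations) {
  if (is.list(evaluations) && !is.data.frame(evaluations)) {
    evaluations <- do.call(rbind, evaluations)
  }
  stopifnot(nrow(evaluations) >= 1L)
  key_c <- ifelse(is.na(evaluations$c_index), -Inf, evaluations$c_index)
  key_chi <- ifelse(is.na(evaluations$chi_square), -Inf,
                    evaluations$chi_square)
  ord <- order(evaluations$degenerate, -key_c, -key_chi,
               evaluations$model_id)
  out <- evaluations[ord, , drop = FALSE]
  rownames(out) <- NULL
  out <- cbind(rank = seq_len(nrow(out)), out)
  class(out) <- c("model_evaluation", "data.frame")
  out
}

#' Drill down the combinations of a k-of-m model
#'
#' Evaluates, for every size-k subset of the model's variables, the
#' all-of-subset rule (a patient is positive only when every factor in
#' the subset is present). An any-3-of-4 model therefore yields 4
#' combination evaluations and an all-m model yields exactly one.
#'
#' @inheritParams evaluate_model
#' @return Stacked `model_evaluation` rows, one per combination.
#' @export
drilldown_best <- function(cohort, model, endpoint = "rfs", n_boot = 200L,
                           seed = NULL) {
  stopifnot(inherits(model, "rule_model"))
  subsets <- utils::combn(model$variables, model$k, simplify = FALSE)
  rows <- lapply(seq_along(subsets), function(i) {
    sub <- rule_model(subsets[[i]], k = length(subsets[[i]]),
                      family = "combination")
    evaluate_model(cohort, sub, endpoint, n_boot,
                   seed = if (is.null(seed)) NULL else seed + i)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("model_evaluation", "data.frame")
  out
}

#' Run the full Silva-based model analysis
#'
#' End-to-end pipeline: exclude high-risk patients, build the candidate
#' cutoff variables, screen them univariately on recurrence-free survival
#' (forcing Silva B + C into the retained set), enumerate the
#' four-/three-/two-factor model families, evaluate every model and the
#' Sedlis criteria on the intermediate-risk cohort, rank by concordance
#' index (chi-square tiebreak), and drill down the combinations of the
#' top-ranked model. Deterministic given cohort and configuration.
#'
#' @param cohort a `silva_cohort` (full cohort, before high-risk
#'   exclusion).
#' @param config an [analysis_config()].
#' @return An object of class `silva_analysis`; see [write_report()] for
#'   file output.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(cohort, "silva_cohort"),
            inherits(config, "analysis_config"))
  n_total <- nrow(cohort)
  analysis_set <- if (config$evaluate_full_cohort) cohort else {
    filter_intermediate(cohort)
  }
  if (nrow(analysis_set) == 0L) {
    stop("intermediate-risk cohort is empty: every patient has a high-risk factor",
         call. = FALSE)
  }
  variables <- make_cutoff_variables(config$cutoffs)
  screen <- univariate_screen(analysis_set, variables,
                              endpoint = config$endpoint,
                              alpha = config$alpha,
                              force_include = config$force_include)
  multivariate <- NULL
  sel <- screen$name[screen$selected]
  if (length(sel) >= 2L) {
    multivariate <- tryCatch(
      multivariate_fit(analysis_set, sel, endpoint = config$endpoint),
      error = function(e) {
        warning("multivariate fit failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }
  families <- c("four_factor", "three_factor", "two_factor")
  models <- list()
  for (fam in families) {
    models <- c(models, enumerate_models(fam, config$models))
  }
  evals <- vector("list", length(models) + 1L)
  failures <- character(0)
  for (i in seq_along(models)) {
    evals[[i]] <- tryCatch({
      ev <- evaluate_model(analysis_set, models[[i]],
                           endpoint = config$endpoint,
                           n_boot = config$n_boot,
                           seed = stream_seed(config$seed, 100L + i))
      ev$family <- models[[i]]$family
      ev
    }, error = function(e) {
      failures <<- c(failures, paste0(models[[i]]$model_id, ": ",
                                      conditionMessage(e)))
      NULL
    })
  }
  evals[[length(models) + 1L]] <- tryCatch({
    ev <- evaluate_sedlis(analysis_set, endpoint = config$endpoint,
                          n_boot = config$n_boot,
                          seed = stream_seed(config$seed, 99L))
    ev$family <- "sedlis"
    ev
  }, error = function(e) {
    failures <<- c(failures, paste0("sedlis: ", conditionMessage(e)))
    NULL
  })
  evaluations <- do.call(rbind, evals[!vapply(evals, is.null, logical(1))])
  class(evaluations) <- c("model_evaluation", "data.frame")
  ranking <- rank_models(evaluations)
  # best rule model = top-ranked non-Sedlis evaluation
  rule_rows <- ranking[ranking$model_id != "sedlis", , drop = FALSE]
  best_id <- rule_rows$model_id[1L]
  best <- models[[which(vapply(models, function(m) m$model_id,
                               character(1)) == best_id)]]
  drilldown <- drilldown_best(analysis_set, best,
                              endpoint = config$endpoint,
                              n_boot = config$n_boot,
                              seed = stream_seed(config$seed, 7L))
  structure(list(
    config = config, n_total = n_total,
    n_high_risk = n_total - nrow(filter_intermediate(cohort)),
    n_intermediate = nrow(filter_intermediate(cohort)),
    n_analysis = nrow(analysis_set),
    screen = screen, multivariate = multivariate,
    models = models, evaluations = evaluations, ranking = ranking,
    best_model = best, drilldown = drilldown, failures = failures
  ), class = "silva_analysis")
}

#' @export
print.silva_analysis <- function(x, ...) {
  cat("Silva-based recurrence-model analysis\n")
  cat(sprintf("  cohort: %d patients, %d high-risk excluded, %d analyzed\n",
              x$n_total, x$n_high_risk, x$n_analysis))
  cat(sprintf("  screened variables retained: %d of %d\n",
              sum(x$screen$selected), nrow(x$screen)))
  cat(sprintf("  evaluations: %d (%d rule models + Sedlis)\n",
              nrow(x$evaluations), length(x$models)))
  if (length(x$failures) > 0L) {
    cat(sprintf("  failed evaluations: %d\n", length(x$failures)))
  }
  best <- x$ranking[1L, ]
  cat(sprintf("  top-ranked: %s\n    C = %.3f, chi-square = %.3f, HR = %.3f\n",
              best$label, best$c_index, best$chi_square, best$hr))
  invisible(x)
}

#' @export
summary.silva_analysis <- function(object, n_top = 10L, ...) {
  cat("Top-ranked evaluations:\n")
  cols <- c("rank", "family", "label", "hr", "cox_p", "chi_square",
            "c_index", "degenerate")
  print(utils::head(as.data.frame(object$ranking)[cols], n_top),
        row.names = FALSE)
  cat("\nBest-model combination drill-down:\n")
  print(as.data.frame(object$drilldown)[
    c("label", "hr", "cox_p", "chi_square", "c_index", "n_positive")],
    row.names = FALSE)
  invisible(object)
}

#' @export
plot.silva_analysis <- function(x, ...) {
  r <- x$ranking
  fam <- factor(r$family, levels = c("four_factor", "three_factor",
                                     "two_factor", "sedlis"))
  graphics::stripchart(r$c_index ~ fam, vertical = TRUE, method = "jitter",
                       pch = 19, ylab = "Harrell's C",
                       xlab = "Model family", ...)
  sed <- r$c_index[r$model_id == "sedlis"]
  if (length(sed) == 1L && !is.na(sed)) {
    graphics::abline(h = sed, lty = 2)
  }
  invisible(x)
}

#' @keywords internal
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write the analysis report to a directory
#'
#' Writes TSV tables (`screen.tsv`, one `evaluations_<family>.tsv` per
#' family plus the Sedlis row, `ranking.tsv`, `drilldown.tsv`) and a JSON
#' summary (`summary.json`) echoing the configuration seed. Output is
#' deterministic: identical analyses produce byte-identical files.
#'
#' @param analysis a `silva_analysis`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(analysis, dir) {
  stopifnot(inherits(analysis, "silva_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1)) &
      !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], fmt_num)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE, eol = "\n")
  }
  wtsv(analysis$screen, "screen.tsv")
  for (fam in unique(analysis$evaluations$family)) {
    rows <- analysis$evaluations[analysis$evaluations$family == fam, ,
                                 drop = FALSE]
    wtsv(rows, paste0("evaluations_", fam, ".tsv"))
  }
  wtsv(analysis$ranking, "ranking.tsv")
  wtsv(analysis$drilldown, "drilldown.tsv")
  summary <- list(
    seed = analysis$config$seed,
    endpoint = analysis$config$endpoint,
    alpha = analysis$config$alpha,
    n_boot = analysis$config$n_boot,
    n_total = analysis$n_total,
    n_high_risk = analysis$n_high_risk,
    n_intermediate = analysis$n_intermediate,
    n_evaluations = nrow(analysis$evaluations),
    n_models = length(analysis$models),
    best_model_id = analysis$best_model$model_id,
    best_model_label = model_label(analysis$best_model),
    failures = analysis$failures)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "summary.json"))
  invisible(dir)
}
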