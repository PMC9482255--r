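# Shared fixtures, built in code.

# A tiny hand-written cohort exercising every categorical level.
make_toy_cohort <- function() {
  as_cohort(data.frame(
    patient_id = c("P1", "P2", "P3", "P4", "P5"),
    age = c(38, 45, 52, 61, 47),
    figo_stage = c(1, 1, 2, 1, 2),
    silva = c("A", "B", "C", "C", "B"),
    tumor_size_cm = c(1.2, 2.5, 3.0, 4.5, 3.5),
    dsi_fraction = c(0, 0.4, 0.8, 1.0, 2 / 3),
    lvsi = c("none", "mild", "substantial", "substantial", "none"),
    ln_site = c("none", "none", "pelvic", "none", "none"),
    margin_positive = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    parametrial_positive = FALSE,
    pni = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    adjuvant = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    rfs_months = c(120, 96, 14, 10, 60),
    rfs_event = c(FALSE, FALSE, TRUE, TRUE, FALSE),
    os_months = c(120, 96, 30, 18, 60),
    os_event = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ), label = "toy")
}

# Brute-force concordance by O(n^2) pair enumeration: a pair is usable
# when times differ and the smaller time carries an event.
oracle_c_index <- function(scores, times, events) {
  conc <- tied <- comp <- 0
  n <- length(times)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (times[i] < times[j] && events[i] == 1) {
      comp <- comp + 1
      if (scores[i] > scores[j]) conc <- conc + 1
      if (scores[i] == scores[j]) tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / comp
}

# Hand risk-table log-rank: O, E and hypergeometric V accumulated per
# distinct event time, independent of the package implementation.
oracle_logrank_chisq <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- c(e1, e2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  O <- E <- V <- 0
  for (t in sort(unique(times[events == 1]))) {
    n <- sum(times >= t)
    n2 <- sum(times >= t & grp == 2)
    d <- sum(times == t & events == 1)
    d2 <- sum(times == t & events == 1 & grp == 2)
    O <- O + d2
    E <- E + d * n2 / n
    if (n > 1) V <- V + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Exact Cox partial log-likelihood for a single covariate, no ties,
# evaluated directly from its definition (for grid-search oracles).
oracle_cox_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Literal clause-by-clause Sedlis evaluation, written independently of
# sedlis_positive().
oracle_sedlis <- function(lvsi, third, size) {
  a <- lvsi && third == "deep"
  b <- lvsi && third == "middle" && size >= 2
  c <- lvsi && third == "superficial" && size >= 5
  d <- !lvsi && (third == "middle" || third == "deep") && size >= 4
  a || b || c || d
}
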