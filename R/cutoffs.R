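# Candidate-factor dichotomization: named binary predicates over records.

#' Cut-point configuration for candidate variables
#'
#' Defaults reproduce the full candidate grid used at the screening stage:
#' age at 40/50/60 years, Silva pattern as "B + C" or "C", tumor size at
#' 2 to 5 cm in 0.5 cm steps, depth of stromal invasion strictly above
#' 1/3 or 2/3 of stromal thickness, and graded LVSI either present at all
#' (">=mild") or substantial only (">mild").
#'
#' @param age numeric vector of age cut points (years).
#' @param silva character subset of `c("BC", "C")`.
#' @param size numeric vector of size cut points (cm), inclusive thresholds.
#' @param dsi character subset of `c("1/3", "2/3")`, strict thresholds.
#' @param lvsi character subset of `c("ge_mild", "gt_mild")`.
#' @return A list of class `cutoff_config`.
#' @export
cutoff_config <- function(age = c(40, 50, 60),
                          silva = c("BC", "C"),
                          size = seq(2, 5, by = 0.5),
                          dsi = c("1/3", "2/3"),
                          lvsi = c("ge_mild", "gt_mild")) {
  stopifnot(is.numeric(age), is.numeric(size),
            all(silva %in% c("BC", "C")),
            all(dsi %in% c("1/3", "2/3")),
            all(lvsi %in% c("ge_mild", "gt_mild")))
  structure(list(age = age, silva = silva, size = size, dsi = dsi,
                 lvsi = lvsi), class = "cutoff_config")
}

#' Build the candidate cutoff variables
#'
#' Each variable is a deterministic binary predicate over a patient record,
#' canonically named (e.g. `size_ge_3`, `dsi_gt_2_3`, `lvsi_gt_mild`).
#' Under the default configuration this yields 16 variables:
#' 3 age + 2 Silva + 7 size + 2 DSI + 2 LVSI.
#'
#' @param config a [cutoff_config()].
#' @return Data frame with columns `name`, `factor`, `threshold`,
#'   `direction` and `label`, one row per variable.
#' @export
make_cutoff_variables <- function(config = cutoff_config()) {
  stopifnot(inherits(config, "cutoff_config"))
  rows <- list()
  add <- function(name, factor, threshold, direction, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, factor = factor, threshold = threshold,
      direction = direction, label = label, stringsAsFactors = FALSE)
  }
  for (a in config$age) {
    add(paste0("age_ge_", a), "age", as.character(a), "at-or-above",
        paste0("Age >=", a))
  }
  for (s in config$silva) {
    if (s == "BC") add("silva_BC", "silva", "BC", "at-or-above", "Silva B + C")
    if (s == "C")  add("silva_C", "silva", "C", "at-or-above", "Silva C")
  }
  for (t in config$size) {
    add(paste0("size_ge_", t), "size", as.character(t), "at-or-above",
        paste0(">=", t, " cm"))
  }
  for (d in config$dsi) {
    nm <- if (d == "1/3") "dsi_gt_1_3" else "dsi_gt_2_3"
    add(nm, "dsi", d, "strictly-above", paste0("DSI >", d))
  }
  for (l in config$lvsi) {
    if (l == "ge_mild") {
      add("lvsi_ge_mild", "lvsi", "mild", "at-or-above", ">=mild LVSI")
    } else {
      add("lvsi_gt_mild", "lvsi", "mild", "strictly-above", ">mild LVSI")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(), factor = character(),
                      threshold = character(), direction = character(),
                      label = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$name)) {
    stop("duplicate cutoff variable name(s): ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @keywords internal
lookup_variable <- function(name, variables = NULL) {
  if (is.null(variables)) variables <- make_cutoff_variables()
  i <- match(name, variables$name)
  if (is.na(i)) stop("unknown cutoff variable: ", name, call. = FALSE)
  variables[i, , drop = FALSE]
}

#' Evaluate a cutoff variable on a cohort
#'
#' Predicate semantics: `silva_C` is true iff the pattern is C; `silva_BC`
#' iff B or C; size thresholds are inclusive (a 3.0 cm tumor satisfies
#' ">=3 cm"); DSI thresholds are strict on the continuous fraction (exactly
#' 2/3 does not satisfy "DSI > 2/3"); `lvsi_ge_mild` is any LVSI and
#' `lvsi_gt_mild` is substantial LVSI only; age thresholds are inclusive.
#'
#' @param cohort a `silva_cohort` (or single-record data frame).
#' @param variable a variable name, or one row of [make_cutoff_variables()].
#' @param variables variable table used to resolve a name (defaults to the
#'   full default candidate set).
#' @return Logical vector, one element per patient.
#' @export
factor_value <- function(cohort, variable, variables = NULL) {
  if (is.character(variable)) {
    variable <- lookup_variable(variable, variables)
  }
  stopifnot(is.data.frame(variable), nrow(variable) == 1L)
  switch(variable$factor,
    age = cohort$age >= as.numeric(variable$threshold),
    silva = if (variable$threshold == "BC") {
      cohort$silva %in% c("B", "C")
    } else {
      cohort$silva == "C"
    },
    size = cohort$tumor_size_cm >= as.numeric(variable$threshold),
    dsi = cohort$dsi_fraction > if (variable$threshold == "1/3") 1 / 3 else 2 / 3,
    lvsi = if (variable$direction == "at-or-above") {
      cohort$lvsi != "none"
    } else {
      cohort$lvsi == "substantial"
    },
    stop("unknown factor: ", variable$factor, call. = FALSE)
  )
}
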