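# Executable decision rules: Sedlis criteria and the Silva-based k-of-m
# model families with exhaustive enumeration.

#' Sedlis criteria
#'
#' The classic intermediate-risk trigger for adjuvant therapy, evaluated
#' from any-grade LVSI, depth-of-invasion thirds and tumor size. A patient
#' is positive when any clause holds:
#' (a) LVSI with deep-third invasion;
#' (b) LVSI with middle-third invasion and size >= 2 cm;
#' (c) LVSI with superficial-third invasion and size >= 5 cm;
#' (d) no LVSI, middle- or deep-third invasion and size >= 4 cm.
#' No clause fires when there is no stromal invasion. The criteria predate
#' graded LVSI, so "positive LVSI" here means any LVSI (mild or
#' substantial); size comparisons are inclusive as printed.
#'
#' @param lvsi_present logical vector: any lymphovascular space invasion.
#' @param dsi_third character/factor vector in
#'   none/superficial/middle/deep (see [dsi_third()]).
#' @param tumor_size numeric vector, cm.
#' @return Logical vector.
#' @examples
#' sedlis_positive(TRUE, "deep", 1)     # clause (a), no size condition
#' sedlis_positive(FALSE, "middle", 4)  # clause (d)
#' @export
sedlis_positive <- function(lvsi_present, dsi_third, tumor_size) {
  lvsi_present <- as.logical(lvsi_present)
  third <- as.character(dsi_third)
  stopifnot(all(third %in% DSI_THIRD_LEVELS), all(tumor_size >= 0))
  (lvsi_present & third == "deep") |
    (lvsi_present & third == "middle" & tumor_size >= 2) |
    (lvsi_present & third == "superficial" & tumor_size >= 5) |
    (!lvsi_present & third %in% c("middle", "deep") & tumor_size >= 4)
}

#' Evaluate the Sedlis criteria on a cohort
#'
#' @param cohort a `silva_cohort`.
#' @return Logical vector, one element per patient.
#' @export
sedlis_indicator <- function(cohort) {
  sedlis_positive(cohort$lvsi != "none", dsi_third(cohort$dsi_fraction),
                  cohort$tumor_size_cm)
}

#' Model-family configuration
#'
#' Variant sets and k ranges for the exhaustive enumeration. The defaults
#' are the six retained screening variables — Silva in \{B + C, C\}, size
#' in \{>=3 cm, >=3.5 cm\}, DSI fixed at >2/3 and LVSI fixed at >mild —
#' with k in \{2,3,4\} for four-factor models, \{1,2,3\} for three-factor
#' and \{1,2\} for two-factor models, which yield the 12/30/16 model
#' counts of the reference analysis.
#'
#' @param silva_variants,size_variants,dsi_variants,lvsi_variants cutoff
#'   variable names per factor slot.
#' @param k_ranges named list of integer k ranges per family.
#' @return A list of class `model_config`.
#' @export
model_config <- function(silva_variants = c("silva_BC", "silva_C"),
                         size_variants = c("size_ge_3", "size_ge_3.5"),
                         dsi_variants = "dsi_gt_2_3",
                         lvsi_variants = "lvsi_gt_mild",
                         k_ranges = list(four_factor = 2:4,
                                         three_factor = 1:3,
                                         two_factor = 1:2)) {
  stopifnot(is.list(k_ranges),
            all(c("four_factor", "three_factor", "two_factor") %in%
                  names(k_ranges)))
  structure(list(silva_variants = silva_variants,
                 size_variants = size_variants,
                 dsi_variants = dsi_variants,
                 lvsi_variants = lvsi_variants,
                 k_ranges = k_ranges), class = "model_config")
}

FAMILY_CODES <- c(four_factor = "4f", three_factor = "3f", two_factor = "2f")

#' Construct a k-of-m rule model
#'
#' A rule model declares a patient positive when at least `k` of its
#' member cutoff variables are present. Variables must be distinct and at
#' most one variant per underlying factor is allowed (a model never
#' contains both "Silva B + C" and "Silva C").
#'
#' @param variables character vector of cutoff variable names, in
#'   canonical slot order (silva, size, dsi, lvsi).
#' @param k required count of positive factors, `1 <= k <= length(variables)`.
#' @param family family tag (`four_factor`, `three_factor`, `two_factor`,
#'   `sedlis`, or `combination` for drill-down subsets).
#' @return An object of class `rule_model`.
#' @export
rule_model <- function(variables, k, family = "custom") {
  stopifnot(is.character(variables), length(variables) >= 1L,
            k >= 1L, k <= length(variables))
  if (anyDuplicated(variables)) {
    stop("rule model variables must be distinct", call. = FALSE)
  }
  vtab <- make_cutoff_variables()
  factors <- vtab$factor[match(variables, vtab$name)]
  if (anyNA(factors)) {
    stop("unknown cutoff variable: ",
         paste(variables[is.na(factors)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(factors)) {
    stop("at most one variant per factor in a model", call. = FALSE)
  }
  id <- paste0(if (family %in% names(FAMILY_CODES)) FAMILY_CODES[[family]]
               else family,
               ".k", k, ".", paste(variables, collapse = "+"))
  structure(list(model_id = id, family = family,
                 variables = variables, k = as.integer(k)),
            class = "rule_model")
}

#' @export
print.rule_model <- function(x, ...) {
  cat(model_label(x), "\n  id:", x$model_id, "\n")
  invisible(x)
}

#' Enumerate a Silva-based model family
#'
#' Four-factor models fill all four factor slots (one variant each):
#' 2 Silva x 2 size variants x k in \{2,3,4\} gives 12 models.
#' Three-factor models replace exactly one of \{size, DSI, LVSI\} with
#' Silva: the (2 + 4 + 4) variable sets times k in \{1,2,3\} give 30.
#' Two-factor models pair Silva with exactly one other factor: the
#' (4 + 2 + 2) sets times k in \{1,2\} give 16. Ordering is canonical and
#' stable: k ascending, then Silva variant, then the partner variants.
#'
#' @param family `"four_factor"`, `"three_factor"` or `"two_factor"`.
#' @param config a [model_config()].
#' @return List of [rule_model()] objects.
#' @export
enumerate_models <- function(family = c("four_factor", "three_factor",
                                        "two_factor"),
                             config = model_config()) {
  family <- match.arg(family)
  stopifnot(inherits(config, "model_config"))
  ks <- as.integer(config$k_ranges[[family]])
  out <- list()
  add <- function(vars, k) {
    out[[length(out) + 1L]] <<- rule_model(vars, k, family = family)
  }
  for (k in ks) {
    if (family == "four_factor") {
      if (k > 4L) next
      # expand.grid varies the first factor fastest: silva, then size
      grid <- expand.grid(silva = config$silva_variants,
                          size = config$size_variants,
                          dsi = config$dsi_variants,
                          lvsi = config$lvsi_variants,
                          stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        add(unlist(grid[r, c("silva", "size", "dsi", "lvsi")],
                   use.names = FALSE), k)
      }
    } else if (family == "three_factor") {
      if (k > 3L) next
      # Silva replaces size: {silva, dsi, lvsi}
      for (dv in config$dsi_variants) for (lv in config$lvsi_variants) {
        for (sv in config$silva_variants) add(c(sv, dv, lv), k)
      }
      # Silva replaces DSI: {silva, size, lvsi}
      for (zv in config$size_variants) for (lv in config$lvsi_variants) {
        for (sv in config$silva_variants) add(c(sv, zv, lv), k)
      }
      # Silva replaces LVSI: {silva, size, dsi}
      for (zv in config$size_variants) for (dv in config$dsi_variants) {
        for (sv in config$silva_variants) add(c(sv, zv, dv), k)
      }
    } else {
      if (k > 2L) next
      for (zv in config$size_variants) for (sv in config$silva_variants) {
        add(c(sv, zv), k)
      }
      for (dv in config$dsi_variants) for (sv in config$silva_variants) {
        add(c(sv, dv), k)
      }
      for (lv in config$lvsi_variants) for (sv in config$silva_variants) {
        add(c(sv, lv), k)
      }
    }
  }
  ids <- vapply(out, function(m) m$model_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate model ids in enumeration", call. = FALSE)
  }
  out
}

#' Apply a rule model to a cohort
#'
#' @param model a [rule_model()].
#' @param cohort a `silva_cohort`.
#' @return Logical vector: TRUE where at least `k` of the model's
#'   variables are present.
#' @export
apply_rule <- function(model, cohort) {
  stopifnot(inherits(model, "rule_model"))
  counts <- Reduce(`+`, lapply(model$variables, function(v) {
    as.integer(factor_value(cohort, v))
  }))
  counts >= model$k
}

#' Human-readable model label
#'
#' Formats a model in the style "Any 3 of 4: Silva C, >=3 cm, DSI >2/3,
#' >mild LVSI" (or "All 4: ..." when k equals the variable count).
#' Labels are bijective with model ids; [parse_model_label()] inverts.
#'
#' @param model a [rule_model()].
#' @return Character scalar.
#' @export
model_label <- function(model) {
  stopifnot(inherits(model, "rule_model"))
  vtab <- make_cutoff_variables()
  labs <- vtab$label[match(model$variables, vtab$name)]
  m <- length(model$variables)
  prefix <- if (model$k == m) paste0("All ", m) else {
    paste0("Any ", model$k, " of ", m)
  }
  paste0(prefix, ": ", paste(labs, collapse = ", "))
}

#' Parse a model label back into a rule model
#'
#' @param label a label produced by [model_label()].
#' @param family family tag for the reconstructed model.
#' @return A [rule_model()].
#' @export
parse_model_label <- function(label, family = "custom") {
  parts <- strsplit(label, ": ", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("unparseable model label: ", label,
                                call. = FALSE)
  head_part <- parts[1]
  var_labels <- strsplit(parts[2], ", ", fixed = TRUE)[[1]]
  vtab <- make_cutoff_variables()
  vars <- vtab$name[match(var_labels, vtab$label)]
  if (anyNA(vars)) stop("unknown variable label in: ", label, call. = FALSE)
  k <- if (grepl("^All ", head_part)) {
    length(vars)
  } else {
    as.integer(sub("^Any ([0-9]+) of [0-9]+$", "\\1", head_part))
  }
  rule_model(vars, k, family = family)
}

#' Tabulate enumerated models
#'
#' @param models list of [rule_model()] objects.
#' @return Data frame with `model_id`, `family`, `variables`
#'   (plus-separated), `k` and `label`.
#' @export
models_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(model_id = m$model_id, family = m$family,
               variables = paste(m$variables, collapse = "+"),
               k = m$k, label = model_label(m), stringsAsFactors = FALSE)
  }))
}
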