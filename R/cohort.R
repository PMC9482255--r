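# Cohort data model: validation, CSV I/O, dichotomization, high-risk exclusion.

#' @keywords internal
SILVA_LEVELS <- c("A", "B", "C")

#' @keywords internal
LVSI_LEVELS <- c("none", "mild", "substantial")

#' @keywords internal
LN_LEVELS <- c("none", "pelvic", "common_iliac", "para_aortic")

#' @keywords internal
DSI_THIRD_LEVELS <- c("none", "superficial", "middle", "deep")

# Canonical CSV header, in order.
COHORT_COLUMNS <- c(
  "patient_id", "age", "figo_stage", "silva", "tumor_size_cm",
  "dsi_fraction", "lvsi", "ln_site", "margin_positive",
  "parametrial_positive", "pni", "adjuvant",
  "rfs_months", "rfs_event", "os_months", "os_event"
)

COHORT_NUMERIC <- c("age", "tumor_size_cm", "dsi_fraction",
                    "rfs_months", "os_months")
COHORT_LOGICAL <- c("margin_positive", "parametrial_positive", "pni",
                    "adjuvant", "rfs_event", "os_event")

#' Construct a validated cohort
#'
#' A cohort is a data frame with one row per patient and the canonical
#' column set (see [read_cohort()] for the CSV encoding). `as_cohort()`
#' validates field domains and the cross-field invariants: `dsi_fraction`
#' in \[0, 1\], `rfs_months <= os_months`, strictly positive follow-up
#' times, unique patient ids, and Silva pattern A implying no
#' lymphovascular space invasion (pattern A is by definition
#' non-destructive invasion without LVSI).
#'
#' @param x data frame with the canonical columns.
#' @param label free-text provenance label stored as an attribute.
#' @return A `silva_cohort` data frame.
#' @export
as_cohort <- function(x, label = "") {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(COHORT_COLUMNS, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing cohort column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[COHORT_COLUMNS]
  x$patient_id <- as.character(x$patient_id)
  x$figo_stage <- as.integer(x$figo_stage)
  for (col in COHORT_NUMERIC) x[[col]] <- as.numeric(x[[col]])
  for (col in COHORT_LOGICAL) x[[col]] <- as.logical(x[[col]])
  x$silva <- toupper(as.character(x$silva))
  x$lvsi <- tolower(as.character(x$lvsi))
  x$ln_site <- tolower(as.character(x$ln_site))
  validate_cohort(x)
  rownames(x) <- NULL
  structure(x, label = label, class = c("silva_cohort", "data.frame"))
}

#' @keywords internal
validate_cohort <- function(x) {
  fail_rows <- function(bad, msg) {
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad)[1L]
      stop(sprintf("row %d (patient_id %s): %s", i,
                   if (is.na(x$patient_id[i])) "<NA>" else x$patient_id[i],
                   msg), call. = FALSE)
    }
  }
  if (nrow(x) == 0L) return(invisible(TRUE))
  if (anyNA(x$patient_id) || any(!nzchar(x$patient_id))) {
    fail_rows(is.na(x$patient_id) | !nzchar(x$patient_id),
              "missing patient_id")
  }
  dup <- duplicated(x$patient_id)
  if (any(dup)) {
    stop("duplicate patient_id: ",
         paste(unique(x$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  for (col in c(COHORT_NUMERIC, "figo_stage")) {
    fail_rows(is.na(x[[col]]), paste0("unparseable or missing ", col))
  }
  for (col in COHORT_LOGICAL) {
    fail_rows(is.na(x[[col]]), paste0("unparseable or missing ", col))
  }
  fail_rows(!(x$silva %in% SILVA_LEVELS),
            "silva must be one of A, B, C")
  fail_rows(!(x$lvsi %in% LVSI_LEVELS),
            "lvsi must be one of none, mild, substantial")
  fail_rows(!(x$ln_site %in% LN_LEVELS),
            "ln_site must be one of none, pelvic, common_iliac, para_aortic")
  fail_rows(!(x$figo_stage %in% c(1L, 2L)), "figo_stage must be 1 or 2")
  fail_rows(x$age <= 0, "age must be positive")
  fail_rows(x$tumor_size_cm < 0, "tumor_size_cm must be non-negative")
  fail_rows(x$dsi_fraction < 0 | x$dsi_fraction > 1,
            "dsi_fraction must lie in [0, 1]")
  fail_rows(x$rfs_months <= 0 | x$os_months <= 0,
            "follow-up times must be strictly positive")
  fail_rows(x$rfs_months > x$os_months,
            "rfs_months must not exceed os_months")
  fail_rows(x$silva == "A" & x$lvsi != "none",
            "Silva pattern A implies lvsi = none")
  invisible(TRUE)
}

#' @export
print.silva_cohort <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("Cohort of %d patient(s)%s\n", nrow(x),
              if (nzchar(lab)) paste0(" [", lab, "]") else ""))
  if (nrow(x) > 0L) {
    cat(sprintf("  Silva A/B/C: %d/%d/%d; recurrences: %d; deaths: %d\n",
                sum(x$silva == "A"), sum(x$silva == "B"),
                sum(x$silva == "C"), sum(x$rfs_event), sum(x$os_event)))
    print.data.frame(utils::head(as.data.frame(x), 6L))
    if (nrow(x) > 6L) cat(sprintf("  ... %d more row(s)\n", nrow(x) - 6L))
  }
  invisible(x)
}

#' Read a patient cohort from CSV
#'
#' Reads a cohort CSV with the canonical header
#' `patient_id, age, figo_stage, silva, tumor_size_cm, dsi_fraction, lvsi,
#' ln_site, margin_positive, parametrial_positive, pni, adjuvant,
#' rfs_months, rfs_event, os_months, os_event`. Categorical codes are
#' decoded case-insensitively (`silva` in A/B/C, `lvsi` in
#' none/mild/substantial, `ln_site` in none/pelvic/common_iliac/para_aortic)
#' and booleans accept `0/1` or `true/false`. Rows failing validation are
#' reported with their 1-based row number and patient id; records missing
#' any modeled field are rejected, not imputed.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names to the column names used in the file, for cohorts exported with
#'   different headers.
#' @param label provenance label attached to the cohort.
#' @return A validated `silva_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, schema = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    if (is.null(names(schema))) {
      stop("schema must be a named character vector (canonical = file name)",
           call. = FALSE)
    }
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        stop("schema error: column '", src, "' (for ", canonical,
             ") not found in file", call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[COHORT_COLUMNS]
  for (col in COHORT_LOGICAL) raw[[col]] <- parse_boolean(raw[[col]], col)
  for (col in COHORT_NUMERIC) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]])
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("row %d (patient_id %s): unparseable value '%s' in %s",
                   i, raw$patient_id[i], raw[[col]][i], col), call. = FALSE)
    }
    raw[[col]] <- v
  }
  as_cohort(raw, label = label)
}

#' @keywords internal
parse_boolean <- function(v, col) {
  s <- tolower(trimws(v))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes")] <- TRUE
  out[s %in% c("0", "false", "f", "no")] <- FALSE
  bad <- is.na(out) & !is.na(v) & nzchar(s)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("row %d: unparseable boolean '%s' in %s", i, v[i], col),
         call. = FALSE)
  }
  out
}

#' Write a cohort to CSV
#'
#' Writes the canonical header and one row per patient; booleans are
#' encoded as 0/1 so that [read_cohort()] is an exact inverse. Writing,
#' re-reading and writing again produces a byte-identical file.
#'
#' @param cohort a `silva_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "silva_cohort"))
  out <- as.data.frame(cohort)
  for (col in COHORT_LOGICAL) out[[col]] <- as.integer(out[[col]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Depth-of-stromal-invasion thirds
#'
#' Maps the continuous invasion fraction to the thirds used by the Sedlis
#' criteria. Intervals are left-open/right-closed: 0 maps to `none`,
#' (0, 1/3\] to `superficial`, (1/3, 2/3\] to `middle`, (2/3, 1\] to
#' `deep`; the exact boundary 1/3 is superficial and 2/3 is middle,
#' consistent with the strict "DSI > 2/3" model variable.
#'
#' @param dsi_fraction numeric vector in \[0, 1\], or a `silva_cohort`
#'   (its `dsi_fraction` column is used).
#' @return Ordered factor with levels none < superficial < middle < deep.
#' @export
dsi_third <- function(dsi_fraction) {
  if (inherits(dsi_fraction, "silva_cohort")) {
    dsi_fraction <- dsi_fraction$dsi_fraction
  }
  stopifnot(is.numeric(dsi_fraction),
            all(dsi_fraction >= 0 & dsi_fraction <= 1))
  idx <- findInterval(dsi_fraction, c(0, 1 / 3, 2 / 3), left.open = TRUE) + 1L
  idx[dsi_fraction == 0] <- 1L
  factor(DSI_THIRD_LEVELS[idx], levels = DSI_THIRD_LEVELS, ordered = TRUE)
}

#' High-risk status
#'
#' A patient is high risk when any of the three high-risk factors is
#' present: lymph-node metastasis (any site), positive surgical margin,
#' or parametrial involvement. Lymphovascular space invasion, depth of
#' invasion and tumor size are intermediate-risk factors and do not enter
#' this definition.
#'
#' @param cohort a `silva_cohort` (or data frame with the relevant columns).
#' @return Logical vector, one element per patient.
#' @export
is_high_risk <- function(cohort) {
  cohort$ln_site != "none" | cohort$margin_positive |
    cohort$parametrial_positive
}

#' Restrict a cohort to intermediate-risk patients
#'
#' Drops every patient with at least one high-risk factor (see
#' [is_high_risk()]), preserving the original row order. The result is the
#' analysis set on which the rule models are screened and evaluated.
#'
#' @param cohort a `silva_cohort`.
#' @return The intermediate-risk sub-cohort (possibly empty).
#' @export
filter_intermediate <- function(cohort) {
  stopifnot(inherits(cohort, "silva_cohort"))
  keep <- !is_high_risk(cohort)
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  as_cohort(out, label = paste0(attr(cohort, "label"), " [intermediate-risk]"))
}
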