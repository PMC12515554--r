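.encounter_cols <- c(
  "encounter_id", "patient_id", "bun_trend_pct", "urine_specific_gravity",
  "fluid_balance_ml_kg_day", "weight_change_pct", "urine_output_ml_kg_h",
  "on_diuretics_or_renal_failure", "fontanelle", "eyes",
  "liver_cm_below_costal_margin", "skin", "cxr_grade"
)

#' Read an encounter CSV
#'
#' One row per encounter, columns named as in the scoring schema (see
#' [compute_fast()]); empty cells mark missing values. Numeric columns are
#' checked to parse; the diuretics flag accepts logical or 0/1.
#'
#' @param path Path to the CSV file.
#' @return Data frame ready for [compute_fast()].
#' @export
read_encounters <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!nrow(d)) stop(sprintf("%s: no encounter rows", path), call. = FALSE)
  if (!"encounter_id" %in% names(d)) {
    stop(sprintf("%s: missing required column 'encounter_id'", path), call. = FALSE)
  }
  extra <- setdiff(names(d), .encounter_cols)
  num_cols <- c("bun_trend_pct", "urine_specific_gravity",
                "fluid_balance_ml_kg_day", "weight_change_pct",
                "urine_output_ml_kg_h", "liver_cm_below_costal_margin")
  for (nm in intersect(num_cols, names(d))) {
    if (!is.numeric(d[[nm]])) {
      parsed <- suppressWarnings(as.numeric(d[[nm]]))
      bad <- which(!is.na(d[[nm]]) & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("%s: column '%s' is not numeric (first bad row: %d)",
                     path, nm, bad[1]), call. = FALSE)
      }
      d[[nm]] <- parsed  # e.g. an entirely-empty column read as logical
    }
  }
  if ("on_diuretics_or_renal_failure" %in% names(d)) {
    d$on_diuretics_or_renal_failure <-
      as.logical(d$on_diuretics_or_renal_failure) %in% TRUE
  }
  if (length(extra)) {
    message("ignoring free-context column(s): ", paste(extra, collapse = ", "))
  }
  d
}

#' Read a labeled-score CSV
#'
#' Expects `encounter_id` plus either a `tfc_high` (0/1 or logical) column,
#' or a `tfc_value` column that is thresholded with [label_tfc()]. Scores
#' come from a `score` (or `total`) column.
#'
#' @param path Path to the CSV file.
#' @param tfc_threshold Threshold applied to `tfc_value` when no `tfc_high`
#'   column is present.
#' @return Data frame with `encounter_id`, `score`, `tfc_high`.
#' @export
read_labeled_scores <- function(path, tfc_threshold = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d)) stop(sprintf("%s: no rows", path), call. = FALSE)
  if (!"score" %in% names(d) && "total" %in% names(d)) d$score <- d$total
  if (!all(c("encounter_id", "score") %in% names(d))) {
    stop(sprintf("%s: need columns encounter_id and score (or total)", path),
         call. = FALSE)
  }
  if (!"tfc_high" %in% names(d)) {
    if (!"tfc_value" %in% names(d) || is.null(tfc_threshold)) {
      stop(sprintf("%s: need a tfc_high column, or tfc_value plus a threshold", path),
           call. = FALSE)
    }
    d$tfc_high <- label_tfc(d$tfc_value, tfc_threshold)
  }
  d$tfc_high <- as.logical(d$tfc_high) | (is.numeric(d$tfc_high) & d$tfc_high != 0)
  d[c("encounter_id", "score", "tfc_high")]
}

#' Dichotomize a TFC value into the high-TFC label
#'
#' The reference monitor grades thoracic fluid content on an ordinal scale
#' without a universally agreed numeric cutoff for "high"; the binary label
#' is therefore an input with a configurable threshold.
#'
#' @param tfc_value Numeric TFC readings.
#' @param threshold Numeric threshold; `tfc_value >= threshold` is high.
#' @return Logical vector.
#' @export
label_tfc <- function(tfc_value, threshold) tfc_value >= threshold

#' Write a cut-point table in the published layout
#'
#' Percentages rendered to two decimals, cuts as `>=c`, plus the exact
#' binomial CI bounds.
#'
#' @param table An [cutpoint_table()] result.
#' @param path Output CSV path.
#' @export
write_roc_table <- function(table, path) {
  out <- data.frame(
    cut_point = sprintf(">=%d", table$cut),
    sensitivity = sprintf("%.2f%%", 100 * table$sensitivity),
    specificity = sprintf("%.2f%%", 100 * table$specificity),
    correctly_classified = sprintf("%.2f%%", 100 * table$correctly_classified),
    sens_ci95 = sprintf("%.2f%%-%.2f%%", 100 * table$sens_lo, 100 * table$sens_hi),
    spec_ci95 = sprintf("%.2f%%-%.2f%%", 100 * table$spec_lo, 100 * table$spec_hi)
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full scoring-and-validation pipeline
#'
#' Binds the modules into the study's workflow: score the encounters (or
#' take pre-computed scores), tabulate cut points against the TFC label,
#' select the operating cut, cross-validate the dichotomized AUC, and — when
#' outcomes are supplied — compare them across the selected cut. All
#' artifacts are written under `out_dir` and regenerate byte-identically
#' from the same inputs and seed.
#'
#' @param encounters_csv Path to a raw-encounter CSV (scored via
#'   [compute_fast()]); alternatively `scores_csv` for pre-computed totals.
#' @param scores_csv Path to a labeled-score CSV (see
#'   [read_labeled_scores()]). Exactly one of `encounters_csv`/`scores_csv`
#'   when scoring, but a labels source is always required: if
#'   `encounters_csv` is given, `scores_csv` may still carry the labels via
#'   `tfc_csv`.
#' @param tfc_csv Path to a CSV with `encounter_id` and `tfc_high` (or
#'   `tfc_value`), required with `encounters_csv`.
#' @param outcomes_csv Optional path to an outcomes CSV (`encounter_id`,
#'   `ventilator_days`, `picu_days`, `hospital_days`).
#' @param out_dir Output directory (created if needed).
#' @param cuts Integer cuts to tabulate.
#' @param policy Cut-point selection policy (see [select_cutpoint()]).
#' @param n_folds,n_repeats Cross-validation settings.
#' @param seed Integer seed for the cross-validation.
#' @param tfc_threshold Optional threshold for a `tfc_value` column.
#' @return Invisibly, a list with the scored table, `roc_table`, selected
#'   cut row, `cv_result`, and outcome comparison (or `NULL`).
#' @export
run_pipeline <- function(encounters_csv = NULL, scores_csv = NULL,
                         tfc_csv = NULL, outcomes_csv = NULL,
                         out_dir = ".", cuts = 0:8,
                         policy = "balanced", n_folds = 10, n_repeats = 200,
                         seed = 1, tfc_threshold = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(encounters_csv)) {
    obs <- read_encounters(encounters_csv)
    res <- compute_fast(obs)
    write.csv(res, file.path(out_dir, "fast_scores.csv"), row.names = FALSE)
    if (is.null(tfc_csv)) stop("`tfc_csv` is required with `encounters_csv`",
                               call. = FALSE)
    lab <- read.csv(tfc_csv, stringsAsFactors = FALSE)
    if (!"tfc_high" %in% names(lab)) {
      if (!"tfc_value" %in% names(lab) || is.null(tfc_threshold)) {
        stop(sprintf("%s: need tfc_high, or tfc_value plus tfc_threshold", tfc_csv),
             call. = FALSE)
      }
      lab$tfc_high <- label_tfc(lab$tfc_value, tfc_threshold)
    }
    d <- merge(data.frame(encounter_id = res$encounter_id, score = res$total,
                          valid = res$valid),
               lab[c("encounter_id", "tfc_high")], by = "encounter_id")
    n_invalid <- sum(!d$valid)
    if (n_invalid) {
      message(sprintf("excluding %d encounter(s) with > 2 missing variables",
                      n_invalid))
    }
    d <- d[d$valid, c("encounter_id", "score", "tfc_high")]
  } else if (!is.null(scores_csv)) {
    res <- NULL
    d <- read_labeled_scores(scores_csv, tfc_threshold)
  } else {
    stop("provide `encounters_csv` or `scores_csv`", call. = FALSE)
  }

  tab <- cutpoint_table(d, cuts = cuts)
  write_roc_table(tab, file.path(out_dir, "roc_table.csv"))
  poly <- data.frame(fpr = c(1, 1 - tab$specificity, 0),
                     tpr = c(1, tab$sensitivity, 0))
  write.csv(poly, file.path(out_dir, "roc_polygon.csv"), row.names = FALSE)

  sel <- select_cutpoint(tab, policy)
  cv <- cv_auc(d, n_folds = n_folds, cut = sel$cut, seed = seed,
               n_repeats = n_repeats)
  jsonlite::write_json(
    list(cut = cv$cut, mean_auc = cv$mean_auc, ci95 = cv$ci95,
         n_folds = cv$n_folds, n_repeats = cv$n_repeats, seed = cv$seed),
    file.path(out_dir, "cv_result.json"), auto_unbox = TRUE, digits = NA)

  cmp <- NULL
  if (!is.null(outcomes_csv)) {
    outc <- read.csv(outcomes_csv, stringsAsFactors = FALSE)
    cmp <- compare_outcomes(d, outc, sel$cut)
    write.csv(as.data.frame(cmp), file.path(out_dir, "outcome_comparison.csv"),
              row.names = FALSE)
  }
  invisible(list(scores = res, roc_table = tab, selected = sel,
                 cv_result = cv, outcome_comparison = cmp))
}
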