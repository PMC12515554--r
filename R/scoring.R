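#' The ten FAST variables
#'
#' Canonical names, in rubric order, of the ten variables that make up the
#' Fluid Assessment Scoring Tool. Each contributes a 0--3 subscore; the total
#' therefore ranges 0--30 when every variable is measurable.
#'
#' @format Character vector of length 10.
#' @export
fast_variables <- c(
  "bun_trend", "urine_sg", "fluid_balance", "weight_change", "urine_output",
  "fontanelle", "eyes", "liver", "skin", "cxr"
)

# categorical level sets, in increasing-severity order (ordinal position is
# the subscore); "closed" fontanelle is unmeasurable, not a severity level
.fontanelle_levels <- c("flat", "full", "bulging", "bulging_tense")
.eyes_levels <- c("normal", "swollen", "puffy_conjunctival_edema",
                  "puffy_unable_to_open")
.skin_levels <- c("no_edema", "limbs_or_abdomen", "limbs_and_face", "anasarca")
.cxr_levels <- c("none", "mild", "moderate", "severe")

.check_finite <- function(x, what) {
  # NA marks a missing observation; NaN/Inf are malformed values
  bad <- is.nan(x) | (!is.na(x) & !is.finite(x))
  if (any(bad)) {
    stop(sprintf("%s: non-finite value(s) at position(s) %s", what,
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# generic half-open binning: subscore k iff lower[k] <= x, with the last bin
# closed per-variable by construction of the breakpoints
.bin3 <- function(x, b1, b2, b3, right = FALSE) {
  # right = FALSE: bins [b1,b2), [b2,b3], (b3, Inf) on the severity axis
  s <- integer(length(x))
  if (right) {
    s[x > b1] <- 1L; s[x > b2] <- 2L; s[x > b3] <- 3L
  } else {
    s[x >= b1] <- 1L
    s[x >= b2] <- 2L
    s[x > b3] <- 3L
  }
  s[is.na(x)] <- NA_integer_
  s
}

#' Score the BUN trend variable
#'
#' A falling blood urea nitrogen suggests dilution by accumulating fluid. The
#' input is the signed percent change versus the previous value (negative =
#' decrease). Decreases of less than 15% score 0; 15--25% score 1; 26--50%
#' score 2; more than 50% score 3. Rising BUN scores 0: the rubric measures
#' overload only.
#'
#' @param bun_trend_pct Signed percent change in BUN (negative = decrease).
#'   `NA` passes through as missing.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
#' @examples
#' score_bun_trend(c(-10, 20, -40, -60))  # 0 0 2 3
score_bun_trend <- function(bun_trend_pct) {
  .check_finite(bun_trend_pct, "bun_trend_pct")
  d <- -bun_trend_pct  # magnitude of the decrease
  .bin3(d, 15, 26, 50)
}

#' Score the urine specific gravity variable
#'
#' Dilute urine accompanies fluid overload. Specific gravity at or above
#' 1.010 scores 0; 1.005--1.009 scores 1; 1.000--1.004 scores 2; below 1.000
#' scores 3 (kept for completeness although urine cannot physically reach it).
#' Values outside the physiologic range \[0.990, 1.060\] raise an error.
#'
#' @param urine_specific_gravity Dimensionless specific gravity.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_urine_sg <- function(urine_specific_gravity) {
  sg <- urine_specific_gravity
  .check_finite(sg, "urine_specific_gravity")
  bad <- !is.na(sg) & (sg < 0.990 | sg > 1.060)
  if (any(bad)) {
    stop(sprintf(
      "urine_specific_gravity: value(s) outside [0.990, 1.060] at position(s) %s",
      paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  s <- integer(length(sg))
  s[sg < 1.010] <- 1L
  s[sg < 1.005] <- 2L
  s[sg < 1.000] <- 3L
  s[is.na(sg)] <- NA_integer_
  s
}

#' Score the fluid balance variable
#'
#' Net positive fluid balance, normalized to mL/kg/day. Below 15 (including
#' any net-negative balance) scores 0; 15--30 scores 1; 30--50 scores 2;
#' above 50 scores 3.
#'
#' @param fluid_balance_ml_kg_day Signed net fluid balance in mL/kg/day.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_fluid_balance <- function(fluid_balance_ml_kg_day) {
  .check_finite(fluid_balance_ml_kg_day, "fluid_balance_ml_kg_day")
  .bin3(fluid_balance_ml_kg_day, 15, 30, 50)
}

#' Score the weight change variable
#'
#' Percent body-weight change against the caller's chosen baseline. Gains
#' under 7% (and any loss) score 0; 7--10% score 1; 11--15% score 2; above
#' 15% score 3.
#'
#' @param weight_change_pct Signed percent weight change.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_weight_change <- function(weight_change_pct) {
  .check_finite(weight_change_pct, "weight_change_pct")
  .bin3(weight_change_pct, 7, 11, 15)
}

#' Score the urine output variable
#'
#' High urine output in a fluid-positive patient reflects the kidneys
#' off-loading excess fluid. Output of 3 mL/kg/h or less scores 0; over 3 up
#' to 3.5 scores 1; over 3.5 up to 4 scores 2; over 4 scores 3. The rubric
#' only applies off diuretics and outside renal failure: when the flag is set
#' the variable is unmeasurable and returns `NA`. Values below 1 mL/kg/h are
#' outside the rubric's normal band (oliguria, a dehydration/renal signal,
#' not overload); they score 0 with a warning.
#'
#' @param urine_output_ml_kg_h Urine output in mL/kg/h, non-negative.
#' @param on_diuretics_or_renal_failure Logical; `TRUE` marks the variable
#'   unmeasurable.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing/unmeasurable.
#' @export
score_urine_output <- function(urine_output_ml_kg_h,
                               on_diuretics_or_renal_failure = FALSE) {
  u <- urine_output_ml_kg_h
  .check_finite(u, "urine_output_ml_kg_h")
  bad <- !is.na(u) & u < 0
  if (any(bad)) {
    stop(sprintf("urine_output_ml_kg_h: negative value(s) at position(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  flag <- rep_len(as.logical(on_diuretics_or_renal_failure), length(u))
  low <- !is.na(u) & u < 1 & !(flag %in% TRUE)
  if (any(low)) {
    warning(sprintf(
      "urine output < 1 mL/kg/h at position(s) %s: oliguria, scored 0 (not overload)",
      paste(which(low), collapse = ", ")), call. = FALSE)
  }
  s <- .bin3(u, 3, 3.5, 4, right = TRUE)
  s[flag %in% TRUE] <- NA_integer_
  s
}

.score_category <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("%s: unknown category %s (expected one of: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  as.integer(match(x, levels) - 1L)
}

#' Score the fontanelle variable
#'
#' Flat scores 0, full 1, bulging 2, bulging and tense 3. In older children
#' the fontanelle is closed and the variable is unmeasurable: `"closed"`
#' returns `NA` (omitted from the total, no reweighting).
#'
#' @param fontanelle One of `"flat"`, `"full"`, `"bulging"`,
#'   `"bulging_tense"`, `"closed"`, or `NA`.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing/closed.
#' @export
score_fontanelle <- function(fontanelle) {
  x <- as.character(fontanelle)
  x[!is.na(x) & x == "closed"] <- NA_character_
  .score_category(x, .fontanelle_levels, "fontanelle")
}

#' Score the eye examination variable
#'
#' Normal appearance 0, swollen 1, puffy with conjunctival edema 2, puffy and
#' unable to open 3.
#'
#' @param eyes One of `"normal"`, `"swollen"`, `"puffy_conjunctival_edema"`,
#'   `"puffy_unable_to_open"`, or `NA`.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_eyes <- function(eyes) .score_category(eyes, .eyes_levels, "eyes")

#' Score the skin/extremities variable
#'
#' No edema 0, edema in limbs or abdomen 1, limbs and face 2, anasarca 3.
#'
#' @param skin One of `"no_edema"`, `"limbs_or_abdomen"`, `"limbs_and_face"`,
#'   `"anasarca"`, or `NA`.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_skin <- function(skin) .score_category(skin, .skin_levels, "skin")

#' Score the chest imaging variable
#'
#' No excessive fluid 0, mild 1, moderate 2, severe 3 pulmonary
#' edema/pleural effusion.
#'
#' @param cxr_grade One of `"none"`, `"mild"`, `"moderate"`, `"severe"`, or
#'   `NA`.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_cxr <- function(cxr_grade) .score_category(cxr_grade, .cxr_levels, "cxr_grade")

#' Score the liver examination variable
#'
#' Congestive hepatomegaly measured as cm palpable below the costal margin.
#' Under 1 cm scores 0; 1 to under 2 cm scores 1; 2--3 cm scores 2; over 3 cm
#' scores 3.
#'
#' @param liver_cm_below_costal_margin Liver edge in cm below the costal
#'   margin, non-negative.
#' @return Integer subscore in `{0,1,2,3}`, `NA` for missing input.
#' @export
score_liver <- function(liver_cm_below_costal_margin) {
  L <- liver_cm_below_costal_margin
  .check_finite(L, "liver_cm_below_costal_margin")
  bad <- !is.na(L) & L < 0
  if (any(bad)) {
    stop(sprintf("liver_cm_below_costal_margin: negative value(s) at position(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  .bin3(L, 1, 2, 3)
}

#' Compute FAST scores for a table of encounters
#'
#' Applies all ten per-variable scorers to a data frame with one row per
#' encounter, sums the non-missing subscores into the total (no rescaling or
#' imputation), and flags encounters with more than two missing variables as
#' invalid (the study's exclusion rule).
#'
#' @param obs Data frame with one row per encounter. Recognised columns:
#'   `encounter_id`, `patient_id`, `bun_trend_pct`, `urine_specific_gravity`,
#'   `fluid_balance_ml_kg_day`, `weight_change_pct`, `urine_output_ml_kg_h`,
#'   `on_diuretics_or_renal_failure`, `fontanelle`, `eyes`,
#'   `liver_cm_below_costal_margin`, `skin`, `cxr_grade`. A raw-value column
#'   that is absent entirely is treated as missing for every encounter. `NA`
#'   (empty CSV cell) marks a missing value.
#' @return A data frame of class `fast_result` with columns `encounter_id`,
#'   the ten subscore columns (named as in [fast_variables]), `n_missing`,
#'   `total` and `valid` (`FALSE` when `n_missing > 2`).
#' @export
#' @examples
#' obs <- data.frame(
#'   encounter_id = "e1", bun_trend_pct = -30, urine_specific_gravity = 1.004,
#'   fluid_balance_ml_kg_day = 20, weight_change_pct = 3,
#'   urine_output_ml_kg_h = 3.8, on_diuretics_or_renal_failure = FALSE,
#'   fontanelle = "closed", eyes = "swollen",
#'   liver_cm_below_costal_margin = 2.5, skin = "no_edema", cxr_grade = "mild"
#' )
#' compute_fast(obs)
compute_fast <- function(obs) {
  if (!is.data.frame(obs)) stop("`obs` must be a data frame", call. = FALSE)
  n <- nrow(obs)
  col <- function(nm, default = NA) {
    if (nm %in% names(obs)) obs[[nm]] else rep(default, n)
  }
  id <- col("encounter_id")
  if (all(is.na(id))) id <- as.character(seq_len(n))

  score_one <- function(fn, nm, ...) {
    tryCatch(fn(...),
             error = function(e) stop(sprintf("variable '%s': %s", nm,
                                              conditionMessage(e)), call. = FALSE))
  }
  sub <- data.frame(
    bun_trend = score_one(score_bun_trend, "bun_trend", col("bun_trend_pct")),
    urine_sg = score_one(score_urine_sg, "urine_sg", col("urine_specific_gravity")),
    fluid_balance = score_one(score_fluid_balance, "fluid_balance",
                              col("fluid_balance_ml_kg_day")),
    weight_change = score_one(score_weight_change, "weight_change",
                              col("weight_change_pct")),
    urine_output = score_one(score_urine_output, "urine_output",
                             col("urine_output_ml_kg_h"),
                             col("on_diuretics_or_renal_failure", FALSE)),
    fontanelle = score_one(score_fontanelle, "fontanelle", col("fontanelle")),
    eyes = score_one(score_eyes, "eyes", col("eyes")),
    liver = score_one(score_liver, "liver", col("liver_cm_below_costal_margin")),
    skin = score_one(score_skin, "skin", col("skin")),
    cxr = score_one(score_cxr, "cxr", col("cxr_grade"))
  )
  m <- as.matrix(sub)
  n_missing <- rowSums(is.na(m))
  total <- rowSums(m, na.rm = TRUE)
  out <- cbind(
    data.frame(encounter_id = id, stringsAsFactors = FALSE),
    sub,
    data.frame(n_missing = as.integer(n_missing),
               total = as.integer(total),
               valid = n_missing <= 2)
  )
  class(out) <- c("fast_result", "data.frame")
  out
}

#' @export
print.fast_result <- function(x, ...) {
  cat(sprintf("FAST scores for %d encounter(s); %d valid (<= 2 missing variables)\n",
              nrow(x), sum(x$valid)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
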