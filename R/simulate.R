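.default_emissions <- list(
  # state-conditional normal location/scale for the raw numeric variables;
  # first entry = latent-normal state, second = latent-overloaded state
  bun_trend_pct = list(mean = c(0, -12), sd = c(10, 14)),
  urine_specific_gravity = list(mean = c(1.016, 1.011), sd = c(0.007, 0.005)),
  fluid_balance_ml_kg_day = list(mean = c(0, 12), sd = c(10, 14)),
  weight_change_pct = list(mean = c(1, 5), sd = c(3, 4)),
  urine_output_ml_kg_h = list(mean = c(2.2, 2.8), sd = c(0.7, 0.9)),
  liver_cm_below_costal_margin = list(mean = c(0.3, 1.0), sd = c(0.6, 0.9))
)

.default_categorical <- list(
  # state-conditional probabilities over the four severity levels
  fontanelle = rbind(neg = c(0.85, 0.10, 0.04, 0.01),
                     pos = c(0.55, 0.27, 0.13, 0.05)),
  eyes = rbind(neg = c(0.85, 0.10, 0.04, 0.01),
               pos = c(0.55, 0.27, 0.13, 0.05)),
  skin = rbind(neg = c(0.85, 0.10, 0.04, 0.01),
               pos = c(0.55, 0.27, 0.13, 0.05)),
  cxr = rbind(neg = c(0.75, 0.15, 0.07, 0.03),
              pos = c(0.45, 0.30, 0.17, 0.08))
)

#' Parameters for the synthetic PICU cohort generator
#'
#' Bundles and validates every knob of the generative model: a latent
#' fluid-overload state with the study's prevalence, state-conditional
#' normal emissions for the six numeric rubric variables, state-conditional
#' multinomials for the four categorical ones, structural unmeasurability
#' (closed fontanelles, diuretics/renal failure suppressing urine output),
#' random per-variable missingness, a Gaussian thoracic-fluid-content model
#' thresholded into the binary high-TFC label, and negative-binomial day
#' counts built cumulatively so ventilator <= PICU <= hospital days always
#' holds. Defaults emulate the development cohort's shape (118 encounters,
#' 66% high-TFC) and are illustrative, not estimates of the real cohort.
#'
#' @param n_encounters Number of encounters to draw.
#' @param prevalence Probability an encounter is latent-overloaded.
#' @param seed Integer seed; the cohort is a pure function of the parameters.
#' @param emissions Named list, per numeric variable: `list(mean = c(neg,
#'   pos), sd = c(neg, pos))`.
#' @param categorical Named list, per categorical variable: a 2x4 matrix of
#'   state-conditional level probabilities (rows neg, pos).
#' @param fontanelle_closed_rate Probability the fontanelle is closed
#'   (unmeasurable), independent of state.
#' @param diuretics_rate Probability of the diuretics/renal-failure flag.
#' @param missing_rate Per-variable probability of random missingness.
#' @param tfc_model `list(mean = c(neg, pos), sd = c(neg, pos), threshold)`;
#'   the binary label is tfc >= threshold.
#' @param outcome_model `list(vent_mu = c(neg, pos), picu_extra_mu = c(neg,
#'   pos), hosp_extra_mu = c(neg, pos), size)`: negative-binomial means for
#'   ventilator days and the PICU/hospital increments, shared dispersion.
#' @return Validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_encounters = 118,
                          prevalence = 0.66,
                          seed = 1,
                          emissions = .default_emissions,
                          categorical = .default_categorical,
                          fontanelle_closed_rate = 0.60,
                          diuretics_rate = 0.30,
                          missing_rate = 0.05,
                          tfc_model = list(mean = c(30, 54), sd = c(8, 10),
                                           threshold = 40),
                          outcome_model = list(vent_mu = c(9, 12),
                                               picu_extra_mu = c(5, 6),
                                               hosp_extra_mu = c(3, 4),
                                               size = 1.5)) {
  p <- list(n_encounters = as.integer(n_encounters), prevalence = prevalence,
            seed = as.integer(seed), emissions = emissions,
            categorical = categorical,
            fontanelle_closed_rate = fontanelle_closed_rate,
            diuretics_rate = diuretics_rate, missing_rate = missing_rate,
            tfc_model = tfc_model, outcome_model = outcome_model)
  probs <- c(prevalence, fontanelle_closed_rate, diuretics_rate, missing_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("prevalence and rate parameters must lie in [0, 1]", call. = FALSE)
  }
  if (p$n_encounters < 1) stop("n_encounters must be >= 1", call. = FALSE)
  for (nm in names(emissions)) {
    e <- emissions[[nm]]
    if (length(e$mean) != 2 || length(e$sd) != 2 || any(e$sd <= 0)) {
      stop(sprintf("emissions$%s must have 2 means and 2 positive sds", nm),
           call. = FALSE)
    }
  }
  for (nm in names(categorical)) {
    m <- categorical[[nm]]
    if (!is.matrix(m) || any(dim(m) != c(2, 4)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-8)) {
      stop(sprintf("categorical$%s must be a 2x4 probability matrix with rows summing to 1",
                   nm), call. = FALSE)
    }
  }
  if (any(tfc_model$sd <= 0)) stop("tfc_model sds must be positive", call. = FALSE)
  if (p$outcome_model$size <= 0) stop("outcome_model$size must be positive",
                                      call. = FALSE)
  structure(p, class = "cohort_params")
}

.draw_levels <- function(state, probs, levels) {
  # state: logical (TRUE = overloaded); probs: 2x4 matrix rows (neg, pos)
  n <- length(state)
  u <- runif(n)
  row <- 1L + as.integer(state)
  cum <- t(apply(probs, 1, cumsum))
  idx <- vapply(seq_len(n), function(i) {
    1L + sum(u[i] > cum[row[i], ])
  }, integer(1))
  levels[pmin(idx, length(levels))]
}

#' Generate a seeded synthetic PICU cohort
#'
#' Draws a full synthetic cohort under [cohort_params()]: raw clinical
#' observations for the ten rubric variables, a thoracic-fluid-content value
#' and its binary high-TFC label, clinical outcomes, and the latent
#' overload state (the simulation truth, for recovery studies). The same
#' parameters and seed always reproduce the identical cohort.
#'
#' @param params A [cohort_params()] object.
#' @return List with data frames `observations` (one row per encounter, raw
#'   values in the scoring-module schema), `labels` (`encounter_id`,
#'   `tfc_value`, `tfc_high`), `outcomes` (`encounter_id`,
#'   `ventilator_days`, `picu_days`, `hospital_days`) and `truth`
#'   (`encounter_id`, `overloaded`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params(n_encounters = 50, seed = 7))
#' res <- compute_fast(cohort$observations)
#' tapply(res$total, cohort$truth$overloaded, mean)
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) params <- do.call(cohort_params, params)
  set.seed(params$seed)
  n <- params$n_encounters
  state <- runif(n) < params$prevalence
  id <- sprintf("sim%05d", seq_len(n))

  emit <- function(nm) {
    e <- params$emissions[[nm]]
    rnorm(n, e$mean[1 + state], e$sd[1 + state])
  }
  obs <- data.frame(
    encounter_id = id,
    patient_id = id,  # independent encounters: one per synthetic patient
    bun_trend_pct = emit("bun_trend_pct"),
    urine_specific_gravity = pmin(pmax(emit("urine_specific_gravity"), 0.990), 1.060),
    fluid_balance_ml_kg_day = emit("fluid_balance_ml_kg_day"),
    weight_change_pct = emit("weight_change_pct"),
    urine_output_ml_kg_h = pmax(emit("urine_output_ml_kg_h"), 0),
    on_diuretics_or_renal_failure = runif(n) < params$diuretics_rate,
    fontanelle = .draw_levels(state, params$categorical$fontanelle,
                              .fontanelle_levels),
    eyes = .draw_levels(state, params$categorical$eyes, .eyes_levels),
    liver_cm_below_costal_margin = pmax(emit("liver_cm_below_costal_margin"), 0),
    skin = .draw_levels(state, params$categorical$skin, .skin_levels),
    cxr_grade = .draw_levels(state, params$categorical$cxr, .cxr_levels),
    stringsAsFactors = FALSE
  )
  obs$fontanelle[runif(n) < params$fontanelle_closed_rate] <- "closed"
  # random missingness on the optional raw-value columns
  miss_cols <- c("bun_trend_pct", "urine_specific_gravity",
                 "fluid_balance_ml_kg_day", "weight_change_pct",
                 "urine_output_ml_kg_h", "fontanelle", "eyes",
                 "liver_cm_below_costal_margin", "skin", "cxr_grade")
  for (nm in miss_cols) {
    obs[[nm]][runif(n) < params$missing_rate] <- NA
  }

  tm <- params$tfc_model
  tfc <- rnorm(n, tm$mean[1 + state], tm$sd[1 + state])
  labels <- data.frame(encounter_id = id, tfc_value = tfc,
                       tfc_high = tfc >= tm$threshold, stringsAsFactors = FALSE)

  om <- params$outcome_model
  vent <- rnbinom(n, size = om$size, mu = om$vent_mu[1 + state])
  picu <- vent + rnbinom(n, size = om$size, mu = om$picu_extra_mu[1 + state])
  hosp <- picu + rnbinom(n, size = om$size, mu = om$hosp_extra_mu[1 + state])
  outcomes <- data.frame(encounter_id = id, ventilator_days = vent,
                         picu_days = picu, hospital_days = hosp,
                         stringsAsFactors = FALSE)

  list(observations = obs, labels = labels, outcomes = outcomes,
       truth = data.frame(encounter_id = id, overloaded = state,
                          stringsAsFactors = FALSE))
}

#' Bias and RMSE of cut-point operating characteristics at the study size
#'
#' Monte-Carlo harness quantifying the small-sample variability of
#' sensitivity and specificity estimates: ground truth is computed once from
#' a very large cohort under the same parameters, then `n_replicates`
#' cohorts of the study's size are scored and tabulated, and the deviation
#' of each replicate's sensitivity/specificity at `cut` from the truth is
#' summarized as bias and RMSE.
#'
#' @param params A [cohort_params()] object; `n_encounters` is the per-
#'   replicate (study) size.
#' @param n_replicates Number of study-sized replicates.
#' @param cut Integer cut at which to read sensitivity and specificity.
#' @param oracle_n Size of the ground-truth cohort.
#' @return List with `truth` (sensitivity/specificity at `cut` from the
#'   oracle cohort), `bias` and `rmse` (named vectors over sensitivity and
#'   specificity), and `n_replicates`.
#' @export
recover_operating_characteristics <- function(params, n_replicates = 200,
                                              cut = 3, oracle_n = 1e6) {
  stopifnot(inherits(params, "cohort_params"))
  op_at_cut <- function(p) {
    cohort <- generate_cohort(p)
    res <- compute_fast(cohort$observations)
    d <- data.frame(score = res$total[res$valid],
                    tfc_high = cohort$labels$tfc_high[res$valid])
    c(sensitivity = mean(d$score[d$tfc_high] >= cut),
      specificity = mean(d$score[!d$tfc_high] < cut))
  }
  big <- params
  big$n_encounters <- as.integer(oracle_n)
  big$seed <- params$seed + 777L
  truth <- suppressWarnings(op_at_cut(big))

  est <- matrix(NA_real_, n_replicates, 2,
                dimnames = list(NULL, c("sensitivity", "specificity")))
  for (r in seq_len(n_replicates)) {
    p <- params
    p$seed <- params$seed + r
    est[r, ] <- suppressWarnings(op_at_cut(p))
  }
  dev <- sweep(est, 2, truth)
  list(truth = truth,
       bias = colMeans(dev),
       rmse = sqrt(colMeans(dev^2)),
       n_replicates = n_replicates)
}
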