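# Independent oracles used across the suite. These deliberately use naive
# algorithms (double loops, full enumeration) so they share no code with the
# implementation they check.

# AUC by explicit enumeration of every positive x negative pair
brute_force_auc <- function(score, tfc_high) {
  pos <- score[tfc_high]
  neg <- score[!tfc_high]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# two-sided exact Mann-Whitney p by enumerating every relabeling; the
# statistic is recomputed from raw rank sums, not via the package
brute_force_mw_p <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  N <- length(x)
  r <- rank(x)
  w_obs <- sum(r[seq_len(na)])
  mu_w <- na * (N + 1) / 2
  sets <- utils::combn(N, na)
  ws <- apply(sets, 2, function(i) sum(r[i]))
  mean(abs(ws - mu_w) >= abs(w_obs - mu_w) - 1e-9)
}

random_labeled_scores <- function(n_pos, n_neg, max_score = 8) {
  data.frame(
    score = c(sample(0:max_score, n_pos, replace = TRUE, prob = (1:(max_score + 1))),
              sample(0:max_score, n_neg, replace = TRUE, prob = rev(1:(max_score + 1)))),
    tfc_high = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}

# exact tail P(X > k) for a sum of independent Bernoulli(p_i), by convolution
poisson_binomial_tail <- function(p, k) {
  dist <- 1
  for (pi in p) dist <- c(dist * (1 - pi), 0) + c(0, dist * pi)
  sum(dist[(k + 2):length(dist)])
}

# one fully-populated encounter at the rubric-normal end
normal_encounter <- function(id = "e1") {
  data.frame(
    encounter_id = id,
    bun_trend_pct = 0, urine_specific_gravity = 1.020,
    fluid_balance_ml_kg_day = 5, weight_change_pct = 0,
    urine_output_ml_kg_h = 2, on_diuretics_or_renal_failure = FALSE,
    fontanelle = "flat", eyes = "normal",
    liver_cm_below_costal_margin = 0, skin = "no_edema", cxr_grade = "none",
    stringsAsFactors = FALSE
  )
}

severe_encounter <- function(id = "e1") {
  data.frame(
    encounter_id = id,
    bun_trend_pct = -60, urine_specific_gravity = 0.995,
    fluid_balance_ml_kg_day = 60, weight_change_pct = 20,
    urine_output_ml_kg_h = 5, on_diuretics_or_renal_failure = FALSE,
    fontanelle = "bulging_tense", eyes = "puffy_unable_to_open",
    liver_cm_below_costal_margin = 4, skin = "anasarca", cxr_grade = "severe",
    stringsAsFactors = FALSE
  )
}
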