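# Survivor proportions of the FAST total per reference class, as printed in
# the study's cut-point table: the sensitivity column is P(score >= c) among
# TFC-high encounters, 1 - specificity is P(score >= c) among TFC-normal
# encounters, for integer cuts 0..8 (scores above 8 lumped at 8).
.study_survivor_pos <- c(1.0000, 0.9872, 0.9487, 0.9231, 0.7949,
                         0.6154, 0.3590, 0.2308, 0.1154)
.study_survivor_neg <- c(1.0000, 0.7000, 0.5000, 0.3250, 0.2000,
                         0.1000, 0.0750, 0.0750, 0.0500)
.study_n_pos <- 78L
.study_n_neg <- 40L

.counts_from_survivor <- function(survivor, n, what) {
  if (any(diff(survivor) > 1e-9)) {
    stop(sprintf("%s: survivor proportions must be non-increasing in the cut", what),
         call. = FALSE)
  }
  if (any(survivor < -1e-9 | survivor > 1 + 1e-9)) {
    stop(sprintf("%s: survivor proportions must lie in [0, 1]", what), call. = FALSE)
  }
  # P(score == c) = S(c) - S(c+1); everything at or above the last printed
  # cut is lumped there
  mass <- c(-diff(survivor), survivor[length(survivor)])
  counts <- round(mass * n)
  if (any(counts < 0)) {
    stop(sprintf("%s: negative count after rounding", what), call. = FALSE)
  }
  if (sum(counts) != n) {
    stop(sprintf("%s: rounded counts sum to %d, expected class size %d",
                 what, sum(counts), n), call. = FALSE)
  }
  as.integer(counts)
}

#' Reconstruct a score-by-label dataset from per-class survivor proportions
#'
#' A cut-point table fully determines the per-class score distribution: the
#' sensitivity column is the positive-class survivor function P(score >= c)
#' and 1 - specificity the negative-class one. Differencing adjacent survivor
#' values, multiplying by the class size and rounding recovers the per-score
#' counts; scores at or above the last printed cut are lumped at that cut.
#' The reconstruction is validated by checking that each class's counts sum
#' exactly to its size.
#'
#' @param survivor_pos Numeric vector, positive-class survivor proportions
#'   P(score >= c) for `cuts` (non-increasing; first entry 1).
#' @param survivor_neg Numeric vector, negative-class survivor proportions,
#'   same cuts.
#' @param n_pos,n_neg Integer class sizes.
#' @param cuts Integer cuts the survivor vectors refer to; default `0:(k-1)`.
#' @return Data frame with columns `encounter_id`, `score`, `tfc_high` —
#'   one row per reconstructed encounter.
#' @seealso [fast_fixture()] for the packaged study table.
#' @export
reconstruct_fixture <- function(survivor_pos, survivor_neg, n_pos, n_neg,
                                cuts = seq_along(survivor_pos) - 1L) {
  if (length(survivor_pos) != length(survivor_neg) ||
      length(survivor_pos) != length(cuts)) {
    stop("survivor_pos, survivor_neg and cuts must have equal length", call. = FALSE)
  }
  if (abs(survivor_pos[1] - 1) > 1e-9) {
    stop("survivor_pos must start at 1 (every positive scores >= the lowest cut)",
         call. = FALSE)
  }
  cp <- .counts_from_survivor(survivor_pos, n_pos, "positive class")
  cn <- .counts_from_survivor(survivor_neg, n_neg, "negative class")
  out <- data.frame(
    score = c(rep(cuts, cp), rep(cuts, cn)),
    tfc_high = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
  out <- data.frame(
    encounter_id = sprintf("enc%03d", seq_len(nrow(out))),
    score = as.integer(out$score),
    tfc_high = out$tfc_high,
    stringsAsFactors = FALSE
  )
  out
}

#' The reconstructed 118-encounter study dataset
#'
#' Rebuilds, from the published cut-point table's survivor proportions, the
#' score-by-label table of the development cohort: 118 PICU encounters, 78
#' with high thoracic fluid content (the positive reference class) and 40
#' without. Per-class score counts are `[1,3,2,10,14,20,10,9,9]` (TFC-high)
#' and `[12,8,7,5,4,1,0,1,2]` (TFC-normal) over scores 0..8, scores above 8
#' lumped at 8. Re-running [cutpoint_table()] on this dataset reproduces
#' every published sensitivity/specificity/accuracy cell at two-decimal
#' percent precision.
#'
#' @return Data frame with columns `encounter_id`, `score`, `tfc_high`
#'   (118 rows). The same table ships as
#'   `system.file("extdata", "fast_fixture.csv", package = "fastscore")`.
#' @export
#' @examples
#' fx <- fast_fixture()
#' table(fx$score, fx$tfc_high)
fast_fixture <- function() {
  reconstruct_fixture(.study_survivor_pos, .study_survivor_neg,
                      .study_n_pos, .study_n_neg)
}
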