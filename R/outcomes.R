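.u_statistic <- function(a, b) {
  r <- rank(c(a, b))  # midranks
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank test reported in the form used for the outcome
#' comparisons: U by midrank assignment, the tie-corrected normal-
#' approximation z, the chi-squared statistic z^2 (1 df), and the two-sided
#' p-value. U counts pairs (a, b) with a > b (ties count 1/2), so 0 means
#' every `a` value lies below every `b` value and `length(a)*length(b)` is
#' the complementary extreme. For small samples (combined n <= 12 by
#' default) the p-value is instead computed by exact enumeration of all
#' relabelings: the fraction whose |U - E(U)| is at least the observed one.
#' All-tied data give chi2 = 0 and p = 1.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact Logical; force (`TRUE`) or suppress (`FALSE`) exact
#'   enumeration. Default `NULL` enumerates when `length(a) + length(b) <= 12`.
#' @return Object of class `mann_whitney`: list with `U`, `z`, `chi2`,
#'   `p_value`, `exact`, `n` (c(n_a, n_b)).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 4, 5), c(3, 6, 7, 8))  # exact p = 8/70
mann_whitney <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  if (is.null(exact)) exact <- N <= 12

  U <- .u_statistic(a, b)
  mu <- na * nb / 2
  tt <- table(c(a, b))
  v <- na * nb / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))

  if (v <= 0) {  # every observation tied
    z <- 0; chi2 <- 0; p <- 1; exact <- FALSE
  } else {
    z <- (U - mu) / sqrt(v)
    chi2 <- z^2
    if (exact) {
      x <- c(a, b)
      us <- apply(combn(N, na), 2, function(i) .u_statistic(x[i], x[-i]))
      p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    } else {
      p <- pchisq(chi2, df = 1, lower.tail = FALSE)
    }
  }
  structure(list(U = U, z = z, chi2 = chi2, p_value = p,
                 exact = exact, n = c(n_a = na, n_b = nb)),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (n = %d, %d)\n", x$n[1], x$n[2]))
  cat(sprintf("  U = %g, chi2(1) = %.4f, p = %.4g%s\n", x$U, x$chi2, x$p_value,
              if (x$exact) " (exact enumeration)" else " (tie-corrected normal approximation)"))
  invisible(x)
}

.outcome_cols <- c("ventilator_days", "picu_days", "hospital_days")

#' Compare clinical outcomes below vs at-or-above a FAST cut
#'
#' Joins scores and outcomes on `encounter_id`, splits encounters into
#' score < cut and score >= cut, and compares each outcome (ventilator days,
#' PICU days, hospital days — whichever columns are present) between the
#' groups with [mann_whitney()]. Medians and IQRs use Tukey hinges
#' (median-of-halves quartiles, via [stats::fivenum()]). A chart where
#' ventilator > PICU or PICU > hospital days draws a warning, not an error.
#'
#' @param scores Data frame with `encounter_id` and `score` columns (e.g.
#'   a [compute_fast()] result with `total` renamed, or [fast_fixture()]).
#'   A `total` column is accepted as a synonym for `score`.
#' @param outcomes Data frame with `encounter_id` and any of
#'   `ventilator_days`, `picu_days`, `hospital_days`.
#' @param cut Integer cut splitting the groups.
#' @return Object of class `outcome_comparison`: a data frame with one row
#'   per outcome — group sizes, medians, Tukey-hinge quartiles, `chi2` and
#'   `p_value` — with attribute `cut`.
#' @export
compare_outcomes <- function(scores, outcomes, cut) {
  if (!"score" %in% names(scores) && "total" %in% names(scores)) {
    scores$score <- scores$total
  }
  for (nm in c("encounter_id", "score")) {
    if (!nm %in% names(scores)) stop(sprintf("`scores` lacks column '%s'", nm),
                                     call. = FALSE)
  }
  present <- intersect(.outcome_cols, names(outcomes))
  if (!"encounter_id" %in% names(outcomes) || !length(present)) {
    stop("`outcomes` must have `encounter_id` and at least one outcome column",
         call. = FALSE)
  }
  d <- merge(scores[c("encounter_id", "score")],
             outcomes[c("encounter_id", present)], by = "encounter_id")
  if (nrow(d) < 4) stop("fewer than 4 encounters after joining on encounter_id",
                        call. = FALSE)
  if (all(c("ventilator_days", "picu_days") %in% present)) {
    bad <- with(d, !is.na(ventilator_days) & !is.na(picu_days) &
                  ventilator_days > picu_days)
    if (any(bad)) warning(sprintf("%d encounter(s) with ventilator_days > picu_days",
                                  sum(bad)), call. = FALSE)
  }
  if (all(c("picu_days", "hospital_days") %in% present)) {
    bad <- with(d, !is.na(picu_days) & !is.na(hospital_days) &
                  picu_days > hospital_days)
    if (any(bad)) warning(sprintf("%d encounter(s) with picu_days > hospital_days",
                                  sum(bad)), call. = FALSE)
  }
  hi <- d$score >= cut
  if (sum(hi) < 2 || sum(!hi) < 2) {
    stop(sprintf("degenerate comparison at cut %d: need >= 2 encounters per group (got %d below, %d at-or-above)",
                 cut, sum(!hi), sum(hi)), call. = FALSE)
  }
  rows <- lapply(present, function(nm) {
    lo_v <- d[[nm]][!hi]; hi_v <- d[[nm]][hi]
    lo_v <- lo_v[!is.na(lo_v)]; hi_v <- hi_v[!is.na(hi_v)]
    mw <- mann_whitney(lo_v, hi_v, exact = FALSE)
    f_lo <- fivenum(lo_v); f_hi <- fivenum(hi_v)
    data.frame(outcome = nm, n_lo = length(lo_v), n_hi = length(hi_v),
               median_lo = f_lo[3], q1_lo = f_lo[2], q3_lo = f_lo[4],
               median_hi = f_hi[3], q1_hi = f_hi[2], q3_hi = f_hi[4],
               chi2 = mw$chi2, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("outcome_comparison", "data.frame"), cut = cut)
}

#' @export
print.outcome_comparison <- function(x, ...) {
  cut <- attr(x, "cut")
  cat(sprintf("Clinical outcomes: FAST < %d (n = %d) vs FAST >= %d (n = %d)\n",
              cut, x$n_lo[1], cut, x$n_hi[1]))
  fmt <- data.frame(
    Outcome = x$outcome,
    `Below cut` = sprintf("%g (%g-%g)", x$median_lo, x$q1_lo, x$q3_lo),
    `At/above cut` = sprintf("%g (%g-%g)", x$median_hi, x$q1_hi, x$q3_hi),
    `X^2` = sprintf("%.4f", x$chi2),
    `p-value` = sprintf("%.2f", x$p_value),
    check.names = FALSE
  )
  print.data.frame(fmt, row.names = FALSE)
  cat("median (IQR, Tukey hinges); Mann-Whitney U test, tie-corrected\n")
  invisible(x)
}
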