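.check_labeled <- function(data) {
  if (!is.data.frame(data) || !all(c("score", "tfc_high") %in% names(data))) {
    stop("`data` must be a data frame with columns `score` and `tfc_high`",
         call. = FALSE)
  }
  score <- data$score
  lab <- data$tfc_high
  if (is.numeric(lab)) lab <- lab != 0
  if (!is.logical(lab) || anyNA(lab)) {
    stop("`tfc_high` must be a complete binary label (logical or 0/1)",
         call. = FALSE)
  }
  if (anyNA(score) || any(score < 0)) {
    stop("`score` must be complete and non-negative", call. = FALSE)
  }
  if (!any(lab) || all(lab)) {
    stop("degenerate input: both a TFC-high and a TFC-normal encounter are required",
         call. = FALSE)
  }
  list(score = score, lab = lab)
}

#' Cut-point table for the FAST score against the TFC reference
#'
#' For each integer cut `c` the score is dichotomized as "predict fluid
#' overload iff score >= c" and compared with the binary high-TFC reference:
#' sensitivity is the fraction of TFC-high encounters at or above the cut,
#' specificity the fraction of TFC-normal encounters below it, and correctly
#' classified the overall accuracy. Exact binomial (Clopper--Pearson) 95%
#' confidence intervals are attached to sensitivity and specificity.
#'
#' @param data Data frame with columns `score` (non-negative integer FAST
#'   totals) and `tfc_high` (logical or 0/1 reference label); an
#'   `encounter_id` column is allowed and ignored.
#' @param cuts Integer cuts to tabulate; default `0:(max(score) + 1)` so the
#'   table spans the full ROC polygon from (1,0) to (0,1).
#' @param conf_level Confidence level for the exact binomial intervals.
#' @return An object of class `roc_table`: a data frame with columns `cut`,
#'   `tp`, `fp`, `fn`, `tn`, `sensitivity`, `specificity`,
#'   `correctly_classified`, `sens_lo`, `sens_hi`, `spec_lo`, `spec_hi`, with
#'   attributes `n_pos`, `n_neg` and `auc` (trapezoidal area under the ROC
#'   polygon traced by the rows).
#' @export
#' @examples
#' tab <- cutpoint_table(fast_fixture())
#' tab
cutpoint_table <- function(data, cuts = NULL, conf_level = 0.95) {
  d <- .check_labeled(data)
  score <- d$score; lab <- d$lab
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (is.null(cuts)) cuts <- 0:(max(score) + 1L)
  cuts <- as.integer(sort(unique(cuts)))

  tp <- vapply(cuts, function(c) sum(score >= c & lab), integer(1))
  fp <- vapply(cuts, function(c) sum(score >= c & !lab), integer(1))
  fn <- n_pos - tp
  tn <- n_neg - fp
  sens <- tp / n_pos
  spec <- tn / n_neg
  acc <- (tp + tn) / (n_pos + n_neg)

  ci <- function(x, n) {
    t(vapply(x, function(k) binom.test(k, n, conf.level = conf_level)$conf.int,
             numeric(2)))
  }
  sci <- ci(tp, n_pos)
  pci <- ci(tn, n_neg)

  out <- data.frame(
    cut = cuts, tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec, correctly_classified = acc,
    sens_lo = sci[, 1], sens_hi = sci[, 2],
    spec_lo = pci[, 1], spec_hi = pci[, 2]
  )
  # trapezoidal area of the (FPR, TPR) polygon, closed at (1,1) and (0,0)
  fpr <- c(1, 1 - spec, 0)
  tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  structure(out, class = c("roc_table", "data.frame"),
            n_pos = n_pos, n_neg = n_neg, auc = auc)
}

#' @export
print.roc_table <- function(x, ...) {
  cat(sprintf("ROC cut-point table: %d TFC-high, %d TFC-normal encounters (AUC %.4f)\n",
              attr(x, "n_pos"), attr(x, "n_neg"), attr(x, "auc")))
  fmt <- data.frame(
    `Cut point` = sprintf(">=%d", x$cut),
    Sensitivity = sprintf("%.2f%%", 100 * x$sensitivity),
    Specificity = sprintf("%.2f%%", 100 * x$specificity),
    `Correctly classified` = sprintf("%.2f%%", 100 * x$correctly_classified),
    check.names = FALSE
  )
  print.data.frame(fmt, row.names = FALSE)
  invisible(x)
}

#' Select an operating cut point from a cut-point table
#'
#' The `balanced` policy (the study's) picks the cut minimizing
#' |sensitivity - specificity|, with ties broken toward higher overall
#' accuracy and then toward the lower cut. `max_accuracy` maximizes the
#' correctly-classified proportion; `youden` maximizes
#' sensitivity + specificity - 1. Ties in the alternates break toward the
#' lower cut.
#'
#' @param table An [cutpoint_table()] result.
#' @param policy One of `"balanced"`, `"max_accuracy"`, `"youden"`.
#' @return The winning row of `table` (single-row data frame).
#' @export
select_cutpoint <- function(table,
                            policy = c("balanced", "max_accuracy", "youden")) {
  policy <- match.arg(policy)
  if (!nrow(table)) stop("empty cut-point table", call. = FALSE)
  key <- switch(policy,
    balanced = order(abs(table$sensitivity - table$specificity),
                     -table$correctly_classified, table$cut),
    max_accuracy = order(-table$correctly_classified, table$cut),
    youden = order(-(table$sensitivity + table$specificity - 1), table$cut)
  )
  out <- table[key[1], , drop = FALSE]
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

#' Empirical AUC by pair counting
#'
#' The probability that a randomly chosen TFC-high encounter outscores a
#' randomly chosen TFC-normal one, with ties credited 1/2 — equivalently the
#' trapezoidal area under the empirical ROC polygon. Computed via midranks,
#' which is algebraically identical to averaging over all
#' positive-by-negative pairs.
#'
#' @inheritParams cutpoint_table
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' empirical_auc(fast_fixture())  # 0.8527
empirical_auc <- function(data) {
  d <- .check_labeled(data)
  r <- rank(d$score)  # midranks
  n_pos <- sum(d$lab); n_neg <- sum(!d$lab)
  (sum(r[d$lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' AUC of the score dichotomized at a cut
#'
#' A binary predictor 1\{score >= cut\} has a two-segment ROC through
#' (1 - specificity, sensitivity), whose area is
#' (sensitivity + specificity) / 2.
#'
#' @param table An [cutpoint_table()] result.
#' @param cut Integer cut present in `table`.
#' @return AUC in \[0, 1\].
#' @export
dichotomized_auc <- function(table, cut) {
  i <- match(cut, table$cut)
  if (is.na(i)) {
    stop(sprintf("cut %s is not in the table (cuts %d..%d)", format(cut),
                 min(table$cut), max(table$cut)), call. = FALSE)
  }
  (table$sensitivity[i] + table$specificity[i]) / 2
}

# stratified fold labels: class proportions preserved, remainders spread by
# the shuffled order, fully determined by the RNG state
.stratified_folds <- function(lab, n_folds) {
  fold <- integer(length(lab))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(lab == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated AUC of the FAST score
#'
#' Stratified k-fold cross-validation of a fixed scoring rule: fold
#' membership preserves the class proportions, and each held-out fold
#' contributes the AUC of its encounters — of the binary predictor
#' 1\{score >= cut\} when `cut` is given ((sensitivity + specificity)/2 on
#' the fold), or the rank-based empirical AUC of the raw score otherwise.
#' Nothing is refit per fold: the score is a fixed rule, so cross-validation
#' here measures the sampling variability of its operating characteristics.
#' A fold that receives only one class has no defined AUC; it is dropped from
#' the mean with a warning. The percentile interval is taken across
#' per-repeat means when `n_repeats > 1`, across folds otherwise.
#'
#' @inheritParams cutpoint_table
#' @param n_folds Number of folds (>= 2; each class must have at least
#'   `n_folds` members for every fold to be scorable).
#' @param cut Integer cut to dichotomize at, or `NULL` for the rank-based
#'   AUC of the raw score.
#' @param seed Integer seed; the whole procedure is reproducible from it.
#' @param n_repeats Number of independent repetitions of the fold split.
#' @return An object of class `cv_result`: list with elements `cut`,
#'   `fold_aucs` (length `n_folds * n_repeats`, `NA` for degenerate folds),
#'   `repeat_means`, `mean_auc`, `ci95`, `n_folds`, `n_repeats`, `seed`.
#' @export
#' @examples
#' cv_auc(fast_fixture(), n_folds = 10, cut = 3, seed = 1, n_repeats = 20)
cv_auc <- function(data, n_folds = 10, cut = NULL, seed, n_repeats = 1) {
  d <- .check_labeled(data)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  score <- d$score; lab <- d$lab
  set.seed(seed)

  fold_auc_one <- function(s, l) {
    if (!any(l) || all(l)) return(NA_real_)
    if (is.null(cut)) {
      r <- rank(s)
      np <- sum(l); nn <- sum(!l)
      (sum(r[l]) - np * (np + 1) / 2) / (np * nn)
    } else {
      (mean(s[l] >= cut) + mean(s[!l] < cut)) / 2
    }
  }

  fold_aucs <- numeric(0)
  repeat_means <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    fold <- .stratified_folds(lab, n_folds)
    aucs <- vapply(seq_len(n_folds),
                   function(k) fold_auc_one(score[fold == k], lab[fold == k]),
                   numeric(1))
    fold_aucs <- c(fold_aucs, aucs)
    repeat_means[r] <- mean(aucs, na.rm = TRUE)
  }
  n_bad <- sum(is.na(fold_aucs))
  if (n_bad > 0) {
    warning(sprintf("%d fold(s) contained a single class; excluded from the mean",
                    n_bad), call. = FALSE)
  }
  ci_src <- if (n_repeats > 1) repeat_means else fold_aucs[!is.na(fold_aucs)]
  structure(list(
    cut = if (is.null(cut)) "continuous" else cut,
    fold_aucs = fold_aucs,
    repeat_means = repeat_means,
    mean_auc = mean(fold_aucs, na.rm = TRUE),
    ci95 = unname(quantile(ci_src, c(0.025, 0.975), na.rm = TRUE)),
    n_folds = n_folds, n_repeats = n_repeats, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validated AUC (cut: %s, %d repeat(s), seed %d)\n  mean AUC %.4f, 95%% percentile interval [%.4f, %.4f]\n",
    x$n_folds, format(x$cut), x$n_repeats, x$seed,
    x$mean_auc, x$ci95[1], x$ci95[2]))
  invisible(x)
}
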