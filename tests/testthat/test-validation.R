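fx <- fast_fixture()
fx_tab <- cutpoint_table(fx, cuts = 0:8)

test_that("fixture reconstruction recovers the per-class score counts", {
  expect_equal(nrow(fx), 118)
  expect_equal(sum(fx$tfc_high), 78)
  pos_counts <- as.vector(table(factor(fx$score[fx$tfc_high], levels = 0:8)))
  neg_counts <- as.vector(table(factor(fx$score[!fx$tfc_high], levels = 0:8)))
  expect_equal(pos_counts, c(1, 3, 2, 10, 14, 20, 10, 9, 9))
  expect_equal(neg_counts, c(12, 8, 7, 5, 4, 1, 0, 1, 2))
})

test_that("reconstruction rejects malformed survivor inputs", {
  expect_error(reconstruct_fixture(c(1, 0.5, 0.6), c(1, 0.5, 0.2), 10, 10),
               "non-increasing")
  expect_error(reconstruct_fixture(c(0.9, 0.5), c(1, 0.5), 10, 10), "start at 1")
  # rounding that cannot hit the class size exactly
  expect_error(reconstruct_fixture(c(1, 0.5), c(1, 0.5), 3, 10), "sum to")
})

test_that("a constant survivor function lumps everyone at the top score", {
  d <- reconstruct_fixture(c(1, 1, 1), c(1, 1, 1), 5, 4, cuts = 0:2)
  expect_true(all(d$score == 2))
  expect_equal(nrow(d), 9)
})

test_that("the cut-point table reproduces every published cell at 2-dp percent", {
  published <- data.frame(
    cut = 0:8,
    sens = c(100.00, 98.72, 94.87, 92.31, 79.49, 61.54, 35.90, 23.08, 11.54),
    spec = c(0.00, 30.00, 50.00, 67.50, 80.00, 90.00, 92.50, 92.50, 95.00),
    acc = c(66.10, 75.42, 79.66, 83.90, 79.66, 71.19, 55.08, 46.61, 39.83)
  )
  expect_equal(round(100 * fx_tab$sensitivity, 2), published$sens)
  expect_equal(round(100 * fx_tab$specificity, 2), published$spec)
  expect_equal(round(100 * fx_tab$correctly_classified, 2), published$acc)
  expect_equal(fx_tab$correctly_classified,
               (fx_tab$tp + fx_tab$tn) / 118)
})

test_that("exact binomial CIs match the reported sensitivity interval shape", {
  # 72/78 at the >=3 cut: reported as 92% (84%-97%)
  row3 <- fx_tab[fx_tab$cut == 3, ]
  expect_equal(row3$tp, 72)
  expect_equal(round(100 * c(row3$sens_lo, row3$sens_hi)), c(84, 97))
  ci <- binom.test(72, 78)$conf.int
  expect_equal(c(row3$sens_lo, row3$sens_hi), as.numeric(ci))
})

test_that("sensitivity is non-increasing and specificity non-decreasing in the cut", {
  set.seed(21)
  for (i in 1:50) {
    d <- random_labeled_scores(sample(3:40, 1), sample(3:40, 1))
    tab <- cutpoint_table(d)
    expect_true(all(diff(tab$sensitivity) <= 1e-12))
    expect_true(all(diff(tab$specificity) >= -1e-12))
    expect_equal(tab$sensitivity[1], 1)
    expect_equal(tab$specificity[1], 0)
    expect_equal(tab$sensitivity[nrow(tab)], 0)
  }
})

test_that("single-class input raises a degenerate-input error", {
  d <- data.frame(score = 1:5, tfc_high = TRUE)
  expect_error(cutpoint_table(d), "degenerate")
  expect_error(empirical_auc(d), "degenerate")
})

test_that("cut-point policies pick the published operating points", {
  expect_equal(select_cutpoint(fx_tab, "max_accuracy")$cut, 3)
  expect_equal(select_cutpoint(fx_tab, "balanced")$cut, 4)
  # J = 0.5981 at cut 3 vs 0.5949 at cut 4: Youden narrowly prefers 3
  expect_equal(select_cutpoint(fx_tab, "youden")$cut, 3)
  one <- fx_tab[3, ]
  expect_equal(select_cutpoint(one, "balanced")$cut, one$cut)
  expect_error(select_cutpoint(fx_tab[0, ], "balanced"), "empty")
})

test_that("pair-counting AUC equals trapezoidal area and the brute-force oracle", {
  expect_equal(empirical_auc(fx), attr(fx_tab, "auc"), tolerance = 1e-12)
  expect_equal(empirical_auc(fx), brute_force_auc(fx$score, fx$tfc_high),
               tolerance = 1e-12)
  # degenerate shapes
  sep <- data.frame(score = c(5, 5, 0, 0), tfc_high = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(empirical_auc(sep), 1)
  tied <- data.frame(score = rep(3, 6), tfc_high = rep(c(TRUE, FALSE), 3))
  expect_equal(empirical_auc(tied), 0.5)
})

test_that("dichotomized AUC is (sensitivity + specificity) / 2", {
  expect_equal(dichotomized_auc(fx_tab, 3), (0.9230769230769231 + 0.675) / 2)
  perfect <- cutpoint_table(data.frame(score = c(5, 5, 0, 0),
                                       tfc_high = c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(dichotomized_auc(perfect, 3), 1)
  expect_equal(dichotomized_auc(fx_tab, 0), 0.5)  # everyone positive
  expect_error(dichotomized_auc(fx_tab, 99), "not in the table")
})

test_that("cross-validation is reproducible and stratified", {
  a <- cv_auc(fx, n_folds = 10, cut = 3, seed = 42, n_repeats = 5)
  b <- cv_auc(fx, n_folds = 10, cut = 3, seed = 42, n_repeats = 5)
  expect_identical(a, b)
  expect_length(a$fold_aucs, 50)
  expect_true(a$mean_auc >= 0 && a$mean_auc <= 1)
  c2 <- cv_auc(fx, n_folds = 10, cut = 3, seed = 43, n_repeats = 5)
  expect_false(identical(a$fold_aucs, c2$fold_aucs))
})

test_that("perfectly separated data cross-validate to AUC 1 for both modes", {
  d <- data.frame(score = rep(c(8, 0), c(20, 20)),
                  tfc_high = rep(c(TRUE, FALSE), c(20, 20)))
  expect_equal(cv_auc(d, n_folds = 5, cut = 3, seed = 1)$mean_auc, 1)
  expect_equal(cv_auc(d, n_folds = 5, cut = NULL, seed = 1)$mean_auc, 1)
})

test_that("folds holding a single class are excluded with a warning", {
  d <- data.frame(score = c(5, 0, 1, 2), tfc_high = c(TRUE, FALSE, FALSE, FALSE))
  expect_warning(cv <- cv_auc(d, n_folds = 4, cut = 3, seed = 1), "single class")
  expect_true(sum(is.na(cv$fold_aucs)) >= 3)
  expect_false(is.na(cv$mean_auc))
})

test_that("cv of a dichotomized fixed rule concentrates at (sens+spec)/2", {
  cv <- cv_auc(fx, n_folds = 10, cut = 3, seed = 99, n_repeats = 500)
  expect_equal(cv$mean_auc, dichotomized_auc(fx_tab, 3), tolerance = 0.03)
})
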