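test_that("confusion counts agree with double-loop counting on random masks", {
  withr::with_seed(4, {
    pred <- matrix(rbinom(400, 1, 0.4), 20, 20)
    truth <- matrix(rbinom(400, 1, 0.3), 20, 20)
    valid <- matrix(runif(400) > 0.1, 20, 20)
  })
  cc <- confusion(pred, truth, valid)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:20) for (j in 1:20) {
    if (!valid[i, j]) next
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1L
    if (pred[i, j] == 0 && truth[i, j] == 0) tn <- tn + 1L
    if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1L
    if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1L
  }
  expect_equal(cc, list(TP = tp, TN = tn, FP = fp, FN = fn))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, sum(valid))
  expect_error(confusion(pred, truth[1:10, ]), "shapes differ")
  # degenerate agreement cases
  perfect <- confusion(truth, truth)
  expect_equal(perfect$FP + perfect$FN, 0L)
  inverted <- confusion(1L - truth, truth)
  expect_equal(inverted$TP + inverted$TN, 0L)
})

test_that("metrics match the defining formulas and handle zero denominators", {
  m <- metrics(list(TP = 2, FP = 1, FN = 1, TN = 6))
  expect_equal(unname(m["dice"]), 2 / 3)
  expect_equal(unname(m["sensitivity"]), 2 / 3)
  expect_equal(unname(m["specificity"]), 6 / 7)
  expect_equal(unname(m["accuracy"]), 0.8)
  perfect <- metrics(list(TP = 5, FP = 0, FN = 0, TN = 10))
  expect_true(all(perfect == 1))
  zero <- metrics(list(TP = 0, FP = 2, FN = 3, TN = 5))
  expect_equal(unname(zero["dice"]), 0)
  expect_equal(unname(zero["sensitivity"]), 0)
  nosig <- metrics(list(TP = 0, FP = 0, FN = 0, TN = 5))
  expect_true(is.na(nosig["dice"]))
})

test_that("metrics agree with brute force on 1000 random confusion tables", {
  withr::with_seed(10, {
    tab <- matrix(rpois(4000, 8), ncol = 4)
  })
  for (k in seq_len(nrow(tab))) {
    tp <- tab[k, 1]; tn <- tab[k, 2]; fp <- tab[k, 3]; fn <- tab[k, 4]
    if (tp + tn + fp + fn == 0) next
    m <- metrics(list(TP = tp, TN = tn, FP = fp, FN = fn))
    if (tp + fn > 0) expect_identical(unname(m["sensitivity"]), tp / (tp + fn))
    if (tn + fp > 0) expect_identical(unname(m["specificity"]), tn / (tn + fp))
    if (2 * tp + fp + fn > 0)
      expect_identical(unname(m["dice"]), 2 * tp / (2 * tp + fp + fn))
    expect_identical(unname(m["accuracy"]), (tp + tn) / (tp + tn + fp + fn))
  }
})

test_that("dice is FP/FN-symmetric and sensitivity monotone in TP", {
  withr::with_seed(2, {
    for (i in 1:50) {
      tp <- rpois(1, 5) + 1; fp <- rpois(1, 5); fn <- rpois(1, 5)
      a <- metrics(list(TP = tp, TN = 3, FP = fp, FN = fn))["dice"]
      b <- metrics(list(TP = tp, TN = 3, FP = fn, FN = fp))["dice"]
      expect_equal(unname(a), unname(b))
      s1 <- metrics(list(TP = tp, TN = 3, FP = fp, FN = fn))["sensitivity"]
      s2 <- metrics(list(TP = tp + 2, TN = 3, FP = fp, FN = fn))["sensitivity"]
      expect_gte(unname(s2), unname(s1))
    }
  })
})

test_that("the 698-vs-730 frame agreement worked example reproduces 4.4%", {
  auto <- seq_len(698)
  manual <- seq_len(730)
  r <- frame_presence_agreement(auto, manual, 2812L)
  expect_equal(round(r$percent_difference, 1), 4.4)
  same <- frame_presence_agreement(1:50, 1:50, 100L)
  expect_equal(same$percent_difference, 0)
  plus1 <- frame_presence_agreement(1:101, 1:100, 500L)
  expect_equal(plus1$percent_difference, 1.0)
  expect_equal(plus1$fp_frac_manual, 0.01)
  undef <- frame_presence_agreement(1:3, integer(0), 10L)
  expect_true(is.na(undef$percent_difference))
})

test_that("122 segments split into five grouped subsets of 23-25", {
  ids <- sprintf("seg%03d", 1:122)
  folds <- make_folds(ids, seed = 1L)
  sizes <- sort(unname(vapply(attr(folds, "subsets"), length, integer(1))))
  expect_equal(sizes, c(24L, 24L, 24L, 25L, 25L))
  # each segment tests exactly once; roles never overlap within a fold
  tested <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tested, ids)
  expect_equal(length(tested), 122L)
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  expect_identical(make_folds(ids, seed = 1L), folds)
  expect_false(identical(make_folds(ids, seed = 2L), folds))
  expect_error(make_folds(ids[1:4]), "at least 5")
})

test_that("observer agreement reproduces regression and Bland-Altman identities", {
  a <- c(1.0, 1.5, 2.1, 0.7, 1.9, 2.4)
  same <- observer_agreement(a, a)
  expect_equal(same$r_squared, 1)
  expect_equal(same$bias, 0)
  expect_equal(same$area_dice, 1)
  expect_equal(same$loa, c(0, 0))
  off <- observer_agreement(a, a + 0.1)
  expect_equal(off$bias, -0.1)
  expect_equal(off$loa, c(-0.1, -0.1))
  withr::with_seed(8, {
    x <- runif(20, 0.5, 2)
    y <- 0.9 * x + rnorm(20, 0, 0.1)
  })
  r <- observer_agreement(x, y)
  fit <- lm(y ~ x)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(r$r_squared, 1 - ss_res / ss_tot)
  expect_equal(r$bias, mean(x - y))
  expect_error(observer_agreement(x, y[1:10]), "length")
})

test_that("the paired t-test matches hand arithmetic and is shift-invariant", {
  x <- c(5, 6, 7, 8)
  same <- paired_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # d = {1, 2, 3}: t = mean / (sd / sqrt(n)) = 2 / (1 / sqrt(3)) = 2 sqrt(3)
  r <- paired_ttest(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  r2 <- paired_ttest(c(2, 4, 6) + 100, c(1, 2, 3) + 100)
  expect_equal(r2$t, r$t)
  expect_equal(r2$p, r$p)
})

test_that("fold aggregation reports mean and sd, skipping undefined entries", {
  fm <- rbind(c(dice = 0.7, sens = 0.8), c(dice = 0.9, sens = NA))
  agg <- aggregate_folds(fm)
  expect_equal(agg$mean[agg$metric == "dice"], 0.8)
  expect_equal(agg$mean[agg$metric == "sens"], 0.8)
  expect_equal(agg$sd[agg$metric == "dice"], sd(c(0.7, 0.9)))
})
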