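# Pixel/candidate/frame-level evaluation: confusion counts over valid
# pixels; sensitivity, specificity, accuracy and Dice; frame-level presence
# agreement; segment-grouped five-fold cross-validation splits; and
# observer-agreement statistics (linear regression, Bland-Altman, area
# Dice). Standard statistics (lm, t.test) come from base R.

#' Confusion counts between predicted and true masks
#'
#' Counts are restricted to valid pixels; TP+TN+FP+FN equals the valid
#' count.
#'
#' @param pred,truth binary matrices (or arrays) of identical shape.
#' @param valid logical mask of the same shape (default: all valid).
#' @return list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(pred, truth, valid = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  if (is.null(valid)) valid <- array(TRUE, dim(pred))
  if (!identical(dim(valid), dim(pred)))
    stop("valid mask shape differs")
  p <- pred[valid] > 0
  t <- truth[valid] > 0
  list(TP = sum(p & t), TN = sum(!p & !t),
       FP = sum(p & !t), FN = sum(!p & t))
}

#' Segmentation metrics from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `accuracy = (TP+TN)/total`, `Dice = 2TP/(2TP+FP+FN)`. A metric with an
#' undefined (zero) denominator is returned as `NA` so aggregation can
#' exclude it; Dice is 0 when TP = 0 with disagreements present.
#'
#' @param c confusion counts from [confusion()].
#' @return named numeric vector (dice, sensitivity, specificity, accuracy).
#' @export
metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("empty confusion table")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  c(dice = rat(2 * c$TP, 2 * c$TP + c$FP + c$FN),
    sensitivity = rat(c$TP, c$TP + c$FN),
    specificity = rat(c$TN, c$TN + c$FP),
    accuracy = (c$TP + c$TN) / total)
}

#' Frame-level presence agreement
#'
#' Percent difference between the automated and manual counts of
#' microvessel-positive frames, relative to the manual count, plus the
#' false-positive/false-negative frame sets as fractions of the manual
#' count and of all frames.
#'
#' @param auto_frames,manual_frames integer vectors of positive frame
#'   indices.
#' @param total_frames number of frames evaluated.
#' @return list with `percent_difference`, `fp_frac_manual`,
#'   `fn_frac_manual`, `fp_frac_total`, `fn_frac_total`.
#' @export
frame_presence_agreement <- function(auto_frames, manual_frames,
                                     total_frames) {
  auto_frames <- unique(auto_frames); manual_frames <- unique(manual_frames)
  n_m <- length(manual_frames); n_a <- length(auto_frames)
  if (n_m == 0)
    return(list(percent_difference = NA_real_, fp_frac_manual = NA_real_,
                fn_frac_manual = NA_real_,
                fp_frac_total = length(setdiff(auto_frames, manual_frames)) /
                  total_frames,
                fn_frac_total = 0))
  fp <- length(setdiff(auto_frames, manual_frames))
  fn <- length(setdiff(manual_frames, auto_frames))
  list(percent_difference = abs(n_m - n_a) / n_m * 100,
       fp_frac_manual = fp / n_m, fn_frac_manual = fn / n_m,
       fp_frac_total = fp / total_frames, fn_frac_total = fn / total_frames)
}

#' Segment-grouped five-fold cross-validation split
#'
#' Segments are shuffled by seed into five near-equal subsets; each fold
#' takes one subset as test and splits the remaining segments ~82/18 into
#' train/validation (approximating 70/15/15 overall). Grouping is strictly
#' by segment: a segment never appears in two roles within a fold.
#'
#' @param segment_ids character vector of segment identifiers (>= 5).
#' @param seed shuffling seed.
#' @param val_frac validation fraction of the non-test segments.
#' @return list of 5 folds, each `list(train, val, test)` of segment ids,
#'   with the subset assignment in `attr(, "subsets")`.
#' @export
make_folds <- function(segment_ids, seed = 1L, val_frac = 0.18) {
  segment_ids <- as.character(segment_ids)
  n <- length(segment_ids)
  if (n < 5L) stop("need at least 5 segments for five folds")
  withr::with_seed(seed, {
    shuffled <- sample(segment_ids)
    # near-equal sizes: distribute the remainder over the last folds
    sizes <- rep(n %/% 5L, 5L) + c(rep(0L, 5L - n %% 5L),
                                   rep(1L, n %% 5L))
    subsets <- split(shuffled, rep(seq_len(5L), times = sizes))
    folds <- lapply(seq_len(5L), function(k) {
      test <- subsets[[k]]
      rest <- unlist(subsets[-k], use.names = FALSE)
      nv <- max(1L, round(val_frac * length(rest)))
      val <- sample(rest, nv)
      list(train = setdiff(rest, val), val = val, test = test)
    })
    attr(folds, "subsets") <- subsets
    folds
  })
}

#' Observer agreement between paired area measurements
#'
#' Least-squares line and R-squared of `second ~ first`; Bland-Altman mean
#' bias and limits of agreement `bias +/- 1.96 sd(d)` with
#' `d = first - second`; per-pair area Dice `2 min(a,b) / (a+b)` aggregated
#' as `2 sum(min) / sum(a+b)`.
#'
#' @param areas_first,areas_second paired area vectors (length >= 3).
#' @return list with `slope`, `intercept`, `r_squared`, `bias`, `loa`
#'   (length-2), `area_dice`.
#' @export
observer_agreement <- function(areas_first, areas_second) {
  if (length(areas_first) != length(areas_second))
    stop("paired lists differ in length")
  if (length(areas_first) < 3L) stop("need at least 3 pairs")
  fit <- stats::lm(areas_second ~ areas_first)
  d <- areas_first - areas_second
  bias <- mean(d)
  s <- stats::sd(d)
  ss_tot <- sum((areas_second - mean(areas_second))^2)
  r2 <- if (ss_tot == 0) NA_real_
        else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       area_dice = 2 * sum(pmin(areas_first, areas_second)) /
         sum(areas_first + areas_second))
}

#' Paired t-test
#'
#' Thin wrapper over `stats::t.test(..., paired = TRUE)`; zero-variance
#' differences are flagged with `NA` statistics rather than an error.
#'
#' @param x,y paired samples.
#' @return list with `t`, `p`, `df`.
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(x) - 1L,
                                 degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, df = length(x) - 1L,
                degenerate = TRUE))
  }
  r <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(r$statistic), p = r$p.value,
       df = unname(r$parameter), degenerate = FALSE)
}

#' Aggregate per-fold metrics as mean and standard deviation
#'
#' @param fold_metrics matrix or data frame, folds in rows, metrics in
#'   columns; `NA` entries (undefined denominators) are excluded.
#' @return data frame with metric, mean, sd.
#' @export
aggregate_folds <- function(fold_metrics) {
  m <- as.matrix(fold_metrics)
  data.frame(metric = colnames(m),
             mean = apply(m, 2, mean, na.rm = TRUE),
             sd = apply(m, 2, stats::sd, na.rm = TRUE),
             row.names = NULL)
}
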