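test_that("a noiseless step edge is recovered exactly on every A-line", {
  H <- 64L; W <- 120L
  fr <- matrix(0.02, H, W)
  fr[, 80:W] <- 0.8
  b <- segment_lumen(fr, catheter_radius_px = 8L)
  expect_true(all(b == 80L))
})

test_that("the baseline lumen detector tracks the phantom boundary within 3 px", {
  g <- tiny_phantom()
  errs <- vapply(c(1L, 4L, 8L, 12L), function(f) {
    b <- segment_lumen(g$pullback$data[f, , ],
                       g$scene$params$catheter_radius_px)
    mean(abs(b - g$scene$lumen_boundary[f, ]))
  }, numeric(1))
  expect_true(all(errs <= 3))
})

test_that("boundary continuity holds across the theta wrap", {
  g <- tiny_phantom()
  b <- segment_lumen(g$pullback$data[5, , ],
                     g$scene$params$catheter_radius_px, max_jump = 4L)
  steps <- abs(diff(c(b, b[1])))
  expect_true(all(steps <= 4L))
})

test_that("guidewire detection overlaps the true interval by at least 90%", {
  g <- tiny_phantom()
  H <- g$scene$params$alines_per_frame
  for (f in c(1L, 6L, 12L)) {
    fr <- g$pullback$data[f, , ]
    b <- segment_lumen(fr, g$scene$params$catheter_radius_px)
    gw <- detect_guidewire(fr, b)
    truth <- circ_interval(g$scene$guidewire$start[f],
                           g$scene$guidewire$len[f], H)
    got <- circ_interval(gw$start, gw$len, H)
    expect_gte(length(intersect(got, truth)) / length(truth), 0.9)
  }
})

test_that("a frame with no shadow yields an empty guidewire interval", {
  H <- 48L; W <- 80L
  fr <- matrix(0.5, H, W)
  b <- rep(10L, H)
  gw <- detect_guidewire(fr, b)
  expect_equal(gw$len, 0L)
})

test_that("a shadow straddling the theta wrap is detected as one interval", {
  H <- 64L; W <- 100L
  set.seed(5)
  fr <- matrix(0.6 + 0.05 * rnorm(H * W), H, W)
  b <- rep(10L, H)
  dark <- circ_interval(57L, 16L, H)   # rows 57..64 and 1..8
  fr[dark, 14:W] <- 0.02
  gw <- detect_guidewire(fr, b)
  got <- circ_interval(gw$start, gw$len, H)
  expect_gte(length(intersect(got, dark)) / length(dark), 0.9)
  expect_lte(gw$len, length(dark) + 4L)
})

test_that("pixel shifting matches its definition and is invertible on the valid mask", {
  # boundary all ones: identity shift (1-based boundary = first tissue column)
  fr <- matrix(runif(60), 6, 10)
  sh <- pixel_shift(fr, rep(1L, 6))
  expect_equal(sh$image, fr)
  # single row, boundary 5, depth 10: row = input[5:10] then 4 zeros
  r1 <- matrix(runif(10), 1, 10)
  sh1 <- pixel_shift(r1, 5L)
  expect_equal(sh1$image[1, ], c(r1[1, 5:10], rep(0, 4)))
  expect_equal(unname(sh1$valid[1, ]), c(rep(TRUE, 6), rep(FALSE, 4)))
  # shift then un-shift reproduces the input over the valid mask
  b <- sample(1:4, 6, replace = TRUE)
  sh2 <- pixel_shift(fr, b)
  back <- pixel_unshift(sh2)
  orig_valid <- pixel_unshift(list(image = sh2$valid * 1, offsets = b)) > 0
  expect_equal(back[orig_valid], fr[orig_valid])
})

test_that("ROI cropping keeps min(roi_depth, depth) columns", {
  fr360 <- matrix(runif(4 * 360), 4, 360)
  expect_equal(ncol(crop_roi(fr360, 300L)$image), 300L)
  fr200 <- matrix(runif(4 * 200), 4, 200)
  cr <- crop_roi(fr200, 300L)
  expect_equal(ncol(cr$image), 200L)
  expect_false(cr$padded)
  fr300 <- matrix(runif(4 * 300), 4, 300)
  expect_equal(crop_roi(fr300, 300L)$image, fr300)
})

test_that("Gaussian denoising is a normalized convolution with reflected borders", {
  # constant image unchanged
  const <- matrix(0.37, 9, 11)
  expect_equal(denoise(const), const, tolerance = 1e-6)
  # unit impulse reproduces the kernel, summing to 1
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- denoise(imp)
  expect_equal(sum(out), 1, tolerance = 1e-6)
  expect_equal(out[8, 8], max(out))
  # random frame equals the double-loop convolution oracle
  set.seed(11)
  fr <- matrix(runif(12 * 14), 12, 14)
  k <- 7L; half <- 3L; sigma <- 1
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  K <- outer(g, g); K <- K / sum(K)
  ref_idx <- function(i, n) {            # scipy-style mirror reflection
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  oracle <- matrix(0, 12, 14)
  for (i in 1:12) for (j in 1:14) {
    acc <- 0
    for (di in -half:half) for (dj in -half:half) {
      acc <- acc + K[di + half + 1, dj + half + 1] *
        fr[ref_idx(i + di, 12L), ref_idx(j + dj, 14L)]
    }
    oracle[i, j] <- acc
  }
  expect_equal(denoise(fr), oracle, tolerance = 1e-12)
  expect_error(denoise(fr, kernel = 6L), "odd")
})

test_that("the full chain keeps labels aligned with the true vessel regions", {
  g <- tiny_phantom()
  f <- ground_truth_frame_presence(g$scene)[1]
  pf <- preprocess_frame(g$pullback$data[f, , ],
                         catheter_radius_px =
                           g$scene$params$catheter_radius_px,
                         labels = g$labels$data[f, , ])
  expect_s3_class(pf, "preprocessed_frame")
  lab_px <- which(pf$labels > 0, arr.ind = TRUE)
  expect_gt(nrow(lab_px), 0)
  # map back through the stored offsets and verify against the raw labels
  for (k in seq_len(nrow(lab_px))) {
    a <- lab_px[k, 1]
    r <- lab_px[k, 2] + pf$lumen_offset[a] - 1L
    expect_equal(g$labels$data[f, a, r], 1L)
  }
})

test_that("guidewire blanking is exact and step order matters", {
  g <- tiny_phantom()
  fr <- g$pullback$data[3, , ]
  pf <- preprocess_frame(fr, catheter_radius_px =
                           g$scene$params$catheter_radius_px)
  gw_rows <- circ_interval(pf$guidewire_interval$start,
                           pf$guidewire_interval$len,
                           nrow(fr))
  expect_true(all(pf$image[gw_rows, ] == 0))
  expect_true(all(!pf$valid_mask[gw_rows, ]))
  # blanked pixels are exactly the interval columns plus the shift padding
  other <- setdiff(seq_len(nrow(fr)), gw_rows)
  pad_only <- !pf$valid_mask[other, , drop = FALSE]
  shifted_valid <- pixel_shift(fr, pf$lumen_offset)$valid[other, ,
                                                          drop = FALSE]
  expect_equal(pad_only, !shifted_valid[, seq_len(ncol(pf$image)),
                                        drop = FALSE])
  # denoise-before-shift is a different operator than the pipeline order
  sh <- pixel_shift(denoise(fr), segment_lumen(fr, 8L))$image
  pipeline <- denoise(pixel_shift(fr, segment_lumen(fr, 8L))$image)
  expect_false(isTRUE(all.equal(sh, pipeline)))
})

test_that("pre-processing is deterministic", {
  g <- tiny_phantom()
  a <- preprocess_frame(g$pullback$data[2, , ], catheter_radius_px = 8L)
  b <- preprocess_frame(g$pullback$data[2, , ], catheter_radius_px = 8L)
  expect_identical(a, b)
})
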