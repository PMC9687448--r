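test_that("disjoint squares become separate blobs with exact areas and boxes", {
  m <- matrix(0L, 12, 12)
  m[2:3, 2:3] <- 1L
  m[8:9, 7:8] <- 1L
  blobs <- extract_blobs(m)
  expect_length(blobs, 2L)
  expect_equal(vapply(blobs, `[[`, numeric(1), "area_px"), c(4, 4))
  b1 <- blobs[[1]]
  expect_equal(unname(b1$box), c(2, 3, 2, 3))
  expect_length(extract_blobs(matrix(0L, 5, 5)), 0L)
  # optional area gate (off by default)
  expect_length(extract_blobs(m, min_area_px = 5L), 0L)
  expect_length(extract_blobs(m, min_area_px = 4L), 2L)
})

test_that("a blob split across the theta edge is a single component", {
  m <- matrix(0L, 10, 8)
  m[c(10, 1), 3:5] <- 1L          # rows 10 and 1 are circular neighbours
  blobs <- extract_blobs(m)
  expect_length(blobs, 1L)
  expect_equal(blobs[[1]]$area_px, 6)
})

test_that("connected components match the flood-fill oracle on random masks", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- matrix(rbinom(30 * 20, 1, 0.25), 30, 20)
    })
    blobs <- extract_blobs(m)
    oracle <- flood_fill_components(m)
    expect_equal(length(blobs), max(oracle))
    # identical pixel partitions
    got <- lapply(blobs, function(b) sort((b$pixels[, 2] - 1) * 30 +
                                            b$pixels[, 1]))
    want <- lapply(seq_len(max(oracle)), function(k) sort(which(oracle == k)))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("patches expand the box by 3 context pixels and resize to 30x30", {
  img <- matrix(runif(60 * 50), 60, 50)
  pf <- list(image = img)
  m <- matrix(0L, 60, 50)
  m[20:29, 15:20] <- 1L            # 10 x 6 box -> 16 x 12 crop
  b <- extract_blobs(m)[[1]]
  p <- make_patch(b, pf)
  expect_s3_class(p, "candidate_patch")
  expect_equal(dim(p$image), c(30L, 30L))
  # a 24x24 box gives exactly a 30x30 crop: the resize is the identity
  m2 <- matrix(0L, 60, 50)
  m2[10:33, 10:33] <- 1L
  b2 <- extract_blobs(m2)[[1]]
  p2 <- make_patch(b2, pf)
  expect_equal(p2$image, img[7:36, 7:36], tolerance = 1e-12)
})

test_that("the blob centroid lands at the patch center within a pixel", {
  img <- matrix(runif(80 * 60), 80, 60)
  m <- matrix(0L, 80, 60)
  m[40:47, 30:35] <- 1L
  b <- extract_blobs(m)[[1]]
  # the centroid sits at the box center, so after crop + resize it maps to
  # the patch center by construction of the symmetric 3-px padding
  box_center <- c((b$box["aline_min"] + b$box["aline_max"]) / 2,
                  (b$box["r_min"] + b$box["r_max"]) / 2)
  expect_equal(unname(abs(box_center - b$centroid)), c(0, 0),
               tolerance = 1)
})

test_that("the classifier has 3 conv, 2 pool and 1 FC layer and a closed-form parameter count", {
  m <- build_classifier()
  types <- vapply(m$layers, `[[`, character(1), "type")
  expect_equal(sum(types == "conv"), 3L)
  expect_equal(sum(types == "maxpool"), 2L)
  expect_equal(sum(types == "fc"), 1L)
  # filters 8/16/32 of size 3x3, BN (gamma+beta) after each conv, FC 32->2
  expected <- (3 * 3 * 1 * 8) + 2 * 8 +
              (3 * 3 * 8 * 16) + 2 * 16 +
              (3 * 3 * 16 * 32) + 2 * 32 +
              (32 * 2 + 2)
  expect_equal(n_params(m), expected)
})

test_that("classifier probabilities are a softmax over two units", {
  m <- build_classifier(seed = 2L)
  p <- predict_patches(m, list(matrix(runif(900), 30, 30),
                               matrix(runif(900), 30, 30)))
  expect_equal(dim(p), c(2L, 2L))
  expect_equal(unname(rowSums(p)), c(1, 1), tolerance = 1e-6)
})

test_that("training rejects single-class sets and is seed-reproducible", {
  withr::with_seed(7, {
    pos <- lapply(1:4, function(i) {
      p <- matrix(runif(900, 0.4, 0.6), 30, 30); p[12:18, 12:18] <- 0.05; p
    })
    neg <- lapply(1:4, function(i) matrix(runif(900, 0.4, 0.6), 30, 30))
  })
  expect_error(train_classifier(build_classifier(), pos, rep(1L, 4)),
               "both classes")
  tc <- train_config(max_epochs = 2L, drop_period = 5, batch_size = 8L,
                     seed = 3L)
  f1 <- train_classifier(build_classifier(seed = 1L), c(pos, neg),
                         c(rep(1L, 4), rep(0L, 4)), tc)
  f2 <- train_classifier(build_classifier(seed = 1L), c(pos, neg),
                         c(rep(1L, 4), rep(0L, 4)), tc)
  expect_identical(f1$history, f2$history)
  p1 <- predict_patches(f1$model, pos)
  p2 <- predict_patches(f2$model, pos)
  expect_identical(p1, p2)
})

test_that("filtering removes exactly the rejected blobs and never adds pixels", {
  img <- matrix(runif(40 * 30), 40, 30)
  pf <- list(image = img)
  m <- matrix(0L, 40, 30)
  m[5:8, 5:8] <- 1L
  m[20:24, 12:15] <- 1L
  m[33:35, 22:24] <- 1L
  blobs <- extract_blobs(m)
  clf <- build_classifier(seed = 9L)
  fc <- filter_candidates(m, blobs, clf, pf, threshold = 0.5)
  expect_true(all(fc$mask <= m))               # cleaned subset of original
  kept <- fc$decisions$kept
  kept_px <- as.integer(sort(unlist(lapply(which(kept), function(i)
    (blobs[[i]]$pixels[, 2] - 1) * 40 + blobs[[i]]$pixels[, 1]))))
  expect_equal(sort(which(fc$mask > 0)), kept_px)
  # degenerate thresholds: keep everything / reject everything
  all_keep <- filter_candidates(m, blobs, clf, pf, threshold = 0)
  expect_equal(all_keep$mask, m)
  none <- filter_candidates(m, blobs, clf, pf, threshold = 1.0000001)
  expect_true(all(none$mask == 0L))
  empty <- filter_candidates(matrix(0L, 4, 4), list(), clf, pf)
  expect_equal(nrow(empty$decisions), 0L)
})
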