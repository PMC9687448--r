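test_that("the network maps any input to same-size two-class scores", {
  m <- build_segnet(seg_model_config(input_dims = c(64L, 48L)), seed = 1L)
  x <- octovessel:::seg_input(m, matrix(runif(64 * 48), 64, 48))
  fw <- octovessel:::seg_forward(m, x)
  expect_equal(dim(fw$logits), c(64L, 48L, 2L, 1L))
  # odd, stride-incompatible dims still come back at input size
  x2 <- octovessel:::seg_input(m, matrix(runif(37 * 45), 37, 45))
  fw2 <- octovessel:::seg_forward(m, x2)
  expect_equal(dim(fw2$logits), c(37L, 45L, 2L, 1L))
})

test_that("two builds with the same seed share identical initial parameters", {
  a <- build_segnet(seed = 42L)
  b <- build_segnet(seed = 42L)
  expect_identical(a$layers, b$layers)
  c <- build_segnet(seed = 43L)
  expect_false(identical(a$layers$stem_conv$params$W,
                         c$layers$stem_conv$params$W))
})

test_that("the analytic receptive field covers the default desk frame", {
  m <- build_segnet(seg_model_config(input_dims = c(256L, 200L)))
  expect_gte(receptive_field(m), 256L)
  # recurrence verified on a hand-computed configuration: stem (k3 s2),
  # two depthwise stages (k3 s2), ASPP rate 1 at stride 8 (1 ->3 ->7 ->15
  # ->31), then 3x3 decoder convs at strides 4 and 2 (+8 +4) = 43
  m1 <- build_segnet(seg_model_config(aspp_dilation_rates = c(1L, 1L, 1L)))
  expect_equal(receptive_field(m1), 43L)
})

test_that("inverse-median-frequency weights match hand arithmetic", {
  expect_equal(unname(class_weights(c(0.8, 0.2))), c(0.625, 2.5))
  expect_equal(unname(class_weights(c(0.5, 0.5))), c(1, 1))
  w <- unname(class_weights(c(0.99, 0.01)))
  expect_equal(w, c(0.5 / 0.99, 50))
  expect_error(class_weights(c(1, 0)), "present")
})

test_that("balanced class weights reduce the loss to unweighted cross-entropy", {
  set.seed(3)
  logits <- array(rnorm(6 * 5 * 2), c(6, 5, 2, 1))
  labels <- array(rbinom(30, 1, 0.5), c(6, 5, 1))
  mask <- array(TRUE, c(6, 5, 1))
  a <- octovessel:::seg_loss(logits, labels, mask, c(1, 1))
  p <- octovessel:::softmax2(logits[, , 1, 1], logits[, , 2, 1])
  py <- ifelse(labels[, , 1] == 1, p$p2, p$p1)
  expect_equal(a$loss, -mean(log(py)))
})

test_that("the learning rate follows the 0.001 x 0.2 stepped schedule", {
  tc <- train_config(drop_period = 1)
  expect_equal(vapply(0:3, function(e) lr_at(tc, e), numeric(1)),
               c(1e-3, 2e-4, 4e-5, 8e-6))
  # fractional drop period: two drops per epoch
  tc2 <- train_config(drop_period = 0.5)
  expect_equal(lr_at(tc2, 0), 1e-3)
  expect_equal(lr_at(tc2, 0.5), 2e-4)
  expect_equal(lr_at(tc2, 1.0), 4e-5)
})

test_that("early stopping fires after five non-improving epochs on a stubbed loss", {
  # validation loss improves through epoch 3, then freezes
  stub <- c(1.0, 0.8, 0.6, rep(0.6, 10))
  tr <- es_tracker(patience = 5L, min_rel_improve = 1e-4)
  stopped_at <- NA_integer_
  for (e in seq_along(stub)) {
    tr <- es_update(tr, stub[e])
    if (tr$stop) { stopped_at <- e; break }
  }
  expect_equal(stopped_at, 8L)
  # an improvement below 0.01% does not reset the counter
  tr2 <- es_tracker()
  for (l in c(1, 1 - 5e-6, 1 - 1e-5, 1 - 2e-5, 1 - 3e-5, 1 - 4e-5))
    tr2 <- es_update(tr2, l)
  expect_true(tr2$stop)
})

test_that("a short training run is reproducible and decreases the loss", {
  g <- tiny_phantom()
  pfs <- lapply(1:6, function(f)
    preprocess_frame(g$pullback$data[f, , ], catheter_radius_px = 8L,
                     labels = g$labels$data[f, , ]))
  frames <- lapply(pfs, `[[`, "image")
  labels <- lapply(pfs, `[[`, "labels")
  masks <- lapply(pfs, `[[`, "valid_mask")
  tc <- train_config(max_epochs = 2L, drop_period = 5, batch_size = 2L,
                     seed = 5L)
  m0 <- build_segnet(seg_model_config(input_dims = dim(frames[[1]])),
                     seed = 5L)
  f1 <- train_segmenter(m0, frames, labels, masks, tc, val_idx = 1L)
  f2 <- train_segmenter(m0, frames, labels, masks, tc, val_idx = 1L)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$train_loss[2], f1$history$train_loss[1])
  expect_error(train_segmenter(m0, list(), list(), list(), tc), "empty")
})

test_that("predicted masks share the input raster and respect the valid mask", {
  g <- tiny_phantom()
  pf <- preprocess_frame(g$pullback$data[1, , ], catheter_radius_px = 8L)
  m <- build_segnet(seg_model_config(input_dims = dim(pf$image)), seed = 1L)
  mask <- predict_mask(m, pf)
  expect_identical(dim(mask), dim(pf$image))
  expect_true(all(mask[!pf$valid_mask] == 0L))
})

test_that("saliency maps are input-sized, normalized and quiet over blanked pixels", {
  g <- tiny_phantom()
  pf <- preprocess_frame(g$pullback$data[2, , ], catheter_radius_px = 8L)
  m <- build_segnet(seg_model_config(input_dims = dim(pf$image)), seed = 2L)
  s <- saliency_map(m, pf)
  expect_identical(dim(s), dim(pf$image))
  expect_gte(min(s), 0); expect_lte(max(s), 1)
})
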