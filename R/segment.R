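# Atrous/ASPP encoder-decoder semantic segmentation of microvessel
# candidates. The encoder is a scaled separable-convolution (depthwise +
# pointwise) stack reaching output stride 8; an ASPP block merges three
# dilation rates plus an image-level pooling branch; the decoder fuses a
# stride-4 skip connection and restores full resolution with bilinear
# upsampling of the logits, so the output raster always equals the input
# raster. Batch normalization and ReLU follow every convolution. The top
# dilation rate is chosen so the analytic receptive field covers the whole
# pre-processed frame.

#' Segmentation model configuration
#'
#' @param input_dims `c(alines, depth)` the model will mostly see (used only
#'   to auto-size the top ASPP dilation so the receptive field covers the
#'   frame; the network itself accepts any input size).
#' @param base_channels channels of the stem; stages use 2x and 4x this.
#' @param aspp_dilation_rates three dilation rates; `NULL` auto-selects
#'   `c(6, 12, r)` with `r` large enough for full-frame receptive field.
#' @param aspp_channels channels per ASPP branch.
#' @param depth_channel concatenate a normalized radial-coordinate channel
#'   to the input. Tissue brightness decays exponentially with depth, so
#'   "dark for its depth" is the discriminative cue; a full-scale backbone
#'   can infer depth from global context, and this channel hands the same
#'   information to the scaled-down network directly.
#' @return a `seg_model_config` list.
#' @export
seg_model_config <- function(input_dims = c(256L, 200L),
                             base_channels = 8L,
                             aspp_dilation_rates = NULL,
                             aspp_channels = 16L,
                             depth_channel = TRUE) {
  if (is.null(aspp_dilation_rates)) {
    # RF after the stride-8 encoder is 15 px; one dilated 3x3 adds 16r
    r_top <- max(12L, ceiling((max(input_dims) - 15) / 16))
    aspp_dilation_rates <- c(4L, 8L, as.integer(r_top))
  }
  structure(list(input_dims = as.integer(input_dims),
                 base_channels = as.integer(base_channels),
                 aspp_dilation_rates = as.integer(aspp_dilation_rates),
                 aspp_channels = as.integer(aspp_channels),
                 depth_channel = isTRUE(depth_channel),
                 output_stride = 8L),
            class = "seg_model_config")
}

#' Build the segmentation network
#'
#' @param config a [seg_model_config()].
#' @param seed seed for the parameter initialization; two builds with the
#'   same seed have identical initial parameters.
#' @return a `seg_model` (layers plus architecture metadata).
#' @export
build_segnet <- function(config = seg_model_config(), seed = 1L) {
  b <- config$base_channels
  c1 <- 2L * b; c2 <- 4L * b
  ca <- config$aspp_channels
  r <- config$aspp_dilation_rates
  cin <- 1L + config$depth_channel
  withr::with_seed(seed, {
    layers <- list(
      stem_conv = nn_conv(3L, 3L, cin, b, stride = 2L),
      stem_bn = nn_bn(b), stem_relu = nn_relu(),
      enc1_dw = nn_dwconv(3L, b, stride = 2L),
      enc1_dwbn = nn_bn(b), enc1_dwrelu = nn_relu(),
      enc1_pw = nn_conv(1L, 1L, b, c1),
      enc1_bn = nn_bn(c1), enc1_relu = nn_relu(),
      enc2_dw = nn_dwconv(3L, c1, stride = 2L),
      enc2_dwbn = nn_bn(c1), enc2_dwrelu = nn_relu(),
      enc2_pw = nn_conv(1L, 1L, c1, c2),
      enc2_bn = nn_bn(c2), enc2_relu = nn_relu(),
      aspp0 = nn_conv(1L, 1L, c2, ca),
      aspp0_bn = nn_bn(ca), aspp0_relu = nn_relu(),
      aspp1_dw = nn_dwconv(3L, c2, dilation = r[1]),
      aspp1_dwbn = nn_bn(c2), aspp1_dwrelu = nn_relu(),
      aspp1_pw = nn_conv(1L, 1L, c2, ca),
      aspp1_bn = nn_bn(ca), aspp1_relu = nn_relu(),
      aspp2_dw = nn_dwconv(3L, c2, dilation = r[2]),
      aspp2_dwbn = nn_bn(c2), aspp2_dwrelu = nn_relu(),
      aspp2_pw = nn_conv(1L, 1L, c2, ca),
      aspp2_bn = nn_bn(ca), aspp2_relu = nn_relu(),
      aspp3_dw = nn_dwconv(3L, c2, dilation = r[3]),
      aspp3_dwbn = nn_bn(c2), aspp3_dwrelu = nn_relu(),
      aspp3_pw = nn_conv(1L, 1L, c2, ca),
      aspp3_bn = nn_bn(ca), aspp3_relu = nn_relu(),
      aspp_img = nn_imgpool(c2, ca),
      proj = nn_conv(1L, 1L, 5L * ca, c2),
      proj_bn = nn_bn(c2), proj_relu = nn_relu(),
      skip_pw = nn_conv(1L, 1L, c1, b),
      skip_bn = nn_bn(b), skip_relu = nn_relu(),
      dec_conv = nn_conv(3L, 3L, c2 + b, c1),
      dec_bn = nn_bn(c1), dec_relu = nn_relu(),
      skip2_pw = nn_conv(1L, 1L, b, b),
      skip2_bn = nn_bn(b), skip2_relu = nn_relu(),
      dec2_conv = nn_conv(3L, 3L, c1 + b, b),
      dec2_bn = nn_bn(b), dec2_relu = nn_relu(),
      head = nn_conv(1L, 1L, b, 2L, bias = TRUE))
    structure(list(layers = layers, config = config, seed = seed),
              class = "seg_model")
  })
}

seg_chains <- function() list(
  stem = c("stem_conv", "stem_bn", "stem_relu"),
  enc1 = c("enc1_dw", "enc1_dwbn", "enc1_dwrelu",
           "enc1_pw", "enc1_bn", "enc1_relu"),
  enc2 = c("enc2_dw", "enc2_dwbn", "enc2_dwrelu",
           "enc2_pw", "enc2_bn", "enc2_relu"),
  aspp0 = c("aspp0", "aspp0_bn", "aspp0_relu"),
  aspp1 = c("aspp1_dw", "aspp1_dwbn", "aspp1_dwrelu",
            "aspp1_pw", "aspp1_bn", "aspp1_relu"),
  aspp2 = c("aspp2_dw", "aspp2_dwbn", "aspp2_dwrelu",
            "aspp2_pw", "aspp2_bn", "aspp2_relu"),
  aspp3 = c("aspp3_dw", "aspp3_dwbn", "aspp3_dwrelu",
            "aspp3_pw", "aspp3_bn", "aspp3_relu"),
  proj = c("proj", "proj_bn", "proj_relu"),
  skip = c("skip_pw", "skip_bn", "skip_relu"),
  dec = c("dec_conv", "dec_bn", "dec_relu"),
  skip2 = c("skip2_pw", "skip2_bn", "skip2_relu"),
  dec2 = c("dec2_conv", "dec2_bn", "dec2_relu"),
  head = "head")

seg_forward <- function(model, x, train = FALSE) {
  L <- model$layers
  ch <- seg_chains()
  run <- function(name, input) seq_forward(L[ch[[name]]], input, train)
  cc <- list()
  cc$stem <- run("stem", x)
  cc$enc1 <- run("enc1", cc$stem$y)
  cc$enc2 <- run("enc2", cc$enc1$y)
  f4 <- cc$enc2$y
  cc$aspp0 <- run("aspp0", f4)
  cc$aspp1 <- run("aspp1", f4)
  cc$aspp2 <- run("aspp2", f4)
  cc$aspp3 <- run("aspp3", f4)
  cc$img <- nn_forward(L$aspp_img, f4, train)
  merged <- concat_channels(cc$aspp0$y, cc$aspp1$y, cc$aspp2$y,
                            cc$aspp3$y, cc$img$y)
  cc$proj <- run("proj", merged)
  d2 <- dim(cc$enc1$y)
  cc$up1 <- nn_resize(cc$proj$y, d2[1], d2[2])
  cc$skip <- run("skip", cc$enc1$y)
  fused <- concat_channels(cc$up1$y, cc$skip$y)
  cc$dec <- run("dec", fused)
  d1 <- dim(cc$stem$y)
  cc$up15 <- nn_resize(cc$dec$y, d1[1], d1[2])
  cc$skip2 <- run("skip2", cc$stem$y)
  fused2 <- concat_channels(cc$up15$y, cc$skip2$y)
  cc$dec2 <- run("dec2", fused2)
  cc$head <- run("head", cc$dec2$y)
  dx <- dim(x)
  cc$up2 <- nn_resize(cc$head$y, dx[1], dx[2])  # x2 bilinear on the logits
  list(logits = cc$up2$y, caches = cc)
}

seg_backward <- function(model, caches, dlogits) {
  L <- model$layers
  ch <- seg_chains()
  grads <- stats::setNames(vector("list", length(L)), names(L))
  back <- function(name, cc, dy) {
    r <- seq_backward(L[ch[[name]]], cc$caches, dy)
    for (i in seq_along(ch[[name]]))
      grads[[ch[[name]][i]]] <<- r$grads[[i]]
    r$dx
  }
  dhead_in <- nn_resize_backward(caches$up2, dlogits)
  ddec2 <- back("head", caches$head, dhead_in)
  dfused2 <- back("dec2", caches$dec2, ddec2)
  p2 <- split_channels(dfused2, c(dim(caches$up15$y)[3],
                                  dim(caches$skip2$y)[3]))
  dstem_a <- back("skip2", caches$skip2, p2[[2]])
  ddec <- nn_resize_backward(caches$up15, p2[[1]])
  dfused <- back("dec", caches$dec, ddec)
  c2 <- dim(caches$up1$y)[3]
  parts <- split_channels(dfused, c(c2, dim(caches$skip$y)[3]))
  denc1_a <- back("skip", caches$skip, parts[[2]])
  dproj <- nn_resize_backward(caches$up1, parts[[1]])
  dmerged <- back("proj", caches$proj, dproj)
  ca <- dim(caches$aspp0$y)[3]
  mp <- split_channels(dmerged, rep(ca, 5))
  df4 <- back("aspp0", caches$aspp0, mp[[1]])
  df4 <- df4 + back("aspp1", caches$aspp1, mp[[2]])
  df4 <- df4 + back("aspp2", caches$aspp2, mp[[3]])
  df4 <- df4 + back("aspp3", caches$aspp3, mp[[4]])
  rimg <- nn_backward(L$aspp_img, caches$img$cache, mp[[5]])
  grads$aspp_img <- rimg$grads
  df4 <- df4 + rimg$dx
  denc1_b <- back("enc2", caches$enc2, df4)
  dstem <- back("enc1", caches$enc1, denc1_a + denc1_b)
  dx <- back("stem", caches$stem, dstem + dstem_a)
  list(dx = dx, grads = grads)
}

seg_apply_states <- function(model, caches) {
  ch <- seg_chains()
  for (name in names(ch)) {
    cc <- caches[[name]]
    if (!is.null(cc) && !is.null(cc$states))
      model$layers[ch[[name]]] <- apply_states(model$layers[ch[[name]]],
                                               cc$states)
  }
  model
}

#' Analytic receptive field of the segmentation network
#'
#' Layer-by-layer recurrence `rf <- rf + (k - 1) * dilation * jump;
#' jump <- jump * stride` along the deepest convolutional path (stem, two
#' stride-2 separable stages, the largest-rate ASPP branch, decoder). The
#' image-level pooling branch is global by construction and excluded, so
#' this is a conservative bound.
#'
#' @param model a `seg_model`.
#' @return receptive field in pixels (square, both axes).
#' @export
receptive_field <- function(model) {
  r <- model$config$aspp_dilation_rates
  path <- list(c(3, 2, 1),            # stem conv, stride 2
               c(3, 2, 1),            # enc1 depthwise, stride 2
               c(3, 2, 1),            # enc2 depthwise, stride 2
               c(3, 1, max(r)))       # widest ASPP branch (at stride 8)
  rf <- 1; jump <- 1
  for (p in path) {
    k <- p[1]; s <- p[2]; d <- p[3]
    rf <- rf + (k - 1) * d * jump
    jump <- jump * s
  }
  rf + 2 * 4 + 2 * 2          # decoder 3x3 convs at strides 4 and 2
}

#' Inverse-median-frequency class weights
#'
#' `weight_c = median(freqs) / freq_c`, so the rarer (microvessel) class
#' gets the larger loss weight. Balanced classes give unit weights.
#'
#' @param pixel_class_freqs named or ordered vector of class pixel
#'   frequencies (> 0, summing to 1).
#' @return per-class weights in the same order.
#' @export
class_weights <- function(pixel_class_freqs) {
  if (any(pixel_class_freqs <= 0))
    stop("every class must be present in the training set")
  stats::median(pixel_class_freqs) / pixel_class_freqs
}

#' Training protocol configuration
#'
#' Defaults follow the shared training protocol of both networks: ADAM with
#' initial learning rate 0.001 multiplied by 0.2 every 0.5 epochs, at most
#' 50 epochs, early stop when the validation loss fails to improve by more
#' than 0.01% over five consecutive epochs, L2 weight penalty, and
#' inverse-median-frequency class weighting for the segmenter.
#'
#' @param lr0 initial learning rate.
#' @param drop_factor multiplicative LR drop.
#' @param drop_period epochs between drops (fractional allowed).
#' @param max_epochs epoch cap.
#' @param patience,min_rel_improve early-stopping rule.
#' @param l2_weight L2 penalty on convolution/FC weights.
#' @param batch_size minibatch size.
#' @param seed seed controlling shuffling (and initialization where a model
#'   is built inside the trainer).
#' @return a `train_config` list.
#' @export
train_config <- function(lr0 = 0.001, drop_factor = 0.2, drop_period = 0.5,
                         max_epochs = 50L, patience = 5L,
                         min_rel_improve = 1e-4, l2_weight = 1e-4,
                         batch_size = 2L, seed = 1L) {
  stopifnot(lr0 > 0, drop_factor > 0, drop_factor < 1, max_epochs >= 1)
  structure(list(lr0 = lr0, drop_factor = drop_factor,
                 drop_period = drop_period,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 min_rel_improve = min_rel_improve,
                 l2_weight = l2_weight, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Model input: the pre-processed frame, optionally with a normalized
# radial-coordinate channel.
seg_input <- function(model, img) {
  d <- dim(img)
  if (!model$config$depth_channel)
    return(array(img, c(d[1], d[2], 1L, 1L)))
  x <- array(0, c(d[1], d[2], 2L, 1L))
  x[, , 1, 1] <- img
  x[, , 2, 1] <- matrix(seq_len(d[2]) / d[2], d[1], d[2], byrow = TRUE)
  x
}

stack_batch <- function(model, frames, idx) {
  d <- dim(frames[[idx[1]]])
  cin <- 1L + model$config$depth_channel
  x <- array(0, c(d[1], d[2], cin, length(idx)))
  for (i in seq_along(idx)) {
    x[, , 1, i] <- frames[[idx[i]]]
    if (cin == 2L)
      x[, , 2, i] <- matrix(seq_len(d[2]) / d[2], d[1], d[2], byrow = TRUE)
  }
  x
}

stack_labels <- function(labels, masks, idx) {
  d <- dim(labels[[idx[1]]])
  y <- array(0, c(d[1], d[2], length(idx)))
  m <- array(FALSE, c(d[1], d[2], length(idx)))
  for (i in seq_along(idx)) {
    y[, , i] <- labels[[idx[i]]]
    m[, , i] <- masks[[idx[i]]]
  }
  list(y = y, m = m)
}

seg_eval_loss <- function(model, frames, labels, masks, idx, wts) {
  tot <- 0
  for (i in idx) {
    fw <- seg_forward(model, stack_batch(model, frames, i), train = FALSE)
    lb <- stack_labels(labels, masks, i)
    tot <- tot + seg_loss(fw$logits, lb$y, lb$m, wts)$loss
  }
  tot / length(idx)
}

#' Train the segmentation network
#'
#' Class-weighted (inverse median frequency), valid-mask-restricted pixel
#' cross-entropy plus an L2 weight penalty, minimized with ADAM under the
#' stepped LR schedule; stops at the early-stopping rule or `max_epochs`.
#'
#' @param model a `seg_model` from [build_segnet()].
#' @param frames,labels,masks parallel lists of pre-processed training
#'   images, 0/1 label matrices and logical valid masks.
#' @param tc a [train_config()].
#' @param val_idx indices of `frames` held out for validation (the rest
#'   train).
#' @param verbose print per-epoch losses.
#' @return `list(model, history)`; `history` has per-epoch train/val loss
#'   and the learning rate in effect. The returned model carries the
#'   weights of the best validation epoch, not necessarily the last one.
#' @export
train_segmenter <- function(model, frames, labels, masks, tc = train_config(),
                            val_idx = NULL, verbose = FALSE) {
  if (!length(frames)) stop("empty training set")
  if (is.null(val_idx))
    val_idx <- seq_len(max(1L, length(frames) %/% 5L))
  train_idx <- setdiff(seq_along(frames), val_idx)
  if (!length(train_idx)) stop("no training frames left after validation split")
  freq1 <- mean(unlist(lapply(train_idx, function(i)
    mean(labels[[i]][masks[[i]]]))))
  wts <- class_weights(c(other = 1 - freq1, vessel = freq1))
  state <- adam_init(model$layers)
  tr <- es_tracker(tc$patience, tc$min_rel_improve)
  history <- data.frame()
  iters_per_epoch <- max(1L, ceiling(length(train_idx) / tc$batch_size))
  t <- 0L
  best_layers <- model$layers
  best_val <- Inf
  withr::with_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = tc$batch_size)) {
        idx <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
        x <- stack_batch(model, frames, idx)
        lb <- stack_labels(labels, masks, idx)
        fw <- seg_forward(model, x, train = TRUE)
        model <- seg_apply_states(model, fw$caches)
        ls <- seg_loss(fw$logits, lb$y, lb$m, wts)
        bw <- seg_backward(model, fw$caches, ls$dlogits)
        t <- t + 1L
        lr <- lr_at(tc, (t - 1L) / iters_per_epoch)
        st <- adam_step(model$layers, bw$grads, state, lr, t, tc$l2_weight)
        model$layers <- st$layers
        state <- st$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      }
      val_loss <- seg_eval_loss(model, frames, labels, masks, val_idx, wts)
      if (val_loss < best_val) {
        best_val <- val_loss
        best_layers <- model$layers
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = val_loss,
                                  lr = lr_at(tc, epoch - 1L)))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        ep_loss / nb, val_loss))
      tr <- es_update(tr, val_loss)
      if (tr$stop) break
    }
  })
  model$layers <- best_layers   # restore the best validation epoch
  list(model = model, history = history, class_weights = wts)
}

#' Predict a binary candidate mask for a pre-processed frame
#'
#' Per-pixel argmax over the two classes by default; a probability
#' `threshold` on the vessel class can be supplied instead. Invalid pixels
#' (guidewire blanking, shift padding) are forced to 0.
#'
#' @param model trained `seg_model`.
#' @param pf a `preprocessed_frame`.
#' @param threshold vessel-probability threshold, or `NULL` for argmax.
#' @return integer 0/1 matrix of the same size as `pf$image`.
#' @export
predict_mask <- function(model, pf, threshold = NULL) {
  d <- dim(pf$image)
  x <- seg_input(model, pf$image)
  fw <- seg_forward(model, x, train = FALSE)
  z1 <- fw$logits[, , 1, 1]; z2 <- fw$logits[, , 2, 1]
  m <- if (is.null(threshold)) (z2 > z1) * 1L else {
    p <- softmax2(z1, z2)
    (p$p2 > threshold) * 1L
  }
  m[!pf$valid_mask] <- 0L
  matrix(as.integer(m), d[1], d[2])
}

#' Saliency map of the vessel-class score
#'
#' Gradient magnitude of the summed vessel-class logit with respect to the
#' input, min-max normalized to \[0, 1\].
#'
#' @param model trained `seg_model`.
#' @param pf a `preprocessed_frame`.
#' @return matrix of the same size as `pf$image`.
#' @export
saliency_map <- function(model, pf) {
  d <- dim(pf$image)
  x <- seg_input(model, pf$image)
  fw <- seg_forward(model, x, train = FALSE)
  dlog <- array(0, dim(fw$logits))
  dlog[, , 2, ] <- 1
  bw <- seg_backward(model, fw$caches, dlog)
  s <- abs(bw$dx[, , 1, 1])
  rng <- range(s)
  if (diff(rng) == 0) return(matrix(0, d[1], d[2]))
  (s - rng[1]) / diff(rng)
}
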