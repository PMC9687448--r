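# Candidate extraction and false-positive rejection. Connected components
# of the segmentation mask (8-connectivity, circular across the theta edge)
# become candidate blobs; each blob's tight bounding box, padded by 3 pixels
# of pre-processed image context and resized to 30x30, is classified as
# microvessel / non-microvessel by a shallow CNN; rejected blobs are removed
# from the mask.

#' Extract candidate blobs from a binary frame mask
#'
#' Connected components under 8-connectivity with circular adjacency across
#' the A-line (theta) edge; a blob split across the first and last rows is
#' one component. Blobs are sorted by centroid (A-line, then depth).
#'
#' @param mask binary matrix (A-lines x depth).
#' @param frame 1-based frame index stored on each blob.
#' @param min_area_px drop components smaller than this (default 1: no
#'   gate; every candidate goes to the classifier).
#' @return list of `candidate_blob` objects with `pixels` (n x 2 matrix of
#'   (A-line, depth)), tight `box` (aline_min/max, r_min/max, closed),
#'   `area_px` and `centroid`.
#' @export
extract_blobs <- function(mask, frame = 1L, min_area_px = 1L) {
  H <- nrow(mask); W <- ncol(mask)
  pos <- which(mask > 0)
  if (!length(pos)) return(list())
  id <- integer(H * W)
  id[pos] <- seq_along(pos)
  parent <- seq_along(pos)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  rows <- ((pos - 1L) %% H) + 1L
  cols <- ((pos - 1L) %/% H) + 1L
  for (dr in -1:1) for (dc in 0:1) {
    if (dc == 0 && dr <= 0) next    # each undirected edge once
    nr <- ((rows - 1L + dr) %% H) + 1L
    nc <- cols + dc
    ok <- nc >= 1L & nc <= W
    nidx <- (nc - 1L) * H + nr
    ok <- ok & id[pmax(nidx, 1L)] > 0L
    if (any(ok)) {
      a <- id[pos[ok]]; b <- id[nidx[ok]]
      for (k in seq_along(a)) union(a[k], b[k])
    }
  }
  root <- vapply(seq_along(pos), find, integer(1))
  comps <- split(seq_along(pos), root)
  if (min_area_px > 1L)
    comps <- comps[lengths(comps) >= min_area_px]
  if (!length(comps)) return(list())
  blobs <- lapply(comps, function(ix) {
    r <- rows[ix]; cc <- cols[ix]
    # circular centroid / extent in theta
    th <- 2 * pi * (r - 1) / H
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    ca <- (ang / (2 * pi) * H) %% H + 1
    da <- ((r - ca + H / 2) %% H) - H / 2
    structure(list(frame = frame,
                   pixels = cbind(aline = r, depth = cc),
                   box = c(aline_min = min(da) + ca, aline_max = max(da) + ca,
                           r_min = min(cc), r_max = max(cc)),
                   area_px = length(ix),
                   centroid = c(aline = ca, depth = mean(cc))),
              class = "candidate_blob")
  })
  ord <- order(vapply(blobs, function(b) b$centroid[1], numeric(1)),
               vapply(blobs, function(b) b$centroid[2], numeric(1)))
  unname(blobs[ord])
}

#' Cut the 30x30 classifier patch of a blob
#'
#' The tight bounding box is expanded by 3 pixels on each edge into the
#' pre-processed image (image context, not zero fill): depth edges replicate
#' past the frame border, A-line edges wrap circularly. The expanded crop is
#' bilinearly resized to `side` x `side`, leaving the candidate at the patch
#' center.
#'
#' @param blob a `candidate_blob`.
#' @param pf a `preprocessed_frame` (or any list with an `image` matrix).
#' @param pad context pixels added on every edge (default 3).
#' @param side output patch side (default 30).
#' @return a `candidate_patch`: `image` (side x side, in \[0, 1\]) and
#'   `blob`.
#' @export
make_patch <- function(blob, pf, pad = 3L, side = 30L) {
  img <- pf$image
  H <- nrow(img); W <- ncol(img)
  b <- blob$box
  ai <- (round(b["aline_min"]) - pad):(round(b["aline_max"]) + pad)
  ai <- ((ai - 1L) %% H) + 1L
  ri <- (b["r_min"] - pad):(b["r_max"] + pad)
  ri <- pmin(pmax(ri, 1L), W)
  crop <- img[ai, ri, drop = FALSE]
  patch <- resize_bilinear(crop, c(side, side))
  structure(list(image = pmin(pmax(patch, 0), 1), blob = blob),
            class = "candidate_patch")
}

#' Build the shallow candidate classifier
#'
#' Layer sequence on a 30x30x1 input: conv 3x3x8 stride 2, BN, ReLU,
#' maxpool 2; conv 3x3x16 stride 2, BN, ReLU, maxpool 2; conv 3x3x32
#' stride 2, BN, ReLU; fully connected; softmax over two output units
#' (1 = microvessel, 0 = non-microvessel).
#'
#' @param seed parameter-initialization seed.
#' @return a `clf_model`.
#' @export
build_classifier <- function(seed = 1L) {
  withr::with_seed(seed, {
    layers <- list(
      nn_conv(3L, 3L, 1L, 8L, stride = 2L), nn_bn(8L), nn_relu(),
      nn_maxpool(),
      nn_conv(3L, 3L, 8L, 16L, stride = 2L), nn_bn(16L), nn_relu(),
      nn_maxpool(),
      nn_conv(3L, 3L, 16L, 32L, stride = 2L), nn_bn(32L), nn_relu(),
      nn_flatten(),
      nn_fc(32L, 2L))
    structure(list(layers = layers, seed = seed, side = 30L),
              class = "clf_model")
  })
}

#' Number of trainable parameters of a classifier
#' @param model a `clf_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$params, length, numeric(1))), numeric(1)))
}

# Classifier input: per-patch min-max normalization. Deep candidates live
# in heavily attenuated tissue, so absolute intensity varies by an order
# of magnitude across patches; normalizing each patch makes the network
# contrast-invariant and stabilizes training.
clf_stack <- function(patches) {
  n <- length(patches)
  s <- nrow(patches[[1]])
  x <- array(0, c(s, s, 1L, n))
  for (i in seq_len(n)) {
    p <- patches[[i]]
    r <- range(p)
    x[, , 1, i] <- if (diff(r) < 1e-8) p * 0 else (p - r[1]) / diff(r)
  }
  x
}

#' Classify patches
#'
#' @param model a trained `clf_model`.
#' @param patches list of side x side matrices (or `candidate_patch`es).
#' @return matrix (n x 2) of class probabilities (columns: other, vessel).
#' @export
predict_patches <- function(model, patches) {
  patches <- lapply(patches, function(p)
    if (inherits(p, "candidate_patch")) p$image else p)
  fw <- seq_forward(model$layers, clf_stack(patches), train = FALSE)
  p <- softmax2(fw$y[1, ], fw$y[2, ])
  cbind(other = p$p1, vessel = p$p2)
}

#' Train the candidate classifier
#'
#' Positive (microvessel) patches are rotation-augmented 7x via
#' [rotate_patch_augment()]; negatives are left untouched, taking a 1:7
#' class ratio to 1:1. Optimization follows the shared protocol (ADAM,
#' stepped LR, early stopping on a held-out validation split).
#'
#' @param model a `clf_model`.
#' @param patches list of side x side matrices.
#' @param labels integer vector, 1 = microvessel, 0 = non-microvessel.
#' @param tc a [train_config()].
#' @param augment rotation-augment the positives (training assembly rule).
#' @param val_frac fraction held out for validation.
#' @return `list(model, history)`.
#' @export
train_classifier <- function(model, patches, labels, tc = train_config(
                               batch_size = 32L),
                             augment = TRUE, val_frac = 0.15) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  if (augment) {
    aug_p <- list(); aug_y <- integer(0)
    for (i in seq_along(patches)) {
      if (labels[i] == 1L) {
        rp <- rotate_patch_augment(patches[[i]])
        aug_p <- c(aug_p, rp)
        aug_y <- c(aug_y, rep(1L, length(rp)))
      } else {
        aug_p <- c(aug_p, patches[i])
        aug_y <- c(aug_y, 0L)
      }
    }
    patches <- aug_p; labels <- aug_y
  }
  y <- labels + 1L  # 1 = other, 2 = vessel
  state <- adam_init(model$layers)
  tr <- es_tracker(tc$patience, tc$min_rel_improve)
  history <- data.frame()
  best_layers <- model$layers
  best_val <- Inf
  withr::with_seed(tc$seed, {
    n <- length(patches)
    vi <- sample.int(n, max(2L, round(val_frac * n)))
    ti <- setdiff(seq_len(n), vi)
    xv <- clf_stack(patches[vi]); yv <- y[vi]
    iters_per_epoch <- max(1L, ceiling(length(ti) / tc$batch_size))
    t <- 0L
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(ti)
      ep_loss <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = tc$batch_size)) {
        idx <- ord[b0:min(b0 + tc$batch_size - 1L, length(ord))]
        fw <- seq_forward(model$layers, clf_stack(patches[idx]),
                          train = TRUE)
        model$layers <- apply_states(model$layers, fw$states)
        ls <- clf_loss(fw$y, y[idx])
        bw <- seq_backward(model$layers, fw$caches, ls$dlogits)
        t <- t + 1L
        lr <- lr_at(tc, (t - 1L) / iters_per_epoch)
        st <- adam_step(model$layers, bw$grads, state, lr, t, tc$l2_weight)
        model$layers <- st$layers
        state <- st$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1L
      }
      vl <- clf_loss(seq_forward(model$layers, xv, train = FALSE)$y, yv)$loss
      if (vl < best_val) {
        best_val <- vl
        best_layers <- model$layers
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = vl,
                                  lr = lr_at(tc, epoch - 1L)))
      tr <- es_update(tr, vl)
      if (tr$stop) break
    }
  })
  model$layers <- best_layers   # restore the best validation epoch
  list(model = model, history = history)
}

#' Remove classifier-rejected blobs from a mask
#'
#' Blobs classified non-microvessel have all their pixels removed; kept
#' blobs are untouched, so the cleaned mask is always a subset of the
#' input mask.
#'
#' @param mask binary matrix the blobs came from.
#' @param blobs list of `candidate_blob`s (from [extract_blobs()]).
#' @param model trained `clf_model`.
#' @param pf the `preprocessed_frame` supplying patch context.
#' @param threshold vessel-probability threshold for keeping a blob.
#' @return `list(mask, decisions)`; `decisions` is a data frame with one
#'   row per blob (frame, box, area, probability, kept).
#' @export
filter_candidates <- function(mask, blobs, model, pf, threshold = 0.5) {
  if (!length(blobs))
    return(list(mask = mask, decisions = data.frame()))
  patches <- lapply(blobs, make_patch, pf = pf)
  pr <- predict_patches(model, patches)[, "vessel"]
  keep <- pr >= threshold
  out <- mask
  for (i in seq_along(blobs)) {
    if (!keep[i]) out[blobs[[i]]$pixels] <- 0L
  }
  dec <- do.call(rbind, lapply(seq_along(blobs), function(i) {
    b <- blobs[[i]]
    data.frame(blob = i, frame = b$frame,
               aline_min = b$box["aline_min"], aline_max = b$box["aline_max"],
               r_min = b$box["r_min"], r_max = b$box["r_max"],
               area_px = b$area_px, probability = pr[i], kept = keep[i],
               row.names = NULL)
  }))
  list(mask = out, decisions = dec)
}
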