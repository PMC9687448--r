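# Five-step polar-domain pre-processing: (1) lumen boundary detection
# (deterministic baseline, pluggable), (2) guidewire/shadow interval
# detection, (3) per A-line pixel shifting so tissue starts at depth 1,
# (4) radial ROI cropping, (5) Gaussian denoising. The guidewire interval is
# blanked to 0 and flagged invalid; the shift/crop bookkeeping kept in the
# result makes the alignment invertible over the valid mask.

#' Baseline lumen boundary detector
#'
#' Deterministic surrogate for a learned lumen segmenter (pluggable through
#' `preprocess_frame(lumen_fn = ...)`): per A-line, the first depth index
#' past the catheter mask where the depth-smoothed intensity exceeds an Otsu
#' threshold for at least `min_run` consecutive pixels, followed by
#' dynamic-programming smoothing across A-lines with a circular theta axis
#' (adjacent boundary steps are capped at `max_jump`, including across the
#' wrap).
#'
#' @param frame 2-D polar frame (A-lines x depth).
#' @param catheter_radius_px catheter dead zone masked before the search.
#' @param max_jump maximum boundary step between adjacent A-lines.
#' @param min_run consecutive above-threshold pixels required.
#' @return integer vector of per-A-line boundary depth indices (1-based,
#'   first tissue pixel).
#' @export
segment_lumen <- function(frame, catheter_radius_px = 12L, max_jump = 4L,
                          min_run = 5L) {
  H <- nrow(frame); W <- ncol(frame)
  search <- frame
  search[, seq_len(min(catheter_radius_px + 2L, W))] <- 0
  # (7,1) moving-average smoothing along depth
  k <- 7L
  sm <- t(apply(search, 1L, function(a)
    stats::filter(c(rep(a[1], 3), a, rep(a[W], 3)), rep(1 / k, k))[4:(W + 3)]))
  thr <- otsu_threshold(sm[sm > 0])
  above <- sm > thr
  cand <- integer(H); conf <- numeric(H)
  for (i in seq_len(H)) {
    r <- rle(above[i, ])
    ends <- cumsum(r$lengths)
    j <- which(r$values & r$lengths >= min_run)
    if (length(j)) {
      first <- ends[j[1]] - r$lengths[j[1]] + 1L
      # the depth smoothing advances the edge by up to half a window;
      # refine to the first raw crossing at or after the smoothed one
      refine <- which(frame[i, first:min(first + 4L, W)] > thr)
      if (length(refine)) first <- first + refine[1] - 1L
      cand[i] <- first
      conf[i] <- sm[i, min(first + 2L, W)]
    } else {
      cand[i] <- NA_integer_
    }
  }
  if (all(is.na(cand))) stop("no lumen found")
  med <- as.integer(stats::median(cand, na.rm = TRUE))
  cand_filled <- ifelse(is.na(cand), med, cand)
  miss <- is.na(cand)
  # DP smoothing, circular: anchor at the most confident A-line, require the
  # wrap step back to the anchor to respect max_jump as well.
  anchor <- which.max(ifelse(miss, -Inf, conf))
  ord <- ((anchor - 1L + seq_len(H) - 1L) %% H) + 1L
  d0 <- cand_filled[anchor]
  states <- seq_len(W)
  INF <- 1e18
  cost <- rep(INF, W); cost[d0] <- 0
  back <- matrix(0L, H, W)
  lambda <- 0.5
  for (s in 2:H) {
    i <- ord[s]
    prev <- cost
    newc <- rep(INF, W)
    bptr <- integer(W)
    for (dlt in (-max_jump):max_jump) {
      shifted <- rep(INF, W)
      src <- states - dlt
      ok <- src >= 1L & src <= W
      shifted[ok] <- prev[src[ok]] + lambda * abs(dlt)
      upd <- shifted < newc
      newc[upd] <- shifted[upd]
      bptr[upd] <- src[upd]
    }
    data_cost <- if (miss[i]) rep(0, W) else abs(states - cand_filled[i])
    cost <- newc + data_cost
    back[s, ] <- bptr
  }
  final_ok <- abs(states - d0) <= max_jump
  cost[!final_ok] <- INF
  d <- which.min(cost)
  path <- integer(H); path[H] <- d
  for (s in H:2) path[s - 1L] <- back[s, path[s]]
  boundary <- integer(H)
  boundary[ord] <- path
  as.integer(boundary)
}

#' Detect the guidewire shadow interval of a frame
#'
#' Scores every circularly contiguous run of "dark" A-lines (beyond-lumen
#' summed intensity below `shadow_frac` of the frame median) by interval
#' darkness minus a bright leading-reflection bonus, plus an optional
#' temporal drift penalty against the previous frame's interval; returns the
#' best-scoring run. An empty interval (length 0) is returned when no A-line
#' falls below the shadow threshold.
#'
#' @param frame 2-D polar frame.
#' @param lumen_boundary per-A-line boundary from [segment_lumen()].
#' @param shadow_frac darkness threshold as a fraction of the median
#'   beyond-lumen A-line sum.
#' @param alpha,beta,gamma weights of darkness, leading-edge brightness, and
#'   temporal center drift.
#' @param prev previous frame's interval `list(start, len)` or `NULL`.
#' @return `list(start, len)`; 1-based start, `len = 0` means no guidewire.
#' @export
detect_guidewire <- function(frame, lumen_boundary, shadow_frac = 0.45,
                             alpha = 1, beta = 0.5, gamma = 0.02,
                             prev = NULL) {
  H <- nrow(frame); W <- ncol(frame)
  s <- vapply(seq_len(H), function(i) {
    cols <- min(lumen_boundary[i] + 4L, W):W
    sum(frame[i, cols])
  }, numeric(1))
  edge <- vapply(seq_len(H), function(i) {
    cols <- lumen_boundary[i]:min(lumen_boundary[i] + 5L, W)
    max(frame[i, cols])
  }, numeric(1))
  med <- stats::median(s)
  dark <- s < shadow_frac * med
  if (!any(dark)) return(list(start = 1L, len = 0L))
  runs <- circular_runs(dark)
  snorm <- s / (med + 1e-12)
  score <- vapply(seq_len(nrow(runs)), function(j) {
    idx <- circ_interval(runs$start[j], runs$len[j], H)
    sc <- alpha * mean(snorm[idx]) - beta * mean(edge[idx])
    if (!is.null(prev) && prev$len > 0) {
      drift <- circ_dist(interval_center(runs$start[j], runs$len[j], H),
                         interval_center(prev$start, prev$len, H), H)
      sc <- sc + gamma * drift
    }
    sc - 1e-3 * runs$len[j]  # prefer the longer run on near-ties
  }, numeric(1))
  j <- which.min(score)
  list(start = runs$start[j], len = runs$len[j])
}

# Runs of TRUE in a logical vector with circular wrap: a run crossing the
# end is reported once, as (start, len) with start near the end.
circular_runs <- function(x) {
  n <- length(x)
  if (all(x)) return(data.frame(start = 1L, len = n))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = starts[r$values], len = r$lengths[r$values])
  if (nrow(out) >= 2L && x[1] && x[n]) {
    first <- which.min(out$start); last <- which.max(out$start)
    out$len[last] <- out$len[last] + out$len[first]
    out <- out[-first, , drop = FALSE]
  }
  out
}

#' Pixel-shift each A-line so tissue starts at depth 1
#'
#' Output row `i` is input row `i` starting at column `lumen_boundary[i]`;
#' the vacated right side is zero-padded and flagged invalid.
#'
#' @param frame 2-D polar frame.
#' @param lumen_boundary per-A-line boundary indices (1-based).
#' @return `list(image, offsets, valid)`; `offsets` holds the applied shift
#'   (boundary index), `valid` is FALSE over the padding.
#' @export
pixel_shift <- function(frame, lumen_boundary) {
  H <- nrow(frame); W <- ncol(frame)
  stopifnot(length(lumen_boundary) == H,
            all(lumen_boundary >= 1L), all(lumen_boundary <= W))
  out <- matrix(0, H, W)
  valid <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    b <- lumen_boundary[i]
    n <- W - b + 1L
    out[i, seq_len(n)] <- frame[i, b:W]
    valid[i, seq_len(n)] <- TRUE
  }
  list(image = out, offsets = as.integer(lumen_boundary), valid = valid)
}

#' Invert a pixel shift over the valid mask
#'
#' @param shifted result of [pixel_shift()].
#' @return matrix in original coordinates (zeros where no data).
#' @export
pixel_unshift <- function(shifted) {
  H <- nrow(shifted$image); W <- ncol(shifted$image)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    b <- shifted$offsets[i]
    n <- W - b + 1L
    out[i, b:W] <- shifted$image[i, seq_len(n)]
  }
  out
}

#' Crop the radial region of interest
#'
#' Keeps depth columns `[1, min(roi_depth, depth)]`; the 300-pixel default
#' corresponds to 1.5 mm at 5 µm per pixel. With `pad = TRUE`, shallower
#' frames are zero-padded up to `roi_depth`.
#'
#' @param frame 2-D (shifted) frame.
#' @param roi_depth ROI depth in pixels.
#' @param pad pad with zeros when the frame is shallower than `roi_depth`.
#' @return `list(image, padded)` where `padded` reports whether padding was
#'   applied.
#' @export
crop_roi <- function(frame, roi_depth = 300L, pad = FALSE) {
  W <- ncol(frame)
  keep <- min(roi_depth, W)
  out <- frame[, seq_len(keep), drop = FALSE]
  padded <- FALSE
  if (pad && keep < roi_depth) {
    out <- cbind(out, matrix(0, nrow(frame), roi_depth - keep))
    padded <- TRUE
  }
  list(image = out, padded = padded)
}

#' Gaussian denoising
#'
#' Discrete 2-D Gaussian convolution (kernel normalized to sum 1), border
#' handled by reflection.
#'
#' @param frame 2-D frame.
#' @param kernel odd kernel size (default 7).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return smoothed matrix.
#' @export
denoise <- function(frame, kernel = 7L, sigma = 1) {
  if (kernel %% 2L == 0L) stop("kernel size must be odd")
  half <- (kernel - 1L) %/% 2L
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  K <- outer(g, g)
  K <- K / sum(K)
  xp <- reflect_pad(frame, half, half)
  H <- nrow(frame); W <- ncol(frame)
  out <- matrix(0, H, W)
  for (di in seq_len(kernel)) for (dj in seq_len(kernel)) {
    out <- out + K[di, dj] * xp[di:(di + H - 1L), dj:(dj + W - 1L)]
  }
  out
}

#' Run the full pre-processing chain on one frame
#'
#' Order: lumen detection, guidewire detection, pixel shift, ROI crop,
#' Gaussian denoise; the guidewire interval is blanked to exact 0 afterwards
#' and flagged invalid (the removed region carries no information).
#'
#' @param frame 2-D raw polar frame.
#' @param catheter_radius_px catheter dead zone for the lumen detector.
#' @param roi_depth radial ROI in pixels.
#' @param kernel,sigma Gaussian filter parameters.
#' @param lumen_fn lumen detector, signature `(frame, catheter_radius_px)`;
#'   defaults to [segment_lumen()] (the deterministic baseline).
#' @param guidewire_prev previous frame's interval for temporal smoothing.
#' @param labels optional 0/1 matrix carried through the identical shift and
#'   crop so training pairs stay aligned.
#' @return a `preprocessed_frame`: `image`, `lumen_offset`,
#'   `guidewire_interval` (`list(start, len)`), `valid_mask`, and `labels`
#'   when supplied.
#' @export
preprocess_frame <- function(frame, catheter_radius_px = 12L,
                             roi_depth = 300L, kernel = 7L, sigma = 1,
                             lumen_fn = NULL, guidewire_prev = NULL,
                             labels = NULL) {
  lumen_fn <- lumen_fn %||%
    function(fr, cr) segment_lumen(fr, catheter_radius_px = cr)
  boundary <- lumen_fn(frame, catheter_radius_px)
  gw <- detect_guidewire(frame, boundary, prev = guidewire_prev)
  sh <- pixel_shift(frame, boundary)
  cr <- crop_roi(sh$image, roi_depth)
  img <- denoise(cr$image, kernel, sigma)
  valid <- crop_roi(sh$valid * 1, roi_depth)$image > 0
  gw_rows <- circ_interval(gw$start, gw$len, nrow(frame))
  if (length(gw_rows)) {
    img[gw_rows, ] <- 0
    valid[gw_rows, ] <- FALSE
  }
  lab_out <- NULL
  if (!is.null(labels)) {
    lab_sh <- pixel_shift(labels, boundary)
    lab_out <- crop_roi(lab_sh$image, roi_depth)$image
    lab_out <- (lab_out > 0.5) * 1L
  }
  structure(list(image = img, lumen_offset = sh$offsets,
                 guidewire_interval = gw, valid_mask = valid,
                 labels = lab_out, roi_depth = ncol(img)),
            class = "preprocessed_frame")
}

#' Pre-process every frame of a pullback
#'
#' @param pullback a `polar_pullback`.
#' @param labels optional `label_volume` carried through shift/crop.
#' @param ... passed to [preprocess_frame()].
#' @return list of `preprocessed_frame` objects (guidewire detection is
#'   temporally smoothed along the pullback).
#' @export
preprocess_pullback <- function(pullback, labels = NULL, ...) {
  out <- vector("list", pullback$n_frames)
  prev <- NULL
  for (f in seq_len(pullback$n_frames)) {
    lab <- if (!is.null(labels)) labels$data[f, , ] else NULL
    out[[f]] <- preprocess_frame(pullback$data[f, , ],
                                 guidewire_prev = prev, labels = lab, ...)
    prev <- out[[f]]$guidewire_interval
  }
  out
}
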