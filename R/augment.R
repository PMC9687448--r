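# Polar-domain offset augmentation: all frames of a pullback are stacked
# into one tall (N * A-lines) x depth array whose theta axis spans 0 to
# N*360 degrees; shifting the starting A-line and re-cutting frames yields
# new framings with no data loss or distortion. Classifier patches are
# additionally rotation-augmented (positives only during training assembly).

#' Concatenate a pullback into one tall 2-D array
#'
#' Row `j` of frame `k` becomes row `(k-1) * alines_per_frame + j`; values
#' are untouched.
#'
#' @param pullback a `polar_pullback`.
#' @return `list(data, alines_per_frame, n_frames)` of class
#'   `concatenated_pullback`.
#' @export
concat_pullback <- function(pullback) {
  stopifnot(inherits(pullback, "polar_pullback"), pullback$n_frames >= 1L)
  H <- pullback$alines_per_frame
  big <- matrix(0, pullback$n_frames * H, pullback$depth_px)
  for (k in seq_len(pullback$n_frames))
    big[(k - 1L) * H + seq_len(H), ] <- pullback$data[k, , ]
  structure(list(data = big, alines_per_frame = H,
                 n_frames = pullback$n_frames),
            class = "concatenated_pullback")
}

#' Offset augmentation over a concatenated pullback
#'
#' Augmented set `s` (s = 1..n_shifts) re-frames the tall array starting at
#' row `s * shift_alines`, cutting consecutive `alines_per_frame`-row
#' frames; a trailing incomplete frame is dropped (the pullback axis is not
#' circular). Every augmented frame is therefore a contiguous block of
#' original rows. Apply with the same parameters to a label volume to keep
#' image/label rows aligned.
#'
#' @param concat a `concatenated_pullback` (or a `label_volume` passed
#'   through [concat_pullback()] semantics via `offset_augment_volume()`).
#' @param shift_alines starting-A-line increment (default 55).
#' @param n_shifts number of shifted framings (default 9).
#' @return list of `n_shifts` 3-D arrays (frame x A-line x depth).
#' @export
offset_augment <- function(concat, shift_alines = 55L, n_shifts = 9L) {
  stopifnot(inherits(concat, "concatenated_pullback"),
            shift_alines >= 1L, n_shifts >= 1L)
  total <- nrow(concat$data)
  if (shift_alines >= total)
    stop("shift_alines must be smaller than the total row count")
  H <- concat$alines_per_frame
  lapply(seq_len(n_shifts), function(s) {
    start <- s * shift_alines
    nfr <- (total - start) %/% H
    if (nfr < 1L)
      stop("shift ", s, " leaves no complete frame")
    vol <- array(0, c(nfr, H, ncol(concat$data)))
    for (k in seq_len(nfr))
      vol[k, , ] <- concat$data[start + (k - 1L) * H + seq_len(H), ,
                                drop = FALSE]
    vol
  })
}

#' Offset-augment an aligned image/label pullback pair
#'
#' @param pullback a `polar_pullback`.
#' @param labels a `label_volume` aligned with it.
#' @inheritParams offset_augment
#' @return list with `images` and `labels`, parallel lists of 3-D arrays.
#' @export
offset_augment_pair <- function(pullback, labels, shift_alines = 55L,
                                n_shifts = 9L) {
  ci <- concat_pullback(pullback)
  cl <- ci
  big <- matrix(0L, nrow(ci$data), ncol(ci$data))
  H <- pullback$alines_per_frame
  for (k in seq_len(pullback$n_frames))
    big[(k - 1L) * H + seq_len(H), ] <- labels$data[k, , ]
  cl$data <- big
  list(images = offset_augment(ci, shift_alines, n_shifts),
       labels = offset_augment(cl, shift_alines, n_shifts))
}

#' Rotate a square patch about its center
#'
#' Bilinear interpolation; source coordinates falling outside the patch are
#' clamped to the nearest edge pixel (edge replication). Exact at multiples
#' of 90 degrees up to interpolation weights of 0/1.
#'
#' @param patch square numeric matrix.
#' @param degrees rotation angle (counter-clockwise).
#' @return rotated matrix of identical size.
#' @export
rotate_patch <- function(patch, degrees) {
  n <- nrow(patch)
  stopifnot(n == ncol(patch))
  a <- degrees * pi / 180
  c0 <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  di <- g$i - c0; dj <- g$j - c0
  # inverse map: rotate destination offsets by -a to find source
  si <- cos(a) * di + sin(a) * dj + c0
  sj <- -sin(a) * di + cos(a) * dj + c0
  si <- pmin(pmax(si, 1), n); sj <- pmin(pmax(sj, 1), n)
  i0 <- pmin(floor(si), n - 1L); j0 <- pmin(floor(sj), n - 1L)
  wi <- si - i0; wj <- sj - j0
  v <- (1 - wi) * (1 - wj) * patch[cbind(i0, j0)] +
       wi * (1 - wj) * patch[cbind(i0 + 1, j0)] +
       (1 - wi) * wj * patch[cbind(i0, j0 + 1)] +
       wi * wj * patch[cbind(i0 + 1, j0 + 1)]
  matrix(v, n, n)
}

#' Rotation augmentation of a classifier patch
#'
#' Returns the original patch plus rotations at 30 to 180 degrees in
#' 30-degree steps — seven patches per input. During training assembly only
#' positive (microvessel) patches are augmented, taking the class ratio from
#' 1:7 to 1:1.
#'
#' @param patch square numeric matrix (the 30x30 candidate patch).
#' @param angles rotation angles in degrees.
#' @return list of `length(angles) + 1` matrices (original first).
#' @export
rotate_patch_augment <- function(patch, angles = seq(30, 180, by = 30)) {
  if (!is.matrix(patch) || nrow(patch) != ncol(patch))
    stop("patch must be square")
  c(list(patch), lapply(angles, function(a) rotate_patch(patch, a)))
}
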