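# Containers and on-disk formats. Pullbacks are multi-page TIFF (one 16-bit
# page per frame) plus a JSON metadata sidecar; label volumes are 8-bit
# multi-page TIFF of {0,1}; ground-truth scenes, candidate tables and track
# tables are JSON/CSV. All exported files use 0-based indices and half-open
# intervals; in-memory R objects use 1-based indices.

#' Polar IVOCT pullback container
#'
#' @param data 3-D numeric array (frame x A-line x depth), values in
#'   \[0, 1\].
#' @param radial_px_um radial pixel size in micrometres.
#' @param frame_pitch_mm pullback distance between frames in millimetres.
#' @param segment_id identifier of the vessel segment (grouping key for
#'   cross-validation).
#' @return an object of class `polar_pullback`.
#' @export
polar_pullback <- function(data, radial_px_um, frame_pitch_mm,
                           segment_id = "segment") {
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data)) || min(data) < 0 || max(data) > 1)
    stop("pullback intensities must be finite and in [0, 1]")
  structure(list(data = data,
                 n_frames = dim(data)[1], alines_per_frame = dim(data)[2],
                 depth_px = dim(data)[3], radial_px_um = radial_px_um,
                 frame_pitch_mm = frame_pitch_mm, segment_id = segment_id),
            class = "polar_pullback")
}

#' @export
print.polar_pullback <- function(x, ...) {
  cat(sprintf(
    "polar_pullback '%s': %d frames x %d A-lines x %d depth px (%g um/px, %g mm/frame)\n",
    x$segment_id, x$n_frames, x$alines_per_frame, x$depth_px,
    x$radial_px_um, x$frame_pitch_mm))
  invisible(x)
}

#' Binary microvessel label volume
#'
#' @param data 3-D array of 0/1 aligned with a pullback (1 = microvessel,
#'   0 = "other": lumen, side branch, calcification, tissue).
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(data) {
  stopifnot(length(dim(data)) == 3L, all(data %in% c(0L, 1L)))
  storage.mode(data) <- "integer"
  structure(list(data = data), class = "label_volume")
}

pullback_sidecar <- function(pb) {
  list(n_frames = pb$n_frames, alines_per_frame = pb$alines_per_frame,
       depth_px = pb$depth_px, radial_px_um = pb$radial_px_um,
       frame_pitch_mm = pb$frame_pitch_mm, segment_id = pb$segment_id)
}

#' Write / read a pullback
#'
#' `write_pullback()` stores the volume as a multi-page 16-bit TIFF (one page
#' per frame) next to a JSON metadata sidecar (`<stem>.json`). Intensities
#' are quantized to the 16-bit grid, after which write/read round trips are
#' bit-exact. `read_pullback()` accepts the TIFF path or a directory of
#' per-frame PNG/TIFF files sorted by name, with the sidecar alongside;
#' integer rasters are normalized to \[0, 1\] by the maximum dtype value.
#'
#' @param pullback a `polar_pullback`.
#' @param path TIFF file path (writing) or TIFF/PNG-directory path (reading).
#' @return `read_pullback()` returns a `polar_pullback`.
#' @export
write_pullback <- function(pullback, path) {
  stopifnot(inherits(pullback, "polar_pullback"))
  pages <- lapply(seq_len(pullback$n_frames),
                  function(f) quantize16(pullback$data[f, , ]))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(pullback_sidecar(pullback), sidecar_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "metadata.json")
  else paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_pullback
#' @export
read_pullback <- function(path) {
  sc_file <- sidecar_path(path)
  if (!file.exists(sc_file))
    stop("missing metadata sidecar: ", sc_file)
  meta <- jsonlite::read_json(sc_file, simplifyVector = TRUE)
  pages <- read_pages(path)
  if (length(pages) != meta$n_frames)
    stop(sprintf("page count (%d) does not match sidecar n_frames (%d)",
                 length(pages), meta$n_frames))
  dims <- dim(pages[[1]])
  if (dims[1] != meta$alines_per_frame || dims[2] != meta$depth_px)
    stop("raster dimensions do not match sidecar metadata")
  vol <- array(0, c(meta$n_frames, dims[1], dims[2]))
  for (f in seq_along(pages)) vol[f, , ] <- pages[[f]]
  polar_pullback(vol, radial_px_um = as.numeric(meta$radial_px_um),
                 frame_pitch_mm = as.numeric(meta$frame_pitch_mm),
                 segment_id = meta$segment_id %||% "segment")
}

# Read TIFF pages or a directory of per-frame PNG/TIFF images (sorted by
# file name). The tiff/png readers already scale integer rasters by the
# maximum dtype value.
read_pages <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    lapply(files, function(f) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
             else tiff::readTIFF(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(img) if (length(dim(img)) == 3L) img[, , 1]
                                else img)
  }
}

#' Write / read a label volume
#'
#' Multi-page 8-bit TIFF of {0, 1}.
#' @param labels a `label_volume`.
#' @param path TIFF file path.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  pages <- lapply(seq_len(dim(labels$data)[1]),
                  function(f) labels$data[f, , ] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- read_pages(path)
  vol <- array(0L, c(length(pages), dim(pages[[1]])))
  for (f in seq_along(pages)) vol[f, , ] <- as.integer(round(pages[[f]]))
  label_volume(vol)
}

#' Write / read a ground-truth scene as JSON
#'
#' Frame and A-line indices are exported 0-based; intervals are half-open.
#' @param scene a `ground_truth_scene`.
#' @param path JSON file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  tube0 <- function(t) list(
    kind = t$kind,
    frame_start = t$frames[1] - 1L,
    frame_end = t$frames[length(t$frames)],  # half-open
    center_aline = t$center_aline - 1L,
    center_depth = t$center_depth - 1,
    r_aline = t$r_aline, r_depth = t$r_depth)
  out <- list(
    lumen_boundary = scene$lumen_boundary - 1L,
    guidewire = data.frame(frame = scene$guidewire$frame - 1L,
                           start = scene$guidewire$start - 1L,
                           end = scene$guidewire$start - 1L +
                                 scene$guidewire$len),
    microvessel_tubes = lapply(scene$microvessel_tubes, tube0),
    side_branches = lapply(scene$side_branches, tube0),
    calcifications = lapply(scene$calcifications, tube0))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tube1 <- function(t) list(
    kind = t$kind, frames = (t$frame_start + 1L):t$frame_end,
    center_aline = unlist(t$center_aline) + 1L,
    center_depth = unlist(t$center_depth) + 1,
    r_aline = t$r_aline, r_depth = t$r_depth)
  structure(list(
    lumen_boundary = as.matrix(x$lumen_boundary) + 1L,
    guidewire = data.frame(frame = x$guidewire$frame + 1L,
                           start = x$guidewire$start + 1L,
                           len = x$guidewire$end - x$guidewire$start),
    microvessel_tubes = lapply(seq_len(length(x$microvessel_tubes$kind %||%
                                                x$microvessel_tubes)),
                               function(i) tube1(pick_row(x$microvessel_tubes, i))),
    side_branches = lapply(seq_len(length(x$side_branches$kind %||%
                                            x$side_branches)),
                           function(i) tube1(pick_row(x$side_branches, i))),
    calcifications = lapply(seq_len(length(x$calcifications$kind %||%
                                             x$calcifications)),
                            function(i) tube1(pick_row(x$calcifications, i)))),
    class = "ground_truth_scene")
}

# jsonlite simplifies a list of homogeneous records to a data frame; undo.
pick_row <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col)
    if (is.list(col)) unlist(col[[i]]) else col[i])
  else x[[i]]
}
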