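# Small shared fixtures: a compact phantom for fast unit tests and a
# memoised end-to-end benchmark shared by the acceptance tests.

tiny_params <- function(seed = 1L, ...) {
  base <- list(preset = "desk", n_frames = 12L, alines_per_frame = 96L,
               depth_px = 120L, lumen_radius_px = 30L,
               catheter_radius_px = 8L, n_microvessels = 3L,
               n_side_branches = 1L, n_calcifications = 1L,
               vessel_frames_max = 6L,
               guidewire_width_alines = c(12L, 16L), seed = seed)
  do.call(phantom_params, utils::modifyList(base, list(...)))
}

tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_pullback(tiny_params())
    cache
  }
})

# The end-to-end benchmark is expensive; run it once and share across tests.
benchmark_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_phantom_benchmark(seed = 1L)
    cache
  }
})

# Independent 2-D connected-components oracle: BFS flood fill on an
# adjacency list with circular rows, kept deliberately simple.
flood_fill_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (s in which(mask > 0)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      r <- ((q - 1L) %% H) + 1L; cc <- ((q - 1L) %/% H) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nr <- ((r - 1L + dr) %% H) + 1L
        nc <- cc + dc
        if (nc < 1L || nc > W) next
        ni <- (nc - 1L) * H + nr
        if (mask[ni] > 0 && lab[ni] == 0L) {
          lab[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

# 3-D (frame, A-line, depth) flood fill with circular A-lines, used to
# verify tube persistence in the generated label volume.
flood_fill_components_3d <- function(vol) {
  d <- dim(vol)
  lab <- array(0L, d)
  cur <- 0L
  idx <- which(vol > 0)
  for (s in idx) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s; lab[s] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      a <- arrayInd(q, d)
      for (df in -1:1) for (da in -1:1) for (dr in -1:1) {
        f <- a[1] + df
        if (f < 1L || f > d[1]) next
        al <- ((a[2] - 1L + da) %% d[2]) + 1L
        r <- a[3] + dr
        if (r < 1L || r > d[3]) next
        ni <- f + (al - 1L) * d[1] + (r - 1L) * d[1] * d[2]
        if (vol[ni] > 0 && lab[ni] == 0L) {
          lab[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}
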