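mkblob <- function(frame, rows, cols) {
  px <- as.matrix(expand.grid(aline = rows, depth = cols))
  structure(list(frame = frame, pixels = px,
                 box = c(aline_min = min(rows), aline_max = max(rows),
                         r_min = min(cols), r_max = max(cols)),
                 area_px = nrow(px),
                 centroid = c(aline = mean(rows), depth = mean(cols))),
            class = "candidate_blob")
}

test_that("a blob repeated over frames 3-7 forms one five-frame track", {
  bf <- lapply(1:8, function(f)
    if (f >= 3 && f <= 7) list(mkblob(f, 10:12, 20:22)) else list())
  tracks <- link_blobs(bf, alines_per_frame = 64L)
  expect_length(tracks, 1L)
  expect_equal(tracks[[1]]$n_frames, 5L)
  expect_equal(tracks[[1]]$frames, 3:7)
})

test_that("non-overlapping blobs on the same frames form separate tracks", {
  bf <- lapply(1:4, function(f)
    list(mkblob(f, 5:6, 10:11), mkblob(f, 40:41, 30:31)))
  tracks <- link_blobs(bf, alines_per_frame = 64L)
  expect_length(tracks, 2L)
  expect_true(all(vapply(tracks, `[[`, numeric(1), "n_frames") == 4))
})

test_that("greedy linking matches an exhaustive overlap oracle on small instances", {
  # brute force: for consecutive frames, enumerate all blob pairings and
  # keep the maximal-overlap matching; instances are small enough to check
  overlap <- function(a, b) {
    ka <- paste(a$pixels[, 1], a$pixels[, 2])
    kb <- paste(b$pixels[, 1], b$pixels[, 2])
    length(intersect(ka, kb))
  }
  for (seed in 1:4) {
    bf <- withr::with_seed(seed, {
      lapply(1:5, function(f) {
        n <- sample(0:2, 1)
        lapply(seq_len(n), function(i) {
          r0 <- sample(1:28, 1); c0 <- sample(1:28, 1)
          mkblob(f, r0:(r0 + 3), c0:(c0 + 3))
        })
      })
    })
    tracks <- link_blobs(bf, alines_per_frame = 32L)
    # every adjacent pair inside a track must overlap
    for (t in tracks) {
      if (t$n_frames >= 2) {
        for (i in seq_len(t$n_frames - 1)) {
          expect_equal(t$frames[i + 1], t$frames[i] + 1)
          expect_gte(overlap(t$blobs[[i]], t$blobs[[i + 1]]), 1)
        }
      }
    }
    # and the track set partitions the blobs exactly
    n_blobs <- sum(lengths(bf))
    expect_equal(sum(vapply(tracks, `[[`, numeric(1), "n_frames")), n_blobs)
    # no two unlinked blobs in consecutive frames of different tracks with
    # overlap while one of them ends a track (greedy maximality)
    ends <- lapply(tracks, function(t)
      list(f = t$frames[t$n_frames], b = t$blobs[[t$n_frames]]))
    starts <- lapply(tracks, function(t)
      list(f = t$frames[1], b = t$blobs[[1]]))
    for (e in ends) for (s in starts) {
      if (s$f == e$f + 1) expect_equal(overlap(e$b, s$b), 0)
    }
  }
})

test_that("the consensus definition rejects short and lumen-connected tracks", {
  short <- list(frames = 4:5, n_frames = 2L,
                blobs = list(mkblob(4, 5:6, 10:11), mkblob(5, 5:6, 10:11)))
  class(short) <- "microvessel_track"
  expect_equal(apply_definition(short)$reason, "too short")
  # with min_frames = 2 the length gate passes; depths 10-11 clear the lumen
  expect_true(apply_definition(short, min_frames = 2L)$keep)
  touching <- list(frames = 1:4, n_frames = 4L,
                   blobs = lapply(1:4, function(f) mkblob(f, 8:9, 1:3)))
  class(touching) <- "microvessel_track"
  expect_equal(apply_definition(touching)$reason, "lumen-connected")
  interior <- list(frames = 1:5, n_frames = 5L,
                   blobs = lapply(1:5, function(f) mkblob(f, 8:9, 40:42)))
  class(interior) <- "microvessel_track"
  expect_true(apply_definition(interior)$keep)
  # the strict "more than three frames" reading
  three <- list(frames = 1:3, n_frames = 3L,
                blobs = lapply(1:3, function(f) mkblob(f, 8:9, 40:42)))
  class(three) <- "microvessel_track"
  expect_true(apply_definition(three, min_frames = 3L)$keep)
  expect_false(apply_definition(three, min_frames = 4L)$keep)
})

test_that("length and diameter follow the stated formulas", {
  t37 <- list(frames = 1:37, n_frames = 37L,
              blobs = lapply(1:37, function(f) mkblob(f, 10:11, 30:31)))
  class(t37) <- "microvessel_track"
  q <- quantify_track(t37, radial_px_um = 5, frame_pitch_mm = 0.2)
  expect_equal(q$length_mm, 7.4)
  one <- list(frames = 1L, n_frames = 1L, blobs = list(mkblob(1, 5, 9)))
  class(one) <- "microvessel_track"
  q1 <- quantify_track(one, 5, 0.2)
  expect_equal(q1$mean_diameter_um, 2 * sqrt(1 / pi) * 5, tolerance = 1e-12)
  expect_error(quantify_track(one), "metadata")
  # translation invariance of the diameter
  shifted <- list(frames = 1L, n_frames = 1L,
                  blobs = list(mkblob(1, 50, 90)))
  class(shifted) <- "microvessel_track"
  expect_equal(quantify_track(shifted, 5, 0.2)$mean_diameter_um,
               q1$mean_diameter_um)
  # length is linear in the frame count
  for (n in c(2L, 5L, 9L)) {
    tn <- list(frames = seq_len(n), n_frames = n,
               blobs = lapply(seq_len(n), function(f) mkblob(f, 1:2, 30:31)))
    class(tn) <- "microvessel_track"
    expect_equal(quantify_track(tn, 5, 0.2)$length_mm, n * 0.2)
  }
})

test_that("track tables carry keep decisions and quantities per track", {
  bf <- lapply(1:6, function(f) {
    out <- list()
    if (f <= 4) out <- c(out, list(mkblob(f, 10:12, 40:42)))   # kept tube
    if (f >= 2 && f <= 3) out <- c(out, list(mkblob(f, 30:32, 1:4))) # branch
    out
  })
  tracks <- link_blobs(bf, alines_per_frame = 64L)
  tt <- track_table(tracks, radial_px_um = 5, frame_pitch_mm = 0.2)
  expect_equal(nrow(tt), 2L)
  kept <- tt[tt$kept, ]
  expect_equal(kept$n_frames, 4L)
  expect_equal(kept$length_mm, 0.8)
  expect_true("lumen-connected" %in% tt$reason | "too short" %in% tt$reason)
})
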