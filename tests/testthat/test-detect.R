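# Detection pipeline: preprocessing contract, particle detection against
# ground truth, size filtering, raw-intensity measurement, and F1-based
# threshold calibration.

test_that("preprocess doubles the grid and degrades gracefully", {
  f <- image_field(matrix(runif(64 * 64, 100, 200), 64, 64))
  det <- preprocess(f)
  expect_equal(dim(det$data), c(128L, 128L))
  expect_true(all(det$data >= 0 & det$data <= 65535))
  expect_equal(det$pixel_size, f$pixel_size / 2)

  flat <- image_field(matrix(7, 32, 32))
  expect_warning(det0 <- preprocess(flat), "constant")
  expect_true(all(det0$data == 0))
  gs <- detect_particles(det0)
  expect_equal(nrow(gs$particles), 0L)
})

test_that("noise-free granules are each detected once, at their center", {
  spec <- demo_scene(n_granules = 10, seed = 21)
  out <- generate_field(spec, seed = 1)
  gs <- detect_granules(out$field,
                        detection_params(relative_threshold = 0.35))
  expect_equal(nrow(gs$particles), 10L)
  m <- match_truth_to_particles(gs, spec$granules)
  expect_true(all(m[, "dist"] <= 1))
  expect_equal(length(unique(m[, "particle"])), 10L)
})

test_that("particle count is monotone non-increasing in the threshold", {
  spec <- demo_scene(n_granules = 18, seed = 31)
  out <- generate_field(spec, seed = 1)
  det <- preprocess(out$field)
  counts <- vapply(seq(0.1, 0.9, by = 0.05), function(thr) {
    nrow(detect_particles(det,
                          detection_params(relative_threshold = thr))$particles)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # and in min_size
  counts_sz <- vapply(c(1L, 4L, 9L, 20L, 60L), function(ms) {
    nrow(detect_particles(det,
                          detection_params(relative_threshold = 0.35,
                                           min_size = ms))$particles)
  }, numeric(1))
  expect_true(all(diff(counts_sz) <= 0))
})

test_that("detection is equivariant under whole-pixel shifts", {
  # granules kept away from the field border, where the shift's edge
  # padding would alter the blur
  base <- demo_scene(n_granules = 0, seed = 41)
  g <- sample_granules(base, 14, seed = 41)
  g <- g[g$row >= 24 & g$row <= 104 & g$col >= 24 & g$col <= 104, ]
  expect_gte(nrow(g), 4)
  spec <- scene_spec(field_shape = base$field_shape, cells = base$cells,
                     granules = g)
  out <- generate_field(spec, seed = 1)
  img <- out$field$data
  dr <- 3L; dc <- 5L
  shifted <- img[c(rep(1L, dr), seq_len(nrow(img) - dr)),
                 c(rep(1L, dc), seq_len(ncol(img) - dc))]
  p <- detection_params(relative_threshold = 0.35)
  g1 <- detect_granules(image_field(img), p)
  g2 <- detect_granules(image_field(shifted), p)
  expect_equal(nrow(g2$particles), nrow(g1$particles))
  c1 <- particle_centroids_raw(g1)
  c2 <- particle_centroids_raw(g2)
  ord1 <- order(c1$row, c1$col)
  ord2 <- order(c2$row, c2$col)
  expect_equal(c2$row[ord2] - c1$row[ord1], rep(dr, nrow(c1)),
               tolerance = 0.05)
  expect_equal(c2$col[ord2] - c1$col[ord1], rep(dc, nrow(c1)),
               tolerance = 0.05)
})

test_that("size exclusion keeps particles at or above the cutoff", {
  # particles with areas 4, 12, 13, 40 on a 40 x 40 detection grid
  lab <- matrix(0L, 40, 40)
  lab[2:3, 2:3] <- 1L                # 4 px
  lab[10:12, 10:13] <- 2L            # 12 px
  lab[20:22, 20:23] <- 3L; lab[23, 20] <- 3L   # 13 px
  lab[30:34, 30:37] <- 4L            # 40 px
  gs <- granule_set_from_mask(lab)
  expect_equal(gs$particles$area, c(4L, 12L, 13L, 40L))

  kept <- filter_by_size(gs, 13L)
  expect_equal(sort(kept$particles$area), c(13L, 40L))
  expect_equal(kept$particles$id, c(1L, 2L))       # labels re-compacted
  expect_setequal(unique(as.vector(kept$label_mask)), c(0L, 1L, 2L))

  expect_equal(filter_by_size(gs, 1L)$particles$area, gs$particles$area)
  expect_equal(nrow(filter_by_size(gs, 41L)$particles), 0L)
})

test_that("maxima are measured on the raw image through the grid map", {
  lab <- matrix(0L, 20, 20)
  lab[3:4, 3:4] <- 1L
  lab[11:14, 11:14] <- 2L
  gs <- granule_set_from_mask(lab)
  raw <- image_field(matrix(42, 10, 10))
  gs <- measure_max_on_raw(gs, raw)
  expect_equal(gs$particles$max_raw_intensity, c(42, 42))

  # rank order of measured maxima equals rank order of true amplitudes
  amps <- seq(150, 400, length.out = 20)
  spec <- demo_scene(field_shape = c(192L, 192L), n_granules = 20,
                     amplitude = amps, min_separation = 8, seed = 17)
  out <- generate_field(spec, seed = 1)
  gs2 <- detect_granules(out$field,
                         detection_params(relative_threshold = 0.2))
  expect_equal(nrow(gs2$particles), 20L)
  m <- match_truth_to_particles(gs2, spec$granules)
  measured <- gs2$particles$max_raw_intensity[m[, "particle"]]
  expect_equal(order(measured), order(spec$granules$amplitude))
  # noise-free additive rendering: peak = cytoplasm + amplitude
  expect_equal(measured, spec$cytoplasm_level + spec$granules$amplitude,
               tolerance = 1e-6)
})

test_that("F1 scoring matches hand-enumerated confusion counts", {
  # 8 disjoint particles; 6 annotations inside 6 distinct particles,
  # 4 annotations in empty background
  lab <- matrix(0L, 60, 60)
  for (i in 1:8) lab[(5 * i):(5 * i + 1), 40:41] <- i
  gs <- granule_set_from_mask(lab)
  ann <- data.frame(
    row = c(sapply(1:6, function(i) (5 * i) / 2 + 0.25), 5, 10, 15, 20),
    col = c(rep(20.25, 6), rep(5, 4))
  )
  res <- f1_against_annotations(gs, ann)
  expect_equal(res$tp, 6L)
  expect_equal(res$precision, 6 / 8)
  expect_equal(res$recall, 6 / 10)
  expect_equal(res$f1, 2 / 3, tolerance = 1e-12)

  # degenerate cases
  empty <- granule_set_from_mask(matrix(0L, 20, 20))
  expect_equal(f1_against_annotations(empty, ann)$f1, 0)
  expect_equal(f1_against_annotations(gs,
                                      ann[0, , drop = FALSE])$f1, 0)
})

test_that("F1 scoring agrees with the brute-force oracle on random cases", {
  for (s in 1:25) {
    set.seed(s)
    n_par <- sample(1:20, 1)
    lab <- matrix(0L, 80, 80)
    pos <- sample(20:60, 2 * n_par, replace = TRUE)
    placed <- 0L
    for (i in seq_len(n_par)) {
      r <- pos[2 * i - 1]; c <- pos[2 * i]
      if (all(lab[(r - 1):(r + 1), (c - 1):(c + 1)] == 0L)) {
        placed <- placed + 1L
        lab[r, c] <- placed
      }
    }
    gs <- granule_set_from_mask(lab)
    n_ann <- sample(0:15, 1)
    ann <- data.frame(row = runif(n_ann, 1, 40), col = runif(n_ann, 1, 40))
    got <- f1_against_annotations(gs, ann)
    want <- oracle_f1(gs, ann)
    expect_equal(got$f1, want$f1, info = sprintf("seed %d", s))
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
  }
})

test_that("threshold calibration returns the grid argmax, ties upward", {
  expect_equal(
    calibrate_threshold(
      list(generate_field(demo_scene(n_granules = 5, seed = 3),
                          seed = 1)$field),
      list(demo_scene(n_granules = 5, seed = 3)$granules[c("row", "col")]),
      grid = 0.6234
    )$best_threshold,
    0.6234
  )

  fields <- list(); anns <- list()
  for (i in 1:3) {
    spec <- demo_scene(n_granules = 8 + i, seed = 50 + i)
    fields[[i]] <- generate_field(spec, seed = i)$field
    anns[[i]] <- spec$granules[c("row", "col")]
  }
  grid <- seq(0.1, 0.6, by = 0.05)
  cal <- calibrate_threshold(fields, anns, grid = grid)

  # independent exhaustive sweep
  mean_f1 <- vapply(grid, function(thr) {
    mean(vapply(seq_along(fields), function(i) {
      gs <- detect_granules(fields[[i]],
                            detection_params(relative_threshold = thr))
      f1_against_annotations(gs, anns[[i]])$f1
    }, numeric(1)))
  }, numeric(1))
  best <- max(grid[mean_f1 == max(mean_f1)])
  expect_equal(cal$best_threshold, best)
  expect_equal(cal$curve$mean_f1, mean_f1)

  # permutation invariance of the grid
  cal2 <- calibrate_threshold(fields, anns, grid = rev(grid))
  expect_equal(cal2$best_threshold, cal$best_threshold)
  expect_equal(cal2$curve, cal$curve)
})
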