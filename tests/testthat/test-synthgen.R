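# Synthetic scene generator: rendering identities, determinism, noise
# statistics, and the validity of every ground-truth record.

test_that("noise-free rendering is the analytic template plus granules", {
  spec0 <- demo_scene(n_granules = 0, seed = 1)
  out <- generate_field(spec0, seed = 1)
  vals <- sort(unique(as.vector(out$field$data)))
  expect_setequal(vals, c(spec0$background_level, spec0$cytoplasm_level))
  expect_equal(max(out$field$data), spec0$cytoplasm_level)

  spec1 <- demo_scene(n_granules = 1, amplitude = 300, seed = 7)
  o1 <- generate_field(spec1, seed = 1)
  g <- spec1$granules
  expect_equal(o1$field$data[g$row, g$col], spec1$cytoplasm_level + 300)
  expect_equal(max(o1$field$data), spec1$cytoplasm_level + 300)
})

test_that("noise-free integrated intensity matches the analytic total", {
  spec <- demo_scene(n_granules = 10, amplitude = 250, seed = 3)
  tmpl <- generate_field(demo_scene(n_granules = 0, seed = 3), seed = 1)
  out <- generate_field(spec, seed = 1)
  analytic <- sum(tmpl$field$data) + sum(2 * pi * spec$granules$sigma^2 *
                                           spec$granules$amplitude)
  expect_equal(sum(out$field$data), analytic, tolerance = 1e-4)
})

test_that("identical spec and seed give bit-identical fields", {
  spec <- demo_scene(n_granules = 8, noise_gaussian_sd = 12,
                     noise_poisson_gain = 2, seed = 2)
  a <- generate_field(spec, seed = 99)
  b <- generate_field(spec, seed = 99)
  c <- generate_field(spec, seed = 100)
  expect_identical(a$field$data, b$field$data)
  expect_false(identical(a$field$data, c$field$data))
})

test_that("noisy fields average back to the noise-free template", {
  spec <- demo_scene(n_granules = 25, noise_gaussian_sd = 10, seed = 4,
                     min_separation = 6)
  clean <- generate_field(demo_scene(n_granules = 25, seed = 4,
                                     min_separation = 6), seed = 1)
  n_seeds <- 100
  acc <- 0
  for (s in seq_len(n_seeds)) {
    acc <- acc + generate_field(spec, seed = s)$field$data
  }
  avg <- acc / n_seeds
  sem <- 10 / sqrt(n_seeds)
  dev <- abs(avg - clean$field$data)
  # ~0.3% of pixels are expected beyond 3 SEM by chance alone
  expect_lt(mean(dev > 3 * sem), 0.01)
  expect_lt(abs(mean(avg) - mean(clean$field$data)), 3 * sem)
})

test_that("scene validation rejects misplaced granules and bad levels", {
  base <- demo_scene(n_granules = 0, seed = 1)
  corner <- data.frame(row = 1, col = 1, sigma = 1.5, amplitude = 300)
  expect_error(
    scene_spec(field_shape = base$field_shape, cells = base$cells,
               granules = corner),
    "outside every cytoplasmic ring"
  )
  expect_error(ring_cell(c(10, 10), 12, 10), "inner_radius")
  expect_error(
    scene_spec(cells = base$cells, cytoplasm_level = -5),
    ">= 0"
  )
})

test_that("kinetics follow the closed-form relaxation law", {
  kin <- kinetics_spec(n_frames = 30, stimulus_frame = 5,
                       initial_partition = 2.5, final_partition = 1.5,
                       rate_k = 0.1)
  rho <- partition_trajectory(kin)
  expect_equal(rho[1:4], rep(2.5, 4))
  expect_equal(rho[5], 2.5)
  expect_equal(rho[15], 1.5 + 1.0 * exp(-1))   # stimulus + 10 frames

  # zero rate: amplitudes constant across every frame of the ground truth
  kin0 <- kinetics_spec(n_frames = 6, stimulus_frame = 2,
                        initial_partition = 2.5, final_partition = 2.5,
                        rate_k = 0)
  spec <- demo_scene(n_granules = 5, seed = 6)
  tl <- generate_timelapse(spec, kin0, seed = 3)
  amps <- tapply(tl$truth$granules$amplitude, tl$truth$granules$frame, mean)
  expect_equal(unname(diff(range(amps))), 0)

  expect_error(
    kinetics_spec(n_frames = 10, stimulus_frame = 2,
                  initial_partition = 2, final_partition = 0.8,
                  rate_k = 0.1),
    "final_partition"
  )
})

test_that("timelapse frames share geometry and honor conservation", {
  spec <- demo_scene(n_granules = 6, seed = 8)
  kin <- kinetics_spec(n_frames = 8, stimulus_frame = 2,
                       initial_partition = 2.5, final_partition = 1.2,
                       rate_k = 0.5)
  tl <- generate_timelapse(spec, kin, seed = 5, conserve_total = TRUE)
  totals <- vapply(tl$frames, function(f) sum(f$data), numeric(1))
  expect_lt(diff(range(totals)) / totals[1], 1e-3)
  expect_true(all(diff(tl$truth$cytoplasm_by_frame) >= 0))
})

test_that("smFISH placement honors the requested in-granule fraction", {
  base <- demo_scene(field_shape = c(192L, 192L), n_granules = 60,
                     min_separation = 7, seed = 11)

  p0 <- generate_smfish_pair(base, n_spots = 40, in_granule_fraction = 0,
                             seed = 2)
  g <- base$granules
  min_d <- vapply(seq_len(nrow(p0$truth$spots)), function(i) {
    min(sqrt((g$row - p0$truth$spots$row[i])^2 +
               (g$col - p0$truth$spots$col[i])^2) / g$sigma)
  }, numeric(1))
  expect_true(all(min_d > 2))
  expect_false(any(p0$truth$spots$in_granule))

  p1 <- generate_smfish_pair(base, n_spots = 50, in_granule_fraction = 1,
                             seed = 2)
  expect_true(all(p1$truth$spots$in_granule))
  expect_equal(nrow(p1$truth$spots), 50)

  pq <- generate_smfish_pair(base, n_spots = 200,
                             in_granule_fraction = 0.25, seed = 2)
  expect_equal(sum(pq$truth$spots$in_granule), 50)
  expect_equal(dim(pq$spot_field$data), dim(pq$granule_field$data))

  no_g <- demo_scene(field_shape = c(192L, 192L), n_granules = 0, seed = 1)
  expect_error(
    generate_smfish_pair(no_g, n_spots = 10, in_granule_fraction = 0.5,
                         seed = 1),
    "requires granules"
  )
})

test_that("calcium traces follow the piecewise law and recover dF/F", {
  flat <- generate_calcium_trace(baseline = 100, peak_delta = 0,
                                 peak_frame = 10, decay_rate = 0.2,
                                 plateau_delta = 0, n_frames = 20,
                                 noise_sd = 0, seed = 1)
  expect_equal(flat$values, rep(100, 20))

  tr <- generate_calcium_trace(baseline = 100, peak_delta = 50,
                               peak_frame = 12, decay_rate = 0.3,
                               plateau_delta = 10, n_frames = 40,
                               noise_sd = 0, seed = 1)
  expect_equal(tr$values[12], 150)
  expect_equal(tr$values[1:5], rep(100, 5))   # baseline through stimulus
  expect_equal(delta_f_over_f(tr)[12], 0.5)

  # Monte-Carlo: noisy peaks average to the true dF/F
  peaks <- vapply(1:200, function(s) {
    max(delta_f_over_f(generate_calcium_trace(
      baseline = 100, peak_delta = 50, peak_frame = 12, decay_rate = 0.3,
      plateau_delta = 0, n_frames = 40, noise_sd = 5, seed = s)))
  }, numeric(1))
  sem <- stats::sd(peaks) / sqrt(length(peaks))
  # the max over noisy frames biases upward by < 1 SEM at this noise level
  expect_lt(abs(mean(peaks) - 0.5), 3 * sem + 0.01)

  expect_error(
    generate_calcium_trace(baseline = 0, peak_delta = 10, peak_frame = 5,
                           decay_rate = 0.1, n_frames = 10, seed = 1),
    "baseline"
  )
})

test_that("scenes and ground truth round-trip through YAML and CSV", {
  spec <- demo_scene(n_granules = 4, noise_gaussian_sd = 3, seed = 9)
  path <- tempfile(fileext = ".yaml")
  write_scene(spec, path)
  back <- read_scene(path)
  expect_equal(back$granules, spec$granules)
  expect_equal(back$cytoplasm_level, spec$cytoplasm_level)
  expect_equal(length(back$cells), length(spec$cells))

  out <- generate_smfish_pair(demo_scene(n_granules = 10, seed = 2,
                                         field_shape = c(192L, 192L)),
                              n_spots = 20, in_granule_fraction = 0.5,
                              seed = 3)
  prefix <- tempfile()
  paths <- write_ground_truth(out$truth, prefix)
  gt <- utils::read.csv(paths[1])
  expect_equal(nrow(gt), 10)
  sp <- utils::read.csv(paths[2])
  expect_equal(sum(sp$in_granule), 10)
})
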