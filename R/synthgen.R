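#' Describe one ring-shaped cell body
#'
#' In high-resolution confocal sections of fly brain cell bodies, most of the
#' cell volume is occupied by the nucleus, so the cytoplasm appears as a
#' bright ring around a darker nuclear void. A cell is therefore described by
#' its center and two radii: pixels at distance `(inner_radius, outer_radius]`
#' from the center render at the cytoplasm level, pixels inside
#' `inner_radius` at the background level.
#'
#' @param center Numeric `c(row, col)` center in pixels.
#' @param inner_radius,outer_radius Nuclear and cell radii in pixels;
#'   `inner_radius < outer_radius`.
#' @return A `ring_cell` list.
#' @export
ring_cell <- function(center, inner_radius, outer_radius) {
  stopifnot(is.numeric(center), length(center) == 2L)
  .stopifnot_scalar(inner_radius, "inner_radius")
  .stopifnot_scalar(outer_radius, "outer_radius")
  if (inner_radius < 0 || inner_radius >= outer_radius) {
    stop("need 0 <= inner_radius < outer_radius", call. = FALSE)
  }
  structure(list(center = as.numeric(center), inner = inner_radius,
                 outer = outer_radius), class = "ring_cell")
}

#' Synthetic scene specification
#'
#' A `scene_spec` declares everything needed to render one synthetic
#' confocal field deterministically: the field geometry, ring-shaped cells,
#' intensity levels, a table of granules, and the noise model. Granules are
#' rendered as isotropic 2D Gaussians (near-diffraction-limited 100-200 nm
#' puncta); each adds `amplitude * exp(-d^2 / (2 sigma^2))` on top of the
#' local cytoplasm level, so the true partition coefficient of a noise-free
#' granule is `(cytoplasm_level + amplitude) / cytoplasm_level`.
#'
#' @param field_shape Integer `c(rows, cols)` in pixels.
#' @param pixel_size Micrometers per pixel (default 0.043).
#' @param cells List of [ring_cell()] descriptors.
#' @param cytoplasm_level Diffuse cytoplasmic intensity (arbitrary camera
#'   units).
#' @param background_level Intensity outside cells and inside nuclei. The
#'   default (half the cytoplasm level) reflects that nuclei in real confocal
#'   sections are dimmer than cytoplasm but not black.
#' @param granules Data frame with columns `row`, `col`, `sigma`,
#'   `amplitude` (pixels / intensity units); every center must fall inside a
#'   cytoplasmic ring.
#' @param noise_gaussian_sd Additive Gaussian read-noise sd (0 disables).
#' @param noise_poisson_gain Photon shot-noise gain; intensities are drawn
#'   as `gain * Poisson(I / gain)` (0 disables).
#' @param bit_depth 16 or 32; rendered values are clipped (camera
#'   saturation), never wrapped.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(field_shape = c(128L, 128L), pixel_size = 0.043,
                       cells = list(), cytoplasm_level = 200,
                       background_level = cytoplasm_level / 2,
                       granules = NULL, noise_gaussian_sd = 0,
                       noise_poisson_gain = 0, bit_depth = 16L) {
  stopifnot(is.numeric(field_shape), length(field_shape) == 2L,
            all(field_shape >= 8))
  .stopifnot_scalar(cytoplasm_level, "cytoplasm_level")
  .stopifnot_scalar(background_level, "background_level")
  .stopifnot_scalar(noise_gaussian_sd, "noise_gaussian_sd")
  .stopifnot_scalar(noise_poisson_gain, "noise_poisson_gain")
  if (cytoplasm_level < 0 || background_level < 0 || noise_gaussian_sd < 0 ||
      noise_poisson_gain < 0) {
    stop("intensity levels and noise parameters must be >= 0", call. = FALSE)
  }
  if (!all(vapply(cells, inherits, logical(1), "ring_cell"))) {
    stop("`cells` must be a list of ring_cell() objects", call. = FALSE)
  }
  if (is.null(granules)) {
    granules <- data.frame(row = numeric(0), col = numeric(0),
                           sigma = numeric(0), amplitude = numeric(0))
  }
  stopifnot(is.data.frame(granules),
            all(c("row", "col", "sigma", "amplitude") %in% names(granules)))
  if (nrow(granules) && (any(granules$sigma <= 0) ||
                         any(granules$amplitude <= 0))) {
    stop("granule sigma and amplitude must be > 0", call. = FALSE)
  }
  spec <- structure(
    list(field_shape = as.integer(field_shape), pixel_size = pixel_size,
         cells = cells, cytoplasm_level = cytoplasm_level,
         background_level = background_level, granules = granules,
         noise_gaussian_sd = noise_gaussian_sd,
         noise_poisson_gain = noise_poisson_gain,
         bit_depth = as.integer(bit_depth)),
    class = "scene_spec"
  )
  .validate_scene(spec)
  spec
}

# Distance of points to each cell center; TRUE when inside some cytoplasmic
# ring (strictly between inner and outer radius).
.in_ring <- function(rows, cols, cells, margin = 0) {
  if (!length(cells)) return(rep(FALSE, length(rows)))
  inside <- rep(FALSE, length(rows))
  for (cell in cells) {
    d <- sqrt((rows - cell$center[1])^2 + (cols - cell$center[2])^2)
    inside <- inside | (d > cell$inner + margin & d < cell$outer - margin)
  }
  inside
}

.validate_scene <- function(spec) {
  g <- spec$granules
  if (nrow(g)) {
    ok <- .in_ring(g$row, g$col, spec$cells)
    if (!all(ok)) {
      stop(sprintf("%d granule center(s) fall outside every cytoplasmic ring",
                   sum(!ok)), call. = FALSE)
    }
    if (any(g$row < 1 | g$row > spec$field_shape[1] |
            g$col < 1 | g$col > spec$field_shape[2])) {
      stop("granule centers must lie inside the field", call. = FALSE)
    }
  }
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("<scene_spec> %d x %d px, %d cell(s), %d granule(s), ",
                     "cytoplasm %g / background %g\n"),
              x$field_shape[1], x$field_shape[2], length(x$cells),
              nrow(x$granules), x$cytoplasm_level, x$background_level))
  invisible(x)
}

# Noise-free scene template: background everywhere, cytoplasm on rings,
# nuclear voids back at background level. Later cells overwrite earlier ones.
.render_template <- function(spec, cytoplasm_level = spec$cytoplasm_level) {
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  img <- matrix(spec$background_level, nr, nc)
  if (length(spec$cells)) {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (cell in spec$cells) {
      d2 <- (rows - cell$center[1])^2 + (cols - cell$center[2])^2
      img[d2 <= cell$outer^2] <- cytoplasm_level
      img[d2 <= cell$inner^2] <- spec$background_level
    }
  }
  img
}

# Add granule Gaussians in a local window (+/- 5 sigma) around each center.
.render_granules <- function(img, granules) {
  if (!nrow(granules)) return(img)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_len(nrow(granules))) {
    g <- granules[i, ]
    w <- ceiling(5 * g$sigma)
    rr <- max(1L, floor(g$row - w)):min(nr, ceiling(g$row + w))
    cc <- max(1L, floor(g$col - w)):min(nc, ceiling(g$col + w))
    dr2 <- (rr - g$row)^2
    dc2 <- (cc - g$col)^2
    img[rr, cc] <- img[rr, cc] +
      g$amplitude * exp(-outer(dr2, dc2, "+") / (2 * g$sigma^2))
  }
  img
}

.apply_noise_and_clip <- function(img, spec) {
  if (spec$noise_poisson_gain > 0) {
    img <- spec$noise_poisson_gain *
      matrix(stats::rpois(length(img), img / spec$noise_poisson_gain),
             nrow(img), ncol(img))
  }
  if (spec$noise_gaussian_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_gaussian_sd),
                        nrow(img), ncol(img))
  }
  pmin(pmax(img, 0), 2^spec$bit_depth - 1)
}

#' Ground-truth record of a synthetic scene
#'
#' Holds everything needed to recompute every expected downstream
#' measurement without the rendered image: the granule table (per frame for
#' time-lapses), RNA spot positions with their in-granule flags, the kinetic
#' law if any, and the seed used.
#'
#' @param granules Data frame `frame, row, col, sigma, amplitude`.
#' @param spots Data frame `row, col, in_granule` or `NULL`.
#' @param kinetics A [kinetics_spec()] or `NULL`.
#' @param seed Integer seed the scene was rendered with.
#' @param cytoplasm_by_frame Per-frame diffuse cytoplasm level (scalar for
#'   single fields).
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(granules, spots = NULL, kinetics = NULL, seed = NA,
                         cytoplasm_by_frame = NA) {
  structure(list(granules = granules, spots = spots, kinetics = kinetics,
                 seed = seed, cytoplasm_by_frame = cytoplasm_by_frame),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d granule record(s), %s spot(s), seed %s\n",
              nrow(x$granules),
              if (is.null(x$spots)) "no" else nrow(x$spots),
              format(x$seed)))
  invisible(x)
}

#' Render one synthetic confocal field with ground truth
#'
#' Deterministically renders `background + ring cytoplasm + granule
#' Gaussians`, then applies the scene's noise model and clips to the
#' declared bit depth. Identical spec and seed give bit-identical output.
#'
#' @param spec A valid [scene_spec()].
#' @param seed Integer seed for the noise draws (required; the package keeps
#'   no global RNG state).
#' @param channel Channel label attached to the field.
#' @return `list(field = image_field, truth = ground_truth)`.
#' @export
generate_field <- function(spec, seed, channel = "granule") {
  stopifnot(inherits(spec, "scene_spec"))
  .validate_scene(spec)
  img <- .render_granules(.render_template(spec), spec$granules)
  img <- .with_seed(seed, .apply_noise_and_clip(img, spec))
  g <- spec$granules
  truth <- ground_truth(
    granules = if (nrow(g)) cbind(frame = 1L, g) else
      cbind(frame = integer(0), g),
    seed = seed, cytoplasm_by_frame = spec$cytoplasm_level
  )
  list(field = image_field(img, pixel_size = spec$pixel_size,
                           channel = channel, bit_depth = spec$bit_depth),
       truth = truth)
}

#' Sample granule positions inside the cytoplasmic rings
#'
#' Rejection-samples granule centers at integer pixel positions inside the
#' scene's rings, keeping a margin from ring borders and a minimum pairwise
#' separation so that puncta are resolvable by the detector.
#'
#' @param spec A [scene_spec()] (its `granules` table is ignored).
#' @param n Number of granules.
#' @param sigma Gaussian radius parameter in pixels (default 1.5, a
#'   point-spread-limited punctum at 0.043 um/px).
#' @param amplitude Peak intensity above the cytoplasm level; scalar or
#'   length-`n` vector.
#' @param min_separation Minimum center-to-center distance in pixels.
#' @param margin Distance kept from the ring borders in pixels.
#' @param seed Integer seed.
#' @return Data frame `row, col, sigma, amplitude` usable as
#'   `scene_spec(granules = ...)`.
#' @export
sample_granules <- function(spec, n, sigma = 1.5, amplitude = 300,
                            min_separation = 6, margin = 3, seed) {
  stopifnot(inherits(spec, "scene_spec"), n >= 0)
  if (n == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), sigma = numeric(0),
                      amplitude = numeric(0)))
  }
  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  ok <- .in_ring(rows, cols, spec$cells, margin = margin)
  cand <- cbind(rows[ok], cols[ok])
  if (nrow(cand) < n) stop("not enough ring area to place granules",
                           call. = FALSE)
  amplitude <- rep_len(amplitude, n)
  sigma <- rep_len(sigma, n)
  .with_seed(seed, {
    picked <- matrix(NA_real_, 0, 2)
    order_idx <- sample.int(nrow(cand))
    for (i in order_idx) {
      p <- cand[i, ]
      if (!nrow(picked) ||
          min((picked[, 1] - p[1])^2 + (picked[, 2] - p[2])^2) >=
            min_separation^2) {
        picked <- rbind(picked, p)
        if (nrow(picked) == n) break
      }
    }
    if (nrow(picked) < n) {
      stop("could not place granules at the requested separation",
           call. = FALSE)
    }
    data.frame(row = picked[, 1], col = picked[, 2], sigma = sigma,
               amplitude = amplitude)
  })
}

#' A ready-made packed-tissue scene
#'
#' Convenience builder for the canonical test scene: a crop from packed
#' tissue, rendered as a 2 x 2 tile of ring-shaped cell bodies whose rings
#' extend past the field borders (as in a region cropped from a field of
#' adjacent cell bodies), with `n_granules` sampled puncta. Cytoplasm
#' covers most of the field, which keeps the cytoplasm-mask threshold (the
#' global mean of the sigma-8-blurred image) strictly inside the
#' cytoplasm.
#'
#' @param field_shape `c(rows, cols)`.
#' @param n_granules Number of granules to sample.
#' @param amplitude,sigma Granule parameters (see [sample_granules()]).
#' @param min_separation Pairwise granule separation in pixels.
#' @param cytoplasm_level,background_level,noise_gaussian_sd,noise_poisson_gain
#'   Passed to [scene_spec()].
#' @param seed Integer seed for granule placement.
#' @return A [scene_spec()] with granules filled in.
#' @export
demo_scene <- function(field_shape = c(128L, 128L), n_granules = 15,
                       amplitude = 300, sigma = 1.5, min_separation = 6,
                       cytoplasm_level = 200,
                       background_level = cytoplasm_level / 2,
                       noise_gaussian_sd = 0, noise_poisson_gain = 0,
                       seed = 1L) {
  outer_r <- round(min(field_shape) * 0.265)
  inner_r <- max(6, round(outer_r * 0.32))
  centers <- expand.grid(r = field_shape[1] * c(0.25, 0.75),
                         c = field_shape[2] * c(0.25, 0.75))
  cells <- lapply(seq_len(nrow(centers)), function(i) {
    ring_cell(c(centers$r[i], centers$c[i]), inner_r, outer_r)
  })
  base <- scene_spec(field_shape = field_shape,
                     cells = cells,
                     cytoplasm_level = cytoplasm_level,
                     background_level = background_level,
                     noise_gaussian_sd = noise_gaussian_sd,
                     noise_poisson_gain = noise_poisson_gain)
  g <- sample_granules(base, n_granules, sigma = sigma, amplitude = amplitude,
                       min_separation = min_separation, seed = seed)
  scene_spec(field_shape = field_shape, cells = base$cells,
             cytoplasm_level = cytoplasm_level,
             background_level = background_level, granules = g,
             noise_gaussian_sd = noise_gaussian_sd,
             noise_poisson_gain = noise_poisson_gain)
}

#' Decondensation kinetics for a time-lapse
#'
#' After a stimulus frame, the mean partition coefficient relaxes
#' exponentially from `initial_partition` to `final_partition`:
#' `rho(t) = final + (initial - final) * exp(-rate_k * (t - stimulus_frame))`
#' for `t >= stimulus_frame`, and `rho(t) = initial` before. A granule
#' dimmer than the cytoplasm is not modeled, so `final_partition >= 1`.
#'
#' @param n_frames Number of frames.
#' @param frame_interval Seconds between frames (default 30).
#' @param stimulus_frame 1-based frame index at which the stimulus is
#'   applied.
#' @param initial_partition,final_partition Partition coefficients before
#'   and long after the stimulus; `initial >= final >= 1`.
#' @param rate_k Per-frame exponential relaxation rate (>= 0).
#' @return A `kinetics_spec` list.
#' @export
kinetics_spec <- function(n_frames, frame_interval = 30, stimulus_frame,
                          initial_partition, final_partition, rate_k) {
  .stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  .stopifnot_scalar(rate_k, "rate_k")
  if (final_partition < 1) {
    stop("final_partition must be >= 1 (granules dimmer than cytoplasm are not modeled)",
         call. = FALSE)
  }
  if (initial_partition < final_partition) {
    stop("need initial_partition >= final_partition", call. = FALSE)
  }
  if (rate_k < 0) stop("rate_k must be >= 0", call. = FALSE)
  if (stimulus_frame < 1 || stimulus_frame >= n_frames) {
    stop("stimulus_frame must fall before the last frame", call. = FALSE)
  }
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 stimulus_frame = as.integer(stimulus_frame),
                 initial_partition = initial_partition,
                 final_partition = final_partition, rate_k = rate_k),
            class = "kinetics_spec")
}

#' Closed-form partition trajectory of a kinetics spec
#'
#' @param kinetics A [kinetics_spec()].
#' @return Numeric vector `rho(t)` for frames `1..n_frames`.
#' @export
partition_trajectory <- function(kinetics) {
  stopifnot(inherits(kinetics, "kinetics_spec"))
  t <- seq_len(kinetics$n_frames)
  rho <- rep(kinetics$initial_partition, kinetics$n_frames)
  post <- t >= kinetics$stimulus_frame
  rho[post] <- kinetics$final_partition +
    (kinetics$initial_partition - kinetics$final_partition) *
    exp(-kinetics$rate_k * (t[post] - kinetics$stimulus_frame))
  rho
}

#' Render a decondensation time-lapse with ground truth
#'
#' All frames share the scene's cell geometry and granule positions; granule
#' amplitudes are set per frame from the kinetic law so that the true
#' partition coefficient of every granule at frame `t` equals `rho(t)`
#' exactly in the noise-free ground truth (`amplitude_t = cytoplasm_t *
#' (rho(t) - 1)`). Noise draws are independent across frames.
#'
#' With `conserve_total = TRUE`, intensity leaving the granules is returned
#' to the diffuse pool: the cytoplasm level rises so that the total
#' noise-free intensity integral is constant across frames (decondensation
#' without protein-level change).
#'
#' @param spec A [scene_spec()]; its granule amplitudes are overridden by
#'   the kinetic law (positions and sigmas are kept).
#' @param kinetics A [kinetics_spec()].
#' @param seed Integer seed.
#' @param conserve_total Redistribute granule intensity into the cytoplasm
#'   (default `FALSE`).
#' @return `list(frames = list of image_field, truth = ground_truth)`.
#' @export
generate_timelapse <- function(spec, kinetics, seed, conserve_total = FALSE) {
  stopifnot(inherits(spec, "scene_spec"), inherits(kinetics, "kinetics_spec"))
  if (!nrow(spec$granules)) stop("scene has no granules", call. = FALSE)
  .validate_scene(spec)
  rho <- partition_trajectory(kinetics)
  g0 <- spec$granules
  # cytoplasm trajectory under conservation of total intensity
  cyto <- rep(spec$cytoplasm_level, kinetics$n_frames)
  if (conserve_total) {
    nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
    rows <- rep(seq_len(nr), nc)
    cols <- rep(seq_len(nc), each = nr)
    ring_area <- sum(.in_ring(rows, cols, spec$cells))
    gmass <- sum(2 * pi * g0$sigma^2)     # integral of a unit-peak Gaussian
    rho0 <- rho[1]
    cyto <- spec$cytoplasm_level * (ring_area + (rho0 - 1) * gmass) /
      (ring_area + (rho - 1) * gmass)
  }
  frames <- vector("list", kinetics$n_frames)
  per_frame <- vector("list", kinetics$n_frames)
  seeds <- .with_seed(seed,
                      sample.int(.Machine$integer.max - 1L,
                                 kinetics$n_frames))
  for (t in seq_len(kinetics$n_frames)) {
    g <- g0
    g$amplitude <- cyto[t] * (rho[t] - 1)
    img <- .render_granules(.render_template(spec, cytoplasm_level = cyto[t]),
                            g)
    img <- .with_seed(seeds[t], .apply_noise_and_clip(img, spec))
    frames[[t]] <- image_field(img, pixel_size = spec$pixel_size,
                               channel = "granule",
                               bit_depth = spec$bit_depth)
    per_frame[[t]] <- cbind(frame = t, g)
  }
  truth <- ground_truth(granules = do.call(rbind, per_frame),
                        kinetics = kinetics, seed = seed,
                        cytoplasm_by_frame = cyto)
  list(frames = frames, truth = truth)
}

#' Render a registered granule / smFISH channel pair
#'
#' Places `round(n_spots * in_granule_fraction)` RNA spots at granule
#' positions (one spot per granule, jittered by at most one pixel) and the
#' remainder in granule-free cytoplasm, more than `2 * sigma + 1` pixels
#' away from every granule center. Both channels share the cell geometry and
#' are returned registered, along with the ground truth of every placement.
#'
#' @param spec A [scene_spec()] with granules (the granule channel).
#' @param n_spots Total number of RNA spots.
#' @param in_granule_fraction Requested fraction of spots inside granules,
#'   in `[0, 1]`.
#' @param seed Integer seed.
#' @param spot_sigma,spot_amplitude Rendering parameters of the smFISH
#'   spots (diffraction-limited, dimmer channel).
#' @param spot_cytoplasm_level,spot_background_level Diffuse levels of the
#'   smFISH channel.
#' @param min_spot_separation Minimum spot-to-spot distance in pixels, so
#'   spots stay individually resolvable.
#' @return `list(granule_field, spot_field, truth)`.
#' @export
generate_smfish_pair <- function(spec, n_spots, in_granule_fraction, seed,
                                 spot_sigma = 1.2, spot_amplitude = 250,
                                 spot_cytoplasm_level = 120,
                                 spot_background_level = 100,
                                 min_spot_separation = 5) {
  stopifnot(inherits(spec, "scene_spec"))
  if (in_granule_fraction < 0 || in_granule_fraction > 1) {
    stop("in_granule_fraction must be in [0, 1]", call. = FALSE)
  }
  g <- spec$granules
  n_in <- round(n_spots * in_granule_fraction)
  if (n_in > 0 && !nrow(g)) {
    stop("in_granule_fraction > 0 requires granules in the scene",
         call. = FALSE)
  }
  if (n_in > nrow(g) && n_in > 0) {
    stop(sprintf("need at least %d granules to host %d in-granule spots",
                 n_in, n_in), call. = FALSE)
  }
  gran <- generate_field(spec, seed, channel = "granule")

  nr <- spec$field_shape[1]; nc <- spec$field_shape[2]
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  in_ring <- .in_ring(rows, cols, spec$cells, margin = 3)
  # candidate out-of-granule positions: cytoplasm, clear of every granule
  clear <- in_ring
  if (nrow(g)) {
    for (i in seq_len(nrow(g))) {
      d2 <- (rows - g$row[i])^2 + (cols - g$col[i])^2
      clear <- clear & d2 > (2 * g$sigma[i] + 1)^2
    }
  }
  spots <- .with_seed(seed + 1L, {
    placed <- matrix(NA_real_, 0, 2)
    flags <- logical(0)
    if (n_in > 0) {
      # an RNA inside a 100-200 nm granule sits within ~1 px of its center
      # at 43 nm/px; sub-pixel jitter keeps the spot inside the footprint
      host <- sample.int(nrow(g), n_in)
      jit <- matrix(stats::runif(2 * n_in, -0.49, 0.49), n_in, 2)
      placed <- cbind(pmin(pmax(g$row[host] + jit[, 1], 1), nr),
                      pmin(pmax(g$col[host] + jit[, 2], 1), nc))
      flags <- rep(TRUE, n_in)
    }
    cand <- which(clear)
    cand <- cand[sample.int(length(cand))]
    for (i in cand) {
      if (nrow(placed) == n_spots) break
      p <- c(rows[i], cols[i])
      if (!nrow(placed) ||
          min((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2) >=
            min_spot_separation^2) {
        placed <- rbind(placed, p)
        flags <- c(flags, FALSE)
      }
    }
    if (nrow(placed) < n_spots) {
      stop("not enough granule-free cytoplasm to place all spots",
           call. = FALSE)
    }
    data.frame(row = placed[, 1], col = placed[, 2], in_granule = flags)
  })

  spot_scene <- scene_spec(
    field_shape = spec$field_shape, pixel_size = spec$pixel_size,
    cells = spec$cells, cytoplasm_level = spot_cytoplasm_level,
    background_level = spot_background_level,
    granules = data.frame(row = spots$row, col = spots$col,
                          sigma = spot_sigma, amplitude = spot_amplitude),
    noise_gaussian_sd = spec$noise_gaussian_sd,
    noise_poisson_gain = spec$noise_poisson_gain,
    bit_depth = spec$bit_depth
  )
  sp <- generate_field(spot_scene, seed + 2L, channel = "smFISH")

  truth <- ground_truth(
    granules = if (nrow(g)) cbind(frame = 1L, g) else
      cbind(frame = integer(0), g),
    spots = spots, seed = seed, cytoplasm_by_frame = spec$cytoplasm_level
  )
  list(granule_field = gran$field, spot_field = sp$field, truth = truth)
}

#' Synthesize a calcium-indicator fluorescence trace
#'
#' Emulates a GCaMP response to a bath-applied stimulus: flat baseline
#' before the stimulus frame, a linear rise to the peak, then exponential
#' decay toward `baseline + plateau_delta` (a lasting intracellular calcium
#' elevation). Optional Gaussian noise is added to every frame.
#'
#' @param baseline Pre-stimulus fluorescence (> 0, so dF/F is defined).
#' @param peak_delta Peak fluorescence increase over baseline.
#' @param peak_frame 1-based frame of the peak.
#' @param decay_rate Per-frame exponential decay rate after the peak.
#' @param plateau_delta Long-term fluorescence increase over baseline.
#' @param n_frames Trace length (> `peak_frame`).
#' @param noise_sd Additive Gaussian noise sd (0 disables).
#' @param seed Integer seed.
#' @param stimulus_frame Frame at which the stimulus is applied (default 5:
#'   four baseline frames, matching the dF/F convention).
#' @param frame_interval Seconds between frames.
#' @return A [calcium_trace()] whose `truth` attribute records the
#'   generating parameters.
#' @export
generate_calcium_trace <- function(baseline, peak_delta, peak_frame,
                                   decay_rate, plateau_delta = 0, n_frames,
                                   noise_sd = 0, seed = 1L,
                                   stimulus_frame = 5L, frame_interval = 30) {
  if (baseline <= 0) stop("baseline must be > 0 (dF/F undefined otherwise)",
                          call. = FALSE)
  if (n_frames <= peak_frame) stop("need n_frames > peak_frame",
                                   call. = FALSE)
  if (stimulus_frame > peak_frame || stimulus_frame < 1) {
    stop("need 1 <= stimulus_frame <= peak_frame", call. = FALSE)
  }
  t <- seq_len(n_frames)
  f <- rep(baseline, n_frames)
  if (peak_frame > stimulus_frame) {
    rise <- t >= stimulus_frame & t <= peak_frame
    f[rise] <- baseline + peak_delta * (t[rise] - stimulus_frame) /
      (peak_frame - stimulus_frame)
  } else {
    f[t == peak_frame] <- baseline + peak_delta
  }
  post <- t > peak_frame
  f[post] <- baseline + plateau_delta + (peak_delta - plateau_delta) *
    exp(-decay_rate * (t[post] - peak_frame))
  if (noise_sd > 0) {
    f <- f + .with_seed(seed, stats::rnorm(n_frames, 0, noise_sd))
  }
  tr <- calcium_trace(f, frame_interval = frame_interval,
                      stimulus_frame = stimulus_frame)
  attr(tr, "truth") <- list(baseline = baseline, peak_delta = peak_delta,
                            peak_frame = peak_frame, decay_rate = decay_rate,
                            plateau_delta = plateau_delta,
                            noise_sd = noise_sd, seed = seed)
  tr
}

#' Write / read scene specifications and ground truth sidecars
#'
#' Scenes round-trip through YAML; ground truth through plain CSV
#' (`<prefix>_granules.csv` with `frame,row,col,sigma,amplitude` and, when
#' spots exist, `<prefix>_spots.csv` with `row,col,in_granule`).
#'
#' @param spec A [scene_spec()].
#' @param path,prefix Output locations.
#' @return The written path(s), invisibly.
#' @export
write_scene <- function(spec, path) {
  stopifnot(inherits(spec, "scene_spec"))
  x <- unclass(spec)
  x$cells <- lapply(spec$cells, function(cl) {
    list(center = cl$center, inner_radius = cl$inner,
         outer_radius = cl$outer)
  })
  x$granules <- as.list(spec$granules)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  x <- yaml::read_yaml(path)
  scene_spec(
    field_shape = unlist(x$field_shape), pixel_size = x$pixel_size,
    cells = lapply(x$cells, function(cl) {
      ring_cell(unlist(cl$center), cl$inner_radius, cl$outer_radius)
    }),
    cytoplasm_level = x$cytoplasm_level,
    background_level = x$background_level,
    granules = as.data.frame(lapply(x$granules, unlist)),
    noise_gaussian_sd = x$noise_gaussian_sd,
    noise_poisson_gain = x$noise_poisson_gain,
    bit_depth = x$bit_depth
  )
}

#' @rdname write_scene
#' @param truth A [ground_truth()].
#' @export
write_ground_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "ground_truth"))
  paths <- paste0(prefix, "_granules.csv")
  utils::write.csv(truth$granules, paths[1], row.names = FALSE)
  if (!is.null(truth$spots)) {
    p2 <- paste0(prefix, "_spots.csv")
    utils::write.csv(truth$spots, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
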