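#' Cytoplasm-mask parameters
#'
#' The diffuse cytoplasmic pool is segmented by blanking granule-containing
#' pixels, applying a wide Gaussian blur (sigma 8 px), and thresholding the
#' blurred image on the interval `[mean, upper_limit]` where `mean` is the
#' blurred image's global mean and `upper_limit` defaults to 65000 (the
#' maximum possible 16-bit-scale intensity used as the interval ceiling).
#'
#' @param blur_sigma Blur sd in raw pixels (default 8).
#' @param upper_limit Upper intensity limit of the thresholding interval.
#' @param blank_dilate_px Radius (raw pixels) by which granule footprints
#'   are dilated before blanking and exclusion. Detected particle masks cut
#'   a punctum roughly at half maximum, so its Gaussian skirt extends a
#'   couple of pixels further; excluding that skirt keeps granule tails out
#'   of the diffuse-pool estimate. 0 blanks the bare footprints.
#' @param normalized_blur With `TRUE`, blanked pixels are ignored in the
#'   local average (normalized convolution) instead of contributing zeros;
#'   the literal blank-then-blur behavior is the default.
#' @return A `cyto_mask_params` list.
#' @export
cyto_mask_params <- function(blur_sigma = 8, upper_limit = 65000,
                             blank_dilate_px = 2, normalized_blur = FALSE) {
  .stopifnot_scalar(blur_sigma, "blur_sigma", positive = TRUE)
  .stopifnot_scalar(upper_limit, "upper_limit", positive = TRUE)
  .stopifnot_scalar(blank_dilate_px, "blank_dilate_px")
  if (blank_dilate_px < 0) stop("blank_dilate_px must be >= 0",
                                call. = FALSE)
  structure(list(blur_sigma = blur_sigma, upper_limit = upper_limit,
                 blank_dilate_px = blank_dilate_px,
                 normalized_blur = isTRUE(normalized_blur)),
            class = "cyto_mask_params")
}

#' Segment the diffuse cytoplasmic pool
#'
#' Blanks every granule footprint (set to zero) on the raw image, blurs
#' with `blur_sigma`, measures the blurred image's mean, and keeps pixels
#' whose blurred value lies in `[mean, upper_limit]`. Granule footprints
#' are excluded from the returned mask, so mask and granules are disjoint
#' by construction.
#'
#' @param raw The raw [image_field()].
#' @param granules The `granule_set` detected on this field (may be empty).
#' @param params A [cyto_mask_params()].
#' @return Logical matrix on the raw grid.
#' @export
cytoplasm_mask <- function(raw, granules, params = cyto_mask_params()) {
  stopifnot(inherits(raw, "image_field"),
            inherits(params, "cyto_mask_params"))
  img <- raw$data
  blanked <- matrix(FALSE, nrow(img), ncol(img))
  if (!is.null(granules)) {
    stopifnot(inherits(granules, "granule_set"))
    if (!all(granules$raw_dim == dim(img))) {
      stop("granule set and raw image do not share geometry", call. = FALSE)
    }
    blanked <- granule_raw_mask(granules) > 0L
    if (params$blank_dilate_px > 0 && any(blanked)) {
      brush <- EBImage::makeBrush(2 * ceiling(params$blank_dilate_px) + 1,
                                  shape = "disc")
      blanked <- EBImage::dilate(blanked, brush) > 0
    }
  }
  work <- img
  work[blanked] <- 0
  if (params$normalized_blur && any(blanked)) {
    w <- .gauss_blur(matrix(as.numeric(!blanked), nrow(img), ncol(img)),
                     params$blur_sigma)
    blurred <- .gauss_blur(work, params$blur_sigma) / pmax(w, .Machine$double.eps)
  } else {
    blurred <- .gauss_blur(work, params$blur_sigma)
  }
  m <- mean(blurred)
  # tolerance keeps pixels that equal the mean up to float rounding
  m_lo <- m - 1e-9 * max(1, abs(m))
  mask <- blurred >= m_lo & blurred <= params$upper_limit & !blanked
  if (!any(mask)) {
    stop("cytoplasm mask is empty: no measurable diffuse pool", call. = FALSE)
  }
  mask
}

#' Per-granule partition coefficients
#'
#' The partition coefficient of a granule is the ratio of its maximal raw
#' intensity to the mean raw intensity of the diffuse cytoplasmic pool
#' (measured on the raw image under the cytoplasm mask). The field mean is
#' the unweighted arithmetic mean over granules; replicate-level summaries
#' belong downstream (see [superplot_summary()]).
#'
#' @param granules A `granule_set` with `max_raw_intensity` measured (see
#'   [measure_max_on_raw()]).
#' @param raw The raw [image_field()].
#' @param mask Logical cytoplasm mask from [cytoplasm_mask()].
#' @param condition,replicate,field Optional labels carried into the
#'   result.
#' @return A `partition_result`: per-granule table, `field_mean`,
#'   `cytoplasm_mean`, `n_granules`, labels.
#' @export
partition_coefficients <- function(granules, raw, mask, condition = NA,
                                   replicate = NA, field = NA) {
  stopifnot(inherits(granules, "granule_set"), inherits(raw, "image_field"),
            is.logical(mask))
  if (!any(mask)) stop("cytoplasm mask is empty", call. = FALSE)
  cyt <- mean(raw$data[mask])
  if (!is.finite(cyt) || cyt <= 0) {
    stop("cytoplasm mean is zero: partition coefficient undefined",
         call. = FALSE)
  }
  p <- granules$particles
  if (nrow(p) && anyNA(p$max_raw_intensity)) {
    stop("granule maxima not measured; run measure_max_on_raw() first",
         call. = FALSE)
  }
  coef <- p$max_raw_intensity / cyt
  structure(list(
    per_granule = data.frame(id = p$id, coefficient = coef,
                             max_raw_intensity = p$max_raw_intensity),
    field_mean = if (length(coef)) mean(coef) else NA_real_,
    cytoplasm_mean = cyt, n_granules = nrow(p),
    condition = condition, replicate = replicate, field = field
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> %d granule(s), field mean %.3f, cytoplasm %.4g\n",
              x$n_granules,
              if (is.na(x$field_mean)) NA else x$field_mean,
              x$cytoplasm_mean))
  invisible(x)
}

#' Detection + mask + coefficients on one raw field
#'
#' Convenience chain used per field and per time point: detect granules,
#' build the cytoplasm mask, and compute coefficients.
#'
#' @param field Raw [image_field()].
#' @param params [detection_params()].
#' @param mask_params [cyto_mask_params()].
#' @param ... Labels passed to [partition_coefficients()].
#' @return A `partition_result` (with `n_granules = 0` and `NA` mean when
#'   nothing is detected).
#' @export
field_partition <- function(field, params = detection_params(),
                            mask_params = cyto_mask_params(), ...) {
  gs <- detect_granules(field, params)
  mask <- cytoplasm_mask(field, gs, mask_params)
  partition_coefficients(gs, field, mask, ...)
}

#' Partition dynamics over a time-lapse
#'
#' For every frame, crops each region, runs detection, the cytoplasm mask
#' and the coefficient measurement, pools granules across regions (or
#' averages region means with `pool = FALSE`), and records the mean
#' partition coefficient. Frames with zero detected granules yield an
#' explicit `NA` mean (carried, not dropped, so they cannot bias
#' time-course averages).
#'
#' @param frames Ordered list of raw [image_field()] frames of equal
#'   shape.
#' @param regions List of crop regions `c(row_min, row_max, col_min,
#'   col_max)`; at least one.
#' @param params [detection_params()].
#' @param mask_params [cyto_mask_params()].
#' @param pool Pool granules across regions before averaging (default)
#'   rather than averaging region means.
#' @return Data frame `frame, mean_coefficient, n_granules`.
#' @export
timelapse_partition <- function(frames, regions,
                                params = detection_params(),
                                mask_params = cyto_mask_params(),
                                pool = TRUE) {
  stopifnot(is.list(frames), length(frames) >= 1L, is.list(regions),
            length(regions) >= 1L)
  dims <- dim(frames[[1]]$data)
  regions <- lapply(regions, .check_region, dim = dims)
  out <- data.frame(frame = seq_along(frames),
                    mean_coefficient = NA_real_, n_granules = 0L)
  for (t in seq_along(frames)) {
    coefs <- list()
    region_means <- numeric(0)
    for (rg in regions) {
      sub <- crop_field(frames[[t]], rg)
      res <- field_partition(sub, params, mask_params)
      coefs[[length(coefs) + 1L]] <- res$per_granule$coefficient
      if (res$n_granules > 0) {
        region_means <- c(region_means, res$field_mean)
      }
    }
    all_coefs <- unlist(coefs)
    out$n_granules[t] <- length(all_coefs)
    if (length(all_coefs)) {
      out$mean_coefficient[t] <- if (pool) mean(all_coefs) else
        mean(region_means)
    }
  }
  out
}

#' Fit the exponential decondensation law to per-frame means
#'
#' Least-squares fit of `rho(t) = final + (initial - final) *
#' exp(-k (t - stimulus_frame))` to the post-stimulus per-frame mean
#' coefficients (frames with `NA` means are dropped).
#'
#' @param timecourse Output of [timelapse_partition()] (or any data frame
#'   with `frame` and `mean_coefficient`).
#' @param stimulus_frame Frame at which relaxation starts.
#' @return `list(initial, final, rate_k, fitted)` where `fitted` is the
#'   fitted trajectory over the post-stimulus frames.
#' @export
fit_partition_kinetics <- function(timecourse, stimulus_frame) {
  d <- timecourse[timecourse$frame >= stimulus_frame &
                    !is.na(timecourse$mean_coefficient), ]
  if (nrow(d) < 4L) stop("need at least 4 post-stimulus frames to fit",
                         call. = FALSE)
  d$tt <- d$frame - stimulus_frame
  start <- list(final = min(d$mean_coefficient),
                delta = max(d$mean_coefficient) - min(d$mean_coefficient),
                k = 0.05)
  fit <- minpack.lm::nlsLM(
    mean_coefficient ~ final + delta * exp(-k * tt), data = d,
    start = start, lower = c(final = 0, delta = 0, k = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  list(initial = unname(cf["final"] + cf["delta"]),
       final = unname(cf["final"]), rate_k = unname(cf["k"]),
       fitted = stats::fitted(fit))
}

#' Whole-cytoplasm protein-level change over a movie
#'
#' Mean intensity over an ROI at `t_end` divided by the mean over the same
#' ROI at `t_start` (e.g. end-of-movie level normalized to its own start).
#' A decondensation that merely redistributes intensity leaves this ratio
#' at 1.
#'
#' @param frames Ordered list of raw [image_field()] frames.
#' @param roi Region `c(row_min, row_max, col_min, col_max)`.
#' @param t_start,t_end 1-based frame indices.
#' @return The normalized ratio (scalar).
#' @export
protein_level_change <- function(frames, roi, t_start, t_end) {
  stopifnot(is.list(frames))
  if (t_start < 1L || t_end < 1L || t_start > length(frames) ||
      t_end > length(frames)) {
    stop("t_start and t_end must index frames of the movie", call. = FALSE)
  }
  roi <- .check_region(roi, dim(frames[[1]]$data))
  m0 <- mean(frames[[t_start]]$data[roi[1]:roi[2], roi[3]:roi[4]])
  m1 <- mean(frames[[t_end]]$data[roi[1]:roi[2], roi[3]:roi[4]])
  if (m0 <= 0) stop("mean intensity at t_start is zero", call. = FALSE)
  m1 / m0
}
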