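#' Detect smFISH spots and their centers of mass
#'
#' Runs the particle-detection chain with spot defaults (relative threshold
#' 0.3434, minimum size 4, no size exclusion) and returns intensity-weighted
#' centers of mass mapped to the raw grid. RNA spots are point objects for
#' colocalization, so only their centers (and areas) are kept.
#'
#' @param field Raw [image_field()] of the RNA channel.
#' @param params A [detection_params()]; defaults to
#'   [spot_detection_params()].
#' @return A `spot_set`: data frame `id, row, col, area` (raw-grid
#'   coordinates) plus the source channel label.
#' @export
detect_spots <- function(field, params = spot_detection_params()) {
  stopifnot(inherits(field, "image_field"))
  det <- suppressWarnings(preprocess(field, params))
  gs <- detect_particles(det, params)
  lab <- gs$label_mask
  f <- gs$resize_factor
  idx <- which(lab > 0L)
  if (!length(idx)) {
    spots <- data.frame(id = integer(0), row = numeric(0),
                        col = numeric(0), area = integer(0))
  } else {
    rc <- arrayInd(idx, dim(lab))
    lv <- lab[idx]
    w <- det$data[idx]
    com_r <- tapply(rc[, 1] * w, lv, sum) / tapply(w, lv, sum)
    com_c <- tapply(rc[, 2] * w, lv, sum) / tapply(w, lv, sum)
    ids <- sort(unique(lv))
    spots <- data.frame(
      id = ids,
      row = .det_to_raw_coord(as.numeric(com_r[as.character(ids)]), f),
      col = .det_to_raw_coord(as.numeric(com_c[as.character(ids)]), f),
      area = as.integer(tapply(lv, lv, length)[as.character(ids)])
    )
  }
  structure(list(spots = spots, channel = field$channel,
                 raw_dim = dim(field$data)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spot(s) from channel '%s'\n",
              nrow(x$spots), x$channel))
  invisible(x)
}

#' Fraction of RNA spots contained in granules
#'
#' Object-based colocalization: a spot counts as "in" a granule when its
#' center-of-mass pixel (rounded to the nearest raw pixel) carries a
#' granule label, i.e. lies inside some particle's raw-grid footprint. A
#' positive `tolerance_px` additionally accepts centers within that
#' distance of a granule footprint (the membership radius some object-based
#' tools expose); strict pixel membership is the default.
#'
#' @param spots A `spot_set` (or data frame with `row`, `col`).
#' @param granules A `granule_set` on the same raw grid.
#' @param tolerance_px Acceptance radius around granule footprints in raw
#'   pixels (default 0 = strict membership).
#' @return `list(fraction, n_in, n_total)`; an error when there are no
#'   spots (the fraction is undefined).
#' @export
fraction_in_granules <- function(spots, granules, tolerance_px = 0) {
  stopifnot(inherits(granules, "granule_set"))
  tab <- if (inherits(spots, "spot_set")) spots$spots else
    as.data.frame(spots)
  if (!nrow(tab)) {
    stop("no spots: colocalization fraction undefined", call. = FALSE)
  }
  raw_lab <- granule_raw_mask(granules)
  pr <- pmin(pmax(round(tab$row), 1L), nrow(raw_lab))
  pc <- pmin(pmax(round(tab$col), 1L), ncol(raw_lab))
  if (tolerance_px > 0 && any(raw_lab > 0L)) {
    brush <- EBImage::makeBrush(2 * ceiling(tolerance_px) + 1, shape = "disc")
    raw_lab <- EBImage::dilate(raw_lab > 0L, brush)
  }
  inside <- raw_lab[cbind(pr, pc)] > 0L
  list(fraction = mean(inside), n_in = sum(inside), n_total = nrow(tab))
}

#' Normalize measurements to a control group
#'
#' Divides every value by the mean of the control values, so the control
#' group maps to mean 1. Used for reporting colocalization fractions and
#' granule counts relative to untreated controls.
#'
#' @param values Numeric vector of measurements.
#' @param control_values Numeric vector of control measurements (mean > 0).
#' @return `values / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  stopifnot(is.numeric(values), is.numeric(control_values),
            length(control_values) >= 1L)
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) {
    stop("control mean must be > 0", call. = FALSE)
  }
  values / m
}
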