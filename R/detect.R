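#' Particle-detection parameters
#'
#' Parameters of the granule/spot detection pipeline: fields are lightly
#' blurred, upsampled two-fold (bilinear), linearly rescaled to the 16-bit
#' range, and thresholded on a band-pass (difference-of-Gaussian) response
#' at a unitless fraction of the in-image response range. The published
#' relative thresholds for this parameterization are 0.6234 for
#' antibody/GFP granule channels and 0.3434 for smFISH spot channels; the
#' band-pass operator itself is this package's own fully specified detector,
#' not a re-implementation of the original SPaDe internals.
#'
#' All pixel sizes (`min_size`, `size_exclusion`) are counted on the
#' two-fold resized detection grid, since detection runs after resizing.
#'
#' @param blur_sigma Preprocessing Gaussian blur sd in raw-grid pixels
#'   (default 0.5, i.e. one detection-grid pixel of smoothing).
#' @param resize_factor Integer upsampling factor (default 2).
#' @param relative_threshold Fraction of the band-pass response range, in
#'   (0, 1); foreground = response exceeding `relative_threshold * range`.
#' @param min_size Minimum particle area in detection-grid pixels
#'   (default 4).
#' @param size_exclusion Areas below this many detection-grid pixels are
#'   excluded after detection (`NULL` disables; 13 is the convention for
#'   antibody-stained granule channels).
#' @param bandpass_sigma Inner scale of the difference-of-Gaussian response
#'   in detection-grid pixels (outer scale is 1.6x).
#' @return A `detection_params` list.
#' @export
detection_params <- function(blur_sigma = 0.5, resize_factor = 2L,
                             relative_threshold = 0.6234, min_size = 4L,
                             size_exclusion = NULL, bandpass_sigma = 2) {
  .stopifnot_scalar(blur_sigma, "blur_sigma")
  .stopifnot_scalar(relative_threshold, "relative_threshold")
  .stopifnot_scalar(bandpass_sigma, "bandpass_sigma", positive = TRUE)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0", call. = FALSE)
  if (relative_threshold <= 0 || relative_threshold >= 1) {
    stop("relative_threshold must lie in (0, 1)", call. = FALSE)
  }
  resize_factor <- as.integer(resize_factor)
  if (resize_factor < 1L) stop("resize_factor must be >= 1", call. = FALSE)
  min_size <- as.integer(min_size)
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  if (!is.null(size_exclusion)) {
    size_exclusion <- as.integer(size_exclusion)
    if (size_exclusion < min_size) {
      stop("size_exclusion must be >= min_size", call. = FALSE)
    }
  }
  structure(list(blur_sigma = blur_sigma, resize_factor = resize_factor,
                 relative_threshold = relative_threshold,
                 min_size = min_size, size_exclusion = size_exclusion,
                 bandpass_sigma = bandpass_sigma),
            class = "detection_params")
}

#' @rdname detection_params
#' @param ... Overrides passed to [detection_params()].
#' @export
spot_detection_params <- function(...) {
  args <- list(...)
  defaults <- list(relative_threshold = 0.3434, size_exclusion = NULL)
  do.call(detection_params, utils::modifyList(defaults, args))
}

#' Preprocess a field onto the detection grid
#'
#' Applies the Gaussian blur, upsamples by `resize_factor` (bilinear), and
#' converts to the 16-bit integer range by linear min-max mapping. The raw
#' field is untouched and remains the reference for intensity measurement.
#' A constant input has no min-max range; it maps to an all-zero detection
#' image (with a warning), which yields zero particles downstream.
#'
#' @param field An [image_field()].
#' @param params A [detection_params()].
#' @return A 16-bit [image_field()] of shape `input * resize_factor`.
#' @export
preprocess <- function(field, params = detection_params()) {
  stopifnot(inherits(field, "image_field"),
            inherits(params, "detection_params"))
  img <- field$data
  if (params$blur_sigma > 0) img <- .gauss_blur(img, params$blur_sigma)
  f <- params$resize_factor
  if (f > 1L) {
    img <- EBImage::resize(img, w = nrow(img) * f, h = ncol(img) * f,
                           filter = "bilinear")
  }
  rng <- range(img)
  if (rng[2] > rng[1]) {
    img <- round((img - rng[1]) / (rng[2] - rng[1]) * 65535)
  } else {
    warning("constant image: min-max mapping degenerates, returning zeros")
    img <- matrix(0, nrow(img), ncol(img))
  }
  image_field(img, pixel_size = field$pixel_size / f,
              channel = field$channel, bit_depth = 16L)
}

# 8-connected component labeling of a logical mask; labels are contiguous
# positive integers ordered by first (column-major) pixel occurrence.
.label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nr <- nrow(mask); nc <- ncol(mask)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(mask))
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(-1L, 1L), c(1L, 1L))) {
    nb_r <- rc[, 1] + off[1]
    nb_c <- rc[, 2] + off[2]
    ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
    if (!any(ok)) next
    nb <- id[cbind(nb_r[ok], nb_c[ok])]
    src <- seq_along(idx)[ok]
    keep <- nb > 0L
    if (any(keep)) edges <- rbind(edges, cbind(src[keep], nb[keep]))
  }
  if (is.null(edges)) {
    membership <- seq_along(idx)
  } else {
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, length(idx) -
                                         igraph::vcount(gr)))
    membership <- igraph::components(gr)$membership
  }
  # re-label in order of first occurrence so labels are deterministic
  first <- match(unique(membership), membership)
  relab <- integer(max(membership))
  relab[membership[sort(first)]] <- seq_along(first)
  lab[idx] <- relab[membership]
  lab
}

# Summarize a label mask into the per-particle table.
.particle_table <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(data.frame(id = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      max_raw_intensity = numeric(0)))
  }
  rc <- arrayInd(idx, dim(lab))
  lv <- lab[idx]
  area <- as.integer(tapply(lv, lv, length))
  data.frame(id = sort(unique(lv)),
             area = area,
             centroid_row = as.numeric(tapply(rc[, 1], lv, mean)),
             centroid_col = as.numeric(tapply(rc[, 2], lv, mean)),
             max_raw_intensity = NA_real_)
}

#' Detect particles on a preprocessed detection image
#'
#' Computes a difference-of-Gaussian band-pass response, marks pixels whose
#' response exceeds `relative_threshold` times the in-image response range
#' as foreground, and keeps 8-connected components of at least `min_size`
#' pixels as particles. Deterministic; an empty foreground is a valid
#' zero-particle result.
#'
#' @param detection_image The output of [preprocess()].
#' @param params The same [detection_params()] used for preprocessing.
#' @return A `granule_set`: label mask on the detection grid, particle
#'   table (`id`, `area`, `centroid_row`, `centroid_col`,
#'   `max_raw_intensity`), and the grid mapping back to the raw image.
#' @export
detect_particles <- function(detection_image, params = detection_params()) {
  stopifnot(inherits(detection_image, "image_field"),
            inherits(params, "detection_params"))
  img <- detection_image$data
  s <- params$bandpass_sigma
  response <- .gauss_blur(img, s) - .gauss_blur(img, 1.6 * s)
  rng <- range(response)
  cut <- params$relative_threshold * (rng[2] - rng[1])
  fg <- response > cut & rng[2] > rng[1]
  lab <- .label8(fg)
  particles <- .particle_table(lab)
  keep <- particles$area >= params$min_size
  gs <- .rebuild_granule_set(lab, particles, keep,
                             resize_factor = params$resize_factor,
                             raw_dim = dim(img) %/% params$resize_factor)
  gs
}

# Drop particles (logical keep vector), compact labels, rebuild the set.
.rebuild_granule_set <- function(lab, particles, keep, resize_factor,
                                 raw_dim) {
  old_ids <- particles$id[keep]
  new_lab <- matrix(0L, nrow(lab), ncol(lab))
  if (length(old_ids)) {
    remap <- integer(max(particles$id))
    remap[old_ids] <- seq_along(old_ids)
    pos <- lab > 0L & lab %in% old_ids
    new_lab[pos] <- remap[lab[pos]]
  }
  particles <- particles[keep, , drop = FALSE]
  particles$id <- seq_len(nrow(particles))
  rownames(particles) <- NULL
  structure(list(label_mask = new_lab, particles = particles,
                 resize_factor = as.integer(resize_factor),
                 raw_dim = as.integer(raw_dim)),
            class = "granule_set")
}

#' @export
print.granule_set <- function(x, ...) {
  cat(sprintf("<granule_set> %d particle(s) on a %d x %d detection grid (x%d)\n",
              nrow(x$particles), nrow(x$label_mask), ncol(x$label_mask),
              x$resize_factor))
  invisible(x)
}

#' Exclude particles below a size threshold
#'
#' Removes particles whose area (detection-grid pixels) is below
#' `exclusion_px` and re-compacts the labels. `exclusion_px = 1` is the
#' identity. The 13-pixel exclusion is the convention for antibody-stained
#' granule channels.
#'
#' @param granules A `granule_set`.
#' @param exclusion_px Minimum retained area in detection-grid pixels.
#' @return The filtered `granule_set`.
#' @export
filter_by_size <- function(granules, exclusion_px) {
  stopifnot(inherits(granules, "granule_set"))
  exclusion_px <- as.integer(exclusion_px)
  if (exclusion_px < 1L) stop("exclusion_px must be >= 1", call. = FALSE)
  keep <- granules$particles$area >= exclusion_px
  .rebuild_granule_set(granules$label_mask, granules$particles, keep,
                       granules$resize_factor, granules$raw_dim)
}

#' Project a granule set's footprints onto the raw grid
#'
#' A raw pixel belongs to a particle when any of the `resize_factor^2`
#' detection pixels it maps to carries that particle's label.
#'
#' @param granules A `granule_set`.
#' @return Integer label matrix on the raw grid.
#' @export
granule_raw_mask <- function(granules) {
  stopifnot(inherits(granules, "granule_set"))
  lab <- granules$label_mask
  f <- granules$resize_factor
  raw <- matrix(0L, granules$raw_dim[1], granules$raw_dim[2])
  idx <- which(lab > 0L)
  if (!length(idx)) return(raw)
  rc <- arrayInd(idx, dim(lab))
  rr <- ceiling(rc[, 1] / f)
  cc <- ceiling(rc[, 2] / f)
  ok <- rr <= nrow(raw) & cc <= ncol(raw)
  raw[cbind(rr[ok], cc[ok])] <- lab[idx][ok]
  raw
}

#' Measure per-particle maxima on the raw image
#'
#' Fills each particle's `max_raw_intensity` with the maximum raw-image
#' value over the particle's raw-grid footprint (detection coordinates
#' mapped back by the resize factor). Partition coefficients are always
#' computed from these raw maxima, never from the rescaled detection image.
#'
#' @param granules A `granule_set`.
#' @param raw The original raw [image_field()] the detection grid came
#'   from.
#' @return The `granule_set` with `max_raw_intensity` filled in.
#' @export
measure_max_on_raw <- function(granules, raw) {
  stopifnot(inherits(granules, "granule_set"), inherits(raw, "image_field"))
  if (!all(granules$raw_dim == dim(raw$data))) {
    stop("raw image shape does not match the granule set's grid map",
         call. = FALSE)
  }
  if (!nrow(granules$particles)) return(granules)
  lab <- granules$label_mask
  f <- granules$resize_factor
  idx <- which(lab > 0L)
  rc <- arrayInd(idx, dim(lab))
  rr <- ceiling(rc[, 1] / f)
  cc <- ceiling(rc[, 2] / f)
  ok <- rr <= nrow(raw$data) & cc <= ncol(raw$data)
  if (!all(ok)) {
    bad <- unique(lab[idx][!ok])
    warning(sprintf("%d particle(s) map outside the raw image and are excluded",
                    length(bad)))
    keepv <- !(granules$particles$id %in% bad)
    granules <- .rebuild_granule_set(lab, granules$particles, keepv, f,
                                     granules$raw_dim)
    return(measure_max_on_raw(granules, raw))
  }
  vals <- raw$data[cbind(rr, cc)]
  mx <- tapply(vals, lab[idx], max)
  granules$particles$max_raw_intensity <-
    as.numeric(mx[as.character(granules$particles$id)])
  granules
}

#' Full detection chain on one raw field
#'
#' Convenience wrapper: [preprocess()] then [detect_particles()], the
#' optional size exclusion, and [measure_max_on_raw()] against the raw
#' input.
#'
#' @param field A raw [image_field()].
#' @param params A [detection_params()].
#' @return A `granule_set` with raw maxima measured.
#' @export
detect_granules <- function(field, params = detection_params()) {
  det <- suppressWarnings(preprocess(field, params))
  gs <- detect_particles(det, params)
  if (!is.null(params$size_exclusion)) {
    gs <- filter_by_size(gs, params$size_exclusion)
  }
  measure_max_on_raw(gs, field)
}

# Continuous detection-grid -> raw-grid coordinate mapping. Raw pixel i
# covers detection pixels f(i-1)+1 .. fi, so centers map back by
# raw = (det + (f-1)/2) / f.
.det_to_raw_coord <- function(x, f) (x + (f - 1) / 2) / f

#' Score detections against point annotations
#'
#' An annotation is a true positive when it falls inside some particle's
#' raw-grid footprint; each particle can absorb at most one annotation
#' (greedily, by distance to the particle centroid). Unmatched annotations
#' are false negatives, unmatched particles false positives.
#' `F1 = 2PR / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param granules A `granule_set`.
#' @param annotations Data frame (or 2-column matrix) of raw-grid points
#'   with columns `row`, `col`.
#' @return `list(f1, precision, recall, tp, fp, fn)`.
#' @export
f1_against_annotations <- function(granules, annotations) {
  stopifnot(inherits(granules, "granule_set"))
  ann <- as.data.frame(annotations)
  if (!all(c("row", "col") %in% names(ann))) {
    names(ann)[1:2] <- c("row", "col")
  }
  n_ann <- nrow(ann)
  n_par <- nrow(granules$particles)
  if (n_ann == 0 && n_par == 0) {
    return(list(f1 = 0, precision = 0, recall = 0, tp = 0L, fp = 0L,
                fn = 0L))
  }
  tp <- 0L
  if (n_ann > 0 && n_par > 0) {
    raw_lab <- granule_raw_mask(granules)
    pr <- pmin(pmax(round(ann$row), 1L), nrow(raw_lab))
    pc <- pmin(pmax(round(ann$col), 1L), ncol(raw_lab))
    hit <- raw_lab[cbind(pr, pc)]
    cand <- which(hit > 0L)
    if (length(cand)) {
      f <- granules$resize_factor
      cent_r <- .det_to_raw_coord(granules$particles$centroid_row, f)
      cent_c <- .det_to_raw_coord(granules$particles$centroid_col, f)
      d <- sqrt((ann$row[cand] - cent_r[hit[cand]])^2 +
                  (ann$col[cand] - cent_c[hit[cand]])^2)
      ord <- cand[order(d)]
      used_ann <- logical(n_ann)
      used_par <- logical(n_par)
      for (i in ord) {
        p <- hit[i]
        if (!used_ann[i] && !used_par[p]) {
          used_ann[i] <- TRUE
          used_par[p] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- n_par - tp
  fn <- n_ann - tp
  precision <- if (n_par > 0) tp / n_par else 0
  recall <- if (n_ann > 0) tp / n_ann else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(f1 = f1, precision = precision, recall = recall, tp = tp, fp = fp,
       fn = fn)
}

#' Calibrate the relative detection threshold by F1 score
#'
#' Runs the detection chain at every threshold in `grid` on every field,
#' scores each against its point annotations, and returns the threshold
#' maximizing the mean F1 (ties broken toward the larger, more conservative
#' threshold). If every threshold scores 0, the largest grid value is
#' returned with a warning.
#'
#' @param fields List of raw [image_field()] objects.
#' @param annotations List (same length) of per-field annotation tables
#'   (`row`, `col`).
#' @param grid Numeric vector of candidate thresholds in (0, 1).
#' @param params Base [detection_params()]; only the threshold is swept.
#' @return `list(best_threshold, curve)` where `curve` is a data frame
#'   `threshold, mean_f1`.
#' @export
calibrate_threshold <- function(fields, annotations,
                                grid = seq(0.1, 0.9, by = 0.02),
                                params = detection_params()) {
  stopifnot(is.list(fields), length(fields) >= 1L,
            length(annotations) == length(fields), length(grid) >= 1L,
            all(grid > 0 & grid < 1))
  # preprocess once per field; only the threshold varies across the grid
  dets <- lapply(fields, function(f) suppressWarnings(preprocess(f, params)))
  mean_f1 <- vapply(grid, function(thr) {
    p <- params
    p$relative_threshold <- thr
    scores <- vapply(seq_along(dets), function(i) {
      gs <- detect_particles(dets[[i]], p)
      if (!is.null(p$size_exclusion)) gs <- filter_by_size(gs,
                                                           p$size_exclusion)
      f1_against_annotations(gs, annotations[[i]])$f1
    }, numeric(1))
    mean(scores)
  }, numeric(1))
  curve <- data.frame(threshold = grid, mean_f1 = mean_f1)
  curve <- curve[order(curve$threshold), ]
  rownames(curve) <- NULL
  if (all(mean_f1 == 0)) {
    warning("no threshold in the grid scores F1 > 0; returning the largest")
    best <- max(grid)
  } else {
    top <- which(mean_f1 == max(mean_f1))
    best <- max(grid[top])
  }
  list(best_threshold = best, curve = curve)
}

#' Read point annotations from CSV
#'
#' Expects columns `row`, `col` and optionally `image_id`; returns a single
#' data frame, or a list split by `image_id` when present.
#'
#' @param path CSV path.
#' @return Data frame or named list of data frames.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path)
  if ("image_id" %in% names(ann)) {
    split(ann[c("row", "col")], ann$image_id)
  } else {
    ann[c("row", "col")]
  }
}
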