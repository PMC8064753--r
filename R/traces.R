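#' Calcium-indicator fluorescence trace
#'
#' An ordered series of ROI-averaged fluorescence values `F(t)` with its
#' acquisition metadata. dF/F requires positive raw values and at least
#' `n_baseline` pre-stimulus frames.
#'
#' @param values Ordered numeric intensities.
#' @param frame_interval Seconds between frames (default 30).
#' @param stimulus_frame 1-based frame at which the stimulus was applied.
#' @param roi_area ROI area in square micrometers (metadata).
#' @return A `calcium_trace`.
#' @export
calcium_trace <- function(values, frame_interval = 30, stimulus_frame = 5L,
                          roi_area = NA_real_) {
  stopifnot(is.numeric(values), length(values) >= 1L)
  structure(list(values = as.numeric(values),
                 frame_interval = frame_interval,
                 stimulus_frame = as.integer(stimulus_frame),
                 roi_area = roi_area),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("<calcium_trace> %d frame(s), %gs interval, stimulus at frame %d\n",
              length(x$values), x$frame_interval, x$stimulus_frame))
  invisible(x)
}

#' Baseline-normalized fluorescence change (dF/F)
#'
#' `dF/F(t) = (F(t) - F0) / F0` with `F0` the mean of the first
#' `n_baseline` values (the frames acquired before the stimulus). By
#' construction the mean of the first `n_baseline` outputs is exactly 0.
#'
#' @param trace A [calcium_trace()] or numeric vector.
#' @param n_baseline Number of pre-stimulus baseline frames (default 4).
#' @return Numeric vector of dF/F values.
#' @export
delta_f_over_f <- function(trace, n_baseline = 4L) {
  values <- if (inherits(trace, "calcium_trace")) trace$values else
    as.numeric(trace)
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L || n_baseline > length(values)) {
    stop("need 1 <= n_baseline <= length(trace)", call. = FALSE)
  }
  if (inherits(trace, "calcium_trace") &&
      trace$stimulus_frame < n_baseline) {
    stop("fewer pre-stimulus frames than n_baseline", call. = FALSE)
  }
  f0 <- mean(values[seq_len(n_baseline)])
  if (f0 <= 0) stop("baseline F0 must be > 0", call. = FALSE)
  (values - f0) / f0
}

#' Endpoint fluorescence change on the t0-normalized scale
#'
#' For dose-response endpoints measured at two time points only: each
#' measurement is normalized so its own t0 equals 1, and the change is the
#' difference on that scale, `f_t30 / f_t0 - 1`. Both the difference and
#' the normalized endpoint are returned (the two readings of an endpoint
#' change; they carry the same information).
#'
#' @param f_t0 Intensity at t = 0 (> 0).
#' @param f_t30 Intensity at the endpoint (e.g. t = 30 min).
#' @return `list(difference, normalized_t30)`; vectorized over inputs.
#' @export
endpoint_change <- function(f_t0, f_t30) {
  if (any(f_t0 <= 0)) stop("f_t0 must be > 0", call. = FALSE)
  norm <- f_t30 / f_t0
  list(difference = norm - 1, normalized_t30 = norm)
}

#' Per-movie normalization of translation-foci counts
#'
#' Each movie's series of "cells with foci" counts is divided by its own
#' maximum, so 1 marks each movie's peak; the across-movie mean and
#' standard error (sample sd over sqrt of the number of movies) are
#' reported per frame. Movies with all-zero counts carry no signal and are
#' excluded with a warning.
#'
#' @param counts Data frame `movie, frame, count` (long format), or a list
#'   of per-movie count vectors.
#' @return `list(per_movie = data.frame(movie, frame, normalized),
#'   summary = data.frame(frame, mean, sem, n_movies))`.
#' @export
foci_timecourse_normalize <- function(counts) {
  if (is.list(counts) && !is.data.frame(counts)) {
    nm <- names(counts)
    if (is.null(nm)) nm <- as.character(seq_along(counts))
    counts <- do.call(rbind, lapply(seq_along(counts), function(i) {
      data.frame(movie = nm[i], frame = seq_along(counts[[i]]),
                 count = counts[[i]])
    }))
  }
  stopifnot(is.data.frame(counts),
            all(c("movie", "frame", "count") %in% names(counts)))
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  maxima <- tapply(counts$count, counts$movie, max)
  dead <- names(maxima)[maxima == 0]
  if (length(dead)) {
    warning(sprintf("excluding movie(s) with all-zero counts: %s",
                    paste(dead, collapse = ", ")))
    counts <- counts[!counts$movie %in% dead, , drop = FALSE]
    if (!nrow(counts)) stop("no movie has a nonzero count", call. = FALSE)
  }
  counts$normalized <- counts$count /
    as.numeric(maxima[as.character(counts$movie)])
  frames <- sort(unique(counts$frame))
  summ <- do.call(rbind, lapply(frames, function(fr) {
    v <- counts$normalized[counts$frame == fr]
    data.frame(frame = fr, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else
                 NA_real_,
               n_movies = length(v))
  }))
  list(per_movie = counts[c("movie", "frame", "normalized")],
       summary = summ)
}

#' Mean reporter intensity in fixed-area ROIs
#'
#' Measures the arithmetic mean intensity in each ROI on a single field,
#' or on the per-pixel maximum-intensity projection when a stack (list of
#' fields) is supplied.
#'
#' @param field An [image_field()] or a list of them (a z-stack).
#' @param rois List of regions `c(row_min, row_max, col_min, col_max)`,
#'   all inside the field.
#' @return Named numeric vector of per-ROI means.
#' @export
reporter_intensity <- function(field, rois) {
  if (is.list(field) && !inherits(field, "image_field")) {
    field <- max_project(field)
  }
  stopifnot(inherits(field, "image_field"), is.list(rois),
            length(rois) >= 1L)
  out <- vapply(rois, function(rg) {
    rg <- .check_region(rg, dim(field$data), what = "roi")
    mean(field$data[rg[1]:rg[2], rg[3]:rg[4]])
  }, numeric(1))
  names(out) <- if (!is.null(names(rois))) names(rois) else
    paste0("roi", seq_along(rois))
  out
}
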