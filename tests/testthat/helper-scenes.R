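# Shared fixture builders; everything is generated in code at test time.

# Continuous detection-grid -> raw-grid mapping (raw pixel i covers
# detection pixels f(i-1)+1 .. fi).
det_to_raw <- function(x, f = 2) (x + (f - 1) / 2) / f

# Detected particle centroids in raw coordinates.
particle_centroids_raw <- function(gs) {
  f <- gs$resize_factor
  data.frame(row = det_to_raw(gs$particles$centroid_row, f),
             col = det_to_raw(gs$particles$centroid_col, f))
}

# For each truth granule, distance to the nearest detected centroid and the
# matched particle index.
match_truth_to_particles <- function(gs, truth_granules) {
  cent <- particle_centroids_raw(gs)
  t(vapply(seq_len(nrow(truth_granules)), function(i) {
    d <- sqrt((cent$row - truth_granules$row[i])^2 +
                (cent$col - truth_granules$col[i])^2)
    j <- which.min(d)
    c(dist = d[j], particle = j)
  }, numeric(2)))
}

# Independent confusion-matrix oracle for annotation scoring: when particle
# footprints are disjoint, each annotation can only belong to the particle
# whose footprint contains it, so TP = number of particles containing at
# least one annotation.
oracle_f1 <- function(gs, ann) {
  raw_lab <- granule_raw_mask(gs)
  n_par <- nrow(gs$particles)
  n_ann <- nrow(ann)
  if (n_par == 0 && n_ann == 0) {
    return(list(f1 = 0, precision = 0, recall = 0))
  }
  hit <- integer(0)
  if (n_ann > 0 && n_par > 0) {
    pr <- pmin(pmax(round(ann$row), 1L), nrow(raw_lab))
    pc <- pmin(pmax(round(ann$col), 1L), ncol(raw_lab))
    hit <- raw_lab[cbind(pr, pc)]
    hit <- hit[hit > 0L]
  }
  tp <- length(unique(hit))
  precision <- if (n_par > 0) tp / n_par else 0
  recall <- if (n_ann > 0) tp / n_ann else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(f1 = f1, precision = precision, recall = recall)
}

# Hand-built granule_set from a label mask (for unit tests of the particle
# operations that do not need the detector).
granule_set_from_mask <- function(lab, resize_factor = 2L,
                                  raw_dim = dim(lab) %/% resize_factor) {
  structure(list(label_mask = lab,
                 particles = punctate:::.particle_table(lab),
                 resize_factor = as.integer(resize_factor),
                 raw_dim = as.integer(raw_dim)),
            class = "granule_set")
}

# A null long-format measurement table for test calibration.
null_replicate_table <- function(k_groups, n_per_group, n_replicates = 3) {
  data.frame(
    condition = rep(paste0("g", seq_len(k_groups)), each = n_per_group),
    replicate = rep(rep(paste0("r", seq_len(n_replicates)),
                        length.out = n_per_group), k_groups),
    value = stats::rnorm(k_groups * n_per_group)
  )
}
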