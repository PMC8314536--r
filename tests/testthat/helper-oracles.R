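# Independent oracles used to verify the package implementations on small
# inputs. These deliberately use different algorithms from the package code.

# AUC as the Mann-Whitney pair statistic: fraction of (positive, negative)
# pairs where the positive scores higher, with half credit for ties.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Connected components by union-find over pixel pairs.
oracle_components <- function(mask, connectivity = 8L) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (a in 1:(n - 1L)) for (b in (a + 1L):n) {
      dr <- abs(idx[a, 1L] - idx[b, 1L])
      dc <- abs(idx[a, 2L] - idx[b, 2L])
      adjacent <- if (connectivity == 4L) dr + dc == 1L else max(dr, dc) == 1L
      if (adjacent) parent[find(a)] <- find(b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[(idx[, 2L] - 1L) * nrow(mask) + idx[, 1L]] <- comp
  out
}

# Point-in-polygon by ray casting (crossing number), for rasterization
# checks independent of pracma.
oracle_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      x_int <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exhaustive arc scan: mean SI of every circular arc of `width` sectors.
oracle_arc_means <- function(si_values, sectors, n_sectors, width) {
  vapply(0:(n_sectors - 1L), function(start) {
    in_arc <- sectors %in% ((start + 0:(width - 1L)) %% n_sectors)
    if (!any(in_arc)) NA_real_ else mean(si_values[in_arc])
  }, numeric(1))
}

# Nominal remote statistics (for noise-free constructions where the
# measured remote SD is exactly zero but thresholds are defined in
# multiples of the nominal SD).
nominal_remote_stats <- function(mean_si, sd_si) {
  structure(list(mean_si = mean_si, sd_si = sd_si, n_pixels = 2L),
            class = "remote_stats")
}
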