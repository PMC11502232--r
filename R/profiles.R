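# Naming clusters by behavior and feeding phase, uniformity testing,
# rate summaries, anatomical enrichment, spike width.

# Peak firing phase of each row of a warped rate matrix, in [0, 1].
.peak_phases <- function(mat) {
  (max.col(mat, ties.method = "first") - 0.5) / ncol(mat)
}

.ks_uniform_D <- function(x) {
  n <- length(x)
  x <- sort(x)
  max(max(seq_len(n) / n - x), max(x - (seq_len(n) - 1) / n))
}

#' Name clusters by preferred behavior and feeding phase
#'
#' Per cluster and behavior, the mean across cells of each cell's peak
#' rate is computed; the preferred behavior is the argmax. Among
#' feeding-preferring clusters, the one whose feeding peak-time
#' distribution is closest to uniform (smallest one-sample KS D) is the
#' homogeneous feeding population `Fd`; the remaining feeding clusters are
#' ordered by the median of their cells' feeding peak phases and named
#' `FOn`, `EF`, `LF`, `FOff` when there are exactly four (generic `F1..`
#' names otherwise). Non-feeding clusters are named `Sol` (social) or
#' `Exp` (object), with numeric suffixes if several prefer one behavior.
#'
#' @param behavior_vectors list of raw-rate (Hz) warped matrices named
#'   `feeding`, `social`, `object` (rows = cells).
#' @param solution a `cluster_solution` or an integer label vector over the
#'   same cells.
#' @return A `population_profile` data.frame: one row per cluster with
#'   `cluster`, `name`, `preferred_behavior`, per-behavior mean/peak rates,
#'   `median_phase`, `ks_D`; per-cell peak phases are attached as the
#'   `peak_phases` attribute (list keyed by cluster).
#' @export
label_populations <- function(behavior_vectors, solution) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels else solution
  behaviors <- c("feeding", "social", "object")
  stopifnot(all(behaviors %in% names(behavior_vectors)))
  n <- length(labels)
  if (nrow(behavior_vectors$feeding) != n) {
    stop("labels and behavior vectors cover different cells")
  }
  clusters <- sort(unique(labels))
  peak <- sapply(behaviors, function(b) {
    apply(behavior_vectors[[b]], 1L, max)
  })
  meanr <- sapply(behaviors, function(b) {
    apply(behavior_vectors[[b]], 1L, mean)
  })
  feed_phase <- .peak_phases(behavior_vectors$feeding)
  prof <- data.frame(cluster = clusters, stringsAsFactors = FALSE)
  for (b in behaviors) {
    prof[[paste0("mean_rate_", b)]] <-
      vapply(clusters, function(cl) mean(meanr[labels == cl, b]), numeric(1))
    prof[[paste0("peak_rate_", b)]] <-
      vapply(clusters, function(cl) mean(peak[labels == cl, b]), numeric(1))
  }
  pref_idx <- max.col(as.matrix(prof[, paste0("peak_rate_", behaviors)]),
                      ties.method = "first")
  prof$preferred_behavior <- behaviors[pref_idx]
  prof$median_phase <- vapply(clusters, function(cl) {
    median(feed_phase[labels == cl])
  }, numeric(1))
  prof$mean_phase <- vapply(clusters, function(cl) {
    mean(feed_phase[labels == cl])
  }, numeric(1))
  prof$ks_D <- vapply(clusters, function(cl) {
    .ks_uniform_D(feed_phase[labels == cl])
  }, numeric(1))

  prof$name <- NA_character_
  feed <- which(prof$preferred_behavior == "feeding")
  if (length(feed) == 1L) {
    prof$name[feed] <- "Fd"
  } else if (length(feed) > 1L) {
    fd <- feed[which.min(prof$ks_D[feed])]
    prof$name[fd] <- "Fd"
    rest <- setdiff(feed, fd)
    ord <- order(prof$median_phase[rest], prof$mean_phase[rest])
    if (any(duplicated(prof$median_phase[rest]))) {
      message("median-phase tie broken by mean phase")
    }
    nm <- if (length(rest) == 4L) c("FOn", "EF", "LF", "FOff")
          else paste0("F", seq_along(rest))
    prof$name[rest[ord]] <- nm
  }
  for (b in c("social", "object")) {
    base <- if (b == "social") "Sol" else "Exp"
    idx <- which(prof$preferred_behavior == b)
    if (length(idx) == 1L) prof$name[idx] <- base
    else if (length(idx) > 1L) prof$name[idx] <- paste0(base, seq_along(idx))
  }
  pp <- lapply(clusters, function(cl) feed_phase[labels == cl])
  names(pp) <- as.character(clusters)
  attr(prof, "peak_phases") <- pp
  class(prof) <- c("population_profile", "data.frame")
  prof
}

#' One-sample KS test of peak-time uniformity with Bonferroni adjustment
#'
#' Tests a sample of peak phases against Uniform(0, 1); the family-wise
#' alpha is split over `n_tests` comparisons (by default populations x
#' behaviors), reproducing e.g. 0.05 / 21 for seven populations and three
#' behaviors.
#'
#' @param peak_phases numeric sample in `[0, 1]` (n >= 5).
#' @param alpha_family family-wise alpha.
#' @param n_tests Bonferroni family size.
#' @return `list(D, p, reject, alpha_adj)`.
#' @export
peak_time_uniformity <- function(peak_phases, alpha_family = 0.05,
                                 n_tests = 1L) {
  if (any(peak_phases < 0 | peak_phases > 1)) {
    stop("peak phases must lie in [0, 1]")
  }
  if (length(peak_phases) < 5L) stop("need at least 5 phases")
  kt <- suppressWarnings(ks.test(peak_phases, "punif"))
  alpha_adj <- alpha_family / n_tests
  list(D = unname(kt$statistic), p = kt$p.value,
       reject = kt$p.value < alpha_adj, alpha_adj = alpha_adj)
}

#' Correlations of mean firing rates between behaviors, per population
#'
#' @param mean_rates cells x 3 matrix of per-behavior mean rates
#'   (columns `feeding`, `social`, `object`; typically z-scored).
#' @param groups population label per cell.
#' @param min_cells smallest group size analyzed.
#' @return Named list per population: `list(r, p, n)` with 3x3 Pearson
#'   matrices; correlations against constant vectors are `NA`.
#' @export
behavior_rate_correlations <- function(mean_rates, groups, min_cells = 3L) {
  mean_rates <- as.matrix(mean_rates)
  stopifnot(ncol(mean_rates) == 3L, nrow(mean_rates) == length(groups))
  bn <- colnames(mean_rates) %||% c("feeding", "social", "object")
  out <- list()
  for (g in unique(groups)) {
    X <- mean_rates[groups == g, , drop = FALSE]
    if (nrow(X) < min_cells) next
    r <- matrix(NA_real_, 3, 3, dimnames = list(bn, bn))
    p <- r
    for (i in 1:3) for (j in 1:3) {
      if (sd(X[, i]) == 0 || sd(X[, j]) == 0) next
      ct <- suppressWarnings(stats::cor.test(X[, i], X[, j]))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
    out[[as.character(g)]] <- list(r = r, p = p, n = nrow(X))
  }
  out
}

#' Anatomical enrichment maps of populations
#'
#' Per population, the 2D location histogram (default 10 x 10 grid of
#' 70 um mediolateral by 38.8 um dorsoventral bins) normalized to unit
#' mass, minus the unit-mass histogram of all cells: positive cells mark
#' locations enriched with that population. Also returns pairwise Pearson
#' correlations between flattened maps.
#'
#' @param locations cells x 2 matrix (`ml_um`, `dv_um`).
#' @param labels population name per cell.
#' @param grid_dim grid dimensions (ML bins, DV bins).
#' @param ml_bin,dv_bin bin sizes in micrometres.
#' @param origin lower corner `(ml, dv)`; defaults to the data minimum.
#' @param min_cells populations with fewer located cells are omitted.
#' @return `list(maps, correlations, grid)`; each map sums to ~0.
#' @export
anatomical_enrichment <- function(locations, labels, grid_dim = c(10L, 10L),
                                  ml_bin = 70, dv_bin = 38.8, origin = NULL,
                                  min_cells = 3L) {
  locations <- as.matrix(locations)
  stopifnot(ncol(locations) == 2L, nrow(locations) == length(labels))
  if (is.null(origin)) origin <- c(min(locations[, 1L]), min(locations[, 2L]))
  ix <- floor((locations[, 1L] - origin[1L]) / ml_bin) + 1L
  iy <- floor((locations[, 2L] - origin[2L]) / dv_bin) + 1L
  ix[locations[, 1L] == origin[1L] + grid_dim[1L] * ml_bin] <- grid_dim[1L]
  iy[locations[, 2L] == origin[2L] + grid_dim[2L] * dv_bin] <- grid_dim[2L]
  if (any(ix < 1L | ix > grid_dim[1L] | iy < 1L | iy > grid_dim[2L])) {
    stop("locations outside the grid extent")
  }
  hist2 <- function(sel) {
    h <- matrix(0, grid_dim[1L], grid_dim[2L])
    for (i in which(sel)) h[ix[i], iy[i]] <- h[ix[i], iy[i]] + 1
    h / sum(h)
  }
  all_h <- hist2(rep(TRUE, length(labels)))
  maps <- list()
  for (g in unique(labels)) {
    sel <- labels == g
    if (sum(sel) < min_cells) {
      warning("population ", g, " has fewer than ", min_cells,
              " located cells; map omitted")
      next
    }
    maps[[as.character(g)]] <- hist2(sel) - all_h
  }
  cm <- NULL
  if (length(maps) >= 2L) {
    flat <- sapply(maps, as.vector)
    cm <- cor(flat)
  }
  list(maps = maps, correlations = cm,
       grid = list(dim = grid_dim, ml_bin = ml_bin, dv_bin = dv_bin,
                   origin = origin))
}

#' Spike width at 25% of spike amplitude
#'
#' Width between the two crossings of 25% of the peak-to-baseline
#' amplitude flanking the waveform extremum, linearly interpolated. The
#' baseline is the waveform median.
#'
#' @param mean_waveform numeric amplitude series.
#' @param fs_hz waveform sampling rate (Hz).
#' @param level fraction of the amplitude (default 0.25).
#' @return Width in ms, or `NA` when a flank never crosses the level.
#' @export
spike_width <- function(mean_waveform, fs_hz, level = 0.25) {
  w <- as.numeric(mean_waveform)
  dev <- w - median(w)
  pk <- which.max(abs(dev))
  amp <- dev[pk]
  if (amp == 0) return(NA_real_)
  dev <- dev * sign(amp)          # analyze positive-going deviation
  thr <- level * abs(amp)
  left <- NA_real_
  for (j in seq(pk - 1L, 1L)) {
    if (pk == 1L) break
    if (dev[j] < thr && dev[j + 1L] >= thr) {
      left <- j + (thr - dev[j]) / (dev[j + 1L] - dev[j])
      break
    }
  }
  right <- NA_real_
  if (pk < length(dev)) for (j in seq(pk, length(dev) - 1L)) {
    if (dev[j] >= thr && dev[j + 1L] < thr) {
      right <- j + (dev[j] - thr) / (dev[j] - dev[j + 1L])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / fs_hz * 1000
}
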