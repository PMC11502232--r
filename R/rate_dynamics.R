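# Firing-rate estimation, episode time warping and feature construction.

#' Gaussian-kernel firing rate on a regular grid
#'
#' The rate is the sum over spikes of a normalized Gaussian (SD
#' `kernel_sd_ms`) centered at each spike, evaluated on `grid`. Spikes are
#' binned to the nearest grid point and convolved with the kernel sampled
#' at the grid step (truncated at 4 SD), which is exact to within half a
#' grid step of spike-position resolution.
#'
#' @param spike_times_s sorted spike times (s).
#' @param kernel_sd_ms Gaussian kernel SD in ms (default 500).
#' @param grid regular, ascending time grid (s) covering the session.
#' @return Numeric vector of rates (Hz) on `grid`.
#' @export
estimate_rate <- function(spike_times_s, kernel_sd_ms = 500, grid) {
  if (is.unsorted(spike_times_s)) stop("spike times must be sorted")
  n <- length(grid)
  if (n < 2L) stop("grid must have at least 2 points")
  dt <- grid[2L] - grid[1L]
  if (max(abs(diff(grid) - dt)) > 1e-6 * dt) stop("grid must be regular")
  if (length(spike_times_s) == 0L) return(numeric(n))
  counts <- tabulate(pmin(pmax(round((spike_times_s - grid[1L]) / dt), 0) + 1L, n),
                     nbins = n)
  sd_s <- kernel_sd_ms / 1000
  half <- ceiling(4 * sd_s / dt)
  kern <- dnorm(seq(-half, half) * dt, sd = sd_s)
  full <- conv_open(counts, kern)
  full[(half + 1L):(half + n)]
}

#' Warp behavioral episodes onto a common phase axis
#'
#' Episodes of one behavior are standardized to the average episode
#' duration: `n_bins = round(mean duration / warp_bin)`, each episode is
#' split into `n_bins` equal sub-intervals, the rate is sampled at each
#' sub-interval (by interpolation of the kernel rate at the sub-interval
#' midpoint; the 500 ms kernel makes the rate smooth at this scale), and
#' bins are averaged across episodes. Phase is defined on the half-open
#' episode interval.
#'
#' @param rate rate series (Hz) from [estimate_rate()].
#' @param grid the time grid of `rate`.
#' @param episodes data.frame with `start_s`, `end_s` rows of one behavior.
#' @param warp_bin_ms warp resolution in ms (default 10).
#' @param n_bins override the bin count (used to pool the mean episode
#'   duration across sessions so all cells share one vector length).
#' @return `list(values, n_bins, n_episodes)` of class
#'   `behavior_rate_vector`; with zero episodes an empty-vector sentinel
#'   (`n_bins = 0`) is returned and the cell is excluded downstream.
#' @export
warp_episodes <- function(rate, grid, episodes, warp_bin_ms = 10,
                          n_bins = NULL) {
  if (nrow(episodes) == 0L) {
    return(structure(list(values = numeric(0), n_bins = 0L, n_episodes = 0L),
                     class = "behavior_rate_vector"))
  }
  dur <- episodes$end_s - episodes$start_s
  if (is.null(n_bins)) n_bins <- max(1L, round(mean(dur) / (warp_bin_ms / 1000)))
  acc <- numeric(n_bins)
  phases <- (seq_len(n_bins) - 0.5) / n_bins
  dt <- grid[2L] - grid[1L]
  n <- length(grid)
  for (i in seq_len(nrow(episodes))) {
    tq <- episodes$start_s[i] + phases * dur[i]
    # direct linear interpolation on the regular grid
    pos <- pmin(pmax((tq - grid[1L]) / dt, 0), n - 1)
    i0 <- pmin(floor(pos) + 1L, n - 1L)
    fr <- pos - (i0 - 1L)
    acc <- acc + rate[i0] * (1 - fr) + rate[i0 + 1L] * fr
  }
  structure(list(values = acc / nrow(episodes), n_bins = as.integer(n_bins),
                 n_episodes = nrow(episodes)),
            class = "behavior_rate_vector")
}

#' Build the z-scored, PCA-reduced firing-rate feature matrix
#'
#' Per cell, the feeding, social and object warped rate vectors are
#' concatenated in that fixed order and z-scored along the row. Bin counts
#' are computed from the grand-mean episode duration pooled across all
#' sessions (one shared length per behavior), so cells from different
#' sessions get equal-length vectors. Rows are then centered column-wise
#' and projected onto principal axes; the minimal number of components with
#' cumulative explained variance at or above `variance_target` is retained.
#'
#' Cells missing episodes of some behavior in their session, or with
#' zero-variance concatenated vectors, are excluded with a warning.
#'
#' @param dataset a [spike_dataset()].
#' @param etho an [ethogram()] sharing session ids with `dataset`.
#' @param config an [pipeline_config()]; `kernel_sd_ms`, `warp_bin_ms` and
#'   `variance_target` are used.
#' @return An object of class `feature_matrix`: `cells` (data.frame of
#'   retained cells), `concatenated` (z-scored rows), `reduced` (scores on
#'   the first `m` axes), `first5` (scores on the first five axes),
#'   `explained_variance`, `m`, `n_bins` (named per behavior),
#'   `behavior_vectors` (raw Hz matrices per behavior), `dropped`.
#' @export
build_feature_matrix <- function(dataset, etho, config = pipeline_config()) {
  behaviors <- c("feeding", "social", "object")
  bin_s <- config$warp_bin_ms / 1000
  n_bins <- vapply(behaviors, function(b) {
    e <- episodes_of(etho, b)
    if (nrow(e) == 0L) return(0L)
    max(1L, as.integer(round(mean(e$end_s - e$start_s) / bin_s)))
  }, integer(1))
  if (any(n_bins == 0L)) {
    stop("ethogram lacks episodes of: ",
         paste(behaviors[n_bins == 0L], collapse = ", "))
  }
  nc <- n_cells(dataset)
  if (nc < 2L) stop("need at least 2 cells")
  vecs <- lapply(behaviors, function(b) matrix(NA_real_, nc, n_bins[[b]]))
  names(vecs) <- behaviors
  ok <- rep(TRUE, nc)
  for (sid in dataset$session_spans$session_id) {
    span <- session_span(dataset, sid)
    grid <- seq(span[1L], span[2L], by = bin_s)
    cell_idx <- which(dataset$cells$session_id == sid)
    eps <- lapply(behaviors, function(b) episodes_of(etho, b, sid))
    names(eps) <- behaviors
    for (i in cell_idx) {
      rate <- estimate_rate(dataset$spikes[[i]], config$kernel_sd_ms, grid)
      for (b in behaviors) {
        if (nrow(eps[[b]]) == 0L) { ok[i] <- FALSE; next }
        w <- warp_episodes(rate, grid, eps[[b]], config$warp_bin_ms,
                           n_bins = n_bins[[b]])
        vecs[[b]][i, ] <- w$values
      }
    }
  }
  if (any(!ok)) {
    warning(sum(!ok), " cell(s) without episodes of every behavior excluded")
  }
  concat <- do.call(cbind, vecs)
  rsd <- apply(concat, 1L, sd)
  flat <- ok & (is.na(rsd) | rsd == 0)
  if (any(flat)) {
    warning(sum(flat), " zero-variance (silent or constant) cell(s) excluded")
    ok <- ok & !flat
  }
  keep <- which(ok)
  if (length(keep) < 2L) stop("fewer than 2 usable cells")
  z <- t(scale(t(concat[keep, , drop = FALSE])))  # per-row z-score
  pca <- prcomp(z, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  m <- which(cumsum(ev) >= config$variance_target)[1L]
  if (is.na(m)) m <- length(ev)
  structure(list(
    cells = dataset$cells[keep, , drop = FALSE],
    concatenated = z,
    reduced = pca$x[, seq_len(m), drop = FALSE],
    first5 = pca$x[, seq_len(min(5L, ncol(pca$x))), drop = FALSE],
    explained_variance = ev,
    m = as.integer(m),
    n_bins = n_bins,
    behavior_vectors = lapply(vecs, function(v) v[keep, , drop = FALSE]),
    dropped = dataset$cells[!ok, , drop = FALSE]),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$reduced), " cells x ",
      ncol(x$concatenated), " bins (",
      paste(names(x$n_bins), x$n_bins, sep = ": ", collapse = ", "),
      "); ", x$m, " components retained (",
      round(100 * sum(x$explained_variance[seq_len(x$m)]), 1),
      "% variance)\n", sep = "")
  invisible(x)
}
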