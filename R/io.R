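#' Read spike trains from the canonical CSV dialect
#'
#' Expects a header `session_id,cell_id,shank_id,time_s`, one row per spike.
#' Rows are grouped per `(session_id, cell_id)` and times sorted. Session
#' spans are inferred as `(0, max time + 1 s)` per session unless a sidecar
#' span table is supplied.
#'
#' @param path CSV file path.
#' @param spans optional data.frame `session_id,t0_s,t1_s` overriding the
#'   inferred spans.
#' @return A [spike_dataset()].
#' @export
read_spike_csv <- function(path, spans = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "cell_id", "shank_id", "time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spike CSV format error: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    return(spike_dataset(
      cells = data.frame(session_id = character(0), cell_id = character(0),
                         shank_id = integer(0)),
      spikes = list(),
      session_spans = data.frame(session_id = character(0), t0_s = numeric(0),
                                 t1_s = numeric(0))))
  }
  neg <- which(df$time_s < 0)
  if (length(neg)) stop("negative spike time at row ", neg[1L] + 1L,
                        " (time_s = ", df$time_s[neg[1L]], ")")
  key <- paste(df$session_id, df$cell_id, sep = "\r")
  grp <- split(seq_len(nrow(df)), key)
  first <- vapply(grp, `[`, integer(1), 1L)
  ord <- order(first)  # keep file order of first appearance
  grp <- grp[ord]
  cells <- data.frame(
    session_id = df$session_id[first[ord]],
    cell_id = as.character(df$cell_id[first[ord]]),
    shank_id = as.integer(df$shank_id[first[ord]]),
    stringsAsFactors = FALSE)
  spikes <- lapply(grp, function(i) sort(df$time_s[i]))
  names(spikes) <- NULL
  if (is.null(spans)) {
    mx <- tapply(df$time_s, df$session_id, max)
    spans <- data.frame(session_id = names(mx), t0_s = 0,
                        t1_s = as.numeric(mx) + 1, stringsAsFactors = FALSE)
  }
  spike_dataset(cells, spikes, spans)
}

#' Write spike trains to the canonical CSV dialect
#'
#' @param dataset a [spike_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(dataset, path) {
  n <- lengths(dataset$spikes)
  df <- data.frame(
    session_id = rep(dataset$cells$session_id, n),
    cell_id = rep(dataset$cells$cell_id, n),
    shank_id = rep(dataset$cells$shank_id, n),
    time_s = unlist(dataset$spikes, use.names = FALSE) %||% numeric(0),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioral ethogram from CSV
#'
#' Header `session_id,behavior,start_s,end_s`; behavior must be one of
#' `feeding`, `social`, `object`. Overlapping episodes within a session are
#' rejected; feeding episodes below the 4.8 s scoring minimum are dropped
#' with a warning.
#'
#' @param path CSV file path.
#' @param min_feeding_s minimal scored feeding-bout duration (s).
#' @return An [ethogram()].
#' @export
read_ethogram_csv <- function(path, min_feeding_s = 4.8) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "behavior", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ethogram CSV format error: missing column(s) ",
                         paste(miss, collapse = ", "))
  ethogram(df, min_feeding_s = min_feeding_s)
}

#' Write an ethogram to CSV
#' @param etho an [ethogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ethogram_csv <- function(etho, path) {
  write.csv(etho$episodes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one channel of a flat interleaved int16 LFP file
#'
#' The flat binary dialect is little-endian int16, channels interleaved
#' sample by sample (the field's `.lfp`/`.dat` convention).
#'
#' @param path binary file path.
#' @param fs_hz sampling rate of the file (canonical 1250).
#' @param n_channels number of interleaved channels.
#' @param channel 1-based channel index to extract.
#' @param scale_uv_per_bit microvolts per least significant bit.
#' @param session_id session identifier attached to the signal.
#' @return An [lfp_signal()] in microvolts.
#' @export
read_lfp_flat <- function(path, fs_hz = 1250, n_channels = 1L, channel = 1L,
                          scale_uv_per_bit = 1, session_id = "s1") {
  if (!file.exists(path)) stop("file not found: ", path)
  nbytes <- file.info(path)$size
  if (nbytes %% (2L * n_channels) != 0) {
    stop("truncated file: ", nbytes, " bytes not divisible by 2 x ",
         n_channels, " channels")
  }
  if (channel > n_channels || channel < 1L) {
    stop("channel ", channel, " out of range (", n_channels, " channels)")
  }
  raw <- readBin(path, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = nbytes / 2L)
  lfp_signal(raw[seq(channel, length(raw), by = n_channels)] * scale_uv_per_bit,
             fs_hz = fs_hz, session_id = session_id)
}

#' Write an LFP signal as flat little-endian int16
#'
#' @param lfp an [lfp_signal()].
#' @param path output path.
#' @param scale_uv_per_bit microvolts per bit used for quantization.
#' @return `path`, invisibly.
#' @export
write_lfp_flat <- function(lfp, path, scale_uv_per_bit = 1) {
  q <- as.integer(pmax(-32768, pmin(32767, round(lfp$samples / scale_uv_per_bit))))
  writeBin(q, path, size = 2L, endian = "little")
  invisible(path)
}

#' Read / write labeled epochs as CSV
#'
#' Dialect `session_id,label,start_s,end_s`.
#' @param path CSV path.
#' @return A list of [epoch_set()] objects, one per `(session_id, label)`.
#' @export
read_epochs_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "label", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("epochs CSV format error: missing column(s) ",
                         paste(miss, collapse = ", "))
  out <- list()
  for (k in unique(paste(df$session_id, df$label, sep = "\r"))) {
    e <- df[paste(df$session_id, df$label, sep = "\r") == k, , drop = FALSE]
    out[[length(out) + 1L]] <- epoch_set(e$label[1L],
                                         cbind(e$start_s, e$end_s),
                                         session_id = e$session_id[1L])
  }
  out
}

#' @rdname read_epochs_csv
#' @param epoch_sets list of [epoch_set()] objects.
#' @export
write_epochs_csv <- function(epoch_sets, path) {
  if (inherits(epoch_sets, "epoch_set")) epoch_sets <- list(epoch_sets)
  rows <- do.call(rbind, lapply(epoch_sets, function(es) {
    if (nrow(es$intervals) == 0L) return(NULL)
    data.frame(session_id = es$session_id, label = es$label,
               start_s = es$intervals[, 1L], end_s = es$intervals[, 2L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(session_id = character(0), label = character(0),
                       start_s = numeric(0), end_s = numeric(0))
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Aggregates every analysis parameter with the study defaults: 500 ms
#' Gaussian rate kernel (SD), 10 ms warp bins, 90% retained variance, 100
#' bootstraps of 90% subsamples, 100 silhouette iterations with a 95-pass
#' minimum, slow/fast gamma bands 30-60 / 61-90 Hz, the 2 SD / 25 ms / 1 SD
#' event rule, 0.5 SD nonrhythmic threshold, 1 ms CCG bins over +/-50 ms,
#' +/-15 ms cofiring window, and 1,000 uniform shifts drawn from -25 to
#' 25 s.
#'
#' @param kernel_sd_ms Gaussian rate-kernel SD (ms).
#' @param warp_bin_ms time-warp bin resolution (ms).
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @param cluster_range integer vector of cluster counts to scan.
#' @param knn_range integer vector of k-NN values to scan.
#' @param n_bootstrap bootstrap iterations for the stability scan.
#' @param subsample_fraction fraction of cells per bootstrap, in (0, 1].
#' @param silhouette_iters,silhouette_min_pass silhouette-consistency runs
#'   and the minimum number of positive-silhouette runs to retain a cell.
#' @param bands named list of detection bands in Hz.
#' @param nonrhythmic_bands named list of screening bands for nonrhythmic
#'   epochs.
#' @param detect_sd,edge_sd,min_event_ms envelope event rule.
#' @param nonrhythmic_sd,min_nonrhythmic_ms nonrhythmic epoch rule.
#' @param ccg_bin_ms,ccg_half_window_ms CCG binning.
#' @param cofire_half_window_ms cofiring probability window (ms).
#' @param shuffle_n,shuffle_range_s shuffle-null settings.
#' @param master_seed master seed from which all stage seeds are spawned.
#' @return A validated list of class `lh_config`.
#' @export
pipeline_config <- function(kernel_sd_ms = 500, warp_bin_ms = 10,
                            variance_target = 0.9,
                            cluster_range = 2:9,
                            knn_range = c(10L, 20L, 30L),
                            n_bootstrap = 100L, subsample_fraction = 0.9,
                            silhouette_iters = 100L, silhouette_min_pass = 95L,
                            bands = list(slow_gamma = c(30, 60),
                                         fast_gamma = c(61, 90)),
                            nonrhythmic_bands = list(delta = c(2, 4),
                                                     theta = c(5, 10),
                                                     beta = c(15, 30),
                                                     gamma = c(30, 120),
                                                     fast = c(120, 200)),
                            detect_sd = 2, edge_sd = 1, min_event_ms = 25,
                            nonrhythmic_sd = 0.5, min_nonrhythmic_ms = 100,
                            ccg_bin_ms = 1, ccg_half_window_ms = 50,
                            cofire_half_window_ms = 15,
                            shuffle_n = 1000L, shuffle_range_s = c(-25, 25),
                            master_seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$cluster_range) == 0L) stop("configuration error: empty cluster_range")
  if (length(cfg$knn_range) == 0L) stop("configuration error: empty knn_range")
  pos <- c("kernel_sd_ms", "warp_bin_ms", "detect_sd", "min_event_ms",
           "ccg_bin_ms", "ccg_half_window_ms", "cofire_half_window_ms",
           "min_nonrhythmic_ms")
  for (p in pos) if (cfg[[p]] <= 0) stop("configuration error: ", p, " must be positive")
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1) {
    stop("configuration error: subsample_fraction must be in (0, 1]")
  }
  if (abs(sum(cfg$shuffle_range_s)) > 1e-12) {
    stop("configuration error: shuffle_range_s must be symmetric about 0")
  }
  if (cfg$silhouette_min_pass > cfg$silhouette_iters) {
    stop("configuration error: silhouette_min_pass exceeds silhouette_iters")
  }
  structure(cfg, class = "lh_config")
}
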