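#' Spike dataset container
#'
#' Holds per-cell spike trains with session and shank identity, plus the
#' recording span of each session. Spike times are seconds, 0-based within
#' the session; all intervals in the package are half-open `[start, end)`.
#'
#' @param cells data.frame with columns `session_id`, `cell_id`, `shank_id`
#'   (one row per cell; `(session_id, cell_id)` unique).
#' @param spikes list of numeric vectors, parallel to the rows of `cells`,
#'   each sorted ascending and non-negative.
#' @param session_spans data.frame with columns `session_id`, `t0_s`, `t1_s`.
#' @return An object of class `spike_dataset`.
#' @export
spike_dataset <- function(cells, spikes, session_spans) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  stopifnot(all(c("session_id", "cell_id", "shank_id") %in% names(cells)),
            length(spikes) == nrow(cells),
            all(c("session_id", "t0_s", "t1_s") %in% names(session_spans)))
  key <- paste(cells$session_id, cells$cell_id)
  if (anyDuplicated(key)) stop("duplicate (session_id, cell_id) pairs")
  span_idx <- match(cells$session_id, session_spans$session_id)
  if (anyNA(span_idx)) stop("cell refers to a session without a span")
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (is.unsorted(s)) stop("spike times must be sorted ascending (cell ",
                             cells$cell_id[i], ")")
    if (length(s) && (s[1L] < session_spans$t0_s[span_idx[i]] ||
                      s[length(s)] >= session_spans$t1_s[span_idx[i]])) {
      stop("spike times outside session span (cell ", cells$cell_id[i], ")")
    }
  }
  structure(list(cells = cells, spikes = spikes,
                 session_spans = as.data.frame(session_spans)),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset> ", nrow(x$cells), " cells, ",
      nrow(x$session_spans), " sessions, ",
      sum(lengths(x$spikes)), " spikes\n", sep = "")
  invisible(x)
}

n_cells <- function(ds) nrow(ds$cells)

session_span <- function(ds, session_id) {
  i <- match(session_id, ds$session_spans$session_id)
  c(ds$session_spans$t0_s[i], ds$session_spans$t1_s[i])
}

#' Behavioral ethogram container
#'
#' Scored behavioral episodes per session. Episodes of the same session must
#' not overlap; the behavior vocabulary is `feeding`, `social`, `object`.
#' Feeding episodes shorter than `min_feeding_s` (scoring minimum) are
#' rejected with a warning by [read_ethogram_csv()] and [ethogram()].
#'
#' @param episodes data.frame with columns `session_id`, `behavior`,
#'   `start_s`, `end_s`.
#' @param min_feeding_s minimal scored feeding-bout duration in seconds.
#' @return An object of class `ethogram`.
#' @export
ethogram <- function(episodes, min_feeding_s = 4.8) {
  episodes <- as.data.frame(episodes, stringsAsFactors = FALSE)
  stopifnot(all(c("session_id", "behavior", "start_s", "end_s") %in% names(episodes)))
  bad <- setdiff(unique(episodes$behavior), c("feeding", "social", "object"))
  if (length(bad)) stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  if (any(episodes$end_s <= episodes$start_s)) stop("episode end must exceed start")
  short <- episodes$behavior == "feeding" &
    (episodes$end_s - episodes$start_s) < min_feeding_s
  if (any(short)) {
    warning(sum(short), " feeding episode(s) below the ", min_feeding_s,
            " s scoring minimum rejected")
    episodes <- episodes[!short, , drop = FALSE]
  }
  episodes <- episodes[order(episodes$session_id, episodes$start_s), , drop = FALSE]
  rownames(episodes) <- NULL
  for (sid in unique(episodes$session_id)) {
    e <- episodes[episodes$session_id == sid, , drop = FALSE]
    if (nrow(e) > 1L) {
      ov <- which(e$start_s[-1L] < e$end_s[-nrow(e)])
      if (length(ov)) {
        stop(sprintf(
          "overlapping episodes in session %s: [%g, %g) %s and [%g, %g) %s",
          sid, e$start_s[ov[1L]], e$end_s[ov[1L]], e$behavior[ov[1L]],
          e$start_s[ov[1L] + 1L], e$end_s[ov[1L] + 1L], e$behavior[ov[1L] + 1L]))
      }
    }
  }
  structure(list(episodes = episodes), class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat("<ethogram> ", nrow(x$episodes), " episodes (",
      paste(names(table(x$episodes$behavior)), table(x$episodes$behavior),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

episodes_of <- function(etho, behavior, session_id = NULL) {
  e <- etho$episodes
  e <- e[e$behavior == behavior, , drop = FALSE]
  if (!is.null(session_id)) e <- e[e$session_id == session_id, , drop = FALSE]
  e
}

#' LFP signal container
#'
#' @param samples numeric vector of the single-channel local field potential
#'   in microvolts.
#' @param fs_hz sampling rate in Hz (canonical 1250).
#' @param session_id session identifier.
#' @return An object of class `lfp_signal`.
#' @export
lfp_signal <- function(samples, fs_hz, session_id = "s1") {
  stopifnot(fs_hz > 0, is.numeric(samples))
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 session_id = session_id),
            class = "lfp_signal")
}

#' @export
print.lfp_signal <- function(x, ...) {
  cat("<lfp_signal> ", length(x$samples), " samples @ ", x$fs_hz, " Hz (",
      round(length(x$samples) / x$fs_hz, 1), " s), session ", x$session_id,
      "\n", sep = "")
  invisible(x)
}

#' Labeled epoch set
#'
#' Sorted disjoint half-open time intervals with a label (e.g. `slow_gamma`,
#' `fast_gamma`, `nonrhythmic`) and the detection parameters that produced
#' them.
#'
#' @param label epoch label.
#' @param intervals 2-column matrix or data.frame of `[start_s, end_s)` rows.
#' @param session_id session identifier.
#' @param params list of detection parameters (kept for provenance).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(label, intervals, session_id = "s1", params = list()) {
  m <- as_interval_matrix(intervals)
  if (nrow(m) > 1L && any(m[-1L, 1L] < m[-nrow(m), 2L])) {
    stop("epoch intervals must be disjoint")
  }
  if (nrow(m) && any(m[, 2L] <= m[, 1L])) stop("epoch end must exceed start")
  structure(list(label = label, intervals = m, session_id = session_id,
                 params = params),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set> '", x$label, "': ", nrow(x$intervals), " intervals, total ",
      round(interval_total(x$intervals), 2), " s, session ", x$session_id,
      "\n", sep = "")
  invisible(x)
}
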