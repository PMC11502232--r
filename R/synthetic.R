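# Synthetic recordings with planted population, oscillation and assembly
# structure. All generators are pure functions of (parameters, seed).

#' Population activity templates
#'
#' Returns the seven canonical templates: four feeding-phase bump
#' populations (FOn, EF, LF, FOff, Gaussian bumps in episode phase with
#' centers 0.05 / 0.30 / 0.70 / 0.95 and width 0.1) and three
#' behavior-homogeneous populations (Fd feeding, Sol social, Exp object).
#' Baseline rates follow the 1.7-3.5 Hz range typical of the recorded
#' region. During the preferred behavior the rate is multiplied by up to
#' `peak_mult`; during the other scored behaviors it is mildly suppressed
#' (`off_mult`), reproducing the strong negative feeding-vs-other rate
#' correlations seen in such populations.
#'
#' @param peak_mult peak rate multiplier at the bump center / during the
#'   preferred behavior (default 3, a free simulation choice).
#' @param off_mult multiplier during non-preferred scored behaviors.
#' @param bump_width Gaussian bump SD in episode-phase units.
#' @return A named list of templates (class `population_template`), each
#'   with `name`, `baseline_hz`, and a `tuning(behavior, phase)` function
#'   returning a rate multiplier.
#' @export
population_templates <- function(peak_mult = 3, off_mult = 0.5,
                                 bump_width = 0.1) {
  baselines <- c(FOn = 3.2, EF = 2.6, LF = 1.7, FOff = 1.9,
                 Fd = 2.7, Sol = 2.6, Exp = 3.5)
  centers <- c(FOn = 0.05, EF = 0.30, LF = 0.70, FOff = 0.95)
  stopifnot(all(diff(centers) > 0))
  make_bump <- function(center) {
    force(center)
    function(behavior, phase) {
      m <- rep(off_mult, length(phase))
      f <- behavior == "feeding"
      m[f] <- 1 + (peak_mult - 1) *
        exp(-(phase[f] - center)^2 / (2 * bump_width^2))
      m
    }
  }
  make_flat <- function(pref) {
    force(pref)
    function(behavior, phase) {
      m <- rep(off_mult, length(phase))
      m[behavior == pref] <- peak_mult
      m
    }
  }
  tpl <- list()
  for (nm in names(baselines)) {
    tuning <- if (nm %in% names(centers)) make_bump(centers[[nm]])
              else make_flat(switch(nm, Fd = "feeding", Sol = "social",
                                    Exp = "object"))
    tpl[[nm]] <- structure(
      list(name = nm, baseline_hz = baselines[[nm]], tuning = tuning,
           phase_center = if (nm %in% names(centers)) centers[[nm]] else NA_real_,
           phase_width = if (nm %in% names(centers)) bump_width else NA_real_),
      class = "population_template")
  }
  tpl
}

#' Construct a custom population template
#'
#' @param name template name.
#' @param baseline_hz baseline firing rate (Hz), non-negative.
#' @param tuning function `(behavior, phase) -> multiplier` (vectorized over
#'   `phase`); `NULL` for a homogeneous Poisson cell (multiplier 1).
#' @return A `population_template`.
#' @export
make_template <- function(name, baseline_hz, tuning = NULL) {
  if (baseline_hz < 0) stop("baseline_hz must be non-negative")
  if (is.null(tuning)) tuning <- function(behavior, phase) rep(1, length(phase))
  if (baseline_hz == 0) stop("degenerate cell: zero baseline and no tuning support")
  structure(list(name = name, baseline_hz = baseline_hz, tuning = tuning,
                 phase_center = NA_real_, phase_width = NA_real_),
            class = "population_template")
}

#' Generate a synthetic behavioral ethogram
#'
#' Episodes of the three behaviors are interleaved with unscored gaps.
#' Feeding-bout durations are lognormal with configurable median (default
#' 22 s, truncated at the 4.8 s scoring minimum); social and object episodes
#' are lognormal with median 4 s, making feeding bouts roughly six times
#' longer, as in the emulated recordings.
#'
#' @param n_sessions number of sessions.
#' @param session_len_s session length in seconds (>= 300).
#' @param seed RNG seed.
#' @param feeding_median_s,feeding_sdlog feeding duration lognormal.
#' @param other_median_s,other_sdlog social/object duration lognormal.
#' @param min_feeding_s feeding scoring minimum (s).
#' @param gap_range_s unscored-gap range between episodes (s).
#' @return An [ethogram()]; the session length is attached as attribute
#'   `session_len_s`.
#' @export
generate_ethogram <- function(n_sessions, session_len_s, seed = 1L,
                              feeding_median_s = 22, feeding_sdlog = 0.5,
                              other_median_s = 4, other_sdlog = 0.5,
                              min_feeding_s = 4.8, gap_range_s = c(3, 12)) {
  if (session_len_s < 300) stop("generation error: session_len_s must be >= 300 s")
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_sessions)) {
    sid <- sprintf("s%02d", s)
    t <- runif(1, gap_range_s[1L], gap_range_s[2L])
    seen <- character(0)
    cycle <- character(0)
    repeat {
      if (length(cycle) == 0L) cycle <- sample(c("feeding", "social", "object"))
      beh <- cycle[1L]; cycle <- cycle[-1L]
      dur <- if (beh == "feeding") {
        d <- rlnorm(1, log(feeding_median_s), feeding_sdlog)
        while (d < min_feeding_s) d <- rlnorm(1, log(feeding_median_s), feeding_sdlog)
        d
      } else {
        rlnorm(1, log(other_median_s), other_sdlog)
      }
      if (t + dur > session_len_s - 1) break
      rows[[length(rows) + 1L]] <- data.frame(
        session_id = sid, behavior = beh, start_s = t, end_s = t + dur,
        stringsAsFactors = FALSE)
      seen <- union(seen, beh)
      t <- t + dur + runif(1, gap_range_s[1L], gap_range_s[2L])
    }
    if (length(seen) < 3L) {
      stop("generation error: session ", sid,
           " too short to place at least one episode per behavior")
    }
  }
  etho <- ethogram(do.call(rbind, rows), min_feeding_s = min_feeding_s)
  attr(etho, "session_len_s") <- session_len_s
  etho
}

# Rate multiplier of one cell at times tt within one session's ethogram.
# Outside scored episodes the multiplier is 1 (baseline firing); inside an
# episode it is the template tuning at the elapsed phase of the episode.
.multiplier_at <- function(tt, template, episodes) {
  m <- rep(1, length(tt))
  if (nrow(episodes) == 0L) return(m)
  edges <- as.vector(t(cbind(episodes$start_s, episodes$end_s)))
  pos <- findInterval(tt, edges)
  inside <- pos %% 2L == 1L
  if (any(inside)) {
    ep <- (pos[inside] + 1L) %/% 2L
    phase <- (tt[inside] - episodes$start_s[ep]) /
      (episodes$end_s[ep] - episodes$start_s[ep])
    m[inside] <- template$tuning(episodes$behavior[ep], phase)
  }
  m
}

#' Generate spike trains with planted population structure
#'
#' Each cell is an inhomogeneous Poisson process simulated by thinning:
#' its template baseline everywhere, multiplied by the template tuning at
#' the elapsed phase inside scored episodes. Cells are spread round-robin
#' across sessions and across `n_shanks` shanks within a session.
#'
#' @param etho an [ethogram()] (from [generate_ethogram()] or read from CSV;
#'   session length is taken from the `session_len_s` attribute or inferred).
#' @param templates list of `population_template`s.
#' @param n_cells_per_pop cells per template.
#' @param seed RNG seed.
#' @param n_shanks number of probe shanks (>= 2 so cross-shank pairs exist).
#' @return `list(dataset = spike_dataset, truth = data.frame(session_id,
#'   cell_id, shank_id, population))`.
#' @export
generate_population_spikes <- function(etho, templates, n_cells_per_pop,
                                       seed = 1L, n_shanks = 4L) {
  if (length(templates) == 0L) stop("templates must be non-empty")
  if (n_shanks < 2L) stop("need at least 2 shanks")
  set.seed(seed)
  sessions <- unique(etho$episodes$session_id)
  len <- attr(etho, "session_len_s") %||% (max(etho$episodes$end_s) + 5)
  spans <- data.frame(session_id = sessions, t0_s = 0, t1_s = len,
                      stringsAsFactors = FALSE)
  cells <- list(); spikes <- list(); truth <- list()
  idx <- 0L
  for (p in seq_along(templates)) {
    tpl <- templates[[p]]
    for (c in seq_len(n_cells_per_pop)) {
      idx <- idx + 1L
      sid <- sessions[((idx - 1L) %% length(sessions)) + 1L]
      shank <- ((idx - 1L) %/% length(sessions)) %% n_shanks + 1L
      eps <- etho$episodes[etho$episodes$session_id == sid, , drop = FALSE]
      lam_max <- tpl$baseline_hz *
        max(1, tpl$tuning("feeding", seq(0, 1, 0.01)),
            tpl$tuning("social", 0.5), tpl$tuning("object", 0.5))
      if (lam_max <= 0) stop("degenerate cell: zero rate everywhere")
      n_cand <- rpois(1, lam_max * len)
      tt <- sort(runif(n_cand, 0, len))
      lam <- tpl$baseline_hz * .multiplier_at(tt, tpl, eps)
      keep <- runif(n_cand) < lam / lam_max
      cid <- sprintf("%s_c%03d", tpl$name, idx)
      cells[[idx]] <- data.frame(session_id = sid, cell_id = cid,
                                 shank_id = shank, stringsAsFactors = FALSE)
      spikes[[idx]] <- tt[keep]
      truth[[idx]] <- data.frame(session_id = sid, cell_id = cid,
                                 shank_id = shank, population = tpl$name,
                                 stringsAsFactors = FALSE)
    }
  }
  list(dataset = spike_dataset(do.call(rbind, cells), spikes, spans),
       truth = do.call(rbind, truth))
}

# 1/f-shaped (pink) background noise via spectral shaping, unit SD.
.pink_noise <- function(n) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))             # avoid the DC singularity
  f <- pmin(f, n - f + 1)               # two-sided frequency index
  X <- X / sqrt(f)
  X[1L] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate an LFP with planted band-limited oscillation bursts
#'
#' The background is 1/f (pink) noise. Each planted event is a sinusoid at
#' the band center with raised-cosine on/off ramps, scaled so that the peak
#' of its rectified-and-smoothed band envelope sits `amplitude_sd` SDs above
#' the background envelope mean of that band (the units of the downstream
#' detection rule).
#'
#' @param session_len_s signal length (s).
#' @param fs_hz sampling rate (Hz).
#' @param event_spec list of specs: `list(band_hz = c(lo, hi),
#'   amplitude_sd =, duration_ms =, count =, label = )` (label optional).
#' @param seed RNG seed.
#' @param noise_sd_uv background SD in microvolts.
#' @param session_id session identifier.
#' @return `list(lfp = lfp_signal, truth = list of epoch_set)` with exact
#'   ground-truth intervals per band.
#' @export
generate_lfp_with_events <- function(session_len_s, fs_hz, event_spec,
                                     seed = 1L, noise_sd_uv = 30,
                                     session_id = "s1") {
  set.seed(seed)
  n <- round(session_len_s * fs_hz)
  x <- .pink_noise(n) * noise_sd_uv
  noise <- lfp_signal(x, fs_hz, session_id)
  truth <- list()
  for (spec in event_spec) {
    band <- spec$band_hz
    if (band[2L] >= fs_hz / 2) stop("band upper edge must be below Nyquist")
    label <- spec$label %||% sprintf("band_%g_%g", band[1L], band[2L])
    count <- spec$count
    if (count == 0L) {
      truth[[label]] <- epoch_set(label, NULL, session_id)
      next
    }
    env <- band_envelope(noise, band)
    target <- env$mean + spec$amplitude_sd * env$sd
    amp <- target * pi / 2                 # rectified-sine mean = (2/pi) * A
    dur <- spec$duration_ms / 1000
    # non-overlapping random placements with a margin of one duration
    starts <- numeric(0)
    tries <- 0L
    while (length(starts) < count) {
      cand <- runif(1, 1, session_len_s - dur - 1)
      if (all(abs(cand - starts) > 2 * dur + 0.2)) starts <- c(starts, cand)
      tries <- tries + 1L
      if (tries > 10000L) stop("could not place non-overlapping events; ",
                               "session too short for the requested count")
    }
    starts <- sort(starts)
    fc <- mean(band)
    for (s0 in starts) {
      i0 <- floor(s0 * fs_hz) + 1L
      m <- round(dur * fs_hz)
      tt <- (seq_len(m) - 1L) / fs_hz
      ramp_n <- max(3L, round(0.1 * m))
      w <- rep(1, m)
      r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      w[seq_len(ramp_n)] <- r
      w[m - ramp_n + seq_len(ramp_n)] <- rev(r)
      burst <- amp * w * sin(2 * pi * fc * tt + runif(1, 0, 2 * pi))
      x[i0:(i0 + m - 1L)] <- x[i0:(i0 + m - 1L)] + burst
    }
    truth[[label]] <- epoch_set(label, cbind(starts, starts + dur), session_id,
                                params = spec)
  }
  list(lfp = lfp_signal(x, fs_hz, session_id), truth = truth)
}

#' Inject epoch-locked synchronous spiking into cell pairs
#'
#' Inside the given epochs only, synchronous spike pairs are inserted at
#' `excess_sync_rate_hz`: the first cell receives a spike at the event time
#' and the second the same spike offset by a uniform +/- `jitter_ms` lag.
#' All original spikes are preserved.
#'
#' @param sim output of [generate_population_spikes()] or a [spike_dataset()].
#' @param epochs an [epoch_set()] (same session as the pairs).
#' @param pairs data.frame with columns `cell_a`, `cell_b` (cell_id values);
#'   members must sit on different shanks.
#' @param excess_sync_rate_hz rate of inserted synchronous events (Hz).
#' @param jitter_ms half-range of the pairwise lag jitter (ms).
#' @param seed RNG seed.
#' @return `list(dataset = spike_dataset, coupled_pairs = data.frame)`.
#' @export
couple_pairs_to_events <- function(sim, epochs, pairs, excess_sync_rate_hz,
                                   jitter_ms = 5, seed = 1L) {
  ds <- if (inherits(sim, "spike_dataset")) sim else sim$dataset
  set.seed(seed)
  iv <- epochs$intervals
  if (nrow(iv) == 0L) {
    warning("empty epoch set: no synchrony inserted")
    return(list(dataset = ds, coupled_pairs = pairs[0, , drop = FALSE]))
  }
  tot <- interval_total(iv)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    ia <- match(pairs$cell_a[r], ds$cells$cell_id)
    ib <- match(pairs$cell_b[r], ds$cells$cell_id)
    if (is.na(ia) || is.na(ib)) stop("unknown cell in pair ", r)
    if (ds$cells$session_id[ia] != ds$cells$session_id[ib]) {
      stop("pair ", r, " spans different sessions")
    }
    if (ds$cells$shank_id[ia] == ds$cells$shank_id[ib]) {
      stop("pair ", r, " members share a shank; cross-shank pairs required")
    }
    if (excess_sync_rate_hz > 0) {
      n_ins <- rpois(1, excess_sync_rate_hz * tot)
      if (n_ins > 0) {
        seg <- sample.int(nrow(iv), n_ins, replace = TRUE,
                          prob = iv[, 2L] - iv[, 1L])
        tA <- runif(n_ins, iv[seg, 1L], iv[seg, 2L])
        tB <- tA + runif(n_ins, -jitter_ms, jitter_ms) / 1000
        span <- session_span(ds, ds$cells$session_id[ia])
        tB <- pmin(pmax(tB, span[1L]), span[2L] - 1e-9)
        ds$spikes[[ia]] <- sort(c(ds$spikes[[ia]], tA))
        ds$spikes[[ib]] <- sort(c(ds$spikes[[ib]], tB))
      }
    }
    out[[r]] <- data.frame(cell_a = pairs$cell_a[r], cell_b = pairs$cell_b[r],
                           epoch_label = epochs$label,
                           excess_sync_rate_hz = excess_sync_rate_hz,
                           jitter_ms = jitter_ms, stringsAsFactors = FALSE)
  }
  list(dataset = ds, coupled_pairs = do.call(rbind, out))
}

#' Simulate a full multi-session recording (preset)
#'
#' The `paper7` preset plants the seven canonical templates at the emulated
#' study scale: 10 sessions of 1,200 s, 50 cells per population (~350
#' cells). Optionally writes `spikes.csv`, `etho.csv`, `lfp.bin` (first
#' session only) and `truth.json` to `out_dir`.
#'
#' @param preset currently only `"paper7"`.
#' @param seed master seed.
#' @param n_sessions,session_len_s,n_cells_per_pop scale overrides.
#' @param lfp_len_s length of the generated LFP segment (s); 0 skips it.
#' @param out_dir optional output directory.
#' @return list with `etho`, `dataset`, `truth`, and (if requested) `lfp`
#'   and its planted `lfp_truth`.
#' @export
simulate_recording <- function(preset = "paper7", seed = 1L,
                               n_sessions = 10L, session_len_s = 1200,
                               n_cells_per_pop = 50L, lfp_len_s = 120,
                               out_dir = NULL) {
  stopifnot(preset == "paper7")
  etho <- generate_ethogram(n_sessions, session_len_s,
                            seed = derive_seed(seed, 11))
  sim <- generate_population_spikes(etho, population_templates(),
                                    n_cells_per_pop,
                                    seed = derive_seed(seed, 12))
  out <- list(etho = etho, dataset = sim$dataset, truth = sim$truth)
  if (lfp_len_s > 0) {
    spec <- list(
      list(band_hz = c(30, 60), amplitude_sd = 4, duration_ms = 150,
           count = max(3L, round(lfp_len_s / 10)), label = "slow_gamma"),
      list(band_hz = c(61, 90), amplitude_sd = 4, duration_ms = 100,
           count = max(3L, round(lfp_len_s / 10)), label = "fast_gamma"))
    lf <- generate_lfp_with_events(lfp_len_s, 1250, spec,
                                   seed = derive_seed(seed, 13),
                                   session_id = out$dataset$session_spans$session_id[1L])
    out$lfp <- lf$lfp
    out$lfp_truth <- lf$truth
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spike_csv(out$dataset, file.path(out_dir, "spikes.csv"))
    write_ethogram_csv(out$etho, file.path(out_dir, "etho.csv"))
    if (!is.null(out$lfp)) write_lfp_flat(out$lfp, file.path(out_dir, "lfp.bin"))
    truth <- list(populations = out$truth,
                  lfp_events = lapply(out$lfp_truth, function(es) {
                    data.frame(label = es$label,
                               start_s = es$intervals[, 1L],
                               end_s = es$intervals[, 2L])
                  }))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  out
}
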