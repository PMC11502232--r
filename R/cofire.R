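# Epoch-conditioned cross-correlograms, cofiring probability, the
# cofiring ratio (CFR), its uniform-shift shuffle null, distribution
# summaries and population-pair group tests.

#' Epoch-conditioned cross-correlogram
#'
#' For each trigger spike inside `trigger_epochs`, response spikes (at any
#' time) are counted at 1 ms lag bins over a +/- `half_window_ms` window;
#' counts are normalized by the cumulative count so the bins sum to one.
#' Only the triggers are epoch-restricted (set `restrict_response = TRUE`
#' to restrict both trains).
#'
#' @param trigger,response spike time vectors (s) of two cells recorded on
#'   different shanks of the same session.
#' @param trigger_epochs an [epoch_set()] selecting the trigger spikes;
#'   `NULL` uses all trigger spikes.
#' @param bin_ms lag bin width (default 1 ms).
#' @param half_window_ms half window (default 50 ms).
#' @param restrict_response also restrict response spikes to the epochs.
#' @return A `ccg_result`: `lags` (bin centers, ms), `probs` (unit mass),
#'   `counts`, `n_trigger`, `epoch_label`, `defined`. With zero epoch
#'   triggers or zero coincidences `defined` is `FALSE` and the pair is
#'   excluded downstream.
#' @export
ccg <- function(trigger, response, trigger_epochs = NULL, bin_ms = 1,
                half_window_ms = 50, restrict_response = FALSE) {
  label <- NULL
  if (!is.null(trigger_epochs)) {
    label <- trigger_epochs$label
    trigger <- trigger[in_intervals(trigger, trigger_epochs$intervals)]
    if (restrict_response) {
      response <- response[in_intervals(response, trigger_epochs$intervals)]
    }
  }
  bin_s <- bin_ms / 1000
  half_s <- half_window_ms / 1000
  counts <- .ccg_counts(as.numeric(trigger), as.numeric(response), bin_s, half_s)
  J <- (length(counts) - 1L) %/% 2L
  total <- sum(counts)
  structure(list(
    lags = seq(-J, J) * bin_ms,
    probs = if (total > 0) counts / total else rep(NA_real_, length(counts)),
    counts = counts, n_trigger = length(trigger),
    epoch_label = label, bin_ms = bin_ms,
    defined = length(trigger) > 0L && total > 0),
    class = "ccg_result")
}

#' Cofiring probability from a CCG
#'
#' Mean of the normalized CCG bin values whose centers lie within
#' +/- `half_window_ms` of the trigger (default 15 ms).
#'
#' @param x a `ccg_result`.
#' @param half_window_ms averaging half window (ms).
#' @return Mean normalized bin probability.
#' @export
cofiring_probability <- function(x, half_window_ms = 15) {
  stopifnot(inherits(x, "ccg_result"))
  if (half_window_ms > max(x$lags)) {
    stop("cofiring window exceeds the CCG extent")
  }
  if (!x$defined) return(NA_real_)
  mean(x$probs[abs(x$lags) <= half_window_ms + 1e-9])
}

#' Cofiring ratio of a cell pair
#'
#' CFR = cofiring probability of the nonrhythmic-triggered CCG divided by
#' that of the gamma-triggered CCG; CFR < 1 indicates stronger cofiring
#' during gamma oscillations.
#'
#' @param trigger,response spike trains (s) of a cross-shank pair.
#' @param nonrhythmic,gamma [epoch_set()]s of the pair's session.
#' @param bin_ms,half_window_ms,cofire_half_window_ms CCG settings.
#' @return `list(cfr, p_nonrhythmic, p_gamma, defined, ...)` of class
#'   `cfr_result`; `defined = FALSE` (pair excluded) when either CCG is
#'   undefined or the gamma cofiring probability is zero.
#' @export
cofiring_ratio <- function(trigger, response, nonrhythmic, gamma,
                           bin_ms = 1, half_window_ms = 50,
                           cofire_half_window_ms = 15) {
  if (nrow(nonrhythmic$intervals) == 0L || nrow(gamma$intervals) == 0L) {
    stop("both epoch sets must be non-empty")
  }
  c_nr <- ccg(trigger, response, nonrhythmic, bin_ms, half_window_ms)
  c_g <- ccg(trigger, response, gamma, bin_ms, half_window_ms)
  p_nr <- if (c_nr$defined) cofiring_probability(c_nr, cofire_half_window_ms) else NA_real_
  p_g <- if (c_g$defined) cofiring_probability(c_g, cofire_half_window_ms) else NA_real_
  ok <- c_nr$defined && c_g$defined && !is.na(p_g) && p_g > 0
  structure(list(cfr = if (ok) p_nr / p_g else NA_real_,
                 p_nonrhythmic = p_nr, p_gamma = p_g,
                 ccg_nonrhythmic = c_nr, ccg_gamma = c_g,
                 defined = ok),
            class = "cfr_result")
}

# Cofire probability from (inside, total) window counts.
.cofire_from_counts <- function(ct, bin_ms, half_window_ms, cofire_half_ms) {
  if (ct[2L] == 0) return(NA_real_)
  n_in <- 2L * as.integer(round(cofire_half_ms / bin_ms)) + 1L
  (ct[1L] / ct[2L]) / n_in
}

#' Uniform-shift shuffle null for the CFR
#'
#' Each epoch-selected trigger spike is independently shifted by a
#' U(-25, 25) s draw (wrapped modulo the session span) and the
#' CCG / cofiring probabilities / CFR are recomputed against the intact
#' response train; repeated `n` times.
#'
#' @param trigger,response spike trains (s).
#' @param nonrhythmic,gamma [epoch_set()]s.
#' @param span session span `c(t0, t1)`; must be at least 50 s.
#' @param n number of shuffles (default 1000).
#' @param range_s shift range (default `c(-25, 25)`).
#' @param seed RNG seed.
#' @param bin_ms,half_window_ms,cofire_half_window_ms CCG settings.
#' @return `list(cfr, n, mean, p2.5, p50, p97.5)` of class `cfr_null`,
#'   where `cfr` holds the control CFR values (NA where undefined).
#' @export
shuffle_null <- function(trigger, response, nonrhythmic, gamma, span,
                         n = 1000L, range_s = c(-25, 25), seed = 1L,
                         bin_ms = 1, half_window_ms = 50,
                         cofire_half_window_ms = 15) {
  if (diff(span) < diff(range_s)) {
    stop("session shorter than the ", diff(range_s), " s shift range")
  }
  t0 <- span[1L]; L <- diff(span)
  trig_nr <- trigger[in_intervals(trigger, nonrhythmic$intervals)]
  trig_g <- trigger[in_intervals(trigger, gamma$intervals)]
  bin_s <- bin_ms / 1000; half_s <- half_window_ms / 1000
  cof_s <- cofire_half_window_ms / 1000
  set.seed(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s_nr <- t0 + (trig_nr - t0 + runif(length(trig_nr), range_s[1L], range_s[2L])) %% L
    s_g <- t0 + (trig_g - t0 + runif(length(trig_g), range_s[1L], range_s[2L])) %% L
    p_nr <- .cofire_from_counts(.cofire_counts(s_nr, response, bin_s, half_s, cof_s),
                                bin_ms, half_window_ms, cofire_half_window_ms)
    p_g <- .cofire_from_counts(.cofire_counts(s_g, response, bin_s, half_s, cof_s),
                               bin_ms, half_window_ms, cofire_half_window_ms)
    out[i] <- if (!is.na(p_g) && !is.na(p_nr) && p_g > 0) p_nr / p_g else NA_real_
  }
  ok <- out[!is.na(out)]
  structure(list(cfr = out, n = n,
                 mean = mean(ok),
                 p2.5 = unname(quantile(ok, 0.025)),
                 p50 = unname(quantile(ok, 0.5)),
                 p97.5 = unname(quantile(ok, 0.975))),
            class = "cfr_null")
}

#' Summaries of original vs shuffle-control CFR distributions
#'
#' Empirical CDFs of original and control CFR, the fraction of pairs with
#' CFR < 1 in each, paired t comparisons in the lower / upper 2.5% tails
#' and the middle 20% of the original-CFR ordering, and a two-sample KS
#' test between the distributions.
#'
#' @param cfrs original per-pair CFR values.
#' @param controls per-pair control CFR values (e.g. shuffle means),
#'   paired with `cfrs`.
#' @param min_pairs minimum pairs for the tail comparisons (default 40).
#' @return `list(ecdf_original, ecdf_control, frac_below_1,
#'   frac_below_1_control, tails, ks)`.
#' @export
cfr_distribution_summary <- function(cfrs, controls, min_pairs = 40L) {
  keep <- !is.na(cfrs) & !is.na(controls)
  cfrs <- cfrs[keep]; controls <- controls[keep]
  n <- length(cfrs)
  out <- list(ecdf_original = ecdf(cfrs), ecdf_control = ecdf(controls),
              frac_below_1 = mean(cfrs < 1),
              frac_below_1_control = mean(controls < 1),
              n = n)
  out$ks <- suppressWarnings(ks.test(cfrs, controls))
  if (n >= min_pairs) {
    ord <- order(cfrs)
    n_tail <- max(2L, floor(0.025 * n))
    n_mid <- max(2L, floor(0.2 * n))
    mid0 <- floor((n - n_mid) / 2) + 1L
    sets <- list(lower = ord[seq_len(n_tail)],
                 upper = ord[seq(n - n_tail + 1L, n)],
                 middle = ord[seq(mid0, mid0 + n_mid - 1L)])
    out$tails <- lapply(sets, function(ix) {
      tt <- t.test(cfrs[ix], controls[ix], paired = TRUE)
      list(n = length(ix), t = unname(tt$statistic), p = tt$p.value,
           mean_original = mean(cfrs[ix]), mean_control = mean(controls[ix]))
    })
  } else {
    out$tails <- NULL
  }
  out
}

#' Population-pair CFR table and group tests
#'
#' Groups pairs by ordered (trigger population, response population) and
#' band, and compares original vs control CFR per group: paired t when the
#' paired differences pass a Shapiro normality check at alpha = 0.05,
#' Wilcoxon signed-rank otherwise.
#'
#' @param cfr_table data.frame with columns `pop_a`, `pop_b`, `band`,
#'   `cfr`, `ctrl_mean` (one row per pair; see [run_pipeline()] for the
#'   canonical CSV dialect).
#' @param min_pairs minimum valid pairs per reported group (default 2;
#'   smaller groups are reported as missing).
#' @param alpha group-test alpha (default 0.05).
#' @return data.frame with one row per (band, pop_a, pop_b) group:
#'   `n_pairs`, `median_cfr`, `median_ctrl`, `test`, `statistic`, `p`,
#'   `significant`.
#' @export
population_pair_assembly <- function(cfr_table, min_pairs = 2L, alpha = 0.05) {
  need <- c("pop_a", "pop_b", "band", "cfr", "ctrl_mean")
  stopifnot(all(need %in% names(cfr_table)))
  tab <- cfr_table[!is.na(cfr_table$cfr) & !is.na(cfr_table$ctrl_mean), ,
                   drop = FALSE]
  key <- interaction(tab$band, tab$pop_a, tab$pop_b, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    g <- tab[key == kk, , drop = FALSE]
    base <- data.frame(band = g$band[1L], pop_a = g$pop_a[1L],
                       pop_b = g$pop_b[1L], n_pairs = nrow(g),
                       median_cfr = median(g$cfr),
                       median_ctrl = median(g$ctrl_mean),
                       stringsAsFactors = FALSE)
    d <- g$cfr - g$ctrl_mean
    if (nrow(g) < max(min_pairs, 3L) || sd(d) == 0) {
      base$test <- NA_character_; base$statistic <- NA_real_
      base$p <- NA_real_; base$significant <- NA
      return(base)
    }
    normal <- tryCatch(shapiro.test(d)$p.value > 0.05, error = function(e) FALSE)
    if (normal) {
      tt <- t.test(g$cfr, g$ctrl_mean, paired = TRUE)
      base$test <- "paired_t"; base$statistic <- unname(tt$statistic)
      base$p <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(g$cfr, g$ctrl_mean, paired = TRUE,
                                         exact = FALSE))
      base$test <- "wilcoxon"; base$statistic <- unname(wt$statistic)
      base$p <- wt$p.value
    }
    base$significant <- base$p < alpha
    base
  })
  do.call(rbind, rows)
}
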