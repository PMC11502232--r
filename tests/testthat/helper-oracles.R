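# Independent oracles and small fixture builders used across the suite.

# Brute-force ARI by explicit pair counting over all C(n, 2) pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (abs(max_idx - exp_idx) < 1e-14 * max(1, max_idx)) {
    return(if (abs(s11 - max_idx) < 1e-12) 1 else 0)
  }
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# AMI oracle: direct MI / entropies plus expected MI via dhyper().
oracle_ami <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hu <- h(ai / n); hv <- h(bj / n)
  if (hu == 0 && hv == 0) return(1)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    if (tab[i, j] > 0) mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (ai[i] * bj[j]))
  }
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
    if (hi < lo) next
    for (nij in lo:hi) {
      p <- stats::dhyper(nij, ai[i], n - ai[i], bj[j])
      emi <- emi + p * nij / n * log(n * nij / (ai[i] * bj[j]))
    }
  }
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  unname((mi - emi) / denom)
}

# Nested-loop CCG counter (lag bins centred at multiples of bin).
oracle_ccg <- function(trigger, response, bin_s, half_s) {
  J <- round(half_s / bin_s)
  counts <- integer(2 * J + 1)
  for (t in trigger) for (s in response) {
    j <- round((s - t) / bin_s)
    if (abs(j) <= J) counts[j + J + 1] <- counts[j + J + 1] + 1L
  }
  counts
}

# Alternating planted gamma-burst / nonrhythmic epoch tiling (no LFP),
# for CFR calibration fixtures.
make_epoch_tiling <- function(session_len_s, seed = 1L) {
  set.seed(seed)
  t <- 5; g <- NULL; nr <- NULL
  while (t < session_len_s - 5) {
    g <- rbind(g, c(t, t + runif(1, 0.1, 0.3)))
    t <- t + 0.5
    nr <- rbind(nr, c(t, t + runif(1, 0.5, 1.5)))
    t <- nr[nrow(nr), 2] + 0.5
  }
  list(gamma = epoch_set("slow_gamma", g),
       nonrhythmic = epoch_set("nonrhythmic", nr))
}

# Homogeneous Poisson train on [0, T).
poisson_train <- function(rate_hz, len_s) {
  sort(runif(rpois(1, rate_hz * len_s), 0, len_s))
}

# Interval recall / precision with >= 50% overlap-of-truth matching.
interval_recall_precision <- function(detected, truth) {
  d <- detected$intervals; tr <- truth$intervals
  hit_t <- vapply(seq_len(nrow(tr)), function(i) {
    ov <- pmax(0, pmin(tr[i, 2], d[, 2]) - pmax(tr[i, 1], d[, 1]))
    any(ov >= 0.5 * (tr[i, 2] - tr[i, 1]))
  }, logical(1))
  hit_d <- if (nrow(d)) vapply(seq_len(nrow(d)), function(i) {
    ov <- pmax(0, pmin(d[i, 2], tr[, 2]) - pmax(d[i, 1], tr[, 1]))
    any(ov >= 0.5 * (tr[, 2] - tr[, 1]))
  }, logical(1)) else logical(0)
  c(recall = mean(hit_t), precision = mean(hit_d))
}

# Tiny two-session recording with three planted templates, for fast
# io / pipeline tests.
make_tiny_recording <- function(seed = 1L, n_cells_per_pop = 6L,
                                n_sessions = 2L, session_len_s = 400) {
  etho <- generate_ethogram(n_sessions, session_len_s, seed = seed)
  tpl <- population_templates()[c("FOn", "Sol", "Exp")]
  sim <- generate_population_spikes(etho, tpl, n_cells_per_pop, seed = seed + 1L)
  list(etho = etho, dataset = sim$dataset, truth = sim$truth)
}
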