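test_that("ethogram generator is deterministic and respects durations", {
  e1 <- generate_ethogram(3, 600, seed = 11)
  e2 <- generate_ethogram(3, 600, seed = 11)
  expect_identical(e1$episodes, e2$episodes)
  expect_error(generate_ethogram(1, 100, seed = 1), "300")

  big <- generate_ethogram(10, 1200, seed = 12)
  fe <- big$episodes[big$episodes$behavior == "feeding", ]
  expect_true(all(fe$end_s - fe$start_s >= 4.8))

  # Monte-Carlo check of the duration sampler: pooled feeding median
  # within 10% of the configured 22 s
  durs <- unlist(lapply(1:12, function(s) {
    e <- generate_ethogram(10, 1200, seed = 100 + s)
    f <- e$episodes[e$episodes$behavior == "feeding", ]
    f$end_s - f$start_s
  }))
  expect_gt(length(durs), 1000)
  expect_lt(abs(median(durs) - 22) / 22, 0.10)
  # feeding bouts are several-fold longer than the other behaviors
  od <- unlist(lapply(1:3, function(s) {
    e <- generate_ethogram(10, 1200, seed = 100 + s)
    o <- e$episodes[e$episodes$behavior != "feeding", ]
    o$end_s - o$start_s
  }))
  expect_gt(median(durs) / median(od), 4)
})

test_that("population spike generator plants the advertised structure", {
  etho <- generate_ethogram(2, 600, seed = 21)
  # amplitude-0 tuning -> homogeneous Poisson with the right count
  flat <- list(make_template("flat", 4))
  sim <- generate_population_spikes(etho, flat, 12, seed = 3)
  counts <- lengths(sim$dataset$spikes)
  expect_true(all(abs(counts - 4 * 600) <= 4 * sqrt(4 * 600)))

  tpl <- population_templates()
  sim7 <- generate_population_spikes(etho, tpl[c("FOn", "Sol")], 10, seed = 5)
  ds <- sim7$dataset
  # Sol cells: social rate exceeds feeding rate in >= 95% of cells
  soc_gt_feed <- vapply(which(sim7$truth$population == "Sol"), function(i) {
    sid <- ds$cells$session_id[i]
    s <- ds$spikes[[i]]
    fe <- etho$episodes[etho$episodes$session_id == sid, ]
    rate_in <- function(beh) {
      iv <- fe[fe$behavior == beh, c("start_s", "end_s")]
      sum(vapply(seq_len(nrow(iv)), function(r)
        sum(s >= iv[r, 1] & s < iv[r, 2]), numeric(1))) /
        sum(iv[, 2] - iv[, 1])
    }
    rate_in("social") > rate_in("feeding")
  }, logical(1))
  expect_gte(mean(soc_gt_feed), 0.95)

  # FOn cells: median warped peak phase in the first 20% of feeding
  cfg <- pipeline_config()
  fm <- build_feature_matrix(ds, etho, cfg)
  fon <- sim7$truth$population[match(paste(fm$cells$session_id, fm$cells$cell_id),
                                     paste(sim7$truth$session_id, sim7$truth$cell_id))] == "FOn"
  ph <- (max.col(fm$behavior_vectors$feeding, ties.method = "first") - 0.5) /
    ncol(fm$behavior_vectors$feeding)
  expect_lt(median(ph[fon]), 0.20)

  # cells are spread over >= 2 shanks and generation is pure in the seed
  expect_gte(length(unique(ds$cells$shank_id)), 2L)
  sim7b <- generate_population_spikes(etho, tpl[c("FOn", "Sol")], 10, seed = 5)
  expect_identical(sim7b$dataset$spikes, ds$spikes)
})

test_that("LFP generator plants band-limited bursts with exact truth", {
  pure <- generate_lfp_with_events(60, 1250, list(), seed = 2)
  expect_length(pure$truth, 0L)
  expect_equal(length(pure$lfp$samples), 60 * 1250)

  one <- generate_lfp_with_events(
    60, 1250, list(list(band_hz = c(30, 60), amplitude_sd = 5,
                        duration_ms = 100, count = 1, label = "slow")),
    seed = 3)
  tr <- one$truth$slow$intervals
  expect_equal(nrow(tr), 1L)
  expect_equal(tr[1, 2] - tr[1, 1], 0.1, tolerance = 1e-9, ignore_attr = TRUE)

  # in-band power inside planted intervals exceeds outside power
  many <- generate_lfp_with_events(
    120, 1250, list(list(band_hz = c(30, 60), amplitude_sd = 5,
                         duration_ms = 150, count = 10, label = "slow")),
    seed = 4)
  bp <- band_envelope(many$lfp, c(30, 60))
  tt <- (seq_along(bp$envelope) - 1) / 1250
  inside <- lhensemble:::in_intervals(tt, many$truth$slow$intervals)
  expect_gt(mean(bp$envelope[inside]^2), 3 * mean(bp$envelope[!inside]^2))
})

test_that("pair coupling inserts epoch-locked synchrony only", {
  tiny <- make_tiny_recording(seed = 31L)
  ds <- tiny$dataset
  sel <- which(ds$cells$session_id == ds$cells$session_id[1])
  a <- sel[1]; b <- sel[which(ds$cells$shank_id[sel] != ds$cells$shank_id[a])[1]]
  pairs <- data.frame(cell_a = ds$cells$cell_id[a], cell_b = ds$cells$cell_id[b])
  ep <- epoch_set("slow_gamma", cbind(seq(10, 300, 10), seq(10, 300, 10) + 0.4),
                  session_id = ds$cells$session_id[a])

  # zero excess rate: dataset unchanged
  same <- couple_pairs_to_events(tiny, ep, pairs, 0, 5, seed = 1)
  expect_identical(same$dataset$spikes, ds$spikes)

  # empty epochs: warning + no-op
  empty <- epoch_set("slow_gamma", NULL, session_id = ds$cells$session_id[a])
  expect_warning(res <- couple_pairs_to_events(tiny, empty, pairs, 2, 5, seed = 1),
                 "empty epoch")
  expect_identical(res$dataset$spikes, ds$spikes)

  # coupled pair: epoch-triggered CCG mass concentrates within the jitter
  cp <- couple_pairs_to_events(tiny, ep, pairs, 3, 5, seed = 2)
  ia <- match(pairs$cell_a, cp$dataset$cells$cell_id)
  ib <- match(pairs$cell_b, cp$dataset$cells$cell_id)
  cc <- ccg(cp$dataset$spikes[[ia]], cp$dataset$spikes[[ib]], ep)
  inwin <- abs(cc$lags) <= 5
  # mass concentrates in the jitter window far beyond the uniform share
  expect_gt(sum(cc$probs[inwin]), 3 * sum(inwin) / length(cc$lags))
  # original spikes all preserved
  expect_true(all(ds$spikes[[ia]] %in% cp$dataset$spikes[[ia]]))

  # pairs on the same shank are rejected
  c2 <- sel[which(ds$cells$shank_id[sel] == ds$cells$shank_id[a])[2]]
  bad <- data.frame(cell_a = ds$cells$cell_id[a], cell_b = ds$cells$cell_id[c2])
  expect_error(couple_pairs_to_events(tiny, ep, bad, 2, 5, seed = 1), "shank")
})

test_that("generated ground truth always satisfies the container invariants", {
  for (seed in 1:3) {
    tiny <- make_tiny_recording(seed = seed)
    expect_s3_class(tiny$dataset, "spike_dataset")  # constructor validates
    expect_s3_class(tiny$etho, "ethogram")
    expect_true(all(tiny$truth$cell_id %in% tiny$dataset$cells$cell_id))
  }
})
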