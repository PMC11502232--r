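test_that("CCG places a shifted copy of the trigger at the right lag", {
  trig <- seq(10, 100, by = 1)
  resp <- trig + 0.005
  ep <- epoch_set("slow_gamma", rbind(c(0, 200)))
  cc <- ccg(trig, resp, ep)
  expect_equal(cc$probs[cc$lags == 5], 1)
  expect_equal(sum(cc$probs), 1)
  expect_equal(cc$n_trigger, length(trig))
  expect_equal(cc$epoch_label, "slow_gamma")
  expect_equal(range(cc$lags), c(-50, 50))

  # zero triggers in epochs -> undefined, flagged
  far <- epoch_set("slow_gamma", rbind(c(150, 160)))
  expect_false(ccg(trig, resp, far)$defined)
})

test_that("CCG equals nested-loop counting on random small instances", {
  set.seed(15)
  for (i in 1:50) {
    nt <- sample(5:100, 1); nr <- sample(5:100, 1)
    trig <- sort(runif(nt, 0, 30)); resp <- sort(runif(nr, 0, 30))
    cc <- ccg(trig, resp, NULL)
    expect_identical(as.integer(cc$counts),
                     oracle_ccg(trig, resp, 0.001, 0.05))
    if (cc$defined) expect_equal(sum(cc$probs), 1, tolerance = 1e-12)
  }
})

test_that("independent Poisson pairs give a flat CCG", {
  set.seed(16)
  trig <- poisson_train(5, 1800); resp <- poisson_train(5, 1800)
  cc <- ccg(trig, resp, NULL)
  expect_lte(max(cc$probs), 3 * mean(cc$probs))
})

test_that("cofiring probability is the mean normalized bin value in the window", {
  flat <- structure(list(lags = seq(-50, 50), probs = rep(1 / 101, 101),
                         counts = rep(1L, 101), n_trigger = 100L,
                         epoch_label = NULL, bin_ms = 1, defined = TRUE),
                    class = "ccg_result")
  expect_equal(cofiring_probability(flat), 1 / 101)

  spike0 <- flat
  spike0$probs <- c(numeric(50), 1, numeric(50))
  expect_equal(cofiring_probability(spike0), 1 / 31)   # 31 one-ms bins in +/-15

  # moving mass from outside to inside the window strictly increases it
  shifted <- flat
  shifted$probs <- c(numeric(10), rep(1 / 91, 91))
  expect_gt(cofiring_probability(shifted), cofiring_probability(flat))

  expect_error(cofiring_probability(flat, 60), "extent")
})

test_that("CFR is exactly 1 under epoch label exchange and < 1 for coupling", {
  set.seed(17)
  trig <- poisson_train(5, 600); resp <- poisson_train(5, 600)
  iv <- cbind(seq(5, 500, 5), seq(5, 500, 5) + 2)
  a <- epoch_set("nonrhythmic", iv)
  b <- epoch_set("slow_gamma", iv)  # identical intervals, label swapped
  r <- cofiring_ratio(trig, resp, a, b)
  expect_equal(r$cfr, 1)

  ep <- make_epoch_tiling(1200, seed = 18)
  trig2 <- poisson_train(5, 1200); resp2 <- poisson_train(5, 1200)
  giv <- ep$gamma$intervals
  ins <- runif(300, 0, lhensemble:::interval_total(giv))
  # place synchronous events inside gamma epochs only
  cum <- cumsum(giv[, 2] - giv[, 1])
  seg <- findInterval(ins, c(0, cum[-length(cum)] + 1e-12)) ; seg[seg == 0] <- 1
  tA <- giv[seg, 1] + (ins - c(0, cum)[seg])
  trig2 <- sort(c(trig2, tA)); resp2 <- sort(c(resp2, tA + runif(300, -0.004, 0.004)))
  r2 <- cofiring_ratio(trig2, resp2, ep$nonrhythmic, ep$gamma)
  expect_lt(r2$cfr, 1)

  expect_error(cofiring_ratio(trig, resp, epoch_set("nonrhythmic", NULL), b),
               "non-empty")
})

test_that("shuffle null is deterministic and brackets planted coupling", {
  ep <- make_epoch_tiling(1200, seed = 19)
  set.seed(20)
  trig <- poisson_train(5, 1200); resp <- poisson_train(5, 1200)
  n1 <- shuffle_null(trig, resp, ep$nonrhythmic, ep$gamma, c(0, 1200),
                     n = 50, seed = 4)
  n2 <- shuffle_null(trig, resp, ep$nonrhythmic, ep$gamma, c(0, 1200),
                     n = 50, seed = 4)
  expect_identical(n1$cfr, n2$cfr)
  expect_equal(n1$mean, 1, tolerance = 0.15)

  expect_error(shuffle_null(trig, resp, ep$nonrhythmic, ep$gamma, c(0, 40),
                            n = 10, seed = 1), "shorter")

  # planted gamma coupling: original CFR below the 2.5th control percentile
  giv <- ep$gamma$intervals
  k <- 400
  seg <- sample.int(nrow(giv), k, replace = TRUE, prob = giv[, 2] - giv[, 1])
  tA <- runif(k, giv[seg, 1], giv[seg, 2])
  trig2 <- sort(c(trig, tA)); resp2 <- sort(c(resp, tA + runif(k, -0.005, 0.005)))
  r <- cofiring_ratio(trig2, resp2, ep$nonrhythmic, ep$gamma)
  nul <- shuffle_null(trig2, resp2, ep$nonrhythmic, ep$gamma, c(0, 1200),
                      n = 200, seed = 5)
  expect_lt(r$cfr, nul$p2.5)
})

test_that("distribution summary is calibrated under self-comparison", {
  set.seed(21)
  ctrl <- rlnorm(200, 0, 0.2)
  s <- cfr_distribution_summary(ctrl, ctrl + rnorm(200, sd = 1e-12))
  expect_lt(s$ks$statistic, 0.05)
  expect_equal(s$frac_below_1, s$frac_below_1_control)
  ec <- s$ecdf_original
  q <- ec(seq(0, 3, 0.1))
  expect_true(all(diff(q) >= 0))
  expect_true(all(q >= 0 & q <= 1))
  expect_named(s$tails, c("lower", "upper", "middle"))

  # a planted gamma-coupled mixture shifts mass below 1
  orig <- c(rlnorm(140, 0, 0.2), rlnorm(60, log(0.6), 0.1))
  ctrl2 <- rlnorm(200, 0, 0.2)
  s2 <- cfr_distribution_summary(orig, ctrl2)
  expect_gt(s2$frac_below_1, s2$frac_below_1_control)

  # too few pairs: tails skipped
  s3 <- cfr_distribution_summary(rlnorm(10), rlnorm(10))
  expect_null(s3$tails)
})

test_that("population-pair table is ordered and gated by group size", {
  set.seed(22)
  tab <- data.frame(
    pop_a = rep(c("FOn", "EF"), each = 10),
    pop_b = rep(c("EF", "FOn"), each = 10),
    band = "slow_gamma",
    cfr = c(rlnorm(10, log(0.7), 0.1), rlnorm(10, 0, 0.1)),
    ctrl_mean = rlnorm(20, 0, 0.02))
  out <- population_pair_assembly(tab)
  expect_equal(nrow(out), 2L)
  # ordered table: FOn->EF differs from EF->FOn
  fe <- out[out$pop_a == "FOn", ]; ef <- out[out$pop_a == "EF", ]
  expect_true(fe$significant)
  expect_lt(fe$median_cfr, 1)
  expect_false(isTRUE(ef$significant && ef$median_cfr < 0.9))

  tab2 <- rbind(tab, data.frame(pop_a = "LF", pop_b = "Sol", band = "slow_gamma",
                                cfr = 0.8, ctrl_mean = 1))
  out2 <- population_pair_assembly(tab2)
  expect_true(is.na(out2$p[out2$pop_a == "LF"]))
})
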