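test_that("k-NN cosine graph has the advertised structure", {
  set.seed(1)
  # two antipodal tight groups: cosine distance separates them perfectly
  X <- rbind(matrix(rnorm(10 * 3, mean = 5, sd = 0.1), 10),
             -matrix(rnorm(10 * 3, mean = 5, sd = 0.1), 10))
  A <- knn_cosine_graph(X, 3)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) == 0))
  expect_equal(sum(A[1:10, 11:20]), 0)  # no cross-group edges

  A2 <- knn_cosine_graph(X, nrow(X) - 1L)
  expect_true(all(A2[upper.tri(A2)] == 1))  # complete graph

  expect_error(knn_cosine_graph(X, nrow(X)), "smaller")
  expect_error(knn_cosine_graph(rbind(X, 0), 3), "zero feature vector")
})

test_that("spectral clustering recovers ideal block structure", {
  A <- matrix(0, 30, 30)
  A[1:15, 1:15] <- 1; A[16:30, 16:30] <- 1; diag(A) <- 0
  sol <- suppressMessages(spectral_cluster(A, 2, seed = 1))
  expect_equal(partition_agreement(sol$labels, rep(1:2, c(15, 15)))$ari, 1)
  expect_equal(sort(unique(sol$labels)), 1:2)

  expect_equal(spectral_cluster(A, 1)$labels, rep(1L, 30))
  expect_error(spectral_cluster(A, 31), "exceeds")

  # three blocks
  B <- matrix(0, 30, 30)
  for (b in 0:2) B[b * 10 + 1:10, b * 10 + 1:10] <- 1
  diag(B) <- 0
  sol3 <- suppressMessages(spectral_cluster(B, 3, seed = 2))
  expect_equal(partition_agreement(sol3$labels, rep(1:3, each = 10))$ari, 1)
})

test_that("ARI and AMI match independent oracles and chance-correct", {
  pa <- partition_agreement(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(pa$ari, 1)
  expect_equal(pa$ami, 1)

  # all one cluster vs non-trivial labels -> ari 0 by chance correction
  expect_equal(partition_agreement(c(1, 1, 2, 2, 3, 3), rep(1, 6))$ari, 0)

  # the 6-item worked case against the brute-force oracle
  a <- c(0, 0, 1, 1, 2, 2); b <- c(0, 0, 0, 1, 1, 1)
  pa <- partition_agreement(a, b)
  expect_equal(pa$ari, oracle_ari(a, b), tolerance = 1e-14)
  expect_equal(pa$ami, oracle_ami(a, b), tolerance = 1e-14)

  expect_error(partition_agreement(1:3, 1:4), "mismatch")

  # property: symmetry and label-permutation invariance, random cases
  set.seed(7)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    a <- sample(1:sample(2:5, 1), n, replace = TRUE)
    b <- sample(1:sample(2:5, 1), n, replace = TRUE)
    p1 <- partition_agreement(a, b)
    p2 <- partition_agreement(b, a)
    expect_equal(p1$ari, p2$ari, tolerance = 1e-12)
    expect_equal(p1$ami, p2$ami, tolerance = 1e-12)
    perm <- sample(max(a))
    p3 <- partition_agreement(perm[a], b)
    expect_equal(p1$ari, p3$ari, tolerance = 1e-12)
    expect_equal(p1$ami, p3$ami, tolerance = 1e-12)
    # independent ARI cross-check from another package
    expect_equal(p1$ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("stability scan prefers planted structure over noise", {
  set.seed(11)
  blobs <- rbind(matrix(rnorm(20 * 4, 0, 0.3), 20) + matrix(c(3, 0, 0, 0), 20, 4, byrow = TRUE),
                 matrix(rnorm(20 * 4, 0, 0.3), 20) + matrix(c(0, 3, 0, 0), 20, 4, byrow = TRUE),
                 matrix(rnorm(20 * 4, 0, 0.3), 20) + matrix(c(0, 0, 3, 0), 20, 4, byrow = TRUE))
  rep_b <- suppressMessages(suppressWarnings(
    stability_scan(blobs, 2:5, c(5, 10), n_boot = 20, seed = 3)))
  g <- rep_b$grid
  # ari_mean is maximal at the planted k = 3 (ties allowed)
  expect_gte(max(g$ari_mean[g$k == 3]), max(g$ari_mean) - 1e-9)

  noise <- matrix(rnorm(60 * 4), 60)
  rep_n <- suppressMessages(suppressWarnings(
    stability_scan(noise, 2:5, c(5, 10), n_boot = 20, seed = 3)))
  expect_gt(max(g$ari_mean), max(rep_n$grid$ari_mean))

  # determinism under a fixed seed
  rep_b2 <- suppressMessages(suppressWarnings(
    stability_scan(blobs, 2:5, c(5, 10), n_boot = 20, seed = 3)))
  expect_identical(rep_b$grid, rep_b2$grid)

  expect_error(stability_scan(blobs, 2:5, c(5), n_boot = 1), "n_boot")
  expect_error(stability_scan(blobs, integer(0), c(5)), "empty")
})

test_that("parameter selection maximizes both criteria with tie-breaks", {
  grid <- expand.grid(k = c(2, 3), knn = c(5, 10))
  grid$ari_mean <- c(0.5, 0.9, 0.5, 0.7)
  grid$ari_sd <- c(0.1, 0.05, 0.1, 0.05)
  grid$ami_mean <- grid$ari_mean
  grid$ami_sd <- grid$ari_sd
  grid$n_boot <- 10
  sel <- select_parameters(grid)
  expect_equal(sel$by_mean, list(k = 3, knn = 5))
  expect_equal(sel$by_mean_over_sd, list(k = 3, knn = 5))

  # exact tie -> smallest k, then smallest knn
  grid$ari_mean <- 0.8; grid$ami_mean <- 0.8
  grid$ari_sd <- 0.1; grid$ami_sd <- 0.1
  sel2 <- select_parameters(grid)
  expect_equal(sel2$by_mean, list(k = 2, knn = 5))

  # perfectly stable cell (sd = 0, mean > 0) dominates the ratio criterion
  grid$ari_sd[2] <- 0; grid$ami_sd[2] <- 0
  sel3 <- select_parameters(grid)
  expect_equal(sel3$by_mean_over_sd, list(k = 3, knn = 5))
})

test_that("cluster quality matches a brute-force all-pairs computation", {
  set.seed(21)
  # clusters of identical vectors -> intra = 1
  X <- rbind(matrix(rep(rnorm(5), each = 10), 10),
             matrix(rep(rnorm(5), each = 10), 10))
  labels <- rep(1:2, each = 10)
  q <- cluster_quality(X + rnorm(100, sd = 1e-8), labels)
  expect_gt(q$intra, 0.999)

  # oracle equivalence on 20 cells
  X2 <- matrix(rnorm(20 * 5), 20)
  lab2 <- sample(1:3, 20, replace = TRUE)
  while (min(table(lab2)) < 2) lab2 <- sample(1:3, 20, replace = TRUE)
  q2 <- cluster_quality(X2, lab2)
  intra <- c(); inter <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    r <- cor(X2[i, ], X2[j, ])
    if (lab2[i] == lab2[j]) intra <- c(intra, r) else inter <- c(inter, r)
  }
  expect_equal(q2$intra, mean(intra), tolerance = 1e-12)
  expect_equal(q2$inter, mean(inter), tolerance = 1e-12)
  expect_equal(q2$ratio, mean(intra) / mean(inter), tolerance = 1e-12)

  # random labels on exchangeable data: intra ~ inter
  set.seed(22)
  ratios <- replicate(30, {
    X3 <- matrix(rnorm(30 * 5), 30)
    cluster_quality(X3, sample(1:3, 30, replace = TRUE))$intra
  })
  expect_lt(abs(mean(ratios)), 0.1)
})

test_that("silhouette filter retains consistent cells and drops ambiguous ones", {
  set.seed(31)
  blob1 <- matrix(rnorm(15 * 4, sd = 0.15), 15) + matrix(c(3, 0, 0, 0), 15, 4, byrow = TRUE)
  blob2 <- matrix(rnorm(15 * 4, sd = 0.15), 15) + matrix(c(0, 3, 0, 0), 15, 4, byrow = TRUE)
  mid <- matrix(c(1.5, 1.5, 0, 0), 1, 4)  # exactly between the centroids
  X <- rbind(blob1, blob2, mid)
  sf <- suppressMessages(silhouette_filter(X, 2, 5, n_iter = 30, min_pass = 28, seed = 2))
  expect_true(all(sf$retained[1:30]))
  expect_false(sf$retained[31])
  expect_lte(sf$pass_counts[31], 5)
  expect_error(silhouette_filter(X, 2, 5, n_iter = 10, min_pass = 11), "min_pass")
})

test_that("per-sample silhouette matches a hand computation", {
  # 4 points on a line, clusters {1,2} and {3,4}
  x <- c(0, 1, 10, 12)
  D <- abs(outer(x, x, "-"))
  lab <- c(1, 1, 2, 2)
  s <- lhensemble:::.silhouette_scores(D, lab)
  # point 1: a = 1, b = mean(10, 12) = 11, s = (11-1)/11
  expect_equal(s[1], 10 / 11, tolerance = 1e-12)
  # point 3: a = 2, b = mean(10, 9) = 9.5, s = (9.5-2)/9.5
  expect_equal(s[3], 7.5 / 9.5, tolerance = 1e-12)
})
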