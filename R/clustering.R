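# Spectral clustering with bootstrap stability selection, agreement
# metrics, quality measures and silhouette-consistency filtering.

# --- cosine geometry -------------------------------------------------------

.row_normalize <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero feature vector: cosine distance undefined")
  X / nrm
}

.cosine_sim <- function(X) {
  Xn <- .row_normalize(X)
  S <- Xn %*% t(Xn)
  diag(S) <- 1
  pmin(pmax(S, -1), 1)
}

# Mutual-or k-NN binary graph from a similarity matrix.
.graph_from_sim <- function(S, knn) {
  n <- nrow(S)
  if (knn >= n) stop("knn must be smaller than the number of cells")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]; s[i] <- -Inf
    nb <- order(s, decreasing = TRUE)[seq_len(knn)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))  # edge if i in knn(j) OR j in knn(i)
  diag(A) <- 0
  A
}

#' k-nearest-neighbor cosine affinity graph
#'
#' Binary symmetric affinity: an edge joins `i` and `j` iff `j` is among
#' the `knn` nearest neighbors of `i` by cosine distance or vice versa.
#'
#' @param features cells x m feature matrix (rows must be nonzero).
#' @param knn number of nearest neighbors, `< nrow(features)`.
#' @return Symmetric binary matrix with zero diagonal.
#' @export
knn_cosine_graph <- function(features, knn) {
  .graph_from_sim(.cosine_sim(as.matrix(features)), knn)
}

# Connected components of a binary adjacency matrix (BFS).
.n_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  cur
}

# Spectral embedding: top-kmax eigenvectors of D^-1/2 A D^-1/2.
# Disconnected graphs get a tiny uniform regularization edge (1e-8).
.spectral_embed <- function(A, kmax) {
  if (.n_components(A) > 1L) {
    message("affinity graph disconnected; adding 1e-8 regularization edges")
    A <- A + 1e-8
    diag(A) <- 0
  }
  d <- rowSums(A)
  Dm <- 1 / sqrt(d)
  M <- A * tcrossprod(Dm)
  e <- eigen(M, symmetric = TRUE)
  e$vectors[, seq_len(kmax), drop = FALSE]
}

# kmeans++-style greedy initialization, then Lloyd iterations; 10 restarts
# with derived seeds for reproducibility.
.kmeanspp <- function(X, k, seed, restarts = 10L) {
  n <- nrow(X)
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, 101L, r))
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    d2 <- rowSums((X - matrix(X[centers[1L], ], n, ncol(X), byrow = TRUE))^2)
    if (k > 1L) for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1L, prob = p)
      dj <- rowSums((X - matrix(X[centers[j], ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
    init <- X[centers, , drop = FALSE]
    init <- init + matrix(rnorm(length(init), sd = 1e-10), nrow = k)
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = init, iter.max = 100L,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km) || any(km$size == 0L)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed to produce non-empty clusters")
  best$cluster
}

# Cluster a precomputed embedding (first k columns, row-normalized).
.cluster_embedding <- function(U, k, seed) {
  if (k == 1L) return(rep(1L, nrow(U)))
  E <- U[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(E^2))
  nrm[nrm == 0] <- 1
  .kmeanspp(E / nrm, k, seed)
}

#' Spectral clustering of an affinity graph
#'
#' Embeds cells via the leading `k` eigenvectors of the symmetric
#' normalized graph Laplacian, row-normalizes the embedding, and clusters
#' it with seeded k-means (greedy ++-style initialization, 10 restarts).
#'
#' @param affinity symmetric affinity matrix (e.g. [knn_cosine_graph()]).
#' @param k number of clusters (`<= nrow(affinity)`).
#' @param seed RNG seed for k-means.
#' @return `list(labels, k, seed)` of class `cluster_solution`; labels are
#'   integers in `1..k`, every label used.
#' @export
spectral_cluster <- function(affinity, k, seed = 1L) {
  n <- nrow(affinity)
  if (k > n) stop("parameter error: k exceeds the number of cells")
  labels <- if (k == 1L) rep(1L, n) else {
    U <- .spectral_embed(affinity, k)
    .cluster_embedding(U, k, seed)
  }
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cluster_solution")
}

# --- partition agreement ---------------------------------------------------

.ari_from_table <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(a, 2)); sb <- sum(choose(b, 2))
  stot <- choose(n, 2)
  if (stot == 0) return(1)
  expected <- sa * sb / stot
  maxi <- (sa + sb) / 2
  if (abs(maxi - expected) < .Machine$double.eps * max(1, maxi)) {
    return(if (sij == maxi) 1 else 0)
  }
  (sij - expected) / (maxi - expected)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Expected mutual information under the hypergeometric (permutation) model.
.expected_mi <- function(a, b, n) {
  s <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n); hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    lp <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
      lgamma(n - bj + 1) - lgamma(n + 1) - lgamma(nij + 1) -
      lgamma(ai - nij + 1) - lgamma(bj - nij + 1) -
      lgamma(n - ai - bj + nij + 1)
    s <- s + sum(exp(lp) * nij / n * log(n * nij / (ai * bj)))
  }
  s
}

.ami_from_table <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  hu <- .entropy(a / n); hv <- .entropy(b / n)
  if (hu == 0 && hv == 0) return(1)  # both single-cluster partitions
  nz <- tab[tab > 0]
  ri <- rowSums(tab); ci <- colSums(tab)
  mi <- 0
  for (i in seq_along(ri)) for (j in seq_along(ci)) {
    if (tab[i, j] > 0) {
      mi <- mi + tab[i, j] / n * log(n * tab[i, j] / (ri[i] * ci[j]))
    }
  }
  emi <- .expected_mi(a, b, n)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < 1e-15) return(0)
  (mi - emi) / denom
}

#' Adjusted Rand index and adjusted mutual information
#'
#' Chance-corrected agreement between two partitions of the same cells:
#' ARI from the pair-counting contingency table, AMI with the
#' hypergeometric expected-MI correction (arithmetic-mean normalization).
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return `list(ari, ami)`.
#' @export
partition_agreement <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label length mismatch")
  tab <- table(labels_a, labels_b)
  list(ari = unname(.ari_from_table(tab)), ami = unname(.ami_from_table(tab)))
}

#' Bootstrap stability scan over (k, knn) combinations
#'
#' For each grid cell the full data are clustered once (the reference);
#' each of `n_boot` bootstraps then clusters a random `frac` subsample
#' (without replacement) and scores ARI and AMI against the reference
#' restricted to the subsampled cells. The same subsamples are shared
#' across the grid.
#'
#' @param features cells x m reduced feature matrix.
#' @param k_range,knn_range grids of cluster counts and k-NN values.
#' @param n_boot bootstrap iterations (>= 2).
#' @param frac subsample fraction.
#' @param seed RNG seed.
#' @return A `stability_report`: `grid` data.frame with
#'   `k, knn, ari_mean, ari_sd, ami_mean, ami_sd, n_boot` plus the
#'   parameter `selected` by both criteria (see [select_parameters()]).
#' @export
stability_scan <- function(features, k_range, knn_range, n_boot = 100L,
                           frac = 0.9, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(k_range) == 0L || length(knn_range) == 0L) stop("empty parameter range")
  if (n_boot < 2L) stop("n_boot must be >= 2 (SD undefined otherwise)")
  if (floor(frac * n) < max(k_range)) {
    stop("subsample smaller than the largest k")
  }
  S <- .cosine_sim(features)
  kmax <- max(k_range)
  # reference clustering of the full data per (knn, k)
  refs <- list()
  for (knn in knn_range) {
    U <- .spectral_embed(.graph_from_sim(S, knn), kmax)
    refs[[as.character(knn)]] <- lapply(k_range, function(k) {
      .cluster_embedding(U, k, derive_seed(seed, 31L, knn * 1000L + k))
    })
  }
  nsub <- floor(frac * n)
  acc <- array(NA_real_, dim = c(length(k_range), length(knn_range), n_boot, 2L))
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, 37L, b))
    idx <- sort(sample.int(n, nsub))
    Ssub <- S[idx, idx]
    for (j in seq_along(knn_range)) {
      knn <- knn_range[j]
      U <- .spectral_embed(.graph_from_sim(Ssub, knn), kmax)
      for (i in seq_along(k_range)) {
        k <- k_range[i]
        lab <- .cluster_embedding(U, k,
                                  derive_seed(seed, 41L, b * 100000L + knn * 100L + k))
        ref <- refs[[as.character(knn)]][[i]][idx]
        ag <- partition_agreement(ref, lab)
        acc[i, j, b, 1L] <- ag$ari
        acc[i, j, b, 2L] <- ag$ami
      }
    }
  }
  grid <- expand.grid(k = k_range, knn = knn_range)
  grid$ari_mean <- as.vector(apply(acc[, , , 1L, drop = FALSE], c(1, 2), mean))
  grid$ari_sd <- as.vector(apply(acc[, , , 1L, drop = FALSE], c(1, 2), sd))
  grid$ami_mean <- as.vector(apply(acc[, , , 2L, drop = FALSE], c(1, 2), mean))
  grid$ami_sd <- as.vector(apply(acc[, , , 2L, drop = FALSE], c(1, 2), sd))
  grid$n_boot <- n_boot
  report <- structure(list(grid = grid, seed = seed), class = "stability_report")
  report$selected <- select_parameters(report)
  report
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> ", nrow(x$grid), " (k, knn) cells, ",
      x$grid$n_boot[1L], " bootstraps\n", sep = "")
  s <- x$selected
  if (!is.null(s)) {
    cat("  by mean:          k = ", s$by_mean$k, ", knn = ", s$by_mean$knn, "\n",
        "  by mean/SD ratio: k = ", s$by_mean_over_sd$k, ", knn = ",
        s$by_mean_over_sd$knn, "\n", sep = "")
  }
  invisible(x)
}

#' Select clustering parameters from a stability report
#'
#' Two candidates mirroring the scan's two criteria: the grid argmax of the
#' mean of `ari_mean` and `ami_mean`, and the argmax of the mean of the
#' variance-adjusted ratios `ari_mean/ari_sd` and `ami_mean/ami_sd`. Grid
#' cells with a zero SD are skipped for the ratio criterion (with a
#' warning). Ties break toward the smallest k, then the smallest knn.
#'
#' @param report a `stability_report` (or its `grid` data.frame).
#' @return `list(by_mean = list(k, knn), by_mean_over_sd = list(k, knn),
#'   grid)` with criterion columns appended.
#' @export
select_parameters <- function(report) {
  grid <- if (inherits(report, "stability_report")) report$grid else report
  grid <- grid[order(grid$k, grid$knn), , drop = FALSE]
  grid$crit_mean <- (grid$ari_mean + grid$ami_mean) / 2
  # sd = 0 with positive mean is the limit of perfect stability (ratio ->
  # +Inf); only a zero mean with zero sd leaves the ratio undefined.
  ratio1 <- function(m, s) ifelse(s > 0, m / s,
                                  ifelse(m > 0, Inf, NA_real_))
  ra <- ratio1(grid$ari_mean, grid$ari_sd)
  rb <- ratio1(grid$ami_mean, grid$ami_sd)
  if (anyNA(ra) || anyNA(rb)) {
    warning(sum(is.na(ra) | is.na(rb)),
            " grid cell(s) with undefined mean/SD ratio skipped")
  }
  grid$crit_ratio <- (ra + rb) / 2
  pick <- function(v) {
    i <- which(v == max(v, na.rm = TRUE))[1L]  # grid sorted: smallest k, knn first
    list(k = grid$k[i], knn = grid$knn[i])
  }
  by_ratio <- if (all(is.na(grid$crit_ratio))) pick(grid$crit_mean)
              else pick(grid$crit_ratio)
  list(by_mean = pick(grid$crit_mean), by_mean_over_sd = by_ratio, grid = grid)
}

#' Intra- vs inter-cluster correlation quality
#'
#' Mean pairwise Pearson correlation between cells' first-five-component
#' score vectors, within and between clusters, and their ratio.
#'
#' @param first5_pcs cells x 5 score matrix.
#' @param labels cluster labels.
#' @return `list(intra, inter, ratio)`.
#' @export
cluster_quality <- function(first5_pcs, labels) {
  X <- as.matrix(first5_pcs)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  sizes <- table(labels)
  if (any(sizes == 1L)) {
    warning("cluster(s) of size 1 excluded from the intra-cluster mean")
  }
  C <- cor(t(X))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(C)
  intra <- mean(C[ut & same])
  inter <- mean(C[ut & !same])
  list(intra = intra, inter = inter, ratio = intra / inter)
}

#' Silhouette-consistency cell filter
#'
#' Repeats the clustering `n_iter` times with distinct derived k-means
#' seeds on a fixed graph embedding and computes each cell's silhouette
#' score per run (cosine distance in feature space: `a` = mean
#' intra-cluster distance, `b` = smallest mean distance to another
#' cluster, `s = (b - a) / max(a, b)`). Cells with `s > 0` in at least
#' `min_pass` runs are retained.
#'
#' @param features cells x m reduced feature matrix.
#' @param k,knn clustering parameters.
#' @param n_iter number of clustering iterations.
#' @param min_pass minimum number of positive-silhouette runs (<= n_iter).
#' @param seed RNG seed.
#' @return `list(retained, pass_counts, reference)` where `reference` is
#'   the full-data `cluster_solution`.
#' @export
silhouette_filter <- function(features, k, knn, n_iter = 100L,
                              min_pass = 95L, seed = 1L) {
  if (min_pass > n_iter) stop("parameter error: min_pass exceeds n_iter")
  features <- as.matrix(features)
  S <- .cosine_sim(features)
  D <- 1 - S
  A <- .graph_from_sim(S, knn)
  U <- .spectral_embed(A, max(2L, k))
  n <- nrow(features)
  pass <- integer(n)
  ref <- NULL
  for (it in seq_len(n_iter)) {
    lab <- .cluster_embedding(U, k, derive_seed(seed, 53L, it))
    if (it == 1L) ref <- lab
    pass <- pass + as.integer(.silhouette_scores(D, lab) > 0)
  }
  list(retained = pass >= min_pass, pass_counts = pass,
       reference = structure(list(labels = ref, k = as.integer(k),
                                  seed = as.integer(seed)),
                             class = "cluster_solution"))
}

# Per-sample silhouette from a distance matrix and labels.
.silhouette_scores <- function(D, labels) {
  n <- nrow(D)
  ks <- sort(unique(labels))
  ind <- outer(labels, ks, "==") * 1
  cnt <- colSums(ind)
  M <- D %*% ind  # total distance from each cell to each cluster
  a <- M[cbind(seq_len(n), match(labels, ks))] / pmax(cnt[match(labels, ks)] - 1, 1)
  Mm <- sweep(M, 2L, cnt, "/")
  Mm[cbind(seq_len(n), match(labels, ks))] <- Inf
  b <- apply(Mm, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[cnt[match(labels, ks)] == 1L] <- 0  # singleton convention
  s
}
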