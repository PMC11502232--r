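#' @useDynLib lhensemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx convolve cor dnorm ecdf fft kmeans ks.test
#'   median prcomp quantile rlnorm rnorm rpois runif sd shapiro.test
#'   t.test var wilcox.test rexp
#' @importFrom utils read.csv write.csv head tail
NULL

# Deterministic per-stage seed spawning from one master seed.
# Offsets are small stage codes; result always a valid 32-bit seed.
derive_seed <- function(master_seed, offset, i = 0L) {
  s <- (as.double(master_seed) * 48271 + as.double(offset) * 16807 + as.double(i)) %%
    2147483629
  as.integer(s) + 1L
}

# --- half-open interval helpers -------------------------------------------
# Intervals are 2-column matrices [start, end), rows sorted, disjoint.

as_interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  m <- matrix(as.numeric(x), ncol = 2)
  colnames(m) <- c("start", "end")
  m[order(m[, 1L]), , drop = FALSE]
}

interval_total <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2L] - m[, 1L])

# TRUE for times lying inside any [start, end) interval.
in_intervals <- function(t, m) {
  if (nrow(m) == 0L) return(rep(FALSE, length(t)))
  edges <- as.vector(t(m))
  findInterval(t, edges) %% 2L == 1L
}

# Merge overlapping / touching intervals.
merge_intervals <- function(m) {
  m <- as_interval_matrix(m)
  if (nrow(m) <= 1L) return(m)
  out <- m[1L, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

# Set difference a \ b for interval matrices.
subtract_intervals <- function(a, b) {
  a <- as_interval_matrix(a); b <- merge_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  res <- NULL
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1L]; e <- a[i, 2L]
    segs <- matrix(c(s, e), ncol = 2)
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1L]; be <- b[j, 2L]
      new <- NULL
      for (r in seq_len(nrow(segs))) {
        ss <- segs[r, 1L]; se <- segs[r, 2L]
        if (be <= ss || bs >= se) {
          new <- rbind(new, c(ss, se))
        } else {
          if (bs > ss) new <- rbind(new, c(ss, bs))
          if (be < se) new <- rbind(new, c(be, se))
        }
      }
      segs <- if (is.null(new)) matrix(numeric(0), ncol = 2) else new
      if (nrow(segs) == 0L) break
    }
    if (nrow(segs) > 0L) res <- rbind(res, segs)
  }
  as_interval_matrix(res)
}

# Pairwise overlap length of one interval with a set.
overlap_lengths <- function(iv, m) {
  if (nrow(m) == 0L) return(numeric(0))
  pmax(0, pmin(iv[2L], m[, 2L]) - pmax(iv[1L], m[, 1L]))
}

# Boolean mask (regular grid) -> interval matrix in seconds.
mask_to_intervals <- function(mask, fs, t0 = 0) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    return(as_interval_matrix(NULL))
  }
  cbind(start = t0 + (starts[keep] - 1L) / fs, end = t0 + ends[keep] / fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear convolution via FFT, zero-padded to a highly composite length
# (stats::convolve pads to exactly n + m - 1, which can be prime and make
# the transform quadratic on long signals).
conv_open <- function(x, y) {
  n <- length(x); m <- length(y)
  L <- stats::nextn(n + m - 1L, c(2L, 3L, 5L))
  fx <- fft(c(x, numeric(L - n)))
  fy <- fft(c(y, numeric(L - m)))
  Re(fft(fx * fy, inverse = TRUE))[seq_len(n + m - 1L)] / L
}
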