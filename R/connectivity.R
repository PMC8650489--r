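# Histogram (plug-in) estimators of entropy, mutual information and the
# normalized mutual information connectivity coefficient.

# Discretize a series into 1..n_bins equal-width bins over its own observed
# range. A constant series occupies a single bin.
bin_series <- function(x, n_bins) {
  if (any(!is.finite(x))) stop("series contains non-finite values", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2] || n_bins == 1L) return(rep(1L, length(x)))
  # right-closed equal-width bins; clamp the maximum into the last bin
  idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L
  idx[idx > n_bins] <- n_bins
  as.integer(idx)
}

default_bins <- function(n_samples) as.integer(ceiling(sqrt(n_samples)))

entropy_from_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Shannon entropy of a discretized series
#'
#' Plug-in entropy (natural log) of the equal-width histogram of `x` over its
#' observed range `[min(x), max(x)]`, with the convention `0 log 0 = 0`. A
#' constant series has entropy 0.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @param n_bins Number of equal-width bins (default `ceiling(sqrt(n))`).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(c(0, 0, 1, 1), 2)  # log(2)
#' @export
shannon_entropy <- function(x, n_bins = default_bins(length(x))) {
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  stopifnot_scalar_count(n_bins, "n_bins")
  entropy_from_counts(tabulate(bin_series(x, n_bins), nbins = n_bins))
}

#' Mutual information of two series via joint histogram
#'
#' `I(X;Y) = H(X) + H(Y) - H(X,Y)` from the joint `n_bins x n_bins`
#' equal-width histogram, each axis binned over its own range (the same edges
#' as the marginal histograms). The result is clamped to be non-negative.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param n_bins Bins per axis (default `ceiling(sqrt(n))`).
#' @return Mutual information in nats.
#' @export
mutual_information <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  stopifnot_scalar_count(n_bins, "n_bins")
  bx <- bin_series(x, n_bins)
  by <- bin_series(y, n_bins)
  hx <- entropy_from_counts(tabulate(bx, nbins = n_bins))
  hy <- entropy_from_counts(tabulate(by, nbins = n_bins))
  hxy <- entropy_from_counts(tabulate(bx + n_bins * (by - 1L),
                                      nbins = n_bins * n_bins))
  max(hx + hy - hxy, 0)
}

#' Normalized mutual information between two series
#'
#' The connectivity coefficient used to weight graph edges: mutual
#' information divided by the geometric mean of the two Shannon entropies,
#' `nmi = I(X;Y) / sqrt(H(X) H(Y))`, clamped into `[0, 1]`. 0 indicates
#' statistical independence and 1 full mutual dependence; the value is
#' invariant to the logarithm base. If either series is constant (zero
#' entropy) the coefficient is defined as 0 and flagged degenerate.
#'
#' @inheritParams mutual_information
#' @return An object of class `dependence_estimate`: list with `h_x`, `h_y`,
#'   `mi` (nats), `nmi`, `n_bins`, `n_samples`, `degenerate`.
#' @examples
#' x <- c(0, 0, 1, 1)
#' nmi_coefficient(x, x, 2)$nmi            # 1: identical series
#' nmi_coefficient(x, c(0, 1, 0, 1), 2)$nmi  # 0: factorizing joint
#' @export
nmi_coefficient <- function(x, y, n_bins = default_bins(length(x))) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  stopifnot_scalar_count(n_bins, "n_bins")
  bx <- bin_series(x, n_bins)
  by <- bin_series(y, n_bins)
  hx <- entropy_from_counts(tabulate(bx, nbins = n_bins))
  hy <- entropy_from_counts(tabulate(by, nbins = n_bins))
  hxy <- entropy_from_counts(tabulate(bx + n_bins * (by - 1L),
                                      nbins = n_bins * n_bins))
  mi <- max(hx + hy - hxy, 0)
  degenerate <- hx == 0 || hy == 0
  nmi <- if (degenerate) 0 else min(max(mi / sqrt(hx * hy), 0), 1)
  structure(list(h_x = hx, h_y = hy, mi = mi, nmi = nmi,
                 n_bins = as.integer(n_bins), n_samples = length(x),
                 degenerate = degenerate),
            class = "dependence_estimate")
}

#' Whole-brain NMI connectivity matrix
#'
#' Computes the symmetric ROI x ROI matrix of pairwise normalized mutual
#' information coefficients over the retained volumes of a time series. Each
#' series is discretized once into `n_bins` equal-width bins over its own
#' range; joint histograms reuse the same per-axis edges. The diagonal is
#' fixed at 0 so graphs built from the matrix are simple. Internally the
#' pairwise joint entropies are obtained from one indicator-matrix product,
#' which is algebraically identical to calling [nmi_coefficient()] per pair.
#'
#' @param ts A [roi_timeseries()] with >= 2 ROIs and >= 2 volumes (typically
#'   after [select_task_volumes()]).
#' @param n_bins Bins per series; default `ceiling(sqrt(n_volumes))`.
#' @return Symmetric numeric matrix with ROI dimnames, entries in `[0, 1]`,
#'   zero diagonal; attributes `n_bins` and `degenerate_rois` (names of
#'   constant ROIs whose coefficients were set to 0).
#' @export
build_connectivity_matrix <- function(ts, n_bins = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  v <- ts$values
  n_roi <- nrow(v)
  n_t <- ncol(v)
  if (n_roi < 2) stop("need at least 2 ROIs", call. = FALSE)
  if (n_t < 2) stop("need at least 2 retained volumes", call. = FALSE)
  if (is.null(n_bins)) n_bins <- default_bins(n_t)
  stopifnot_scalar_count(n_bins, "n_bins")
  k <- as.integer(n_bins)

  bins <- matrix(0L, n_roi, n_t)
  for (i in seq_len(n_roi)) bins[i, ] <- bin_series(v[i, ], k)

  # Marginal entropies per ROI.
  h <- apply(bins, 1L, function(b) entropy_from_counts(tabulate(b, nbins = k)))

  # One-hot indicators stacked ROI-major: row (i-1)*k + a marks bins[i,]==a.
  U <- matrix(0, n_roi * k, n_t)
  U[cbind(rep(seq_len(n_roi), n_t) * k - k + as.vector(bins), # nolint
          rep(seq_len(n_t), each = n_roi))] <- 1
  C <- U %*% t(U)                       # pairwise joint bin counts
  P <- C / n_t
  E <- -P * log(P)
  E[!is.finite(E)] <- 0                 # 0 log 0 = 0
  grp <- rep(seq_len(n_roi), each = k)
  hj <- rowsum(E, grp)                  # sum over x-bins
  hj <- t(rowsum(t(hj), grp))           # sum over y-bins -> ROI x ROI H(X,Y)

  mi <- outer(h, h, `+`) - hj
  mi[mi < 0] <- 0
  denom <- sqrt(outer(h, h))
  nmi <- matrix(0, n_roi, n_roi)
  ok <- denom > 0
  nmi[ok] <- mi[ok] / denom[ok]
  nmi[nmi > 1] <- 1
  nmi <- (nmi + t(nmi)) / 2             # exact symmetry
  diag(nmi) <- 0
  dimnames(nmi) <- list(ts$roi_names, ts$roi_names)
  attr(nmi, "n_bins") <- k
  attr(nmi, "degenerate_rois") <- ts$roi_names[h == 0]
  nmi
}
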