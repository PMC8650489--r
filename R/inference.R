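# Monte-Carlo permutation inference: two-tailed permutation t-tests with
# optional exhaustive enumeration, Bonferroni thresholds, and the
# partition-distance significance test.

welch_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  num <- mean(a) - mean(b)
  den <- sqrt(stats::var(a) / na + stats::var(b) / nb)
  if (den == 0) return(if (num == 0) 0 else sign(num) * Inf)
  num / den
}

#' Two-tailed Monte-Carlo permutation t-test
#'
#' Compares two independent samples with the Welch t statistic; the null
#' distribution is built by randomly reassigning the pooled observations to
#' groups of the original sizes. The two-tailed p-value is
#' `(#\{|t*| >= |t_obs|\} + 1) / (n_perm + 1)` (add-one smoothing, so p is
#' never 0 and never below `1/(n_perm+1)`). When the label-assignment space
#' `choose(n, n_a)` does not exceed 10,000 the full assignment set is
#' enumerated instead of sampled and the p-value is exact.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param n_perm Number of Monte-Carlo randomizations; default 20000.
#' @param seed Integer seed (ignored in the exhaustive branch).
#' @return List of class `permutation_result`: `observed` (Welch t),
#'   `p_value`, `n_perm` (randomizations actually used), `exhaustive`,
#'   `seed`.
#' @export
permutation_ttest <- function(a, b, n_perm = 20000L, seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample needs at least 2 observations", call. = FALSE)
  stopifnot_scalar_count(n_perm, "n_perm")
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  t_obs <- welch_t(a, b)
  n_assign <- choose(n, na)
  if (n_assign <= 10000) {
    idx <- utils::combn(n, na)
    t_null <- apply(idx, 2L, function(ii) welch_t(pooled[ii], pooled[-ii]))
    p <- (sum(abs(t_null) >= abs(t_obs) - 1e-12) + 1) / (ncol(idx) + 1)
    res <- list(observed = t_obs, p_value = p, n_perm = ncol(idx),
                exhaustive = TRUE, seed = seed)
  } else {
    t_null <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
      ii <- sample.int(n, na)
      welch_t(pooled[ii], pooled[-ii])
    }, numeric(1)))
    p <- (sum(abs(t_null) >= abs(t_obs)) + 1) / (n_perm + 1)
    res <- list(observed = t_obs, p_value = p, n_perm = as.integer(n_perm),
                exhaustive = FALSE, seed = as.integer(seed))
  }
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: statistic = %.4f, p = %.5g (%s%d randomizations)\n",
              x$observed, x$p_value,
              if (isTRUE(x$exhaustive)) "exhaustive, " else "", x$n_perm))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level in `(0, 1)`.
#' @param m Number of comparisons, >= 1.
#' @return Per-comparison threshold `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 20)  # 0.0025
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  stopifnot_scalar_count(m, "m")
  alpha / m
}

#' Permutation test on a partition distance
#'
#' Assesses whether two modular decompositions are more similar than chance:
#' the observed statistic is `partition_distance(p, q)`, and the null
#' distribution is obtained by randomly permuting `q`'s affiliation labels
#' across nodes (preserving module sizes). With `alternative = "less"` (the
#' default) the p-value is the add-one-smoothed fraction of null distances
#' at most the observed one — small p means the decompositions agree beyond
#' chance. `alternative = "greater"` tests for excess dissimilarity.
#'
#' @param p,q [modular_partition()] objects (or affiliation vectors) over the
#'   same node set.
#' @param n_perm Number of label permutations; default 20000.
#' @param seed Integer seed.
#' @param alternative `"less"` (more similar than chance) or `"greater"`.
#' @return A `permutation_result` with `observed` = the partition distance.
#' @export
partition_distance_test <- function(p, q, n_perm = 20000L, seed = 1L,
                                    alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot_scalar_count(n_perm, "n_perm")
  ap <- if (inherits(p, "modular_partition")) unname(p$affiliation) else as.integer(p)
  aq <- if (inherits(q, "modular_partition")) unname(q$affiliation) else as.integer(q)
  if (length(ap) != length(aq))
    stop("partitions must cover the same node set", call. = FALSE)
  obs <- partition_distance(ap, aq)
  null_pd <- with_seed(seed, vapply(seq_len(n_perm), function(r)
    partition_distance(ap, aq[sample.int(length(aq))]), numeric(1)))
  hits <- if (alternative == "less") sum(null_pd <= obs + 1e-12)
          else sum(null_pd >= obs - 1e-12)
  structure(list(observed = obs, p_value = (hits + 1) / (n_perm + 1),
                 n_perm = as.integer(n_perm), exhaustive = FALSE,
                 seed = as.integer(seed), alternative = alternative),
            class = "permutation_result")
}
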