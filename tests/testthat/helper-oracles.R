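# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: explicit loops, cut()-based binning, Floyd-Warshall,
# exhaustive partition enumeration.

# Plug-in entropy via explicit count loop over floor-binned indices.
oracle_entropy <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  idx <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1, bins)
  h <- 0
  for (b in seq_len(bins)) {
    p <- sum(idx == b) / length(x)
    if (p > 0) h <- h - p * log(p)
  }
  h
}

oracle_mi <- function(x, y, bins) {
  rx <- range(x); ry <- range(y)
  bx <- if (rx[1] == rx[2]) rep(1, length(x))
        else pmin(floor((x - rx[1]) / (rx[2] - rx[1]) * bins) + 1, bins)
  by <- if (ry[1] == ry[2]) rep(1, length(y))
        else pmin(floor((y - ry[1]) / (ry[2] - ry[1]) * bins) + 1, bins)
  n <- length(x)
  mi <- 0
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    pab <- sum(bx == a & by == b) / n
    pa <- sum(bx == a) / n
    pb <- sum(by == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (pa * pb))
  }
  max(mi, 0)
}

# All-pairs shortest paths on inverse-weight lengths, O(N^3).
floyd_warshall <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(w) {
  d <- floyd_warshall(w)
  n <- nrow(w)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Per-node weighted clustering via exhaustive triangle enumeration.
oracle_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (j in nb) for (h in nb)
      if (j != h && w[j, h] > 0)
        t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    ci[i] <- t_i / (k * (k - 1))
  }
  ci
}

# Newman modularity by the literal double sum.
oracle_modularity <- function(w, memb) {
  two_m <- sum(w)
  s <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j])
      q <- q + (w[i, j] - s[i] * s[j] / two_m) / two_m
  q
}

# All set partitions of n elements as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in seq_len(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(1L, 1L)
  out
}

oracle_best_q <- function(w) {
  parts <- all_partitions(nrow(w))
  max(vapply(parts, function(p) oracle_modularity(w, p), numeric(1)))
}

# Participation coefficient via per-module edge-count loop.
oracle_pc <- function(w, memb) {
  n <- nrow(w)
  pc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k == 0) next
    acc <- 0
    for (m in unique(memb)) acc <- acc + (sum(memb[nb] == m) / k)^2
    pc[i] <- 1 - acc
  }
  pc
}

# Exhaustive two-sample permutation p-value using stats::t.test Welch
# statistics (an independent route to the test statistic).
oracle_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  tt <- function(x, y) unname(stats::t.test(x, y)$statistic)
  t_obs <- tt(a, b)
  idx <- utils::combn(n, na)
  t_null <- apply(idx, 2, function(ii) tt(pooled[ii], pooled[-ii]))
  (sum(abs(t_null) >= abs(t_obs) - 1e-12) + 1) / (ncol(idx) + 1)
}

# Variation of information via an explicit contingency loop.
oracle_pd <- function(p, q) {
  n <- length(p)
  ent <- function(z) {
    h <- 0
    for (v in unique(z)) {
      pr <- sum(z == v) / n
      h <- h - pr * log(pr)
    }
    h
  }
  mi <- 0
  for (a in unique(p)) for (b in unique(q)) {
    pab <- sum(p == a & q == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (sum(p == a) / n * sum(q == b) / n))
  }
  (ent(p) + ent(q) - 2 * mi) / log(n)
}
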