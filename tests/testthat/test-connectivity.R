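test_that("entropy matches hand and brute-force oracles", {
  expect_equal(shannon_entropy(rep(3.7, 10), 4), 0)
  expect_equal(shannon_entropy(c(0, 0, 1, 1), 2), log(2))
  expect_equal(shannon_entropy(c(0, 0, 0, 1), 2),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  set.seed(21)
  for (r in 1:10) {
    x <- rnorm(50)
    bins <- sample(2:12, 1)
    expect_equal(shannon_entropy(x, bins), oracle_entropy(x, bins))
  }
  expect_error(shannon_entropy(c(1, NA, 2), 2), "non-finite")
})

test_that("mutual information matches the joint-histogram oracle", {
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1), 2), 0)
  x <- c(0.1, 0.4, 0.8, 0.9)
  expect_equal(mutual_information(x, x, 2), shannon_entropy(x, 2))
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 1, 1), 2),
               log(2) - (0.75 * log(0.75) + 0.25 * log(0.25)) -
                 (-2 * 0.25 * log(0.25) - 0.5 * log(0.5)))
  set.seed(22)
  for (r in 1:10) {
    x <- rnorm(60); y <- 0.5 * x + rnorm(60)
    bins <- sample(2:10, 1)
    expect_equal(mutual_information(x, y, bins), oracle_mi(x, y, bins))
  }
})

test_that("NMI hits its defining anchors and stays symmetric", {
  x <- rnorm(360)
  expect_equal(nmi_coefficient(x, x)$nmi, 1)
  expect_equal(nmi_coefficient(c(0, 0, 1, 1), c(0, 1, 0, 1), 2)$nmi, 0)
  est <- nmi_coefficient(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(est$nmi, est$mi / sqrt(est$h_x * est$h_y))
  expect_equal(round(est$nmi, 4), 0.3456)

  set.seed(23)
  for (r in 1:5) {
    a <- rnorm(40); b <- rnorm(40)
    expect_identical(nmi_coefficient(a, b)$nmi, nmi_coefficient(b, a)$nmi)
  }

  # degenerate constant series: defined as 0 and flagged, never NaN
  d <- nmi_coefficient(rep(1, 20), rnorm(20))
  expect_equal(d$nmi, 0)
  expect_true(d$degenerate)
})

test_that("NMI is invariant to the entropy log base", {
  # recompute in bits by hand: every entropy scales by 1/log(2), the ratio
  # mi / sqrt(hx hy) cancels the base exactly
  set.seed(24)
  x <- rnorm(80); y <- x + rnorm(80)
  est <- nmi_coefficient(x, y, 9)
  to_bits <- 1 / log(2)
  nmi_bits <- (est$mi * to_bits) / sqrt((est$h_x * to_bits) * (est$h_y * to_bits))
  expect_equal(est$nmi, nmi_bits)
})

test_that("added independent noise does not raise NMI (median over seeds)", {
  deltas <- vapply(1:10, function(seed) {
    set.seed(seed)
    x <- rnorm(120)
    y <- x + rnorm(120, sd = 0.3)
    y_noisier <- y + rnorm(120, sd = 1.5)
    nmi_coefficient(x, y_noisier)$nmi - nmi_coefficient(x, y)$nmi
  }, numeric(1))
  expect_lte(median(deltas), 0)
})

test_that("the matrix builder equals pairwise coefficients exactly", {
  set.seed(25)
  v <- matrix(rnorm(6 * 50), 6, 50)
  v[4, ] <- 5                       # a constant ROI
  ts <- roi_timeseries(v, tr_s = 2.5)
  m <- build_connectivity_matrix(ts)
  bins <- attr(m, "n_bins")
  expect_equal(bins, ceiling(sqrt(50)))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(m[i, j], nmi_coefficient(v[i, ], v[j, ], bins)$nmi,
                 tolerance = 1e-12)
  expect_true(max(abs(m - t(m))) == 0)
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(attr(m, "degenerate_rois"), "ROI004")
  expect_true(all(m[4, ] == 0))

  # two identical non-constant rows -> off-diagonal coefficient 1
  v2 <- rbind(rnorm(30), 0, 0)
  v2[2, ] <- v2[1, ]; v2[3, ] <- rnorm(30)
  m2 <- build_connectivity_matrix(roi_timeseries(v2, tr_s = 2.5))
  expect_equal(m2[1, 2], 1)
})

test_that("planted modules show higher within- than between-module NMI", {
  for (seed in 1:5) {
    spec <- cohort_spec(n_per_group = c(A = 1), n_rois = 60,
                        design = make_block_design(6, 20, 20, 2.5),
                        structure = planted_structure(rep(1:3, each = 20),
                                                      within_coupling = 0.8,
                                                      between_coupling = 0.05),
                        seed = seed)
    s <- simulate_subject(spec, "A", 1)
    m <- build_connectivity_matrix(select_task_volumes(s$ts, spec$design))
    memb <- rep(1:3, each = 20)
    same <- outer(memb, memb, `==`) & upper.tri(m)
    diff <- !outer(memb, memb, `==`) & upper.tri(m)
    expect_gt(mean(m[same]), mean(m[diff]))
  }
})
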