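test_that("block designs have the right volume bookkeeping", {
  d <- make_block_design(15, 30, 30, 2.5)
  expect_equal(d$n_volumes, 360)
  expect_equal(sum(d$task_mask), 180)
  expect_true(d$task_mask[1])            # task-first
  expect_false(d$task_mask[13])          # first rest volume of block 1

  d1 <- make_block_design(1, 30, 30, 30)
  expect_equal(d1$task_mask, c(TRUE, FALSE))

  d2 <- make_block_design(2, 10, 20, 2.5)
  expect_equal(d2$n_volumes, 2 * (10 + 20) / 2.5)
  expect_equal(sum(d2$task_mask), 2 * 10 / 2.5)

  expect_error(make_block_design(2, 10, 17, 2.5), "remainder")
})

test_that("subject simulation is reproducible and respects the null", {
  spec <- small_spec(seed = 7)
  s1 <- simulate_subject(spec, "A", 3)
  s2 <- simulate_subject(spec, "A", 3)
  expect_identical(s1, s2)
  s3 <- simulate_subject(spec, "A", 4)
  expect_false(identical(s1$ts$values, s3$ts$values))
  expect_true(all(s1$motion >= 0))
  expect_equal(ncol(s1$ts$values), spec$design$n_volumes)

  # zero coupling -> ROIs are mutually independent noise: mean off-diagonal
  # NMI does not exceed the null 95th percentile
  spec0 <- cohort_spec(n_per_group = c(A = 1), n_rois = 12,
                       design = make_block_design(6, 20, 20, 2.5),
                       structure = planted_structure(rep_len(1:3, 12),
                                                     within_coupling = 0,
                                                     between_coupling = 0),
                       seed = 5)
  s <- simulate_subject(spec0, "A", 1)
  ts <- select_task_volumes(s$ts, spec0$design)
  m <- build_connectivity_matrix(ts)
  off <- m[upper.tri(m)]
  # permutation null: same marginals, volumes shuffled independently per ROI
  set.seed(1)
  null_vals <- replicate(200, {
    v <- ts$values
    i <- sample(nrow(v), 2)
    nmi_coefficient(v[i[1], ], sample(v[i[2], ]))$nmi
  })
  expect_lt(mean(off), quantile(null_vals, 0.95))
})

test_that("cohort generation is deterministic with requested group sizes", {
  spec <- small_spec(seed = 2, n_sub = c(A = 3, B = 2))
  coh <- simulate_cohort(spec)
  expect_length(coh, 5)
  expect_equal(table(vapply(coh, `[[`, "", "group")),
               table(rep(c("A", "B"), c(3, 2))))
  expect_identical(coh, simulate_cohort(spec))

  single <- simulate_cohort(small_spec(seed = 2, n_sub = c(A = 1)))
  expect_length(single, 1)
})

test_that("stronger within-module coupling raises within-module NMI", {
  med_within <- function(seed, w) {
    spec <- cohort_spec(n_per_group = c(A = 1), n_rois = 15,
                        design = make_block_design(6, 20, 20, 2.5),
                        structure = planted_structure(rep(1:3, each = 5),
                                                      within_coupling = w,
                                                      between_coupling = 0),
                        seed = seed)
    s <- simulate_subject(spec, "A", 1)
    m <- build_connectivity_matrix(select_task_volumes(s$ts, spec$design))
    memb <- rep(1:3, each = 5)
    same <- outer(memb, memb, `==`) & upper.tri(m)
    median(m[same])
  }
  for (seed in 1:5) {
    lo <- med_within(seed, 0.2)
    hi <- med_within(seed, 0.8)
    expect_gte(hi, lo)
  }
})

test_that("with no planted structure, within and between pairs are exchangeable", {
  n_pass <- 0
  for (seed in 1:5) {
    spec <- cohort_spec(n_per_group = c(A = 1), n_rois = 18,
                        design = make_block_design(6, 20, 20, 2.5),
                        structure = planted_structure(rep(1:3, each = 6),
                                                      within_coupling = 0,
                                                      between_coupling = 0),
                        seed = seed)
    s <- simulate_subject(spec, "A", 1)
    m <- build_connectivity_matrix(select_task_volumes(s$ts, spec$design))
    memb <- rep(1:3, each = 6)
    same <- outer(memb, memb, `==`) & upper.tri(m)
    diff <- !outer(memb, memb, `==`) & upper.tri(m)
    p <- wilcox.test(m[same], m[diff])$p.value
    if (p > 0.01) n_pass <- n_pass + 1
  }
  expect_gte(n_pass, 4)
})

test_that("atlas fixtures label every ROI with at least two voxels", {
  atl <- make_atlas_fixture(3, 2, 1, c(6, 6, 6), seed = 4)
  tab <- table(atl$labels[atl$labels > 0])
  expect_length(tab, 6)
  expect_true(all(tab >= 2))
  expect_equal(atl$roi_names,
               c("ctx001", "ctx002", "ctx003", "sub001", "sub002", "cbl001"))

  big <- make_atlas_fixture(142, 36, 34, c(24, 24, 24), seed = 1)
  expect_equal(length(unique(big$labels[big$labels > 0])), 212)

  one <- make_atlas_fixture(1, 0, 0, c(2, 2, 2), seed = 1)
  expect_gte(sum(one$labels == 1), 2)

  expect_error(make_atlas_fixture(5, 0, 0, c(2, 2, 2)), "cannot hold")
})
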