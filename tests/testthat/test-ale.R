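test_that("kernel SD matches the published two-component formula and its limits", {
  spec <- kernel_spec()
  for (n in c(1, 5, 10, 40, 120, 479))
    expect_equal(kernel_sd(spec, n), reference_kernel_sd(n), tolerance = 1e-12)
  expect_lt(kernel_sd(spec, 40), kernel_sd(spec, 10))  # tighter with more subjects
  expect_equal(kernel_sd(spec, 1e9), 5.7 / (2 * sqrt(2 / pi)), tolerance = 1e-4)
  expect_error(kernel_sd(spec, 0), "n_subjects")
})

test_that("MA map of a single focus peaks there with the kernel's central value", {
  g <- tiny_grid(9, 9, 9, voxel_mm = 2)
  e <- fixed_experiment(1, 25, c(8, 8, 8))
  ma <- modeled_activation(e, g, kernel_spec())
  peak_row <- which.max(ma)
  expect_equal(unname(alesim:::mask_centers(g)[peak_row, ]), c(8, 8, 8))
  # independent kernel evaluation: normalised Gaussian over the offset ball
  sd_mm <- reference_kernel_sd(25)
  r <- ceiling(5 * sd_mm / 2)
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r)) * 2
  r2 <- rowSums(off^2)
  w <- exp(-r2 / (2 * sd_mm^2))
  w <- w[r2 <= (5 * sd_mm)^2]
  expect_equal(max(ma), max(w) / sum(w), tolerance = 1e-10)
  expect_true(all(ma >= 0 & ma < 1))
  # zero beyond the truncation radius
  d2 <- rowSums(sweep(alesim:::mask_centers(g), 2, c(8, 8, 8), "-")^2)
  expect_true(all(ma[d2 > (5 * sd_mm)^2] == 0))
})

test_that("overlapping foci combine by maximum, distant foci independently", {
  g <- tiny_grid(20, 7, 7, voxel_mm = 4)
  spec <- kernel_spec()
  one <- modeled_activation(fixed_experiment(1, 30, c(8, 12, 12)), g, spec)
  dup <- modeled_activation(fixed_experiment(1, 30, rbind(c(8, 12, 12),
                                                          c(8, 12, 12))), g, spec)
  expect_identical(dup, one)  # max, not sum
  far1 <- modeled_activation(fixed_experiment(1, 30, c(4, 12, 12)), g, spec)
  far2 <- modeled_activation(fixed_experiment(1, 30, c(72, 12, 12)), g, spec)
  both <- modeled_activation(fixed_experiment(1, 30, rbind(c(4, 12, 12),
                                                           c(72, 12, 12))), g, spec)
  expect_equal(both, pmax(far1, far2))
  expect_error(modeled_activation(fixed_experiment(1, 30, c(999, 0, 0)), g, spec),
               "outside")
})

test_that("ALE union follows 1 - prod(1 - MA)", {
  expect_equal(ale_union(cbind(0.1, 0.05)), 1 - 0.9 * 0.95)  # 0.145
  m <- cbind(c(0.2, 0), c(0.1, 0))
  expect_equal(ale_union(m), c(1 - 0.8 * 0.9, 0))
  expect_identical(ale_union(cbind(c(0, 0))), c(0, 0))  # single map: ALE = MA
  expect_true(all(ale_union(m) >= apply(m, 1, max)))
  expect_error(ale_union(list(1:3 / 10, 1:4 / 10)), "mismatch")
})

test_that("single-experiment voxel null equals the tabulated MA distribution", {
  g <- tiny_grid(5, 5, 4)
  ma <- cbind(modeled_activation(fixed_experiment(1, 20, c(4, 4, 2)), g,
                                 kernel_spec()))
  bw <- 1e-5
  vn <- voxel_null(ma, bin_width = bw)
  bins <- floor(ma[, 1] / bw + 1e-9)
  expected <- tabulate(bins + 1, nbins = max(bins) + 1) / nrow(ma)
  expect_equal(vn$pmf, expected, tolerance = 1e-12)
  expect_equal(sum(vn$pmf), 1, tolerance = 1e-12)
  expect_equal(vn$tail[1], 1, tolerance = 1e-12)
})

test_that("voxel null agrees with exhaustive enumeration for 2-3 experiments", {
  g <- tiny_grid(5, 5, 4)  # 100 voxels
  spec <- kernel_spec()
  exps <- list(fixed_experiment(1, 15, c(4, 4, 2)),
               fixed_experiment(2, 60, rbind(c(2, 2, 4), c(8, 8, 6))),
               fixed_experiment(3, 30, c(6, 2, 2)))
  for (K in 2:3) {
    ma <- ma_matrix(exps[seq_len(K)], g, spec)
    bw <- 1e-5
    vn <- voxel_null(ma, bin_width = bw)
    edges <- (seq(0, length(vn$pmf) - 1, by = 37)) * bw
    impl_tail <- vapply(edges, function(t) {
      b <- as.integer(round(t / bw)) + 1L
      if (b > length(vn$tail)) 0 else vn$tail[b]
    }, numeric(1))
    # left-edge representatives under-estimate each value by less than
    # 2 * bw per experiment (input binning + combination flooring), so the
    # implementation tail is bracketed by the exact tails at shifted edges
    upper <- brute_force_tail(ma, edges) + 1e-9
    lower <- brute_force_tail(ma, edges + 2 * K * bw) - 1e-9
    expect_true(all(impl_tail <= upper))
    expect_true(all(impl_tail >= lower))
  }
})

test_that("cluster-forming cutoff is the conservative tail quantile", {
  g <- tiny_grid(5, 5, 4)
  ma <- cbind(modeled_activation(fixed_experiment(1, 20, c(4, 4, 2)), g,
                                 kernel_spec()))
  bw <- 1e-5
  vn <- voxel_null(ma, bin_width = bw)
  # independent tabulation over binned values
  binned <- floor(ma[, 1] / bw + 1e-9) * bw
  oracle <- function(p) {
    edges <- sort(unique(c(binned, max(binned) + bw)))
    edges[which(vapply(edges, function(t) mean(binned >= t), numeric(1)) <= p)[1]]
  }
  for (p in c(0.3, 0.05, 0.01)) {
    cut <- cluster_forming_cutoff(vn, p)
    expect_lte(mean(binned >= cut), p)
    expect_lte(cut, oracle(p) + 1e-12)
  }
  expect_gte(cluster_forming_cutoff(vn, 0.001), cluster_forming_cutoff(vn, 0.01))
  # p close to 1: cutoff sits at the distribution minimum (next bin edge)
  expect_equal(cluster_forming_cutoff(vn, 1 - 1e-9), min(binned) + bw,
               tolerance = 1e-12)
  expect_error(cluster_forming_cutoff(vn, 0), "p must")
})

test_that("connected components respect the chosen neighbourhood", {
  g <- tiny_grid(6, 6, 6)
  # two voxels sharing only a corner
  rows <- c(which(g$mask_vox[, 1] == 0 & g$mask_vox[, 2] == 0 & g$mask_vox[, 3] == 0),
            which(g$mask_vox[, 1] == 1 & g$mask_vox[, 2] == 1 & g$mask_vox[, 3] == 1))
  cs26 <- label_clusters(g, rows, connectivity = 26)
  cs6 <- label_clusters(g, rows, connectivity = 6)
  expect_identical(nrow(cs26$clusters), 1L)
  expect_identical(nrow(cs6$clusters), 2L)
  one <- label_clusters(g, rows[1])
  expect_identical(one$clusters$size, 1L)
  empty <- label_clusters(g, integer())
  expect_identical(nrow(empty$clusters), 0L)
  expect_error(label_clusters(g, rows, connectivity = 10), "connectivity")
})

test_that("max-statistic null is reproducible and bounded by the kernel peak", {
  g <- tiny_grid(9, 9, 9, voxel_mm = 4)
  spec <- kernel_spec()
  ds <- list(fixed_experiment(1, 30, c(16, 16, 16)))
  set.seed(11)
  n1 <- max_stat_null(ds, g, spec, cf_cutoff = 0.5, iterations = 20)
  set.seed(11)
  n2 <- max_stat_null(ds, g, spec, cf_cutoff = 0.5, iterations = 20)
  expect_identical(n1$max_ale, n2$max_ale)
  expect_identical(n1$max_cluster, n2$max_cluster)
  # one experiment, one focus: the max ALE is the kernel peak every iteration
  kern <- alesim:::ale_kernel(spec, 30, 4)
  expect_true(all(abs(n1$max_ale - max(kern$values)) < 1e-12))
  expect_true(all(n1$max_cluster == 0))  # cutoff above the peak
})

test_that("FWE thresholds use the conservative order statistic with strict exceedance", {
  g <- tiny_grid(5, 5, 4)
  ale <- numeric(g$n_mask)
  ale[1:10] <- 0.5  # a 10-voxel block (connected: consecutive x indices)
  null <- structure(list(max_ale = (1:100) / 1000,
                         max_cluster = rep(c(0L, 12L), 50),
                         iterations = 100L), class = "max_stat_null")
  # threshold = 95th order statistic = 0.095
  cs <- threshold_vfwe(ale, null, g, alpha = 0.05)
  expect_identical(nrow(cs$clusters), 1L)
  expect_identical(cs$clusters$size, 10L)
  # observed max below all null maxima: empty set
  cs0 <- threshold_vfwe(ale * 0 + 1e-4, null, g, alpha = 0.05)
  expect_identical(nrow(cs0$clusters), 0L)
  # ALE exactly at the threshold is not significant (strict >)
  ale_eq <- numeric(g$n_mask); ale_eq[1] <- sort(null$max_ale)[95]
  expect_identical(nrow(threshold_vfwe(ale_eq, null, g, 0.05)$clusters), 0L)
  expect_error(threshold_vfwe(ale, null, g, alpha = 1.2), "alpha")
})

test_that("cFWE keeps only clusters larger than the null size quantile", {
  g <- tiny_grid(16, 16, 16, voxel_mm = 4)
  ma <- ma_matrix(list(fixed_experiment(1, 40, c(32, 32, 32)),
                       fixed_experiment(2, 40, c(32, 32, 32)),
                       fixed_experiment(3, 40, c(32, 32, 32))), g, kernel_spec())
  ale <- ale_union(ma)
  vn <- voxel_null(ma)
  null_small <- structure(list(max_ale = rep(1, 100),
                               max_cluster = rep(1000L, 100)),
                          class = "max_stat_null")
  expect_identical(nrow(threshold_cfwe(ale, vn, null_small, g)$clusters), 0L)
  null_perm <- structure(list(max_ale = rep(1, 100),
                              max_cluster = rep(0L, 100)),
                         class = "max_stat_null")
  kept <- threshold_cfwe(ale, vn, null_perm, g)
  unc <- threshold_uncorrected(ale, vn, g)
  expect_gt(nrow(unc$clusters), 0L)  # triple convergence is suprathreshold
  expect_identical(kept$clusters$size, unc$clusters$size)  # all survive
  # uncorrected is a superset of cFWE at matching cluster-forming p
  expect_gte(nrow(unc$clusters), nrow(threshold_cfwe(ale, vn, null_small, g)$clusters))
})
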