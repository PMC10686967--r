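test_that("clusters are classified true when any voxel touches the vicinity box", {
  g <- make_synthetic_mask(voxel_mm = 4)
  vic <- vicinity()
  row_near <- g$lookup[1 + (world_to_voxel(g, c(-26, -26, 58)) - 1) %*%
                         c(1, g$dim[1], g$dim[1] * g$dim[2])] + 1
  row_far <- g$lookup[1 + (world_to_voxel(g, c(38, 22, 10)) - 1) %*%
                        c(1, g$dim[1], g$dim[1] * g$dim[2])] + 1
  cs <- label_clusters(g, c(row_near, row_far), connectivity = 26)
  cls <- classify_clusters(cs, vic, g)
  expect_identical(length(cls$true_idx), 1L)
  expect_identical(length(cls$spurious_idx), 1L)
  # membership decided by the member voxel inside the box
  tr <- cs$members[[cls$true_idx]]
  expect_true(all(abs(alesim:::mask_centers(g)[tr, ] - c(-30, -26, 58)) <= 4))
  empty <- label_clusters(g, integer())
  cls0 <- classify_clusters(empty, vic, g)
  expect_identical(cls0$true_idx, integer())
  expect_identical(cls0$spurious_idx, integer())
})

test_that("contribution fractions follow the sorted cumulative-product formula", {
  # voxel with sorted MA (0.1, 0.05): f1 = 0.1/0.145, f2 = 1
  f <- contribution_profile(1L, rbind(c(0.05, 0.1)))
  expect_equal(f, c(0.1 / 0.145, 1), tolerance = 1e-12)
  # one experiment: f1 = 1 everywhere
  expect_equal(contribution_profile(1:3, cbind(c(.2, .3, .1))), 1)
  # equal MA x from each of K experiments: closed form
  x <- 0.07; K <- 5
  fk <- contribution_profile(1L, matrix(x, 1, K))
  expect_equal(fk, (1 - (1 - x)^(1:K)) / (1 - (1 - x)^K), tolerance = 1e-12)
  expect_error(contribution_profile(1L, rbind(c(0, 0))), "zero")
  expect_error(contribution_profile(integer(), rbind(c(0.1))), "empty")
})

test_that("contribution profiles are monotone with f_K = 1 on random clusters", {
  set.seed(8)
  for (rep in 1:20) {
    K <- sample(2:8, 1)
    nv <- sample(1:6, 1)
    ma <- matrix(runif(nv * K, 0, 0.3) * rbinom(nv * K, 1, 0.6), nv, K)
    ma[, 1] <- pmax(ma[, 1], 1e-4)  # keep ALE positive
    f <- contribution_profile(seq_len(nv), ma)
    expect_true(all(diff(f) >= -1e-12))
    expect_equal(f[K], 1, tolerance = 1e-12)
  }
})

test_that("dataset evaluation separates detection from spurious convergence", {
  g <- make_synthetic_mask(voxel_mm = 4)
  vic <- vicinity()
  ds <- structure(list(experiments = list(), n_total = 5L, n_signal = 2L,
                       stratum = NULL), class = "simulated_dataset")
  lin <- function(xyz) g$lookup[1 + (world_to_voxel(g, xyz) - 1) %*%
                                  c(1, g$dim[1], g$dim[1] * g$dim[2])] + 1
  ma <- matrix(0, g$n_mask, 5)
  rows <- c(lin(c(-30, -26, 58)), lin(c(38, 22, 10)))
  ma[rows, 1] <- 0.2
  ma[rows, 2] <- 0.1
  clusters <- list(cfwe = label_clusters(g, rows, ale = ale_union(ma)))
  ev <- evaluate_dataset(ds, clusters, ma, vic, g)
  expect_true(ev$summary$detected)
  expect_identical(ev$summary$true_size, 1L)
  expect_identical(ev$summary$n_spurious, 1L)
  expect_equal(ev$contributions$f1, 0.2 / (1 - 0.8 * 0.9), tolerance = 1e-12)
  # no significant clusters
  ev0 <- evaluate_dataset(ds, list(cfwe = label_clusters(g, integer())),
                          ma, vic, g)
  expect_false(ev0$summary$detected)
  expect_identical(ev0$summary$n_spurious, 0L)
  expect_null(ev0$contributions)
})

test_that("aggregation computes sensitivity, spurious rate and pooled contributions", {
  summaries <- data.frame(
    method = "cfwe", n_total = rep(c(10L, 20L), each = 5),
    n_signal = 0L, stratum_subjects = NA_character_,
    stratum_foci = NA_character_,
    detected = c(rep(c(TRUE, FALSE), c(3, 2)), rep(c(TRUE, FALSE), c(4, 1))),
    true_size = c(5L, 6L, 7L, 0L, 0L, 2L, 2L, 2L, 2L, 0L),
    n_spurious = c(1L, 0L, 0L, 0L, 0L, rep(0L, 5)))
  contribs <- data.frame(method = "cfwe", n_total = 10L, n_signal = 0L,
                         stratum_subjects = NA_character_,
                         stratum_foci = NA_character_, cluster = 1L,
                         size = 3L, f1 = 0.6, f2 = 0.9)
  tab <- aggregate_outcomes(summaries, contribs)
  r10 <- tab[tab$n_total == 10, ]
  expect_equal(r10$sensitivity, 0.6)
  expect_equal(r10$spurious_rate, 0.2)
  expect_equal(r10$mean_true_size, 6)
  expect_equal(r10$mean_f1, 0.6)
  r20 <- tab[tab$n_total == 20, ]
  expect_equal(r20$sensitivity, 0.8)
  expect_true(is.na(r20$mean_f1))  # no spurious clusters: undefined
})
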