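test_that("zero displacement reproduces the true location exactly", {
  g <- make_synthetic_mask(voxel_mm = 4)
  truth <- ground_truth(displacement_sd = 0)
  expect_equal(displaced_true_focus(truth, g), c(-30, -26, 58))
})

test_that("displacement has the configured per-axis spread and stays in the mask", {
  # fine 1 mm grid so voxel snapping barely distorts the spread
  g <- make_synthetic_mask(voxel_mm = 1, semi_axes = c(20, 20, 20),
                           center = c(-30, -26, 58))
  truth <- ground_truth(displacement_sd = 2)
  set.seed(4)
  draws <- t(replicate(4000, displaced_true_focus(truth, g)))
  expect_true(all(alesim:::in_mask(g, draws)))
  offs <- sweep(draws, 2, c(-30, -26, 58), "-")
  snap_var <- 1 / 12  # variance added by snapping to 1 mm voxel centers
  for (ax in 1:3)
    expect_equal(sd(offs[, ax]), sqrt(4 + snap_var), tolerance = 0.05)
})

test_that("signal experiments carry the displaced truth as their first focus", {
  g <- make_synthetic_mask(voxel_mm = 4)
  set.seed(7)
  ds <- simulate_dataset(20, 3, g, truth = ground_truth(displacement_sd = 0))
  sig <- vapply(ds$experiments, function(e) e$is_signal, logical(1))
  expect_identical(sum(sig), 3L)
  for (e in ds$experiments[sig])
    expect_equal(unname(e$foci[1, ]), c(-30, -26, 58))
  for (e in ds$experiments)
    expect_true(all(alesim:::in_mask(g, e$foci)))
  # foci count drawn k -> experiment has exactly k rows (vacuous by
  # construction, checked via the sampler support)
  nf <- vapply(ds$experiments, function(e) nrow(e$foci), integer(1))
  expect_true(all(nf >= 1 & nf <= 75))
  ns <- vapply(ds$experiments, function(e) e$n_subjects, integer(1))
  expect_true(all(ns >= 2 & ns <= 479))
})

test_that("dataset constraints are enforced", {
  g <- make_synthetic_mask(voxel_mm = 4)
  expect_error(simulate_dataset(10, 11, g), "n_signal")
  expect_error(simulate_dataset(0, 0, g), "n_total")
  set.seed(1)
  ds <- simulate_dataset(15, 0, g)
  expect_identical(ds$n_signal, 0L)
  expect_false(any(vapply(ds$experiments, function(e) e$is_signal, logical(1))))
})

test_that("stratified datasets restrict both samplers to their quartile bins", {
  g <- make_synthetic_mask(voxel_mm = 4)
  set.seed(2)
  ds <- simulate_dataset(10, 0, g,
                         stratum = list(subjects = "low", foci = "high"))
  ns <- vapply(ds$experiments, function(e) e$n_subjects, integer(1))
  nf <- vapply(ds$experiments, function(e) nrow(e$foci), integer(1))
  expect_true(all(ns >= 2 & ns <= 13))
  expect_true(all(nf >= 9 & nf <= 75))
})

test_that("condition grids enumerate the documented ranges", {
  main <- enumerate_grid("main", replicates = 500)
  expect_identical(nrow(main), 31L * 11L)  # 341 conditions
  expect_true(any(main$n_total == 15 & main$n_signal == 0))
  expect_true(any(main$n_total == 45 & main$n_signal == 10))
  q <- enumerate_grid("quantile", replicates = 10)
  expect_identical(nrow(q), 16L * 26L)
  expect_true(all(q$n_signal == 0))
  expect_identical(length(unique(paste(q$stratum_subjects, q$stratum_foci))),
                   16L)
  s <- enumerate_grid("small", replicates = 10)
  expect_identical(s$n_total, 5:15)
  expect_error(enumerate_grid("huge"))
  expect_error(enumerate_grid("main", replicates = 0), "replicates")
})

test_that("foci tables round-trip losslessly", {
  g <- make_synthetic_mask(voxel_mm = 4)
  set.seed(3)
  ds <- simulate_dataset(8, 2, g)
  f <- tempfile(fileext = ".tsv")
  write_foci_table(ds, f)
  back <- read_foci_table(f)
  expect_identical(back$n_total, ds$n_total)
  expect_identical(back$n_signal, ds$n_signal)
  for (i in seq_along(ds$experiments)) {
    expect_identical(back$experiments[[i]]$n_subjects,
                     ds$experiments[[i]]$n_subjects)
    expect_equal(back$experiments[[i]]$foci, ds$experiments[[i]]$foci)
    expect_identical(back$experiments[[i]]$is_signal,
                     ds$experiments[[i]]$is_signal)
  }
})
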