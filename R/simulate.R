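#' Ground-truth effect description
#'
#' The simulated "true" effect: a location in the left primary motor cortex
#' at MNI (-30, -26, 58), around which signal experiments report a focus
#' displaced by an isotropic Gaussian of per-axis SD `displacement_sd`.
#'
#' @param location World-mm coordinates of the true effect.
#' @param displacement_sd Per-axis SD (mm) of the displacement applied to
#'   the reported coordinate; must be `>= 0`. The default is a 10 mm FWHM
#'   spread (`10 / (2 * sqrt(2 * log(2)))`, about 4.25 mm), the
#'   displacement convention of the simulation lineage this design follows.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(location = c(-30, -26, 58),
                         displacement_sd = 10 / (2 * sqrt(2 * log(2)))) {
  stopifnot(length(location) == 3, displacement_sd >= 0)
  structure(list(location = location, displacement_sd = displacement_sd),
            class = "ground_truth")
}

#' Displaced true-effect focus
#'
#' Adds an isotropic Gaussian offset (per-axis SD `truth$displacement_sd`)
#' to the true location and snaps the result to the nearest mask voxel
#' center, resampling the offset in the rare case that it leaves the mask.
#' With zero displacement the true location itself is returned.
#'
#' @param truth A [ground_truth()] object; its location must lie in the mask.
#' @param grid A `voxel_grid`.
#' @return World-mm coordinate (length-3 vector) of a mask voxel center.
#' @export
displaced_true_focus <- function(truth, grid) {
  if (!in_mask(grid, truth$location))
    stop("ground-truth location is not a mask voxel center")
  if (truth$displacement_sd == 0) {
    return(voxel_to_world(grid, world_to_voxel(grid, truth$location)))
  }
  repeat {
    cand <- truth$location + rnorm(3, 0, truth$displacement_sd)
    idx <- round((cand - grid$origin) / grid$voxel_mm) + 1
    if (any(idx < 1) || any(idx > grid$dim)) next
    snapped <- grid$origin + (idx - 1) * grid$voxel_mm
    if (in_mask(grid, snapped)) return(snapped)
  }
}

#' Simulate one experiment
#'
#' Draws the experiment's subject count and foci count from the calibrated
#' samplers, samples that many focus coordinates uniformly from the
#' gray-matter mask and — for signal experiments — replaces the first focus
#' by a displaced copy of the true location.
#'
#' @param id Experiment identifier.
#' @param subject_sampler,foci_sampler [make_count_sampler()] objects.
#' @param grid A `voxel_grid`.
#' @param signal Logical: does this experiment carry the true effect?
#' @param truth A [ground_truth()] object (required when `signal`).
#' @return An object of class `experiment`: list with `id`, `n_subjects`,
#'   `foci` (k x 3 matrix of world mm) and `is_signal`.
#' @export
simulate_experiment <- function(id, subject_sampler, foci_sampler, grid,
                                signal = FALSE, truth = ground_truth()) {
  n_subjects <- sample_counts(subject_sampler, 1)
  n_foci <- sample_counts(foci_sampler, 1)
  foci <- sample_uniform_focus(grid, n_foci)
  if (signal) foci[1, ] <- displaced_true_focus(truth, grid)
  structure(list(id = id, n_subjects = n_subjects, foci = foci,
                 is_signal = isTRUE(signal)),
            class = "experiment")
}

#' Simulate a dataset of experiments
#'
#' Builds `n_total` experiments of which the first `n_signal` report a focus
#' in the vicinity of the true location (experiment labels are exchangeable,
#' so taking the first `n_signal` is without loss of generality). When a
#' stratum is given, both samplers are restricted to the corresponding
#' quartile ranges before sampling.
#'
#' @param n_total Number of experiments (`>= 1`).
#' @param n_signal Number of signal experiments (`0 <= n_signal <= n_total`).
#' @param grid A `voxel_grid`.
#' @param subject_sampler,foci_sampler Calibrated samplers; defaults are the
#'   BrainMap-VBM-calibrated ones.
#' @param truth A [ground_truth()] object.
#' @param stratum Optional list/row with elements `subjects` and `foci`, each
#'   a stratum category (see [stratum_range()]).
#' @param seed Optional integer seed (stored with the dataset).
#' @return An object of class `simulated_dataset`.
#' @export
simulate_dataset <- function(n_total, n_signal = 0, grid,
                             subject_sampler = vbm_subject_sampler(),
                             foci_sampler = vbm_foci_sampler(),
                             truth = ground_truth(),
                             stratum = NULL, seed = NULL) {
  if (n_total < 1) stop("n_total must be >= 1")
  if (n_signal < 0 || n_signal > n_total)
    stop("n_signal must lie in [0, n_total]")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(stratum)) {
    subject_sampler <- make_count_sampler(
      subject_sampler$anchors, subject_sampler$target_mean,
      subject_sampler$target_sd, subject_sampler$tie_mass,
      support = stratum_range("subjects", stratum$subjects, subject_sampler$anchors))
    foci_sampler <- make_count_sampler(
      foci_sampler$anchors, foci_sampler$target_mean,
      foci_sampler$target_sd, foci_sampler$tie_mass,
      support = stratum_range("foci", stratum$foci, foci_sampler$anchors))
  }
  exps <- lapply(seq_len(n_total), function(i)
    simulate_experiment(i, subject_sampler, foci_sampler, grid,
                        signal = i <= n_signal, truth = truth))
  structure(list(experiments = exps, n_total = as.integer(n_total),
                 n_signal = as.integer(n_signal),
                 stratum = stratum, seed = seed, truth = truth),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset: %d experiments (%d signal)%s\n",
              x$n_total, x$n_signal,
              if (is.null(x$stratum)) "" else
                sprintf(", stratum %s/%s", x$stratum$subjects, x$stratum$foci)))
  invisible(x)
}

#' Enumerate a study condition grid
#'
#' Expands one of the three condition grids of the validation study:
#' \describe{
#'   \item{main}{dataset sizes 15..45 crossed with 0..10 signal experiments
#'     (341 conditions).}
#'   \item{quantile}{the 16 subject-by-foci quartile strata crossed with
#'     dataset sizes 5..30, pure noise (`n_signal = 0`).}
#'   \item{small}{dataset sizes 5..15, pure noise; the small-dataset
#'     addendum to the contribution analysis.}
#' }
#'
#' @param grid_id `"main"`, `"quantile"` or `"small"`.
#' @param replicates Number of datasets per condition (`>= 1`; the full-scale
#'   study uses 500).
#' @return A data.frame of class `study_grid` with columns `n_total`,
#'   `n_signal`, `stratum_subjects`, `stratum_foci`, `replicates`.
#' @export
enumerate_grid <- function(grid_id = c("main", "quantile", "small"),
                           replicates = 500) {
  grid_id <- match.arg(grid_id)
  if (replicates < 1) stop("replicates must be >= 1")
  g <- switch(grid_id,
    main = expand.grid(n_total = 15:45, n_signal = 0:10,
                       stratum_subjects = NA_character_,
                       stratum_foci = NA_character_,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    quantile = {
      s <- strata_grid()
      d <- expand.grid(n_total = 5:30, row = seq_len(nrow(s)),
                       KEEP.OUT.ATTRS = FALSE)
      data.frame(n_total = d$n_total, n_signal = 0L,
                 stratum_subjects = s$subjects[d$row],
                 stratum_foci = s$foci[d$row],
                 stringsAsFactors = FALSE)
    },
    small = data.frame(n_total = 5:15, n_signal = 0L,
                       stratum_subjects = NA_character_,
                       stratum_foci = NA_character_,
                       stringsAsFactors = FALSE))
  g$replicates <- as.integer(replicates)
  attr(g, "grid_id") <- grid_id
  class(g) <- c("study_grid", class(g))
  g
}

#' Dataset export and import as a foci table
#'
#' Writes a dataset as a plain tab-separated table with one row per focus
#' (columns `experiment`, `n_subjects`, `x`, `y`, `z`, `signal`);
#' `read_foci_table()` reconstructs the dataset losslessly (up to the
#' sampler provenance).
#'
#' @param dataset A `simulated_dataset`.
#' @param path File path.
#' @return `write_foci_table()` invisibly returns `path`;
#'   `read_foci_table()` returns a `simulated_dataset`.
#' @export
write_foci_table <- function(dataset, path) {
  rows <- do.call(rbind, lapply(dataset$experiments, function(e) {
    data.frame(experiment = e$id, n_subjects = e$n_subjects,
               x = e$foci[, 1], y = e$foci[, 2], z = e$foci[, 3],
               signal = as.integer(e$is_signal))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_foci_table
#' @export
read_foci_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  ids <- unique(tab$experiment)
  exps <- lapply(ids, function(id) {
    sub <- tab[tab$experiment == id, , drop = FALSE]
    structure(list(id = id, n_subjects = sub$n_subjects[1],
                   foci = unname(as.matrix(sub[, c("x", "y", "z")])),
                   is_signal = sub$signal[1] == 1L),
              class = "experiment")
  })
  n_signal <- sum(vapply(exps, function(e) e$is_signal, logical(1)))
  structure(list(experiments = exps, n_total = length(exps),
                 n_signal = as.integer(n_signal),
                 stratum = NULL, seed = NULL, truth = ground_truth()),
            class = "simulated_dataset")
}
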