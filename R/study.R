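#' Study configuration
#'
#' Bundles every tunable of the simulation-validation pipeline. The defaults
#' are the desk-scale conditions: a 4 mm synthetic mask, 100 Monte-Carlo
#' max-statistic iterations, alpha .05, cluster-forming p .001, and the
#' BrainMap-VBM-calibrated samplers. `voxel_mm = 2` with
#' `mc_iterations = 10000` reproduces the faithful settings.
#'
#' @param conditions Data.frame of conditions with columns `n_total`,
#'   `n_signal` and optionally `stratum_subjects` / `stratum_foci` (see
#'   [enumerate_grid()]), or a grid id string passed to [enumerate_grid()].
#' @param replicates Datasets per condition.
#' @param voxel_mm Grid resolution in mm.
#' @param mc_iterations Monte-Carlo iterations for the max-statistic null.
#' @param alpha Family-wise error level.
#' @param p_cf Cluster-forming voxel-level probability.
#' @param displacement_sd Per-axis SD (mm) of the true-focus displacement.
#' @param methods Thresholding methods to run: subset of
#'   `c("vfwe", "cfwe", "uncorrected")`.
#' @param connectivity Cluster connectivity (6, 18, 26).
#' @param bin_width Voxel-null histogram bin width.
#' @param seed Master seed; per-dataset seeds are derived from it,
#'   independent of scheduling order.
#' @param jobs Number of parallel workers (forked; results are
#'   worker-count-invariant).
#' @param out_dir Optional output directory for condition checkpoints,
#'   result tables and the run manifest.
#' @param subject_sampler,foci_sampler Calibrated samplers.
#' @param grid Optional pre-built `voxel_grid` (default: synthetic mask at
#'   `voxel_mm`).
#' @return An object of class `study_config`.
#' @export
study_config <- function(conditions = "main", replicates = 500,
                         voxel_mm = 4, mc_iterations = 100,
                         alpha = 0.05, p_cf = 0.001,
                         displacement_sd = 10 / (2 * sqrt(2 * log(2))),
                         methods = c("vfwe", "cfwe"), connectivity = 26,
                         bin_width = 1e-5, seed = 1L, jobs = 1L,
                         out_dir = NULL,
                         subject_sampler = vbm_subject_sampler(),
                         foci_sampler = vbm_foci_sampler(),
                         grid = NULL) {
  if (is.character(conditions)) conditions <- enumerate_grid(conditions, replicates)
  stopifnot(all(c("n_total", "n_signal") %in% names(conditions)))
  if (!("stratum_subjects" %in% names(conditions)))
    conditions$stratum_subjects <- NA_character_
  if (!("stratum_foci" %in% names(conditions)))
    conditions$stratum_foci <- NA_character_
  if (replicates < 1) stop("replicate count must be >= 1")
  for (p in c(alpha, p_cf)) if (p <= 0 || p >= 1)
    stop("probabilities must lie in (0, 1)")
  if (mc_iterations < 1) stop("mc_iterations must be >= 1")
  methods <- match.arg(methods, c("vfwe", "cfwe", "uncorrected"),
                       several.ok = TRUE)
  structure(list(conditions = conditions, replicates = as.integer(replicates),
                 voxel_mm = voxel_mm, mc_iterations = as.integer(mc_iterations),
                 alpha = alpha, p_cf = p_cf, displacement_sd = displacement_sd,
                 methods = methods, connectivity = as.integer(connectivity),
                 bin_width = bin_width, seed = as.integer(seed),
                 jobs = as.integer(jobs), out_dir = out_dir,
                 subject_sampler = subject_sampler,
                 foci_sampler = foci_sampler, grid = grid),
            class = "study_config")
}

#' Preset study configurations
#'
#' \describe{
#'   \item{desk-null}{Null datasets (sizes 15, 25, 35; 200 replicates) for
#'     alpha-control checks at desk scale.}
#'   \item{desk-contribution-cfwe}{500 null datasets of 23 experiments,
#'     cFWE, for the dominant-contribution criterion.}
#'   \item{desk-contribution-vfwe}{500 null datasets of 14 experiments,
#'     vFWE.}
#'   \item{full-main}{The full 15..45 x 0..10 grid at 500 replicates, 2 mm,
#'     10,000 Monte-Carlo iterations (not desk scale).}
#'   \item{full-quantile}{The 16-stratum homogeneity grid (sizes 5..30).}
#'   \item{full-small}{The small-dataset addendum (sizes 5..15).}
#' }
#'
#' @param name Preset name.
#' @param seed Master seed.
#' @param ... Overrides passed to [study_config()].
#' @return A `study_config`.
#' @export
study_preset <- function(name = c("desk-null", "desk-contribution-cfwe",
                                  "desk-contribution-vfwe", "full-main",
                                  "full-quantile", "full-small"),
                         seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    "desk-null" = list(
      conditions = data.frame(n_total = c(15L, 25L, 35L), n_signal = 0L),
      replicates = 200, methods = c("vfwe", "cfwe")),
    "desk-contribution-cfwe" = list(
      conditions = data.frame(n_total = 23L, n_signal = 0L),
      replicates = 500, methods = "cfwe"),
    "desk-contribution-vfwe" = list(
      conditions = data.frame(n_total = 14L, n_signal = 0L),
      replicates = 500, methods = "vfwe"),
    "full-main" = list(conditions = "main", replicates = 500, voxel_mm = 2,
                        mc_iterations = 10000),
    "full-quantile" = list(conditions = "quantile", replicates = 500,
                            voxel_mm = 2, mc_iterations = 10000,
                            methods = "cfwe"),
    "full-small" = list(conditions = "small", replicates = 500,
                         voxel_mm = 2, mc_iterations = 10000))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(study_config, args)
}

# schedule-independent per-dataset seed: a small multiplicative hash of
# (master seed, condition index, replicate index), kept below 2^31 - 1
derive_seed <- function(master, condition, replicate) {
  h <- (master %% 2147483647) + 1
  for (x in c(condition, replicate, 17L)) {
    h <- (h * 48271 + (x %% 2147483647) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

#' Analyse one dataset with the full ALE pipeline
#'
#' Computes MA maps, the ALE map, the analytic voxel null, the Monte-Carlo
#' max-statistic null (when an FWE method is requested) and the requested
#' thresholded cluster sets.
#'
#' @param dataset A `simulated_dataset`.
#' @param grid A `voxel_grid`.
#' @param spec A [kernel_spec()].
#' @param methods Subset of `c("vfwe", "cfwe", "uncorrected")`.
#' @param alpha,p_cf,mc_iterations,connectivity,bin_width See
#'   [study_config()].
#' @return List with `ma`, `ale`, `vnull`, `msnull` (or `NULL`) and
#'   `clusters` (named list of `cluster_set`s).
#' @export
analyze_dataset <- function(dataset, grid, spec = kernel_spec(),
                            methods = c("vfwe", "cfwe"), alpha = 0.05,
                            p_cf = 0.001, mc_iterations = 100,
                            connectivity = 26, bin_width = 1e-5) {
  ma <- ma_matrix(dataset, grid, spec)
  ale <- ale_union(ma)
  vnull <- voxel_null(ma, bin_width)
  cutoff <- cluster_forming_cutoff(vnull, p_cf)
  msnull <- NULL
  if (any(c("vfwe", "cfwe") %in% methods))
    msnull <- max_stat_null(dataset, grid, spec, cutoff, mc_iterations,
                            connectivity)
  clusters <- list()
  for (m in methods) {
    clusters[[m]] <- switch(m,
      vfwe = threshold_vfwe(ale, msnull, grid, alpha, connectivity),
      cfwe = threshold_cfwe(ale, vnull, msnull, grid, alpha, p_cf,
                            connectivity),
      uncorrected = threshold_uncorrected(ale, vnull, grid, p_cf,
                                          connectivity))
  }
  list(ma = ma, ale = ale, vnull = vnull, msnull = msnull,
       clusters = clusters)
}

run_condition <- function(ci, config, grid, spec, vic) {
  cond <- config$conditions[ci, ]
  stratum <- if (!is.na(cond$stratum_subjects))
    list(subjects = cond$stratum_subjects, foci = cond$stratum_foci) else NULL
  truth <- ground_truth(displacement_sd = config$displacement_sd)
  one <- function(rep) {
    seed <- derive_seed(config$seed, ci, rep)
    set.seed(seed)
    ds <- simulate_dataset(cond$n_total, cond$n_signal, grid,
                           config$subject_sampler, config$foci_sampler,
                           truth, stratum = stratum)
    ds$seed <- seed
    an <- analyze_dataset(ds, grid, spec, config$methods, config$alpha,
                          config$p_cf, config$mc_iterations,
                          config$connectivity, config$bin_width)
    ev <- evaluate_dataset(ds, an$clusters, an$ma, vic, grid)
    ev$summary$replicate <- rep
    if (!is.null(ev$contributions)) ev$contributions$replicate <- rep
    ev
  }
  reps <- seq_len(config$replicates)
  res <- if (config$jobs > 1)
    parallel::mclapply(reps, one, mc.cores = config$jobs,
                       mc.preschedule = TRUE) else lapply(reps, one)
  list(summary = do.call(rbind, lapply(res, `[[`, "summary")),
       contributions = {
         cc <- Filter(Negate(is.null), lapply(res, `[[`, "contributions"))
         if (length(cc)) do.call(rbind, cc) else NULL
       })
}

#' Run a full simulation-validation study
#'
#' Orchestrates dataset simulation, ALE analysis, inference and evaluation
#' over all conditions of the configuration. Per-dataset seeds are derived
#' from the master seed and the (condition, replicate) labels, so results
#' are identical across reruns and worker counts. When `out_dir` is set,
#' per-condition records are checkpointed as tab-separated files and reused
#' on rerun, and a JSON run manifest is written.
#'
#' @param config A [study_config()].
#' @return List of class `study_result` with `summaries` (one row per
#'   dataset and method), `contributions` (one row per spurious cluster),
#'   `tables` (condition-level aggregate from [aggregate_outcomes()]) and
#'   `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  grid <- if (is.null(config$grid)) make_synthetic_mask(config$voxel_mm)
          else config$grid
  spec <- kernel_spec()
  vic <- vicinity()
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "checkpoints"), recursive = TRUE,
               showWarnings = FALSE)
    manifest <- list(
      seed = config$seed, replicates = config$replicates,
      voxel_mm = config$voxel_mm, mc_iterations = config$mc_iterations,
      alpha = config$alpha, p_cf = config$p_cf,
      displacement_sd = config$displacement_sd, methods = config$methods,
      connectivity = config$connectivity, bin_width = config$bin_width,
      n_conditions = nrow(config$conditions),
      package_version = as.character(utils::packageVersion("alesim")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  summaries <- list()
  contributions <- list()
  for (ci in seq_len(nrow(config$conditions))) {
    sum_file <- if (!is.null(out_dir))
      file.path(out_dir, "checkpoints", sprintf("cond_%04d_summary.tsv", ci))
    con_file <- if (!is.null(out_dir))
      file.path(out_dir, "checkpoints", sprintf("cond_%04d_contrib.tsv", ci))
    strat_cols <- c(stratum_subjects = "character", stratum_foci = "character")
    if (!is.null(out_dir) && file.exists(sum_file)) {
      summaries[[ci]] <- read.table(sum_file, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    colClasses = strat_cols)
      contributions[[ci]] <- if (file.exists(con_file))
        read.table(con_file, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = strat_cols) else NULL
      next
    }
    res <- run_condition(ci, config, grid, spec, vic)
    summaries[[ci]] <- res$summary
    contributions[[ci]] <- res$contributions
    if (!is.null(out_dir)) {
      write.table(res$summary, sum_file, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      if (!is.null(res$contributions))
        write.table(res$contributions, con_file, sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
  }
  summaries <- do.call(rbind, summaries)
  cc <- Filter(Negate(is.null), contributions)
  contributions <- if (length(cc)) do.call(rbind, cc) else NULL
  tables <- aggregate_outcomes(summaries, contributions)
  if (!is.null(out_dir))
    write.table(tables, file.path(out_dir, "condition_tables.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(summaries = summaries, contributions = contributions,
                 tables = tables, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study result: %d dataset-method records, %d conditions\n",
              nrow(x$summaries), nrow(x$tables)))
  invisible(x)
}

#' Smallest dataset size meeting a contribution criterion
#'
#' Given a curve of mean dominant-experiment contribution (`f1`) versus
#' dataset size, returns the smallest size whose mean contribution falls
#' strictly below the criterion (default 50%), or `NA` if the curve never
#' reaches it.
#'
#' @param curve Data.frame with columns `n_total` (or `size`) and `mean_f1`
#'   (or `f1`).
#' @param criterion Contribution threshold (default 0.5).
#' @return Integer size or `NA_integer_`.
#' @export
derive_minimum_size <- function(curve, criterion = 0.5) {
  size <- curve[[intersect(c("n_total", "size"), names(curve))[1]]]
  f1 <- curve[[intersect(c("mean_f1", "f1"), names(curve))[1]]]
  if (is.null(size) || is.null(f1) || !length(size))
    stop("empty curve: need size and f1 columns")
  ok <- !is.na(f1) & f1 < criterion
  if (!any(ok)) return(NA_integer_)
  as.integer(min(size[ok]))
}
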