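#' ALE spatial-uncertainty kernel specification
#'
#' The ALE kernel models the spatial uncertainty of a reported focus as an
#' isotropic 3-D Gaussian whose width shrinks with the number of subjects.
#' Two Euclidean-distance uncertainty components are combined: a
#' between-subject component (default 11.6 mm, scaled by `1/sqrt(n)`) and a
#' between-template component (default 5.7 mm). Each is converted to a
#' per-axis SD by dividing by `2 * sqrt(2 / pi)` (the mean Euclidean
#' displacement of an isotropic trivariate Gaussian with unit per-axis SD),
#' following the reference ALE implementation lineage.
#'
#' @param subject_uncertainty Between-subject Euclidean-distance uncertainty
#'   in mm.
#' @param template_uncertainty Between-template Euclidean-distance
#'   uncertainty in mm.
#' @param truncate_sd Kernel truncation radius in SD units (default 5;
#'   truncation error below 1e-6 of kernel mass).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(subject_uncertainty = 11.6,
                        template_uncertainty = 5.7,
                        truncate_sd = 5) {
  stopifnot(subject_uncertainty > 0, template_uncertainty > 0, truncate_sd > 0)
  structure(list(subject_uncertainty = subject_uncertainty,
                 template_uncertainty = template_uncertainty,
                 truncate_sd = truncate_sd),
            class = "kernel_spec")
}

#' Per-axis Gaussian SD of the ALE kernel
#'
#' `sd = sqrt(sd_template^2 + sd_subject^2 / n)` with each component equal
#' to its Euclidean-distance constant divided by `2 * sqrt(2 / pi)`. The SD
#' is strictly decreasing in `n` and tends to the template-only component as
#' `n` grows.
#'
#' @param spec A [kernel_spec()].
#' @param n_subjects Number of subjects (`>= 1`).
#' @return Kernel SD in mm.
#' @export
kernel_sd <- function(spec, n_subjects) {
  if (any(n_subjects < 1)) stop("n_subjects must be >= 1")
  conv <- 2 * sqrt(2 / pi)
  sqrt((spec$template_uncertainty / conv)^2 +
         (spec$subject_uncertainty / conv)^2 / n_subjects)
}

# Discrete kernel lookup table on the voxel lattice: integer offsets within
# truncate_sd * sd and Gaussian weights normalised to unit total mass, so a
# kernel value is the modeled probability that the true signal lies in that
# voxel. Cached per (n, voxel size, constants).
.kernel_cache <- new.env(parent = emptyenv())

ale_kernel <- function(spec, n_subjects, voxel_mm) {
  key <- sprintf("%g|%g|%g|%g|%d", spec$subject_uncertainty,
                 spec$template_uncertainty, spec$truncate_sd, voxel_mm,
                 as.integer(n_subjects))
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  sd_mm <- kernel_sd(spec, n_subjects)
  r_vox <- ceiling(spec$truncate_sd * sd_mm / voxel_mm)
  ax <- -r_vox:r_vox
  off <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r2 <- rowSums(off^2) * voxel_mm^2
  keep <- r2 <= (spec$truncate_sd * sd_mm)^2
  off <- off[keep, , drop = FALSE]
  w <- exp(-r2[keep] / (2 * sd_mm^2))
  kern <- list(offsets = unname(off), values = w / sum(w), sd_mm = sd_mm)
  storage.mode(kern$offsets) <- "integer"
  .kernel_cache[[key]] <- kern
  kern
}

# 0-based voxel coordinates of an experiment's foci; error when a focus lies
# outside the grid bounding box
foci_voxels <- function(experiment, grid) {
  idx <- world_to_voxel(grid, experiment$foci)
  idx - 1L
}

#' Modeled-activation (MA) map of one experiment
#'
#' Places the experiment's subject-count-specific Gaussian kernel at each
#' focus and takes the voxelwise maximum over foci (overlapping kernels do
#' not add). Values are probabilities in `[0, 1)` and are exactly zero
#' beyond the truncation radius of every focus.
#'
#' @param experiment An `experiment` (see [simulate_experiment()]).
#' @param grid A `voxel_grid`.
#' @param spec A [kernel_spec()].
#' @return Numeric vector of length `grid$n_mask`.
#' @export
modeled_activation <- function(experiment, grid, spec = kernel_spec()) {
  ma_matrix(list(experiment), grid, spec)[, 1]
}

#' MA maps for all experiments of a dataset
#'
#' @param experiments A list of `experiment` objects or a
#'   `simulated_dataset`.
#' @param grid A `voxel_grid`.
#' @param spec A [kernel_spec()].
#' @return Numeric matrix, `grid$n_mask` rows by one column per experiment.
#' @export
ma_matrix <- function(experiments, grid, spec = kernel_spec()) {
  if (inherits(experiments, "simulated_dataset"))
    experiments <- experiments$experiments
  foci <- lapply(experiments, foci_voxels, grid = grid)
  kerns <- lapply(experiments, function(e)
    ale_kernel(spec, e$n_subjects, grid$voxel_mm)[c("offsets", "values")])
  cpp_ma_matrix(grid$dim, grid$lookup, grid$n_mask, foci, kerns)
}

#' ALE score map: voxelwise union of MA maps
#'
#' `ALE(v) = 1 - prod_i (1 - MA_i(v))`, the probability that at least one
#' experiment's modeled signal lies at the voxel under independence.
#'
#' @param ma_maps A numeric matrix (voxels x experiments, as from
#'   [ma_matrix()]) or a list of equal-length MA vectors.
#' @return Numeric vector of ALE values in `[0, 1)`.
#' @export
ale_union <- function(ma_maps) {
  if (is.list(ma_maps)) {
    if (length(unique(vapply(ma_maps, length, integer(1)))) != 1)
      stop("grid mismatch: MA maps have different lengths")
    ma_maps <- do.call(cbind, ma_maps)
  }
  if (is.null(dim(ma_maps))) ma_maps <- cbind(ma_maps)
  p <- rep(1, nrow(ma_maps))
  for (k in seq_len(ncol(ma_maps))) p <- p * (1 - ma_maps[, k])
  1 - p
}

#' Analytic voxel-level null distribution of the ALE score
#'
#' Under the null of spatial independence, each experiment's MA value at a
#' voxel is an independent draw from the empirical distribution of its MA
#' values over the mask. The null ALE distribution is obtained by
#' discretising each per-experiment MA histogram to bins of `bin_width` and
#' convolving them through the union formula in `(1 - MA)` space
#' (deterministic, no Monte Carlo).
#'
#' @param ma_maps MA matrix or list as in [ale_union()].
#' @param bin_width Histogram bin width in ALE units (default `1e-5`).
#' @return Object of class `voxel_null`: list with `bin_width`, `pmf` (bin
#'   masses, left edges `0, bin_width, ...`) and `tail`
#'   (`tail[b] = P(ALE >= (b-1) * bin_width)`).
#' @export
voxel_null <- function(ma_maps, bin_width = 1e-5) {
  if (is.list(ma_maps)) ma_maps <- do.call(cbind, ma_maps)
  if (is.null(dim(ma_maps))) ma_maps <- cbind(ma_maps)
  pmf <- cpp_voxel_null(ma_maps, bin_width)
  structure(list(bin_width = bin_width, pmf = pmf,
                 tail = rev(cumsum(rev(pmf)))),
            class = "voxel_null")
}

#' @export
print.voxel_null <- function(x, ...) {
  cat(sprintf("voxel null: %d bins of width %g, P(ALE > 0) = %.4g\n",
              length(x$pmf), x$bin_width, 1 - x$pmf[1]))
  invisible(x)
}

#' Cluster-forming ALE cutoff at an uncorrected voxel-level p
#'
#' The smallest histogram bin edge whose tail probability does not exceed
#' `p` (conservative under discretisation); voxels with ALE strictly above
#' the cutoff are suprathreshold.
#'
#' @param null A [voxel_null()] object.
#' @param p Uncorrected voxel-level probability (default 0.001).
#' @return ALE score cutoff.
#' @export
cluster_forming_cutoff <- function(null, p = 0.001) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  tail <- c(null$tail, 0)  # one bin past the maximum: tail 0
  b <- which(tail <= p)[1]
  (b - 1) * null$bin_width
}

#' Monte-Carlo max-statistic null for FWE correction
#'
#' Per iteration, every experiment's foci are redrawn uniformly over the
#' mask (keeping its subject count and foci count), the ALE map is
#' recomputed, and the maximum ALE score and the maximum size of connected
#' components above the cluster-forming cutoff are recorded.
#'
#' @param dataset A `simulated_dataset` (only subject and foci counts are
#'   used).
#' @param grid A `voxel_grid`.
#' @param spec A [kernel_spec()].
#' @param cf_cutoff Cluster-forming ALE cutoff (from
#'   [cluster_forming_cutoff()]).
#' @param iterations Number of Monte-Carlo iterations (`>= 1`; 10,000 for
#'   faithful runs, 100 for desk-scale presets).
#' @param connectivity Voxel neighbourhood: 6, 18 or 26 (default).
#' @return Object of class `max_stat_null`: list with numeric `max_ale` and
#'   integer `max_cluster`, each of length `iterations`.
#' @export
max_stat_null <- function(dataset, grid, spec = kernel_spec(), cf_cutoff,
                          iterations = 100, connectivity = 26) {
  exps <- if (inherits(dataset, "simulated_dataset")) dataset$experiments else dataset
  kerns <- lapply(exps, function(e)
    ale_kernel(spec, e$n_subjects, grid$voxel_mm)[c("offsets", "values")])
  n_foci <- vapply(exps, function(e) nrow(e$foci), integer(1))
  res <- cpp_max_stat_null(grid$dim, grid$mask_vox, grid$lookup, kerns,
                           n_foci, as.integer(iterations), cf_cutoff,
                           as.integer(connectivity))
  structure(list(max_ale = res[, 1], max_cluster = as.integer(res[, 2]),
                 iterations = as.integer(iterations)),
            class = "max_stat_null")
}

# conservative empirical FWE quantile: the ceil((1 - alpha) * N)-th order
# statistic; significance uses strict ">"
fwe_quantile <- function(samples, alpha) {
  sort(samples)[ceiling((1 - alpha) * length(samples))]
}

# assemble a cluster_set from suprathreshold mask-voxel rows (1-based)
make_cluster_set <- function(rows, ale, grid, connectivity) {
  if (length(rows) == 0) {
    return(structure(list(
      clusters = data.frame(id = integer(), size = integer(),
                            peak_ale = numeric(), peak_x = numeric(),
                            peak_y = numeric(), peak_z = numeric()),
      members = list(), connectivity = connectivity), class = "cluster_set"))
  }
  labels <- cpp_label_components(grid$mask_vox[rows, , drop = FALSE],
                                 grid$dim, as.integer(connectivity))
  ids <- sort(unique(labels))
  members <- lapply(ids, function(l) rows[labels == l])
  info <- do.call(rbind, lapply(seq_along(ids), function(i) {
    m <- members[[i]]
    pk <- m[which.max(ale[m])]
    w <- grid$origin + grid$mask_vox[pk, ] * grid$voxel_mm
    data.frame(id = i, size = length(m), peak_ale = max(ale[m]),
               peak_x = w[1], peak_y = w[2], peak_z = w[3])
  }))
  structure(list(clusters = info, members = members,
                 connectivity = connectivity), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d cluster(s)\n", nrow(x$clusters)))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Connected-component labelling of a voxel set
#'
#' @param grid A `voxel_grid`.
#' @param rows 1-based mask-voxel row indices forming the binary set.
#' @param ale ALE values used for peak reporting (defaults to zeros).
#' @param connectivity 6, 18 or 26 (default).
#' @return A `cluster_set`: per-cluster table (id, size, peak ALE, peak mm)
#'   plus member voxel indices.
#' @export
label_clusters <- function(grid, rows, ale = NULL, connectivity = 26) {
  if (is.null(ale)) ale <- numeric(grid$n_mask)
  make_cluster_set(as.integer(rows), ale, grid, connectivity)
}

#' Voxel-level FWE thresholding
#'
#' Keeps voxels whose ALE score strictly exceeds the empirical
#' `(1 - alpha)` quantile (conservative order statistic) of the Monte-Carlo
#' max-ALE null, and returns their connected components.
#'
#' @param ale ALE map (vector over mask voxels).
#' @param null A [max_stat_null()].
#' @param alpha Family-wise error level in (0, 1), default 0.05.
#' @param grid A `voxel_grid`.
#' @param connectivity 6, 18 or 26.
#' @return A `cluster_set`.
#' @export
threshold_vfwe <- function(ale, null, grid, alpha = 0.05, connectivity = 26) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (length(null$max_ale) < 1) stop("empty max-statistic null")
  thr <- fwe_quantile(null$max_ale, alpha)
  make_cluster_set(which(ale > thr), ale, grid, connectivity)
}

#' Cluster-level FWE thresholding
#'
#' Forms clusters of voxels with ALE above the cluster-forming cutoff
#' (voxel-level `p_cf`, default 0.001, from the analytic voxel null) and
#' keeps those whose size strictly exceeds the empirical `(1 - alpha)`
#' quantile of the Monte-Carlo max-cluster-size null.
#'
#' @inheritParams threshold_vfwe
#' @param vnull A [voxel_null()].
#' @param p_cf Cluster-forming voxel-level probability.
#' @return A `cluster_set` of the surviving clusters.
#' @export
threshold_cfwe <- function(ale, vnull, null, grid, alpha = 0.05,
                           p_cf = 0.001, connectivity = 26) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cutoff <- cluster_forming_cutoff(vnull, p_cf)
  cs <- make_cluster_set(which(ale > cutoff), ale, grid, connectivity)
  if (nrow(cs$clusters) == 0) return(cs)
  size_thr <- fwe_quantile(null$max_cluster, alpha)
  keep <- cs$clusters$size > size_thr
  cs$clusters <- cs$clusters[keep, , drop = FALSE]
  cs$members <- cs$members[keep]
  if (nrow(cs$clusters)) cs$clusters$id <- seq_len(nrow(cs$clusters))
  cs
}

#' Uncorrected thresholding
#'
#' All connected components of voxels with ALE above the cluster-forming
#' cutoff at uncorrected voxel-level `p`, with no size filter.
#'
#' @inheritParams threshold_cfwe
#' @param p Uncorrected voxel-level probability (default 0.001).
#' @return A `cluster_set`.
#' @export
threshold_uncorrected <- function(ale, vnull, grid, p = 0.001,
                                  connectivity = 26) {
  cutoff <- cluster_forming_cutoff(vnull, p)
  make_cluster_set(which(ale > cutoff), ale, grid, connectivity)
}

#' Write a cluster table as tab-separated text
#'
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_cluster_table <- function(clusters, path) {
  write.table(clusters$clusters, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
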