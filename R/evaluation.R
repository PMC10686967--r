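#' Detection vicinity around the ground-truth location
#'
#' A cluster counts as a true-location detection when any of its voxels lies
#' within an axis-aligned box of `half_width` mm per axis around the center
#' (default 4 mm, i.e. 2 voxels at 2 mm resolution). A Euclidean-ball
#' variant is available but non-default.
#'
#' @param center World-mm center, default the canonical true location.
#' @param half_width Half-width in mm per axis (> 0).
#' @param shape `"box"` (default) or `"ball"`.
#' @return An object of class `vicinity`.
#' @export
vicinity <- function(center = c(-30, -26, 58), half_width = 4,
                     shape = c("box", "ball")) {
  stopifnot(half_width > 0, length(center) == 3)
  structure(list(center = center, half_width = half_width,
                 shape = match.arg(shape)), class = "vicinity")
}

#' Split clusters into true-location and spurious clusters
#'
#' @param clusters A `cluster_set`.
#' @param vic A [vicinity()].
#' @param grid A `voxel_grid`.
#' @return List with integer cluster indices `true_idx` and `spurious_idx`.
#' @export
classify_clusters <- function(clusters, vic, grid) {
  n <- nrow(clusters$clusters)
  if (n == 0) return(list(true_idx = integer(), spurious_idx = integer()))
  hits <- vapply(clusters$members, function(m) {
    w <- sweep(grid$mask_vox[m, , drop = FALSE] * grid$voxel_mm, 2,
               grid$origin, "+")
    d <- sweep(w, 2, vic$center, "-")
    if (vic$shape == "box") any(apply(abs(d) <= vic$half_width + 1e-9, 1, all))
    else any(rowSums(d^2) <= vic$half_width^2 + 1e-9)
  }, logical(1))
  list(true_idx = which(hits), spurious_idx = which(!hits))
}

#' Dominant-experiment contribution profile of a cluster
#'
#' For each voxel of the cluster the experiments' MA values are sorted in
#' decreasing order and combined by the cumulative union
#' `1 - prod(1 - MA)`; the fraction `f_k(v)` is the partial union of the
#' `k` most dominant experiments divided by the full ALE value. The profile
#' is the voxel average of these fractions: `f_1` is the share of the
#' single most dominant experiment, `f_2` of the top two, and `f_K = 1`
#' exactly.
#'
#' @param members 1-based mask-voxel rows of the cluster (or a single
#'   cluster's entry of `cluster_set$members`).
#' @param ma_maps MA matrix (voxels x experiments, [ma_matrix()]).
#' @return Numeric vector `f` of length `ncol(ma_maps)`, non-decreasing with
#'   `f[K] = 1`.
#' @export
contribution_profile <- function(members, ma_maps) {
  if (length(members) == 0) stop("cluster is empty")
  sub <- ma_maps[members, , drop = FALSE]
  K <- ncol(sub)
  f <- matrix(0, nrow(sub), K)
  for (v in seq_len(nrow(sub))) {
    s <- sort(sub[v, ], decreasing = TRUE)
    cum <- 1 - cumprod(1 - s)
    ale_v <- cum[K]
    if (ale_v <= 0) stop("ALE value is zero at a cluster voxel")
    f[v, ] <- cum / ale_v
  }
  colMeans(f)
}

#' Evaluate one analysed dataset on the three outcome measures
#'
#' Computes, per thresholding method: whether a significant cluster hit the
#' true-location vicinity (detection), the size of the largest true cluster,
#' the number of spurious clusters, and the contribution profile of every
#' spurious cluster.
#'
#' @param dataset The `simulated_dataset` that was analysed.
#' @param clusters_by_method Named list of `cluster_set`s (e.g. `vfwe`,
#'   `cfwe`, `uncorrected`).
#' @param ma_maps MA matrix of the dataset ([ma_matrix()]).
#' @param vic A [vicinity()].
#' @param grid A `voxel_grid`.
#' @return List with `summary` (one data.frame row per method: `method`,
#'   `n_total`, `n_signal`, `detected`, `true_size`, `n_spurious`) and
#'   `contributions` (one row per spurious cluster: `method`, `cluster`,
#'   `size`, `f1`, `f2`).
#' @export
evaluate_dataset <- function(dataset, clusters_by_method, ma_maps, vic, grid) {
  summaries <- list()
  contribs <- list()
  strat_s <- if (is.null(dataset$stratum)) NA_character_ else dataset$stratum$subjects
  strat_f <- if (is.null(dataset$stratum)) NA_character_ else dataset$stratum$foci
  for (method in names(clusters_by_method)) {
    cs <- clusters_by_method[[method]]
    cls <- classify_clusters(cs, vic, grid)
    true_size <- if (length(cls$true_idx))
      max(cs$clusters$size[cls$true_idx]) else 0L
    summaries[[method]] <- data.frame(
      method = method, n_total = dataset$n_total, n_signal = dataset$n_signal,
      stratum_subjects = strat_s, stratum_foci = strat_f,
      detected = length(cls$true_idx) > 0, true_size = as.integer(true_size),
      n_spurious = length(cls$spurious_idx), stringsAsFactors = FALSE)
    if (length(cls$spurious_idx)) {
      prof <- lapply(cls$spurious_idx, function(i)
        contribution_profile(cs$members[[i]], ma_maps))
      contribs[[method]] <- data.frame(
        method = method, n_total = dataset$n_total,
        n_signal = dataset$n_signal,
        stratum_subjects = strat_s, stratum_foci = strat_f,
        cluster = cls$spurious_idx,
        size = cs$clusters$size[cls$spurious_idx],
        f1 = vapply(prof, function(p) p[1], numeric(1)),
        f2 = vapply(prof, function(p) p[min(2, length(p))], numeric(1)),
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, unname(summaries)),
       contributions = if (length(contribs)) do.call(rbind, unname(contribs))
                       else NULL)
}

#' Aggregate outcome records over study conditions
#'
#' Per condition and method: sensitivity (fraction of datasets detected),
#' spurious rate (fraction with at least one spurious cluster), mean
#' true-cluster size, and the mean `f1`/`f2` contribution fractions over
#' spurious clusters pooled within the condition, with a normal-approximation
#' 95% confidence band.
#'
#' @param summaries Row-bound `summary` data.frames from
#'   [evaluate_dataset()].
#' @param contributions Row-bound `contributions` data.frames (may be
#'   `NULL`).
#' @param by Grouping columns (default method and condition labels).
#' @return A data.frame, one row per group; contribution columns are `NA`
#'   for groups without spurious clusters.
#' @export
aggregate_outcomes <- function(summaries, contributions = NULL,
                               by = c("method", "n_total", "n_signal",
                                      "stratum_subjects", "stratum_foci")) {
  by <- intersect(by, names(summaries))
  group_key <- function(df, cols) {
    keyed <- lapply(df[cols], function(x) ifelse(is.na(x), "<na>", as.character(x)))
    interaction(keyed, drop = TRUE, lex.order = TRUE)
  }
  groups <- split(summaries, group_key(summaries, by))
  rows <- lapply(groups, function(g) {
    out <- g[1, by, drop = FALSE]
    out$n_datasets <- nrow(g)
    out$sensitivity <- mean(g$detected)
    out$spurious_rate <- mean(g$n_spurious > 0)
    out$mean_true_size <- if (any(g$detected))
      mean(g$true_size[g$detected]) else NA_real_
    out$n_spurious_clusters <- 0L
    out$mean_f1 <- out$f1_lo <- out$f1_hi <- NA_real_
    out$mean_f2 <- NA_real_
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(contributions) && nrow(contributions)) {
    cb <- intersect(by, names(contributions))
    for (g in split(contributions, group_key(contributions, cb))) {
      sel <- rep(TRUE, nrow(tab))
      for (col in cb) sel <- sel & (is.na(tab[[col]]) & is.na(g[[col]][1]) |
                                      !is.na(tab[[col]]) & !is.na(g[[col]][1]) &
                                      tab[[col]] == g[[col]][1])
      if (!any(sel)) next
      n <- nrow(g)
      m1 <- mean(g$f1); se1 <- if (n > 1) sd(g$f1) / sqrt(n) else NA_real_
      tab$n_spurious_clusters[sel] <- n
      tab$mean_f1[sel] <- m1
      tab$f1_lo[sel] <- m1 - qnorm(0.975) * se1
      tab$f1_hi[sel] <- m1 + qnorm(0.975) * se1
      tab$mean_f2[sel] <- mean(g$f2)
    }
  }
  tab
}
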