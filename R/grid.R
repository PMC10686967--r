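#' Masked voxel grid
#'
#' Internal constructor for the masked brain grid shared by all modules. The
#' grid is a regular isotropic lattice in world (MNI-style) millimetre
#' coordinates; `origin` is the world coordinate of voxel index `(1,1,1)`.
#'
#' @param dim Integer vector of length 3 (grid shape).
#' @param voxel_mm Isotropic voxel size in mm (> 0).
#' @param origin World-mm coordinate of the first voxel center.
#' @param mask Logical array of dimension `dim`.
#' @return An object of class `voxel_grid` with precomputed mask index
#'   structures used by the compiled kernels.
#' @keywords internal
new_voxel_grid <- function(dim, voxel_mm, origin, mask) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_mm > 0,
            identical(dim(mask), dim))
  mask_idx <- which(mask)                      # 1-based linear indices
  if (length(mask_idx) < 1) stop("empty mask: no voxels survive")
  ijk <- arrayInd(mask_idx, dim) - 1L          # 0-based voxel coords, V x 3
  lookup <- rep(-1L, prod(dim))
  lookup[mask_idx] <- seq_along(mask_idx) - 1L # 0-based mask row or -1
  structure(list(dim = dim, voxel_mm = voxel_mm, origin = origin,
                 mask = mask, mask_idx = mask_idx, mask_vox = ijk,
                 lookup = lookup, n_mask = length(mask_idx)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %dx%dx%d @ %g mm, origin (%g, %g, %g), %d mask voxels (%.2f L)\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_mm,
              x$origin[1], x$origin[2], x$origin[3], x$n_mask,
              x$n_mask * x$voxel_mm^3 / 1e6))
  invisible(x)
}

# world-mm coordinates of all mask voxel centers (V x 3)
mask_centers <- function(grid) {
  sweep(grid$mask_vox * grid$voxel_mm, 2, grid$origin, "+")
}

#' Synthetic ellipsoidal gray-matter mask
#'
#' Builds a brain-like mask without any external volume: all voxel centers
#' inside an axis-aligned ellipsoid centered at `center`. The default
#' semi-axes (70, 85, 72) mm give a mask volume of roughly 1.8 L, comparable
#' to a lenient (>10% probability) gray-matter mask. The grid is aligned so
#' that `align` — by default the canonical ground-truth location
#' (-30, -26, 58) — falls exactly on a voxel center at any voxel size that
#' divides its offsets.
#'
#' @param voxel_mm Isotropic voxel size in mm (default 4 for desk-scale
#'   simulation; use 2 for the faithful resolution).
#' @param semi_axes Ellipsoid semi-axes in mm (3 positive values).
#' @param center World-mm center of the ellipsoid.
#' @param align World-mm point forced onto a voxel center.
#' @return A `voxel_grid`.
#' @export
make_synthetic_mask <- function(voxel_mm = 4, semi_axes = c(70, 85, 72),
                                center = c(0, 0, 0), align = c(-30, -26, 58)) {
  if (any(semi_axes <= 0)) stop("empty mask: ellipsoid semi-axes must be positive")
  lo <- center - semi_axes
  hi <- center + semi_axes
  # first voxel center: on the lattice through `align`, at or just below lo
  origin <- align - voxel_mm * ceiling((align - lo) / voxel_mm)
  dim <- floor((hi - origin) / voxel_mm) + 1L
  ax <- lapply(1:3, function(d) origin[d] + voxel_mm * (seq_len(dim[d]) - 1L))
  u2 <- lapply(1:3, function(d) ((ax[[d]] - center[d]) / semi_axes[d])^2)
  mask <- outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+") < 1
  if (!any(mask)) stop("empty mask: ellipsoid contains no voxel centers")
  new_voxel_grid(dim, voxel_mm, origin, mask)
}

#' Gray-matter mask from a tissue probability map
#'
#' Reads a NIfTI tissue-probability volume (values in `[0, 1]`), resamples it
#' by nearest neighbour onto an isotropic grid of the requested voxel size,
#' and thresholds it at strictly greater than `gm_threshold` (default 10%
#' gray-matter probability). Nearest-neighbour resampling of probabilities
#' before thresholding avoids smoothing-induced mask growth.
#'
#' @param path Path to a NIfTI volume (`.nii` / `.nii.gz`).
#' @param gm_threshold Probability cutoff; voxels are kept when probability
#'   `> gm_threshold` (strict).
#' @param voxel_mm Target isotropic voxel size in mm.
#' @param align World-mm point forced onto a voxel center (default the
#'   canonical ground-truth location).
#' @return A `voxel_grid`.
#' @export
load_tpm_mask <- function(path, gm_threshold = 0.10, voxel_mm = 2,
                          align = c(-30, -26, 58)) {
  vol <- RNifti::readNifti(path)
  v <- as.array(vol)
  if (length(dim(v)) > 3) v <- array(v, dim(v)[1:3])
  if (min(v, na.rm = TRUE) < -1e-6 || max(v, na.rm = TRUE) > 1 + 1e-6)
    stop("tissue probability volume must have values in [0, 1]")
  v[is.na(v)] <- 0
  # bounding box of the source volume in world mm, via its stored transform
  d <- dim(v)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  wc <- RNifti::voxelToWorld(corners, vol)
  lo <- apply(wc, 2, min); hi <- apply(wc, 2, max)
  origin <- align - voxel_mm * ceiling((align - lo) / voxel_mm)
  ndim <- as.integer(floor((hi - origin) / voxel_mm) + 1)
  centers <- as.matrix(expand.grid(
    origin[1] + voxel_mm * (seq_len(ndim[1]) - 1L),
    origin[2] + voxel_mm * (seq_len(ndim[2]) - 1L),
    origin[3] + voxel_mm * (seq_len(ndim[3]) - 1L)))
  src <- round(RNifti::worldToVoxel(centers, vol))
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] &
        src[, 2] >= 1 & src[, 2] <= d[2] &
        src[, 3] >= 1 & src[, 3] <= d[3]
  prob <- numeric(nrow(src))
  prob[ok] <- v[src[ok, , drop = FALSE]]
  mask <- array(prob > gm_threshold, dim = ndim)
  if (!any(mask)) stop("empty mask: no voxel exceeds the probability threshold")
  new_voxel_grid(ndim, voxel_mm, origin, mask)
}

#' World/voxel coordinate conversion
#'
#' `world_to_voxel()` maps world-mm coordinates to the nearest voxel index
#' (1-based); `voxel_to_world()` maps voxel indices to the world coordinates
#' of their centers. The round trip voxel -> world -> voxel is the identity.
#'
#' @param grid A `voxel_grid`.
#' @param xyz Numeric vector of length 3 or an n x 3 matrix of world-mm
#'   coordinates.
#' @param ijk Integer vector of length 3 or an n x 3 matrix of 1-based voxel
#'   indices.
#' @return An object of the same shape holding voxel indices / world
#'   coordinates. Out-of-grid input is an error.
#' @export
world_to_voxel <- function(grid, xyz) {
  m <- rbind(xyz)
  idx <- round(sweep(m, 2, grid$origin, "-") / grid$voxel_mm) + 1
  if (any(idx < 1) || any(sweep(idx, 2, grid$dim, ">")))
    stop("coordinate outside the grid bounding box")
  storage.mode(idx) <- "integer"
  if (is.null(dim(xyz))) idx[1, ] else idx
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(grid, ijk) {
  m <- rbind(ijk)
  if (any(m < 1) || any(sweep(m, 2, grid$dim, ">")) || any(m != round(m)))
    stop("voxel index outside the grid")
  w <- sweep((m - 1) * grid$voxel_mm, 2, grid$origin, "+")
  if (is.null(dim(ijk))) w[1, ] else w
}

#' Uniform focus sampling from the mask
#'
#' Draws focus locations uniformly over the mask voxels; each returned
#' coordinate is the world center of a mask voxel and every mask voxel is
#' equally likely.
#'
#' @param grid A `voxel_grid`.
#' @param n Number of foci to draw.
#' @return An `n x 3` matrix of world-mm coordinates.
#' @export
sample_uniform_focus <- function(grid, n = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (grid$n_mask < 1) stop("empty mask")
  rows <- sample.int(grid$n_mask, n, replace = TRUE)
  sweep(grid$mask_vox[rows, , drop = FALSE] * grid$voxel_mm, 2, grid$origin, "+")
}

# TRUE where the world coordinate is the center of a mask voxel
in_mask <- function(grid, xyz) {
  m <- rbind(xyz)
  idx <- round(sweep(m, 2, grid$origin, "-") / grid$voxel_mm) + 1
  inside <- !(apply(idx < 1, 1, any) | apply(sweep(idx, 2, grid$dim, ">"), 1, any))
  out <- logical(nrow(m))
  lin <- 1 + (idx[inside, 1, drop = TRUE] - 1) +
    grid$dim[1] * ((idx[inside, 2, drop = TRUE] - 1) +
                     grid$dim[2] * (idx[inside, 3, drop = TRUE] - 1))
  out[inside] <- grid$lookup[lin] >= 0
  out
}

#' Write a mask-voxel map as a NIfTI volume
#'
#' Expands a vector of per-mask-voxel values (an MA map, ALE map, p-map or
#' binary cluster mask) to the full grid and writes it as NIfTI, with the
#' grid's world transform in the header.
#'
#' @param values Numeric vector of length `grid$n_mask`.
#' @param grid A `voxel_grid`.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @param background Value outside the mask (default 0).
#' @return Invisibly, the path.
#' @export
write_map_nifti <- function(values, grid, path, background = 0) {
  stopifnot(length(values) == grid$n_mask)
  arr <- array(background, dim = grid$dim)
  arr[grid$mask_idx] <- values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid$voxel_mm, 3)
  aff <- diag(c(rep(grid$voxel_mm, 3), 1))
  aff[1:3, 4] <- grid$origin  # world coordinate of voxel (1,1,1)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
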