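# Shared fixtures and independent oracles.

# small fully-masked rectangular grid
tiny_grid <- function(nx = 5, ny = 5, nz = 4, voxel_mm = 2,
                      origin = c(0, 0, 0)) {
  mask <- array(TRUE, c(nx, ny, nz))
  alesim:::new_voxel_grid(c(nx, ny, nz), voxel_mm, origin, mask)
}

# hand-built experiment (no samplers involved)
fixed_experiment <- function(id, n_subjects, foci, signal = FALSE) {
  structure(list(id = id, n_subjects = n_subjects,
                 foci = rbind(foci), is_signal = signal),
            class = "experiment")
}

# reference kernel SD via the FWHM conversion chain of the published
# two-component uncertainty model (independent of kernel_sd's direct form)
reference_kernel_sd <- function(n, subj = 11.6, templ = 5.7) {
  ed_to_fwhm <- sqrt(8 * log(2)) / (2 * sqrt(2 / pi))
  fwhm <- sqrt((templ * ed_to_fwhm)^2 + (subj * ed_to_fwhm)^2 / n)
  fwhm / sqrt(8 * log(2))
}

# exact tail P(ALE >= t) by exhaustive enumeration of all ordered voxel
# placements (V^K combinations); feasible for V <= 100, K <= 3
brute_force_tail <- function(ma, edges) {
  V <- nrow(ma)
  K <- ncol(ma)
  combos <- expand.grid(rep(list(seq_len(V)), K), KEEP.OUT.ATTRS = FALSE)
  surv <- rep(1, nrow(combos))
  for (k in seq_len(K)) surv <- surv * (1 - ma[combos[[k]], k])
  ale <- 1 - surv
  vapply(edges, function(t) mean(ale >= t - 1e-15), numeric(1))
}

# pooled mean f1/f2 over spurious clusters of a study result
pooled_contrib <- function(res, method) {
  cc <- res$contributions
  cc <- cc[cc$method == method, , drop = FALSE]
  if (is.null(cc) || nrow(cc) == 0) return(c(f1 = NA_real_, f2 = NA_real_))
  c(f1 = mean(cc$f1), f2 = mean(cc$f2))
}
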