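#' Quantile anchors for a count distribution
#'
#' Bundles the five printed summaries of an integer count distribution
#' (minimum, quartiles, maximum) that the quantile-anchored samplers are
#' calibrated against.
#'
#' @param minimum,q25,q50,q75,maximum Integers with
#'   `minimum <= q25 <= q50 <= q75 <= maximum`, all `>= 1`.
#' @return An object of class `quantile_anchors`.
#' @seealso [make_count_sampler()], [vbm_subject_anchors()]
#' @export
quantile_anchors <- function(minimum, q25, q50, q75, maximum) {
  v <- c(minimum = minimum, q25 = q25, q50 = q50, q75 = q75, maximum = maximum)
  if (any(!is.finite(v)) || any(v < 1) || any(v != round(v)))
    stop("invalid anchors: all anchors must be integers >= 1")
  if (is.unsorted(v))
    stop("invalid anchors: need minimum <= q25 <= q50 <= q75 <= maximum")
  structure(lapply(as.list(v), as.integer), class = "quantile_anchors")
}

#' @export
print.quantile_anchors <- function(x, ...) {
  cat(sprintf("quantile anchors: min %d | q25 %d | q50 %d | q75 %d | max %d\n",
              x$minimum, x$q25, x$q50, x$q75, x$maximum))
  invisible(x)
}

#' Printed BrainMap-VBM summaries for subject and foci counts
#'
#' Anchors and moment targets describing the subject-count and foci-count
#' distributions of the structural (VBM) subset of the BrainMap database
#' (after removal of >500-subject outliers): subjects min 2, quartiles
#' 13/20/32, max 479, mean 30.63, SD 40.91; foci min 1, quartiles 2/4/8,
#' max 75, mean 6.54, SD 7.88.
#'
#' @return `vbm_subject_anchors()` / `vbm_foci_anchors()` return
#'   [quantile_anchors()] objects; `vbm_subject_sampler()` /
#'   `vbm_foci_sampler()` return calibrated samplers (see
#'   [make_count_sampler()]).
#' @export
vbm_subject_anchors <- function() quantile_anchors(2L, 13L, 20L, 32L, 479L)

#' @rdname vbm_subject_anchors
#' @export
vbm_foci_anchors <- function() quantile_anchors(1L, 2L, 4L, 8L, 75L)

#' @rdname vbm_subject_anchors
#' @export
vbm_subject_sampler <- function()
  make_count_sampler(vbm_subject_anchors(), target_mean = 30.63, target_sd = 40.91)

#' @rdname vbm_subject_anchors
#' @export
vbm_foci_sampler <- function()
  make_count_sampler(vbm_foci_anchors(), target_mean = 6.54, target_sd = 7.88)

# pmf of the quantile-anchored family for a given tail decay rate rho.
# Mass model: with probability 3*tie_mass one of the interior anchors
# (q25/q50/q75) is returned; the remaining mass is split equally over the
# four inter-quartile bins, uniform within each of the lower three and
# geometric (weight rho^(x - q75 - 1), rho > 0, possibly > 1) within the
# upper tail (q75, max].
anchored_pmf <- function(anchors, rho, tie_mass) {
  a <- anchors
  vals <- a$minimum:a$maximum
  p <- numeric(length(vals))
  at <- function(x) x - a$minimum + 1L
  core <- 1 - 3 * tie_mass
  add_bin <- function(p, lo, hi, mass, fallback) {
    if (hi >= lo) {
      idx <- at(lo:hi)
      p[idx] <- p[idx] + mass / length(idx)
    } else {
      p[at(fallback)] <- p[at(fallback)] + mass
    }
    p
  }
  p <- add_bin(p, a$minimum, a$q25, core / 4, a$q25)
  p <- add_bin(p, a$q25 + 1L, a$q50, core / 4, a$q50)
  p <- add_bin(p, a$q50 + 1L, a$q75, core / 4, a$q75)
  if (a$maximum > a$q75) {
    tail_vals <- (a$q75 + 1L):a$maximum
    lw <- (tail_vals - a$q75 - 1L) * log(rho)
    w <- exp(lw - max(lw))
    idx <- at(tail_vals)
    p[idx] <- p[idx] + core / 4 * w / sum(w)
  } else {
    p[at(a$maximum)] <- p[at(a$maximum)] + core / 4
  }
  for (q in c(a$q25, a$q50, a$q75)) p[at(q)] <- p[at(q)] + tie_mass
  list(values = vals, prob = p)
}

#' Build a calibrated count sampler from printed summaries
#'
#' Constructs an integer sampler whose population quartiles sit at the given
#' anchors and whose mean matches `target_mean`. The distribution is
#' piecewise: uniform over the integers of each inter-quartile bin, with a
#' geometric-decay upper tail on `(q75, maximum]` whose rate is calibrated
#' (by root finding) so the population mean equals `target_mean` exactly. A
#' small tie mass at each interior anchor reproduces the clustering of real
#' count data at its reported quartile values and keeps the sampler's
#' quartiles strictly at the anchors. The standard deviation is induced, not
#' enforced; the realised value is stored in the returned object for
#' inspection.
#'
#' @param anchors A [quantile_anchors()] object.
#' @param target_mean Target population mean; must lie within
#'   `[minimum, maximum]` and be attainable by the family, else an
#'   infeasible-calibration error is raised.
#' @param target_sd Optional target standard deviation, recorded for
#'   comparison with the realised SD (not enforced).
#' @param tie_mass Probability mass placed on each interior anchor
#'   (default 0.02).
#' @param support Optional inclusive integer range `c(lo, hi)` restricting
#'   the sampler (used for quantile-stratified sampling); the pmf is
#'   conditioned on the range.
#' @return An object of class `count_sampler` with elements `values`,
#'   `prob`, `anchors`, `rho`, `mean`, `sd`, `target_mean`, `target_sd`,
#'   `support`.
#' @examples
#' s <- vbm_subject_sampler()
#' s$mean           # 30.63 by calibration
#' sample_counts(s, 5, seed = 1)
#' @export
make_count_sampler <- function(anchors, target_mean, target_sd = NULL,
                               tie_mass = 0.02, support = NULL) {
  if (!inherits(anchors, "quantile_anchors"))
    anchors <- do.call(quantile_anchors, as.list(anchors))
  a <- anchors
  if (!is.finite(target_mean) || target_mean < a$minimum || target_mean > a$maximum)
    stop("infeasible calibration: target_mean outside [minimum, maximum]")
  if (tie_mass < 0 || tie_mass >= 1 / 3) stop("tie_mass must be in [0, 1/3)")

  pmf_mean <- function(rho) {
    pm <- anchored_pmf(a, rho, tie_mass)
    sum(pm$values * pm$prob)
  }

  if (a$maximum == a$minimum) {
    rho <- 1
  } else if (a$maximum > a$q75 + 1L) {
    # mean is continuous and increasing in rho; bracket on log scale
    lo <- -12; hi <- 12
    m_lo <- pmf_mean(exp(lo)); m_hi <- pmf_mean(exp(hi))
    if (target_mean < m_lo || target_mean > m_hi)
      stop(sprintf(
        "infeasible calibration: target_mean %.4g outside attainable [%.4g, %.4g]",
        target_mean, m_lo, m_hi))
    rho <- exp(uniroot(function(lr) pmf_mean(exp(lr)) - target_mean,
                       c(lo, hi), tol = 1e-12)$root)
  } else {
    rho <- 1
    if (abs(pmf_mean(rho) - target_mean) > 0.02 * target_mean)
      stop("infeasible calibration: no tail to tune and fixed mean misses target")
  }

  pm <- anchored_pmf(a, rho, tie_mass)
  if (!is.null(support)) {
    if (length(support) != 2 || support[1] > support[2])
      stop("support must be an inclusive range c(lo, hi)")
    keep <- pm$values >= support[1] & pm$values <= support[2]
    if (!any(keep) || sum(pm$prob[keep]) <= 0)
      stop("support restriction leaves no probability mass")
    pm$values <- pm$values[keep]
    pm$prob <- pm$prob[keep] / sum(pm$prob[keep])
  }
  mu <- sum(pm$values * pm$prob)
  sdev <- sqrt(max(0, sum(pm$values^2 * pm$prob) - mu^2))
  structure(list(values = pm$values, prob = pm$prob, anchors = a, rho = rho,
                 tie_mass = tie_mass, mean = mu, sd = sdev,
                 target_mean = target_mean, target_sd = target_sd,
                 support = support),
            class = "count_sampler")
}

#' @export
print.count_sampler <- function(x, ...) {
  cat(sprintf(
    "count sampler on [%d, %d]: mean %.3f (target %.3f), sd %.2f%s, tail rate %.4f\n",
    min(x$values), max(x$values), x$mean, x$target_mean, x$sd,
    if (is.null(x$target_sd)) "" else sprintf(" (target %.2f)", x$target_sd),
    x$rho))
  invisible(x)
}

#' Draw integer counts from a calibrated sampler
#'
#' @param sampler A [make_count_sampler()] object.
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of length `n`, each value inside the sampler's
#'   support.
#' @export
sample_counts <- function(sampler, n, seed = NULL) {
  stopifnot(inherits(sampler, "count_sampler"))
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("empty request: n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (length(sampler$values) == 1L) return(rep(sampler$values, n))
  sample(sampler$values, size = n, replace = TRUE, prob = sampler$prob)
}

#' Inclusive integer range of a quartile stratum
#'
#' The four categories partition the support `[minimum, maximum]` into
#' `low = [minimum, q25]`, `low-medium = (q25, q50]`,
#' `high-medium = (q50, q75]` and `high = (q75, maximum]` (half-open on the
#' left, on integers).
#'
#' @param parameter `"subjects"` or `"foci"` (label only; the ranges are
#'   determined by `anchors`).
#' @param category One of `"low"`, `"low-medium"`, `"high-medium"`, `"high"`.
#' @param anchors A [quantile_anchors()] object.
#' @return Integer vector `c(lo, hi)`.
#' @export
stratum_range <- function(parameter = c("subjects", "foci"),
                          category,
                          anchors) {
  parameter <- match.arg(parameter)
  if (!inherits(anchors, "quantile_anchors")) stop("anchors must be quantile_anchors")
  a <- anchors
  switch(match.arg(category, stratum_categories()),
         "low"         = c(a$minimum, a$q25),
         "low-medium"  = c(a$q25 + 1L, a$q50),
         "high-medium" = c(a$q50 + 1L, a$q75),
         "high"        = c(a$q75 + 1L, a$maximum))
}

#' @rdname stratum_range
#' @export
stratum_categories <- function() c("low", "low-medium", "high-medium", "high")

#' All 16 subject-by-foci stratum combinations
#'
#' @return A data.frame with columns `subjects` and `foci`, one row per
#'   category pair (16 rows).
#' @export
strata_grid <- function() {
  g <- expand.grid(subjects = stratum_categories(),
                   foci = stratum_categories(),
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g[order(match(g$subjects, stratum_categories()),
          match(g$foci, stratum_categories())), , drop = FALSE]
}
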