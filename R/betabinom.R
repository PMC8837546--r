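# Beta-binomial allele-count model.
#
# Read counts at heterozygous SNPs and somatic SNVs are modelled as
# V ~ Bin(n, p) with p ~ Beta(m * omega, (1 - m) * omega): m is the expected
# allele fraction (BAF_seg for SNPs, BAF_som for clonal somatic variants on
# the major allele) and omega is a sample-specific concentration, a
# pseudo-coverage controlling over-dispersion relative to the binomial.

#' Beta-binomial model parameters
#'
#' @param m Mean allele fraction in (0, 1).
#' @param omega Concentration (pseudo-coverage), positive; calibrated
#'   per sample within \[50, 1000\].
#' @return List of class `betabinom_model`.
#' @export
betabinom_model <- function(m, omega) {
  if (!is.finite(m) || m <= 0 || m >= 1) stop("m must lie in (0, 1)")
  if (!is.finite(omega) || omega <= 0) stop("omega must be positive")
  structure(list(m = m, omega = omega, alpha = m * omega,
                 beta = (1 - m) * omega), class = "betabinom_model")
}

# log pmf of the beta-binomial at counts k (vectorised over k)
betabinom_lpmf <- function(k, n, alpha, beta) {
  lchoose(n, k) + lbeta(k + alpha, n - k + beta) - lbeta(alpha, beta)
}

#' Upper tail of the beta-binomial: P(V >= v)
#'
#' Exact summation of the probability mass from `v` to `n`.
#'
#' @param v Observed count (0..n); vectorised.
#' @param n Total count.
#' @param model A `betabinom_model`.
#' @return P(V >= v), monotone non-increasing in `v`.
#' @export
betabinom_tail <- function(v, n, model) {
  stopifnot(inherits(model, "betabinom_model"))
  if (any(v < 0 | v > n)) stop("v must lie in 0..n")
  pmf <- exp(betabinom_lpmf(0:n, n, model$alpha, model$beta))
  upper <- rev(cumsum(rev(pmf)))        # upper[k+1] = P(V >= k)
  pmin(1, upper[v + 1L])
}

#' Two-sided beta-binomial p-value
#'
#' Doubled smaller tail, capped at 1: for a discrete distribution this is
#' simple and conservative.
#'
#' @inheritParams betabinom_tail
#' @return p in (0, 1\].
#' @export
betabinom_two_sided <- function(v, n, model) {
  stopifnot(inherits(model, "betabinom_model"))
  if (any(v < 0 | v > n)) stop("v must lie in 0..n")
  pmf <- exp(betabinom_lpmf(0:n, n, model$alpha, model$beta))
  lower <- cumsum(pmf)                  # P(V <= v)
  upper <- rev(cumsum(rev(pmf)))        # P(V >= v)
  pmin(1, 2 * pmin(lower[v + 1L], upper[v + 1L]))
}

# mid-p two-sided value: doubled smaller tail with half the point mass
# removed. Unbiased under the null for discrete counts, used for QQ-slope
# calibration where the conservative doubled tail would bias omega upward.
betabinom_two_sided_mid <- function(v, n, model) {
  pmf <- exp(betabinom_lpmf(0:n, n, model$alpha, model$beta))
  lower <- cumsum(pmf)
  upper <- rev(cumsum(rev(pmf)))
  pt <- pmf[v + 1L]
  pmin(1, 2 * pmin(lower[v + 1L] - pt / 2, upper[v + 1L] - pt / 2))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Step-up q-values (monotone in rank).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Robust QQ-plot slope of a p-value set
#'
#' Theil-Sen slope of observed -log10 p order statistics against the
#' -log10 quantiles of the uniform distribution. Ties at p = 1 are
#' excluded. For large inputs the order statistics are thinned to a
#' deterministic evenly spaced subset of 500 before forming pairwise
#' slopes, keeping the estimator exact-median and reproducible.
#'
#' Under a well-calibrated null the slope is 1; slopes above 1 indicate
#' inflation (under-estimated dispersion), below 1 deflation.
#'
#' @param p Vector of p-values.
#' @param max_points Order-statistic cap before pairwise slopes.
#' @return Theil-Sen slope (numeric).
#' @export
qq_slope <- function(p, max_points = 500L) {
  keep <- is.finite(p) & p < 1
  n_all <- length(p)
  if (sum(keep) < 10L) stop("too few informative p-values for a QQ slope")
  # ranks within the full set so expected quantiles stay calibrated
  ps <- sort(p[keep])
  ranks <- seq_along(ps)
  y <- -log10(ps)
  x <- -log10(ranks / (n_all + 1))
  m <- length(y)
  if (m > max_points) {
    idx <- unique(round(seq(1L, m, length.out = max_points)))
    y <- y[idx]; x <- x[idx]
  }
  dx <- outer(x, x, `-`)
  dy <- outer(y, y, `-`)
  ok <- upper.tri(dx) & abs(dx) > 0
  stats::median(dy[ok] / dx[ok])
}

#' Calibrate the beta-binomial concentration from heterozygous SNPs
#'
#' For candidate omega values, two-sided beta-binomial p-values are
#' computed for every heterozygous SNP against its segment's mean phased
#' BAF; omega is chosen so the robust QQ slope of those p-values equals 1
#' (the SNP counts then look exactly as over-dispersed as the model).
#' Search: 40 log-spaced grid points in `bounds`, followed by local
#' root-refinement between the bracketing neighbours; the result is clamped
#' to `bounds`.
#'
#' @param het_snps Data frame with columns `major_count`, `minor_count` and
#'   `segment` (index/key into `segments`).
#' @param segments Data frame with column `baf_seg` (and rownames or order
#'   matching `het_snps$segment`).
#' @param bounds Search interval for omega.
#' @param grid_size Number of log-spaced grid points.
#' @param mid_p Use mid-p two-sided values during calibration (default):
#'   for discrete counts the plain doubled tail is conservative and would
#'   bias the calibrated omega upward.
#' @return List with `omega`, `slope` (QQ slope at the returned omega) and
#'   `grid` (the profiled grid, for diagnostics).
#' @export
calibrate_omega <- function(het_snps, segments, bounds = c(50, 1000),
                            grid_size = 40L, mid_p = TRUE) {
  stopifnot(all(c("major_count", "minor_count", "segment") %in%
                  names(het_snps)))
  if (nrow(het_snps) < 100L) {
    stop("need at least 100 heterozygous SNPs to calibrate omega; ",
         "supply more loci")
  }
  v <- het_snps$major_count
  n <- v + het_snps$minor_count
  m_seg <- segments$baf_seg[het_snps$segment]
  if (any(!is.finite(m_seg))) stop("het SNP with unresolvable segment BAF")
  slope_at <- function(omega) {
    # group by segment BAF and depth for vectorised tail computation
    p <- numeric(length(v))
    for (mm in unique(m_seg)) {
      sel <- which(m_seg == mm)
      model <- betabinom_model(mm, omega)
      for (nn in unique(n[sel])) {
        s2 <- sel[n[sel] == nn]
        p[s2] <- if (mid_p) betabinom_two_sided_mid(v[s2], nn, model)
        else betabinom_two_sided(v[s2], nn, model)
      }
    }
    qq_slope(p)
  }
  grid <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = grid_size))
  slopes <- vapply(grid, slope_at, numeric(1L))
  best <- which.min(abs(slopes - 1))
  omega <- grid[best]
  # slope increases with omega; refine by root finding if a sign change
  # brackets the best grid point
  lo <- max(1L, best - 1L); hi <- min(grid_size, best + 1L)
  g <- function(w) slope_at(w) - 1
  if (sign(slopes[lo] - 1) != sign(slopes[hi] - 1) && lo != hi) {
    root <- tryCatch(
      stats::uniroot(g, lower = grid[lo], upper = grid[hi], tol = 1)$root,
      error = function(e) omega)
    omega <- root
  }
  omega <- min(max(omega, bounds[1]), bounds[2])
  list(omega = omega, slope = slope_at(omega),
       grid = data.frame(omega = grid, slope = slopes))
}

#' Fisher's method for combining independent p-values
#'
#' @param p Vector of p-values.
#' @return Combined p-value from the chi-squared distribution with
#'   `2 * length(p)` degrees of freedom.
#' @export
fisher_combine <- function(p) {
  stopifnot(length(p) >= 1L, all(p > 0 & p <= 1))
  stat <- -2 * sum(log(p))
  stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
}
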