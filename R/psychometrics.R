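#' Cronbach's alpha
#'
#' Internal-consistency reliability of a composite of k components:
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2} are
#' the component variances and \eqn{s_T^2} the variance of the row sum.
#' Can be negative for badly behaved components; complete cases only.
#'
#' @param m numeric matrix or data frame, persons in rows, components in
#'   columns (>= 2 columns, >= 3 complete rows).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("at least 2 components required", call. = FALSE)
  if (nrow(m) < 3L) stop("at least 3 complete cases required", call. = FALSE)
  vt <- stats::var(rowSums(m))
  if (vt <= 0) stop("total score has zero variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Spearman-Brown prophecy formula
#'
#' Reliability of a composite of `k` parallel components each with
#' reliability `r`: \eqn{kr / (1 + (k-1)r)}. `k` may be fractional
#' (lengthening or shortening a test).
#'
#' @param r single-component reliability in (0, 1).
#' @param k length factor, > 0.
#' @return composite reliability.
#' @export
#' @examples
#' spearman_brown(0.618, 5)   # ~0.890
spearman_brown <- function(r, k) {
  if (any(r <= 0 | r >= 1)) stop("'r' must lie in (0, 1)", call. = FALSE)
  if (any(k <= 0)) stop("'k' must be positive", call. = FALSE)
  k * r / (1 + (k - 1) * r)
}

#' Inverse Spearman-Brown: single-component reliability from a composite
#'
#' Back-calculates the reliability of one component from the reliability
#' `R` of a `k`-component composite: \eqn{R / (k - (k-1)R)}. Exact inverse
#' of [spearman_brown()].
#'
#' @param R composite reliability in (0, 1).
#' @param k number of components, > 1.
#' @return single-component reliability.
#' @export
#' @examples
#' spearman_brown_inverse(0.890, 5)   # ~0.618
spearman_brown_inverse <- function(R, k) {
  if (any(R <= 0 | R >= 1)) stop("'R' must lie in (0, 1)", call. = FALSE)
  if (any(k <= 1)) stop("'k' must exceed 1", call. = FALSE)
  den <- k - (k - 1) * R
  if (any(den <= 0)) stop("denominator k - (k-1)R must be positive", call. = FALSE)
  R / den
}

#' Composite reliability of a two-part assessment
#'
#' Spearman-Brown at k = 2 applied to the mean of the two component
#' reliabilities — the two-number combination consistent with quoting an
#' "overall" reliability for a pair of papers.
#'
#' @param r1,r2 component reliabilities in (0, 1).
#' @return composite reliability.
#' @export
#' @examples
#' composite_reliability_two_parts(0.762, 0.746)   # ~0.86
composite_reliability_two_parts <- function(r1, r2) {
  spearman_brown(mean(c(r1, r2)), 2)
}

#' Correction for attenuation (disattenuation)
#'
#' \eqn{r_{xy} / \sqrt{r_{xx} r_{yy}}}: the correlation two measures would
#' show if both were perfectly reliable. Values with magnitude above 1 are
#' possible from sampling error and are reported as computed (with a
#' warning), never clipped.
#'
#' @param r_xy observed correlation, `|r_xy| <= 1`.
#' @param r_xx,r_yy reliabilities in (0, 1].
#' @return disattenuated correlation.
#' @export
#' @examples
#' disattenuate(0.849, 0.909, 0.796)   # ~0.998
disattenuate <- function(r_xy, r_xx, r_yy) {
  if (any(c(r_xx, r_yy) <= 0) || any(c(r_xx, r_yy) > 1))
    stop("reliabilities must lie in (0, 1]", call. = FALSE)
  if (abs(r_xy) > 1) stop("|r_xy| must not exceed 1", call. = FALSE)
  out <- r_xy / sqrt(r_xx * r_yy)
  if (abs(out) > 1)
    warning(sprintf("disattenuated correlation %.3f exceeds 1 in magnitude",
                    out), call. = FALSE)
  out
}

#' Power of a two-independent-sample mean comparison
#'
#' Normal-approximation power for detecting a standardized mean difference
#' `d` between groups of sizes `n1` and `n2`. The noncentrality is
#' \eqn{d\sqrt{n_1 n_2/(n_1+n_2)}}; one-sided power is
#' \eqn{\Phi(\lambda - z_{1-\alpha})}, two-sided adds the (usually
#' negligible) opposite tail.
#'
#' @param d standardized effect size, >= 0.
#' @param n1,n2 group sizes, >= 2.
#' @param alpha significance level in (0, 1).
#' @param tails 1 (directional) or 2.
#' @return power in (0, 1).
#' @export
#' @examples
#' power_two_sample(0.42, 95, 495, alpha = 0.05, tails = 1)   # ~0.98
power_two_sample <- function(d, n1, n2, alpha = 0.05, tails = 2) {
  if (d < 0) stop("'d' must be non-negative", call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("'tails' must be 1 or 2", call. = FALSE)
  lambda <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == 1) {
    stats::pnorm(lambda - stats::qnorm(1 - alpha))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(lambda - z) + stats::pnorm(-lambda - z)
  }
}
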