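#' Maximum-likelihood diagonal Gaussian fit
#'
#' Fits an axis-aligned (zero-correlation) Gaussian to `n x d` samples:
#' per-axis mean and maximum-likelihood standard deviation (1/n normalisation).
#' Axes whose standard deviation falls below `sigma_floor` are flagged
#' degenerate; downstream code excludes degenerate pairs from selection.
#'
#' @param samples Numeric matrix (n x d) or vector (treated as n x 1).
#' @param sigma_floor Non-negative threshold below which an axis is flagged.
#' @return A list with `mean` and `sd` (length-d vectors) and `degenerate`
#'   (logical vector).
#' @export
fit_gaussian <- function(samples, sigma_floor = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  n <- nrow(samples)
  if (n < 2L) abort("need at least 2 samples to fit a Gaussian")
  mu <- colMeans(samples)
  sig <- sqrt(colMeans(sweep(samples, 2L, mu)^2))
  list(mean = unname(mu), sd = unname(sig), degenerate = unname(sig <= sigma_floor))
}

#' One-dimensional quantization margin
#'
#' The margin `m` is the half-width of the excluded band around the population
#' centre: a subject whose per-axis spread is `sigma` and whose mean sits
#' exactly at the margin boundary has probability mass `alpha` on the wrong
#' side of the centre. `m` solves
#' `integral_0^m N(0, sigma) = 1/2 - alpha`, i.e. in closed form
#' `m = sigma * qnorm(1 - alpha)`.
#'
#' Margins are strictly decreasing in `alpha` and scale linearly in `sigma`;
#' `alpha = 0.5` gives a zero margin.
#'
#' @param sigma Positive standard deviation of the worst-case subject.
#' @param alpha Maximum allowable wrong-side probability mass, in (0, 0.5].
#' @return The margin (non-negative scalar; vectorised over inputs).
#' @export
compute_margin_1d <- function(sigma, alpha) {
  if (any(alpha <= 0 | alpha > 0.5)) abort("`alpha` must lie in (0, 0.5]")
  if (any(sigma <= 0)) abort("`sigma` must be positive")
  sigma * qnorm(1 - alpha)
}

#' Two-dimensional quantization margins
#'
#' Computes per-axis margins `(m_x, m_y)` for a feature pair. Under the
#' default `"independent"` convention each axis gets its own one-dimensional
#' margin, `m_axis = sigma_axis * qnorm(1 - alpha)`, so the wrong-side mass is
#' at most `alpha` per axis. The alternative `"joint"` convention instead
#' requires the probability mass of the axis-aligned Gaussian over the
#' rectangle `[0, m_x] x [0, m_y]` to equal `1/2 - alpha` with a shared
#' standardized margin `u = m_x/sigma_x = m_y/sigma_y`; because that rectangle
#' can hold at most a quarter of the mass, the joint reading is only feasible
#' for `alpha >= 0.25` and is an error otherwise; at exactly `alpha = 0.25`
#' the solution is an infinite margin.
#'
#' @param sigma_x,sigma_y Positive per-axis standard deviations.
#' @param alpha Overlap parameter in (0, 0.5].
#' @param convention `"independent"` (default) or `"joint"`.
#' @return Named numeric vector `c(m_x, m_y)`.
#' @export
compute_margin_2d <- function(sigma_x, sigma_y, alpha,
                              convention = c("independent", "joint")) {
  convention <- match.arg(convention)
  if (any(sigma_x <= 0) || any(sigma_y <= 0)) abort("sigmas must be positive")
  if (any(alpha <= 0 | alpha > 0.5)) abort("`alpha` must lie in (0, 0.5]")
  if (convention == "independent") {
    u <- qnorm(1 - alpha)
    return(c(m_x = unname(sigma_x * u), m_y = unname(sigma_y * u)))
  }
  # joint: (Phi(u) - 1/2)^2 = 1/2 - alpha, shared standardized margin u
  if (any(alpha < 0.25)) {
    abort("joint margin convention is infeasible for alpha < 0.25 (quadrant mass <= 1/4)")
  }
  u <- qnorm(0.5 + sqrt(0.5 - alpha))
  c(m_x = unname(sigma_x * u), m_y = unname(sigma_y * u))
}
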