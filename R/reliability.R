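#' IRT conditional reliability of the diagnostic sum score
#'
#' Computes, over a grid of latent general-factor scores \eqn{\theta}, how
#' much variance in the observed diagnostic sum score is attributable to the
#' latent factor - the conditional, scale-free \eqn{R^2} translation of IRT
#' reliability.  Items follow the two-parameter normal-ogive model
#' \eqn{P_i(\theta) = \Phi((\lambda_i\theta - \tau_i)/\sqrt{1-\lambda_i^2})}.
#' With expected score \eqn{T(\theta) = \Sigma_i P_i(\theta)}, true-score
#' slope \eqn{T'(\theta)} and conditional error variance
#' \eqn{\sigma^2_E(\theta) = \Sigma_i P_i(\theta)(1 - P_i(\theta))}, the
#' conditional reliability with the latent variance fixed at 1 is
#' \deqn{R^2(\theta) = \frac{T'(\theta)^2}{T'(\theta)^2 +
#'   \sigma^2_E(\theta)}.}
#'
#' @param sol a `bifactor_solution` (general loadings from column 1,
#'   thresholds from `sol$tau`), or a numeric vector of general loadings.
#' @param prevalences per-item prevalences used to derive thresholds when
#'   `sol` does not carry them.
#' @param theta_grid latent z-score grid (default -2 to 6 in steps of 0.1,
#'   covering the range relevant for extreme-elevation analyses).
#' @return A data frame of class `reliability_curve` with columns `theta`,
#'   `r2`, `expected_score`, `slope` and `error_var`.
#' @export
#' @examples
#' curve <- conditional_reliability(rep(0.6, 10), prevalences = rep(0.05, 10))
#' range(curve$r2)
conditional_reliability <- function(sol, prevalences = NULL,
                                    theta_grid = seq(-2, 6, by = 0.1)) {
  if (inherits(sol, "bifactor_solution")) {
    lam <- sol$Lambda[, 1]
    tau <- sol$tau %||% stats::qnorm(1 - prevalences)
  } else {
    lam <- as.numeric(sol)
    if (is.null(prevalences)) stop("prevalences required when sol is a vector")
    tau <- stats::qnorm(1 - prevalences)
  }
  if (any(abs(lam) >= 1)) stop("|loadings| must be < 1")
  if (length(tau) != length(lam)) stop("loadings/thresholds length mismatch")
  d <- sqrt(1 - lam^2)
  G <- length(theta_grid)
  Z <- sweep(outer(theta_grid, lam), 2, tau, "-") / rep(d, each = G)
  P <- stats::pnorm(Z)
  expected <- rowSums(P)
  slope <- rowSums(sweep(stats::dnorm(Z), 2, lam / d, "*"))
  err <- rowSums(P * (1 - P))
  r2 <- ifelse(slope^2 + err > 0, slope^2 / (slope^2 + err), 0)
  structure(data.frame(theta = theta_grid, r2 = r2,
                       expected_score = expected, slope = slope,
                       error_var = err),
            class = c("reliability_curve", "data.frame"))
}

#' Interval of the latent score where reliability meets a standard
#'
#' @param curve a `reliability_curve`.
#' @param level reliability standard (default 0.70, the conventional
#'   acceptability threshold).
#' @return numeric `c(lo, hi)`: the range of grid points with `r2 >= level`
#'   (NA if never reached).
#' @export
reliability_interval <- function(curve, level = 0.70) {
  ok <- curve$theta[curve$r2 >= level]
  if (!length(ok)) return(c(NA_real_, NA_real_))
  range(ok)
}
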