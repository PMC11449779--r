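#' Diagnostic sum score
#'
#' Row sum of the binary diagnosis columns: the observed proxy for the latent
#' general psychopathology factor.
#'
#' @param data a `family_dataset` (or any data frame with `dx_*` columns).
#' @return integer vector, one score per person, in `[0, n_conditions]`.
#' @export
sum_score <- function(data) {
  as.integer(rowSums(dx_matrix(data)))
}

#' General-factor scores under the normal-ogive model
#'
#' Expected a-posteriori (EAP) scores for the general factor: each item is
#' modelled as a two-parameter normal-ogive in the general dimension,
#' \eqn{P_i(\theta) = \Phi((\lambda_i \theta - \tau_i)/\sqrt{1-\lambda_i^2})},
#' with a standard-normal prior on \eqn{\theta}.  Posterior means are computed
#' by quadrature per unique response pattern and standardized to mean 0,
#' SD 1 across persons.
#'
#' @param data a `family_dataset`.
#' @param sol a `bifactor_solution` providing general loadings; thresholds are
#'   taken from `sol$tau` when present, otherwise from the observed
#'   prevalences in `data`.
#' @param grid quadrature grid over the latent score.
#' @return numeric vector of standardized factor scores.
#' @export
factor_scores <- function(data, sol, grid = seq(-6, 9, by = 0.05)) {
  X <- dx_matrix(data)
  p <- ncol(X)
  lam <- sol$Lambda[, 1]
  if (length(lam) != p) stop("solution and data disagree on condition count")
  tau <- sol$tau %||% stats::qnorm(1 - colMeans(X))
  if (any(abs(lam) >= 1)) stop("|loadings| must be < 1")
  d <- sqrt(1 - lam^2)
  P <- stats::pnorm(sweep(outer(grid, lam), 2, tau, "-") /
                      rep(d, each = length(grid)))
  logP <- log(pmax(P, 1e-300))
  logQ <- log(pmax(1 - P, 1e-300))
  key <- as.vector(X %*% 2^(seq_len(p) - 1))
  uk <- unique(key)
  Xu <- X[match(uk, key), , drop = FALSE]
  ll <- Xu %*% t(logP) + (1 - Xu) %*% t(logQ)        # patterns x grid
  lw <- sweep(ll, 2, stats::dnorm(grid, log = TRUE), "+")
  lw <- lw - apply(lw, 1, max)
  w <- exp(lw)
  eap_u <- as.vector(w %*% grid) / rowSums(w)
  scores <- eap_u[match(key, uk)]
  as.vector(scale(scores))
}
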