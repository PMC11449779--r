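# Monte-Carlo oracle for the conditional reliability: simulate binary
# responses from the normal-ogive model in a narrow window around theta0,
# then estimate the true-score slope and the conditional variance from the
# data alone (local linear regression), independently of the closed-form
# derivative/variance expressions.
mc_conditional_r2 <- function(lam, tau, theta0, n = 200000, h = 0.25) {
  theta <- runif(n, theta0 - h, theta0 + h)
  d <- sqrt(1 - lam^2)
  P <- pnorm((outer(theta, lam) - rep(tau, each = n)) / rep(d, each = n))
  X <- matrix(rbinom(n * length(lam), 1, P), n, length(lam))
  S <- rowSums(X)
  fit <- lm(S ~ theta)
  slope <- coef(fit)[["theta"]]
  cond_var <- mean(residuals(fit)^2)
  slope^2 / (slope^2 + cond_var)
}
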