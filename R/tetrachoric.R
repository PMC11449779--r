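#' Bivariate standard-normal CDF
#'
#' \eqn{P(X \le h, Y \le k)} for standard-normal `(X, Y)` with correlation
#' `rho`, via Plackett's reduction to a one-dimensional integral over the
#' correlation parameter.
#'
#' @param h,k upper limits.
#' @param rho correlation in `[-1, 1]`.
#' @return the joint probability.
#' @export
pbvnorm <- function(h, k, rho) {
  if (abs(rho) >= 0.9999) {
    # degenerate limits
    return(if (rho > 0) stats::pnorm(min(h, k))
           else max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  }
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  integrand <- function(r)
    exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) / sqrt(1 - r^2)
  base + stats::integrate(integrand, 0, rho, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value / (2 * pi)
}

# Quadrant probabilities of a dichotomized bivariate normal with thresholds
# (tau1, tau2) and latent correlation rho; cells ordered (00, 01, 10, 11)
# where "1" means liability above threshold.
bvn_cell_probs <- function(tau1, tau2, rho) {
  p00 <- pbvnorm(tau1, tau2, rho)
  p0x <- stats::pnorm(tau1)
  px0 <- stats::pnorm(tau2)
  p <- c(`00` = p00, `01` = p0x - p00, `10` = px0 - p00,
         `11` = 1 - p0x - px0 + p00)
  pmax(p, 1e-12)
}

#' Maximum-likelihood tetrachoric correlation from a 2x2 table
#'
#' Estimates the latent bivariate-normal correlation from the cell counts of
#' two dichotomized variables.  Thresholds are fixed at the probit of the
#' observed margins; the correlation maximizes the multinomial likelihood of
#' the four cells.  A 0.5 continuity correction is applied to every cell when
#' any cell is empty.
#'
#' @param n00,n01,n10,n11 cell counts; `n11` is the count with both variables
#'   equal to 1.
#' @return list with `rho` (estimate), `tau` (the two thresholds) and
#'   `corrected` (whether the continuity correction was applied).
#' @export
#' @examples
#' tetrachoric_from_counts(45, 5, 5, 45)$rho
tetrachoric_from_counts <- function(n00, n01, n10, n11) {
  cells <- c(n00, n01, n10, n11)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  n <- sum(cells)
  p1x <- (cells[3] + cells[4]) / n   # P(first variable = 1)
  px1 <- (cells[2] + cells[4]) / n
  tau1 <- stats::qnorm(1 - p1x)
  tau2 <- stats::qnorm(1 - px1)
  nll <- function(rho) -sum(cells * log(bvn_cell_probs(tau1, tau2, rho)))
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-8)
  list(rho = opt$minimum, tau = c(tau1, tau2), corrected = corrected)
}

#' Pairwise tetrachoric correlation matrix of binary diagnoses
#'
#' Computes all pairwise maximum-likelihood tetrachoric correlations of a
#' binary indicator matrix, together with per-condition probit thresholds.
#' If the resulting matrix is not positive semi-definite it is smoothed by
#' clipping negative eigenvalues and rescaling to unit diagonal (reported via
#' a message and the `smoothed` field).
#'
#' @param data a binary matrix (n x p) or a `family_dataset` (its `dx_*`
#'   columns are used).
#' @return An object of class `tetrachoric_matrix`: list with `R` (p x p
#'   correlation matrix), `tau` (thresholds, probit of 1 - prevalence), `n`
#'   (sample size) and `smoothed` (logical).
#' @export
tetrachoric_matrix <- function(data) {
  X <- if (is.data.frame(data)) dx_matrix(data) else as.matrix(data)
  if (!all(X %in% c(0, 1))) stop("data must be binary (0/1)")
  cn <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  const <- which(apply(X, 2, function(v) length(unique(v)) == 1L))
  if (length(const))
    stop("constant column(s): ", paste(cn[const], collapse = ", "))
  n <- nrow(X)
  p <- ncol(X)
  cross <- crossprod(X)
  prev <- diag(cross) / n
  tau <- stats::qnorm(1 - prev)
  R <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      n11 <- cross[i, j]
      n10 <- cross[i, i] - n11
      n01 <- cross[j, j] - n11
      n00 <- n - n11 - n10 - n01
      R[i, j] <- R[j, i] <- tetrachoric_from_counts(n00, n01, n10, n11)$rho
    }
  }
  dimnames(R) <- list(cn, cn)
  smoothed <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals, p) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
    dimnames(R) <- list(cn, cn)
    smoothed <- TRUE
    message("tetrachoric matrix smoothed to nearest PSD (min eigenvalue ",
            signif(min(ev$values), 3), ")")
  }
  structure(list(R = R, tau = stats::setNames(tau, cn), n = n,
                 smoothed = smoothed),
            class = "tetrachoric_matrix")
}

#' @export
print.tetrachoric_matrix <- function(x, ...) {
  cat(sprintf("<tetrachoric_matrix> %d conditions, n = %d%s\n",
              ncol(x$R), x$n, if (x$smoothed) " (smoothed)" else ""))
  print(round(x$R, 3))
  invisible(x)
}
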