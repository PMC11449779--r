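#' Principal-axis factor extraction with iterated communalities
#'
#' @param R correlation matrix.
#' @param nfactors number of factors.
#' @param max_iter,tol iteration control.
#' @return list with `loadings` (p x nfactors), `communalities`, `iterations`.
#' @keywords internal
#' @noRd
fa_principal_axis <- function(R, nfactors, max_iter = 200L, tol = 1e-7) {
  p <- ncol(R)
  h2 <- tryCatch(1 - 1 / diag(solve(R)),       # squared multiple correlations
                 error = function(e) rep(max(abs(R - diag(p))), p))
  h2 <- pmin(pmax(h2, 0), 0.999)
  heywood <- FALSE
  lam <- matrix(0, p, nfactors)
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    vals <- pmax(e$values[seq_len(nfactors)], 0)
    lam <- e$vectors[, seq_len(nfactors), drop = FALSE] %*%
      diag(sqrt(vals), nfactors)
    h2_new <- rowSums(lam^2)
    if (any(h2_new > 1)) {
      heywood <- TRUE
      h2_new <- pmin(h2_new, 0.995)
    }
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  if (heywood)
    warning("Heywood case: communality exceeded 1; clipped to 0.995")
  rownames(lam) <- colnames(R)
  list(loadings = lam, communalities = h2, iterations = it)
}

# Quartimin (oblimin, gamma = 0) rotation by oblique gradient projection.
rotate_quartimin <- function(A, max_iter = 1000L, tol = 1e-5) {
  k <- ncol(A)
  if (k == 1L)
    return(list(loadings = A, Phi = matrix(1, 1, 1), converged = TRUE))
  N <- matrix(1, k, k) - diag(k)
  vg <- function(L) {
    L2 <- L^2
    M <- L2 %*% N
    list(f = sum(L2 * M) / 4, G = L * M)
  }
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  o <- vg(L)
  f <- o$f
  G <- -t(t(L) %*% o$G %*% Ti)
  ss <- Inf
  trace_f <- numeric(0)
  for (it in seq_len(max_iter)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    ss <- sqrt(sum(Gp^2))
    trace_f <- c(trace_f, f)
    if (ss < tol) break
    al <- 2 * al
    repeat {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      ot <- vg(L)
      if (ot$f < f - 0.5 * ss^2 * al || al < 1e-12) break
      al <- al / 2
    }
    Tm <- Tt
    f <- ot$f
    G <- -t(t(L) %*% ot$G %*% Ti)
  }
  if (ss >= tol)
    stop("quartimin rotation did not converge in ", max_iter,
         " iterations; criterion trace tail: ",
         paste(signif(utils::tail(trace_f, 5), 6), collapse = ", "))
  list(loadings = L, Phi = t(Tm) %*% Tm, converged = TRUE, iterations = it)
}

# One-factor (second-order) fit of the factor correlation matrix.
#
# method "equal" constrains the second-order loadings to equality
# (tau-equivalent second order): gamma_j = sqrt(mean off-diagonal of Phi).
# With s = 3 first-order factors the free one-factor model is
# just-identified (3 loadings, 3 correlations) and with s = 2 it is
# under-identified, so the free fit amplifies sampling asymmetries in Phi
# directly into the general/specific split; the equality constraint keeps
# the split well-determined.  method "free" fits the loadings by
# unweighted least squares on the off-diagonal elements (s >= 3).
fit_second_order <- function(Phi, method = c("equal", "free")) {
  method <- match.arg(method)
  s <- ncol(Phi)
  if (s == 1L) return(1)
  if (method == "equal" || s == 2L) {
    if (s == 2L) {
      g <- sqrt(min(abs(Phi[1, 2]), 0.985))
      return(c(g, sign(Phi[1, 2]) * g))
    }
    gbar <- mean(Phi[lower.tri(Phi)])
    return(rep(sqrt(min(max(gbar, 0), 0.97)), s))
  }
  e <- eigen(Phi, symmetric = TRUE)
  g0 <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
  if (mean(g0) < 0) g0 <- -g0
  g0 <- pmin(pmax(g0, -0.9), 0.9)
  obj <- function(g) {
    D <- Phi - tcrossprod(g)
    sum(D[lower.tri(D)]^2)
  }
  opt <- stats::optim(g0, obj, method = "L-BFGS-B",
                      lower = -0.995, upper = 0.995)
  opt$par
}

# Flip each column so its largest-magnitude loading is positive.
fix_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Extract factors and rotate to a bifactor (general + specific) solution
#'
#' Implements the exploratory bifactor workflow for binary diagnoses:
#' (1) eigenvalues of the tetrachoric matrix are reported for the scree;
#' (2) `s` factors are extracted by principal-axis factoring with iterated
#' communalities; (3) the factors are rotated obliquely (quartimin);
#' (4) a one-factor model is fitted to the factor correlations, giving
#' second-order loadings \eqn{\gamma}; (5) the Schmid-Leiman
#' orthogonalization yields a general column \eqn{\lambda_g = P\gamma} and
#' specific columns \eqn{\lambda_{s,j} = P_{\cdot j}\sqrt{1-\gamma_j^2}};
#' (6) optionally (default), the unrotated loadings are rotated by orthogonal
#' Procrustes toward this rank-deficient target - the "direct" variant, which
#' returns loadings in the column space of the extracted factors.
#'
#' Each loading column is sign-fixed so its largest-magnitude entry is
#' positive.
#'
#' @param R a [tetrachoric_matrix()] or a plain correlation matrix.
#' @param s number of factors to extract (>= 1); the returned loading matrix
#'   has `1 + s` columns of rank `s`.
#' @param direct use the direct (Procrustes-refined) variant (default) rather
#'   than the classic Schmid-Leiman product.  The refinement keeps the
#'   loadings inside the column space of the extracted factors, so
#'   \eqn{\Lambda\Lambda' + \Psi} reproduces the oblique solution's fit
#'   exactly.
#' @param second_order `"equal"` (default) constrains the second-order
#'   loadings to equality, which keeps the general/specific split
#'   well-determined when the second-order model has no spare degrees of
#'   freedom (it is just-identified at `s = 3` and under-identified at
#'   `s = 2`); `"free"` fits them by least squares on the factor
#'   correlations.
#' @return An object of class `bifactor_solution`: list with `Lambda`
#'   (p x (1+s) loadings; column 1 = general), `eigenvalues` (descending, of
#'   `R`), `n_factors` (= s), `method`, `tau` (thresholds if available),
#'   `pattern` and `Phi` (oblique pattern and factor correlations) and
#'   `second_order` (the \eqn{\gamma} vector).
#' @export
extract_and_rotate <- function(R, s, direct = TRUE,
                               second_order = c("equal", "free")) {
  second_order <- match.arg(second_order)
  tau <- NULL
  if (inherits(R, "tetrachoric_matrix")) {
    tau <- R$tau
    R <- R$R
  }
  R <- as.matrix(R)
  p <- ncol(R)
  if (s < 1) stop("s must be >= 1")
  if (s >= p) stop("s must be smaller than the number of conditions")
  eigenvalues <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  pa <- fa_principal_axis(R, s)
  A <- pa$loadings
  if (s == 1L) {
    Lambda <- cbind(general = fix_signs(A)[, 1], specific_1 = 0)
    P <- A
    Phi <- matrix(1, 1, 1)
    gam <- 1
  } else {
    rot <- rotate_quartimin(A)
    P <- fix_signs(rot$loadings)
    Phi <- rot$Phi
    # re-apply the sign flips to Phi so it matches the sign-fixed pattern
    flips <- vapply(seq_len(s), function(j) {
      i <- which.max(abs(rot$loadings[, j]))
      if (rot$loadings[i, j] < 0) -1 else 1
    }, numeric(1))
    Phi <- diag(flips, s) %*% Phi %*% diag(flips, s)
    gam <- fit_second_order(Phi, method = second_order)
    if (mean(gam) < 0) gam <- -gam
    lam_g <- P %*% gam
    Ls <- sweep(P, 2, sqrt(pmax(1 - gam^2, 0)), "*")
    target <- cbind(lam_g, Ls)
    if (direct) {
      M <- crossprod(A, target)
      sv <- svd(M)
      Lambda <- A %*% (sv$u %*% t(sv$v))
    } else {
      Lambda <- target
    }
    Lambda <- fix_signs(Lambda)
    colnames(Lambda) <- c("general", paste0("specific_", seq_len(s)))
  }
  rownames(Lambda) <- colnames(R)
  structure(list(
    Lambda = Lambda,
    eigenvalues = eigenvalues,
    n_factors = s,
    method = if (direct && s > 1) "direct_schmid_leiman" else "schmid_leiman",
    tau = tau,
    pattern = P,
    Phi = Phi,
    second_order = gam), class = "bifactor_solution")
}

#' @export
print.bifactor_solution <- function(x, ...) {
  cat(sprintf("<bifactor_solution> %d factors (%s)\n", x$n_factors, x$method))
  cat("eigenvalues:", paste(round(utils::head(x$eigenvalues, 5), 2),
                            collapse = ", "), "...\n")
  print(round(x$Lambda, 2))
  invisible(x)
}

tucker_phi <- function(x, y) {
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) stop("zero-norm loading column; congruence undefined")
  sum(x * y) / sqrt(nx * ny)
}

#' Tucker congruence between two bifactor solutions
#'
#' Computes the per-factor Tucker congruence coefficient
#' \eqn{\phi = \Sigma xy / \sqrt{\Sigma x^2 \Sigma y^2}} between matching
#' loading columns.  The general columns are compared directly; specific
#' columns are matched by the permutation maximizing total absolute
#' congruence (recorded in the result).
#'
#' @param sol_a,sol_b `bifactor_solution` objects or plain loading matrices of
#'   equal dimension.
#' @param threshold factors with `phi >=` this value are considered equal
#'   (default 0.95).
#' @return An object of class `congruence_report`: list with `phi` (per
#'   factor), `permutation` (applied to the specifics of `sol_b`) and
#'   `overall` (all `phi >= threshold`).
#' @export
#' @examples
#' a <- cbind(c(0.6, 0.6, 0.6, 0))
#' b <- cbind(c(0.6, 0.6, 0.6, 0.3))
#' congruence(a, b)$phi
congruence <- function(sol_a, sol_b, threshold = 0.95) {
  La <- if (inherits(sol_a, "bifactor_solution")) sol_a$Lambda else as.matrix(sol_a)
  Lb <- if (inherits(sol_b, "bifactor_solution")) sol_b$Lambda else as.matrix(sol_b)
  if (!all(dim(La) == dim(Lb)))
    stop("solutions must have the same dimensions")
  k <- ncol(La)
  phi <- numeric(k)
  phi[1] <- tucker_phi(La[, 1], Lb[, 1])
  perm <- integer(0)
  if (k > 1) {
    idx <- 2:k
    phimat <- outer(idx, idx, Vectorize(function(i, j)
      tucker_phi(La[, i], Lb[, j])))
    perms <- all_permutations(length(idx))
    scores <- vapply(seq_len(nrow(perms)), function(r)
      sum(abs(phimat[cbind(seq_along(idx), perms[r, ])])), numeric(1))
    best <- perms[which.max(scores), ]
    phi[idx] <- phimat[cbind(seq_along(idx), best)]
    perm <- best
  }
  names(phi) <- colnames(La) %||% paste0("F", seq_len(k))
  structure(list(phi = phi, permutation = perm,
                 overall = all(phi >= threshold), threshold = threshold),
            class = "congruence_report")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' @export
print.congruence_report <- function(x, ...) {
  cat("<congruence_report>\n")
  print(round(x$phi, 3))
  cat(sprintf("all factors congruent (phi >= %.2f): %s\n", x$threshold,
              x$overall))
  invisible(x)
}

#' Measurement-invariance check across sibling groups
#'
#' Fits the bifactor model separately in two groups (e.g. older vs. younger
#' siblings), reports per-factor Tucker congruence between the group
#' solutions, and percentile-bootstrap intervals for the loading differences
#' (group A minus group B, after permutation/sign alignment of specifics).
#'
#' @param data a `family_dataset`.
#' @param group_by column whose two values define the groups (default
#'   `"role"`; for sibling pairs this contrasts older vs. younger siblings).
#' @param s number of factors to extract per group.
#' @param n_boot bootstrap resamples for the loading-difference intervals
#'   (default 500).
#' @param conf_level interval coverage.
#' @param min_group smallest admissible group size.
#' @param seed optional RNG seed for the bootstrap.
#' @return list with `congruence` (a `congruence_report`), `solutions`,
#'   `diff` (point loading differences), `diff_lower`/`diff_upper`
#'   (percentile bounds), and `n_boot_ok` (resamples that converged).
#' @export
invariance_check <- function(data, group_by = "role", s = 3, n_boot = 500L,
                             conf_level = 0.95, min_group = 500L,
                             seed = NULL) {
  assert_family_dataset(data)
  if (!group_by %in% names(data)) stop("no column named '", group_by, "'")
  vals <- sort(unique(data[[group_by]]))
  if (length(vals) != 2L)
    stop("group_by column must take exactly two values; got ",
         length(vals))
  g1 <- data[data[[group_by]] == vals[1], ]
  g2 <- data[data[[group_by]] == vals[2], ]
  if (nrow(g1) < min_group || nrow(g2) < min_group)
    stop("each group must have at least ", min_group, " persons")
  fit_one <- function(d) extract_and_rotate(tetrachoric_matrix(d), s)
  sol1 <- fit_one(g1)
  sol2 <- fit_one(g2)
  cong <- congruence(sol1, sol2)
  L2 <- align_to(sol2$Lambda, cong)
  diff_pt <- sol1$Lambda - L2
  if (!is.null(seed)) set.seed(seed)
  boots <- vector("list", n_boot)
  ok <- 0L
  for (b in seq_len(n_boot)) {
    res <- tryCatch({
      s1 <- fit_one(g1[sample.int(nrow(g1), replace = TRUE), ])
      s2 <- fit_one(g2[sample.int(nrow(g2), replace = TRUE), ])
      c1 <- congruence(sol1, s1)
      c2 <- congruence(sol1, s2)
      align_to(s1$Lambda, c1) - align_to(s2$Lambda, c2)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      ok <- ok + 1L
      boots[[ok]] <- res
    }
  }
  boots <- boots[seq_len(ok)]
  alpha <- (1 - conf_level) / 2
  arr <- array(unlist(boots), dim = c(dim(diff_pt), ok))
  lower <- apply(arr, c(1, 2), stats::quantile, probs = alpha)
  upper <- apply(arr, c(1, 2), stats::quantile, probs = 1 - alpha)
  dimnames(lower) <- dimnames(upper) <- dimnames(diff_pt)
  list(congruence = cong, solutions = list(sol1, sol2), groups = vals,
       diff = diff_pt, diff_lower = lower, diff_upper = upper,
       n_boot_ok = ok)
}

# Reorder/sign-align the specific columns of Lambda according to a
# congruence_report computed against a reference solution.
align_to <- function(Lambda, cong) {
  k <- ncol(Lambda)
  if (k > 1 && length(cong$permutation)) {
    Lambda <- Lambda[, c(1L, 1L + cong$permutation), drop = FALSE]
  }
  for (j in seq_len(k)) {
    if (cong$phi[j] < 0) Lambda[, j] <- -Lambda[, j]
  }
  Lambda
}
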