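#' Simulate sibling and twin families from a liability-threshold bifactor model
#'
#' Generates person-level family data with known ground truth.  Each family
#' contains two members (a full-sibling pair or an MZ/DZ twin pair).  Latent
#' general and specific factors are drawn so that the cross-member correlation
#' equals \eqn{a^2 + c^2} for MZ twins and \eqn{0.5 a^2 + c^2} for DZ twins and
#' full siblings, per each factor's ACE triple.  Binary diagnoses arise by
#' thresholding standard-normal condition liabilities at
#' \eqn{\tau_i = \Phi^{-1}(1-\pi_i)}.
#'
#' In discontinuous mode, an additive non-familial shock of size
#' `discontinuity_shift` SD is applied to a member's general liability,
#' independently across family members, with the per-person probability
#' implied by [shock_probability()]: `discontinuity_rate` sets the share of
#' shock-origin persons among those scoring above `discontinuity_threshold`
#' SD of the observed sum score.  With rate 0 the output is bit-for-bit
#' identical to homogeneous mode at the same seed.
#'
#' @param config a [generator_config()].
#' @return A `family_dataset`: a data frame with one row per person and columns
#'   `family_id`, `person_id`, `role` (`older_sib`/`younger_sib` or
#'   `twin1`/`twin2`), `relationship` (`full_sibling`, `MZ`, `DZ`), `age`,
#'   one 0/1 column `dx_<condition>` per condition, `id_severity` (filled by
#'   [simulate_id_negative_control()]; `"none"` here), and, when
#'   `config$keep_truth`, the latent truth columns `latent_general`,
#'   `latent_additive_general` and `latent_specific_<j>`.
#' @export
#' @examples
#' cfg <- generator_config(n_sib_pairs = 200, n_mz_pairs = 50,
#'                         n_dz_pairs = 50, seed = 42)
#' fam <- simulate_families(cfg)
#' table(fam$relationship) / 2
#' mean(sum_score(fam))
simulate_families <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("config must be a generator_config")
  q_shock <- 0
  if (config$extreme_mode == "discontinuous" && config$discontinuity_rate > 0) {
    set.seed(derive_seed(config$seed, 4243L))
    q_shock <- shock_probability(config)
  }
  set.seed(config$seed)
  blocks <- list(
    list(n = config$n_sib_pairs, rel = "full_sibling", r_a = 0.5,
         roles = c("older_sib", "younger_sib")),
    list(n = config$n_mz_pairs, rel = "MZ", r_a = 1,
         roles = c("twin1", "twin2")),
    list(n = config$n_dz_pairs, rel = "DZ", r_a = 0.5,
         roles = c("twin1", "twin2")))
  fam_offset <- 0L
  out <- vector("list", 3L)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (b$n > 0) {
      out[[k]] <- simulate_block(b$n, b$rel, b$r_a, b$roles, config,
                                 fam_offset, q_shock)
      fam_offset <- fam_offset + b$n
    }
  }
  d <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(d) <- NULL
  attr(d, "conditions") <- config$conditions
  class(d) <- c("family_dataset", "data.frame")
  d
}

# Draw a latent factor for n pairs with ACE triple `ace` and additive
# cross-member correlation r_a.  Returns the factor values for both members
# and the additive components (needed by the ID negative control).
draw_pair_factor <- function(n, ace, r_a) {
  a <- sqrt(ace[1]); cc <- sqrt(ace[2]); e <- sqrt(ace[3])
  A1 <- stats::rnorm(n)
  A2 <- r_a * A1 + sqrt(1 - r_a^2) * stats::rnorm(n)
  C <- stats::rnorm(n)
  list(f1 = a * A1 + cc * C + e * stats::rnorm(n),
       f2 = a * A2 + cc * C + e * stats::rnorm(n),
       A1 = A1, A2 = A2)
}

simulate_block <- function(n, rel, r_a, roles, config, fam_offset,
                           q_shock = 0) {
  p <- length(config$conditions)
  s <- ncol(config$loadings_specific)
  lg <- config$loadings_general
  ls <- config$loadings_specific
  tau <- config$thresholds
  uniq <- sqrt(1 - (lg^2 + rowSums(ls^2)))
  b_age <- config$age_beta

  G <- draw_pair_factor(n, config$ace_general, r_a)
  S <- lapply(seq_len(s), function(j)
    draw_pair_factor(n, config$ace_specific[j, ], r_a))

  lo <- config$age_range[1]; hi <- config$age_range[2]
  if (rel == "full_sibling") {
    a1 <- stats::runif(n, lo, hi); a2 <- stats::runif(n, lo, hi)
    age1 <- pmax(a1, a2); age2 <- pmin(a1, a2)   # older sib listed first
  } else {
    age1 <- age2 <- stats::runif(n, lo, hi)       # twins share age
  }
  age_mu <- (lo + hi) / 2
  age_sd <- (hi - lo) / sqrt(12)

  g1 <- G$f1; g2 <- G$f2
  if (config$extreme_mode == "discontinuous" && config$discontinuity_rate > 0) {
    g1 <- g1 + config$discontinuity_shift * (stats::runif(n) < q_shock)
    g2 <- g2 + config$discontinuity_shift * (stats::runif(n) < q_shock)
  }

  S1 <- do.call(cbind, lapply(S, `[[`, "f1"))
  S2 <- do.call(cbind, lapply(S, `[[`, "f2"))

  member_dx <- function(g, Sm, age) {
    inner <- tcrossprod(g, lg) + Sm %*% t(ls) +
      matrix(stats::rnorm(n * p), n, p) %*% diag(uniq, p)
    zage <- (age - age_mu) / age_sd
    L <- sqrt(1 - b_age^2) * inner + b_age * zage
    storage.mode(L) <- "double"
    matrix(as.integer(L > rep(tau, each = n)), n, p)
  }
  D1 <- member_dx(g1, S1, age1)
  D2 <- member_dx(g2, S2, age2)

  fam <- fam_offset + seq_len(n)
  weave <- function(x1, x2) {
    out <- vector(mode = typeof(x1), 2L * n)
    out[seq(1L, 2L * n, 2L)] <- x1
    out[seq(2L, 2L * n, 2L)] <- x2
    out
  }
  weave_mat <- function(m1, m2) {
    out <- matrix(0L, 2L * n, p)
    out[seq(1L, 2L * n, 2L), ] <- m1
    out[seq(2L, 2L * n, 2L), ] <- m2
    out
  }
  dx <- weave_mat(D1, D2)
  colnames(dx) <- paste0("dx_", config$conditions)
  d <- data.frame(
    family_id = rep(fam, each = 2L),
    person_id = 2L * rep(fam, each = 2L) - rep(c(1L, 0L), n),
    role = rep(roles, n),
    relationship = rel,
    age = weave(age1, age2),
    stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(dx))
  d$id_severity <- "none"
  if (config$keep_truth) {
    d$latent_general <- weave(g1, g2)
    d$latent_additive_general <- weave(G$A1, G$A2)
    for (j in seq_len(s)) {
      d[[paste0("latent_specific_", j)]] <- weave(S1[, j], S2[, j])
    }
  }
  d
}

#' Assign intellectual-disability severity as a negative-control exposure
#'
#' Overlays an intellectual-disability (ID) diagnosis of graded severity on an
#' existing synthetic family dataset.  A latent cognitive (g-like) trait is
#' constructed whose additive-genetic part correlates negatively
#' (`id_params$gp_cor`) with the additive part of the general psychopathology
#' liability, mirroring the inverse association between general cognitive
#' ability and general psychopathology.  Familial ID cases are assigned by
#' thresholding the lower tail of this trait (the conceptual cuts are 2, 3.33
#' and 4.33 SD below the cognitive mean for mild, moderate and severe-profound
#' classes); the remaining share of cases in each class
#' (`1 - familial_share`) arises de novo, i.e. in randomly chosen persons
#' independent of family liability.  Because the familial share decreases with
#' severity, sibling aggregation of the p sum score attenuates from mild to
#' severe-profound exposure -- the signature the negative control is designed
#' to exhibit.
#'
#' @param config the [generator_config()] used to generate `data`
#'   (`id_params` controls prevalences, familial shares, the g-p additive
#'   correlation and the g-trait heritability).
#' @param data a `family_dataset` with retained latent truth columns.
#' @return `data` with `id_severity` filled in
#'   (`none`/`mild`/`moderate`/`severe_profound`).
#' @export
simulate_id_negative_control <- function(config, data) {
  assert_family_dataset(data)
  if (!"latent_additive_general" %in% names(data))
    stop("data must retain latent truth (keep_truth = TRUE) for the ID overlay")
  idp <- config$id_params
  prev <- idp$prevalence
  share <- idp$familial_share
  if (any(diff(prev) >= 0))
    warning("ID severity prevalences are not strictly decreasing; proceeding")
  set.seed(derive_seed(config$seed, 77L))

  # order rows pair-wise to draw a familial g trait with the right structure
  ord <- order(data$family_id, data$person_id)
  d <- data[ord, ]
  n_pair <- nrow(d) / 2L
  i1 <- seq(1L, nrow(d), 2L); i2 <- i1 + 1L
  r_a <- ifelse(d$relationship[i1] == "MZ", 1, 0.5)

  # independent familial additive trait with the relationship-specific correlation
  A1 <- stats::rnorm(n_pair)
  A2 <- r_a * A1 + sqrt(1 - r_a^2) * stats::rnorm(n_pair)
  rho <- idp$gp_cor
  gA1 <- rho * d$latent_additive_general[i1] + sqrt(1 - rho^2) * A1
  gA2 <- rho * d$latent_additive_general[i2] + sqrt(1 - rho^2) * A2
  h2 <- idp$g_h2
  g <- numeric(nrow(d))
  g[i1] <- sqrt(h2) * gA1
  g[i2] <- sqrt(h2) * gA2
  g <- g + sqrt(1 - h2) * stats::rnorm(nrow(d))

  # familial cases: lower-tail bands of the g trait, most severe innermost
  u <- stats::pnorm(g)
  c_sev <- prev[3] * share[3]
  c_mod <- c_sev + prev[2] * share[2]
  c_mild <- c_mod + prev[1] * share[1]
  sev <- rep("none", nrow(d))
  sev[u < c_mild] <- "mild"
  sev[u < c_mod] <- "moderate"
  sev[u < c_sev] <- "severe_profound"

  # de-novo cases among the remainder, independent of family liability
  v <- stats::runif(nrow(d))
  q_sev <- prev[3] * (1 - share[3])
  q_mod <- q_sev + prev[2] * (1 - share[2])
  q_mild <- q_mod + prev[1] * (1 - share[1])
  none <- sev == "none"
  sev[none & v < q_mild] <- "mild"
  sev[none & v < q_mod] <- "moderate"
  sev[none & v < q_sev] <- "severe_profound"

  data$id_severity[ord] <- sev   # map back to the original row order
  data
}

#' Per-person shock probability implied by an extreme-tail phenocopy share
#'
#' Converts `config$discontinuity_rate` - the target share of shock-origin
#' persons among those scoring above `config$discontinuity_threshold` SD of
#' the *observed* sum score (the scale on which all proband thresholds are
#' defined) - into the per-person shock probability `q`.  The base and
#' shocked tail masses `p0` and `ps` of the sum score are obtained by an
#' internal Monte-Carlo pass over `m` singleton persons simulated without
#' shocks (sharing one set of draws, so `ps` and `p0` are positively
#' coupled), and `q` solves `share = q ps / (q ps + (1-q) p0)`.
#'
#' Called internally by [simulate_families()] with an RNG state derived from
#' the config seed, so generation stays deterministic.
#'
#' @param config a [generator_config()] with `extreme_mode = "discontinuous"`.
#' @param m Monte-Carlo sample size for the tail-mass estimates.
#' @return per-person shock probability.
#' @export
shock_probability <- function(config, m = 200000L) {
  rate <- config$discontinuity_rate
  if (rate <= 0) return(0)
  p <- length(config$conditions)
  ns <- ncol(config$loadings_specific)
  lg <- config$loadings_general
  ls <- config$loadings_specific
  uniq <- sqrt(1 - (lg^2 + rowSums(ls^2)))
  G <- stats::rnorm(m)
  S <- matrix(stats::rnorm(m * ns), m, ns)
  E <- matrix(stats::rnorm(m * p), m, p) %*% diag(uniq, p)
  base_liab <- tcrossprod(G, lg) + S %*% t(ls) + E
  b <- config$age_beta
  sc0 <- rowSums(sqrt(1 - b^2) * base_liab >
                   rep(config$thresholds, each = m))
  shifted <- sqrt(1 - b^2) *
    (base_liab + tcrossprod(rep(config$discontinuity_shift, m), lg))
  sc1 <- rowSums(shifted > rep(config$thresholds, each = m))
  cut_raw <- mean(sc0) + config$discontinuity_threshold * stats::sd(sc0)
  p0 <- mean(sc0 > cut_raw)
  ps <- mean(sc1 > cut_raw)
  if (ps <= 0) stop("shock never reaches the extreme region; increase shift")
  rate * p0 / (ps * (1 - rate) + rate * p0)
}
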