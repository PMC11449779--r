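#' Wide table of twin pairs
#'
#' @param data a `family_dataset`.
#' @param score `"sum_score"` or the name of a numeric column.
#' @return data frame with one row per twin pair: `family_id`, `zygosity`,
#'   `y1`, `y2`.
#' @export
twin_pair_table <- function(data, score = "sum_score") {
  assert_family_dataset(data)
  tw <- data[data$relationship %in% c("MZ", "DZ"), ]
  if (nrow(tw) == 0) stop("no twin pairs in data")
  y <- if (score == "sum_score") sum_score(tw) else tw[[score]]
  ord <- order(tw$family_id, tw$person_id)
  tw <- tw[ord, ]; y <- y[ord]
  i1 <- seq(1L, nrow(tw), 2L)
  data.frame(family_id = tw$family_id[i1], zygosity = tw$relationship[i1],
             y1 = y[i1], y2 = y[i1 + 1L])
}

icc_double_entry <- function(y1, y2) {
  stats::cor(c(y1, y2), c(y2, y1))
}

# ML fit of the ACE (or AE) model on standardized twin pairs via per-zygosity
# sufficient statistics.  stats = list(mz = c(n, ssq, spr), dz = ...) where
# ssq = sum(y1^2 + y2^2), spr = sum(y1 * y2).
fit_ace_ml <- function(stats_mz, stats_dz, ae = FALSE) {
  nll <- function(par) {
    a2 <- par[1]
    c2 <- if (ae) 0 else par[2]
    if (a2 + c2 > 0.995) return(1e10)
    val <- 0
    for (z in list(c(stats_mz, r = a2 + c2),
                   c(stats_dz, r = 0.5 * a2 + c2))) {
      n <- z[1]; ssq <- z[2]; spr <- z[3]; r <- z[4]
      val <- val + n * log(1 - r^2) + (ssq - 2 * r * spr) / (1 - r^2)
    }
    val
  }
  if (ae) {
    opt <- stats::optimize(function(a) nll(a), c(0, 0.995), tol = 1e-9)
    a2 <- opt$minimum; c2 <- 0
  } else {
    opt <- stats::optim(c(0.3, 0.1), nll, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(0.995, 0.995))
    a2 <- opt$par[1]; c2 <- opt$par[2]
  }
  c(a2 = a2, c2 = c2, e2 = 1 - a2 - c2)
}

#' Intraclass correlations and classical ACE twin model
#'
#' Computes double-entry intraclass correlations per zygosity and fits the
#' classical twin decomposition of variance into additive-genetic (A),
#' shared-environment (C) and nonshared-environment (E) components by maximum
#' likelihood on standardized pairs, with expected correlations
#' \eqn{a^2 + c^2} (MZ) and \eqn{0.5a^2 + c^2} (DZ).  When the DZ correlation
#' is less than half the MZ correlation, or the C estimate hits its zero
#' bound, the C component is dropped and the AE model reported.  Confidence
#' intervals are percentile bootstrap over pairs, stratified by zygosity.
#'
#' @param data a `family_dataset` containing twins.
#' @param score `"sum_score"` or a numeric column name.
#' @param n_boot bootstrap resamples (default 1000; set 0 to skip CIs).
#' @param conf_level interval coverage.
#' @param min_pairs minimum pairs per zygosity.
#' @param seed optional RNG seed for the bootstrap.
#' @return An object of class `ace_result`: list with `r_mz`, `r_dz` (each
#'   with CI), `a2`, `c2`, `e2` (with CIs), `model` (`"ACE"` or `"AE"`),
#'   `n_mz`, `n_dz`.
#' @export
intraclass_and_ace <- function(data, score = "sum_score", n_boot = 1000L,
                               conf_level = 0.95, min_pairs = 50L,
                               seed = NULL) {
  tp <- twin_pair_table(data, score)
  tp_mz <- tp[tp$zygosity == "MZ", ]
  tp_dz <- tp[tp$zygosity == "DZ", ]
  if (nrow(tp_mz) < min_pairs || nrow(tp_dz) < min_pairs)
    stop("need at least ", min_pairs, " pairs per zygosity")
  mu <- mean(c(tp$y1, tp$y2)); sdv <- stats::sd(c(tp$y1, tp$y2))
  if (sdv == 0) stop("score has zero variance")
  std <- function(d) data.frame(y1 = (d$y1 - mu) / sdv, y2 = (d$y2 - mu) / sdv)
  zmz <- std(tp_mz); zdz <- std(tp_dz)
  point <- ace_point(zmz, zdz)
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    reps <- replicate(n_boot, {
      bm <- zmz[sample.int(nrow(zmz), replace = TRUE), ]
      bd <- zdz[sample.int(nrow(zdz), replace = TRUE), ]
      ace_point(bm, bd, force_model = point$model)$est
    })
    alpha <- (1 - conf_level) / 2
    ci <- apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  }
  structure(c(point, list(ci = ci, n_mz = nrow(tp_mz), n_dz = nrow(tp_dz),
                          n_boot = n_boot, mean = mu, sd = sdv)),
            class = "ace_result")
}

ace_point <- function(zmz, zdz, force_model = NULL) {
  r_mz <- icc_double_entry(zmz$y1, zmz$y2)
  r_dz <- icc_double_entry(zdz$y1, zdz$y2)
  suff <- function(d) c(n = nrow(d), ssq = sum(d$y1^2 + d$y2^2),
                        spr = sum(d$y1 * d$y2))
  ae <- if (is.null(force_model)) 2 * r_dz < r_mz else force_model == "AE"
  est <- fit_ace_ml(suff(zmz), suff(zdz), ae = ae)
  if (!ae && est["c2"] < 1e-6) {   # C on the boundary: drop it
    ae <- TRUE
    est <- fit_ace_ml(suff(zmz), suff(zdz), ae = TRUE)
  }
  list(r_mz = r_mz, r_dz = r_dz,
       est = c(est, r_mz = r_mz, r_dz = r_dz),
       a2 = unname(est["a2"]), c2 = unname(est["c2"]),
       e2 = unname(est["e2"]), model = if (ae) "AE" else "ACE")
}

#' @export
print.ace_result <- function(x, ...) {
  cat(sprintf("<ace_result> model = %s (%d MZ / %d DZ pairs)\n", x$model,
              x$n_mz, x$n_dz))
  cat(sprintf("  r_mz = %.3f, r_dz = %.3f\n", x$r_mz, x$r_dz))
  cat(sprintf("  a2 = %.3f, c2 = %.3f, e2 = %.3f\n", x$a2, x$c2, x$e2))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI a2: (%.3f, %.3f)  e2: (%.3f, %.3f)\n",
                x$ci[1, "a2"], x$ci[2, "a2"], x$ci[1, "e2"], x$ci[2, "e2"]))
  }
  invisible(x)
}

#' AE group model for DeFries-Fulker extremes analysis
#'
#' Identifies the group heritability from extreme-group correlations.  Under
#' the AE group model the MZ group correlation estimates the share of the
#' proband group's mean deviation attributable to additive genetics, so
#' \eqn{h^2_g = t_{MZ}} and the group nonshared environment is
#' \eqn{e^2_g = 1 - h^2_g}.  The DZ prediction \eqn{t_{DZ} = 0.5 h^2_g} is
#' returned as a model-adequacy check, and the classical difference estimator
#' \eqn{2(t_{MZ} - t_{DZ})} is reported alongside.
#'
#' @param t_mz,t_dz extreme-group correlations (mean transformed co-twin
#'   deviation) for MZ and DZ probands; `t_dz` optional.
#' @return list with `h2g`, `e2g`, `t_dz_predicted`, `h2g_diff`
#'   (the `2(t_mz - t_dz)` alternative, NA if `t_dz` missing) and
#'   `truncated` (whether `h2g` was clipped into `[0, 1]`).
#' @export
#' @examples
#' df_group_model(0.44, 0.17)
df_group_model <- function(t_mz, t_dz = NULL) {
  h2g <- min(max(t_mz, 0), 1)
  list(h2g = h2g,
       e2g = 1 - h2g,
       t_dz_predicted = 0.5 * h2g,
       h2g_diff = if (is.null(t_dz)) NA_real_ else 2 * (t_mz - t_dz),
       truncated = !identical(h2g, t_mz) && (t_mz < 0 || t_mz > 1))
}

#' Default proband thresholds for the extremes analysis
#'
#' Four thresholds on the observed p sum score mirroring the severity bands
#' used for intellectual disability: the raw-score mapping (`=2`, `>=2`,
#' `>=3`, `>=4`) corresponds to approximately 2-3.33, >2, >4.33 and >5.33 SD
#' above a sum-score mean near 0.19 with SD near 0.60.
#'
#' @param scale `"raw"` (integer sum-score cutoffs) or `"sd"` (z-score
#'   cutoffs).
#' @return data frame with columns `label`, `lo`, `hi` (band is
#'   `lo <= score <= hi` for raw, `lo <= z < hi` for sd).
#' @export
default_cutoffs <- function(scale = c("raw", "sd")) {
  scale <- match.arg(scale)
  if (scale == "raw") {
    data.frame(label = c("eq2_mild", "ge2_mild_profound",
                         "ge3_severe_profound", "ge4_profound"),
               lo = c(2, 2, 3, 4), hi = c(2, Inf, Inf, Inf),
               scale = "raw", stringsAsFactors = FALSE)
  } else {
    data.frame(label = c("band_2_3.33", "ge_2", "ge_4.33", "ge_5.33"),
               lo = c(2, 2, 4.33, 5.33), hi = c(3.33, Inf, Inf, Inf),
               scale = "sd", stringsAsFactors = FALSE)
  }
}

#' DeFries-Fulker extremes analysis of group heritability
#'
#' For each proband threshold: (1) scores are z-standardized by the full twin
#' sample's mean and SD (both zygosities pooled); (2) pairs are double-entered
#' so each member serves as proband when eligible; (3) probands are members
#' meeting the cutoff rule; (4) proband and co-twin z-scores are divided by
#' the zygosity-pooled proband mean z (the DF transformation, which fixes the
#' proband group mean at 1); (5) the extreme-group correlation `t` is the
#' mean transformed co-twin score per zygosity; (6) the AE group model
#' ([df_group_model()]) identifies `h2g` from `t_mz`, with
#' `e2g = 1 - h2g`, the DZ prediction `0.5 * h2g` as an adequacy check, and
#' the `2(t_mz - t_dz)` and augmented DF-regression estimators logged for
#' comparison.  Thresholds with fewer than `min_probands` probands in either
#' zygosity are skipped with a warning.  CIs are percentile bootstrap over
#' pairs, stratified by zygosity.
#'
#' @param data a `family_dataset` containing twins.
#' @param cutoffs a cutoff table as returned by [default_cutoffs()].
#' @param score `"sum_score"` or a numeric column name.
#' @param min_probands minimum double-entry proband count per zygosity
#'   (default 20).
#' @param n_boot bootstrap resamples (default 1000; 0 skips CIs).
#' @param conf_level interval coverage.
#' @param seed optional RNG seed for the bootstrap.
#' @return An object of class `extremes_result`: data frame with one row per
#'   threshold (`label`, `lo`, `hi`, `n_probands_mz`, `n_probands_dz`,
#'   `t_mz`, `t_dz`, `h2g`, `e2g`, CIs, `t_dz_predicted`, `h2g_diff`,
#'   `h2g_aug`), with the population mean/SD as attributes.
#' @export
df_extremes <- function(data, cutoffs = default_cutoffs(),
                        score = "sum_score", min_probands = 20L,
                        n_boot = 1000L, conf_level = 0.95, seed = NULL) {
  tp <- twin_pair_table(data, score)
  mu <- mean(c(tp$y1, tp$y2)); sdv <- stats::sd(c(tp$y1, tp$y2))
  if (sdv == 0) stop("population SD of the score is zero")
  res <- df_extremes_point(tp, cutoffs, mu, sdv, min_probands, warn = TRUE)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    imz <- which(tp$zygosity == "MZ"); idz <- which(tp$zygosity == "DZ")
    reps <- replicate(n_boot, {
      bi <- c(sample(imz, replace = TRUE), sample(idz, replace = TRUE))
      b <- tp[bi, ]
      bres <- df_extremes_point(b, cutoffs, mu, sdv, min_probands = 1L,
                                warn = FALSE)
      rbind(bres$h2g, bres$e2g, bres$t_mz, bres$t_dz)
    })
    alpha <- (1 - conf_level) / 2
    qs <- apply(reps, c(1, 2), stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    res$h2g_lower <- qs[1, 1, ]; res$h2g_upper <- qs[2, 1, ]
    res$e2g_lower <- qs[1, 2, ]; res$e2g_upper <- qs[2, 2, ]
  }
  attr(res, "mean") <- mu
  attr(res, "sd") <- sdv
  attr(res, "n_boot") <- n_boot
  class(res) <- c("extremes_result", "data.frame")
  res
}

df_extremes_point <- function(tp, cutoffs, mu, sdv, min_probands,
                              warn = FALSE) {
  z1 <- (tp$y1 - mu) / sdv
  z2 <- (tp$y2 - mu) / sdv
  raw_p <- c(tp$y1, tp$y2)                 # double entry: proband raw score
  pz <- c(z1, z2); cz <- c(z2, z1)          # proband z, co-twin z
  zyg <- rep(tp$zygosity, 2L)
  out <- lapply(seq_len(nrow(cutoffs)), function(i) {
    cut <- cutoffs[i, ]
    elig <- if (identical(cut$scale, "sd"))
      pz >= cut$lo & pz < cut$hi
    else
      raw_p >= cut$lo & raw_p <= cut$hi
    n_mz <- sum(elig & zyg == "MZ"); n_dz <- sum(elig & zyg == "DZ")
    if (n_mz < min_probands || n_dz < min_probands) {
      if (warn)
        warning("threshold '", cut$label, "' skipped: ", n_mz, " MZ / ",
                n_dz, " DZ probands (< ", min_probands, ")")
      return(data.frame(label = cut$label, lo = cut$lo, hi = cut$hi,
                        n_probands_mz = n_mz, n_probands_dz = n_dz,
                        t_mz = NA_real_, t_dz = NA_real_,
                        t_mz_se = NA_real_, t_dz_se = NA_real_,
                        h2g = NA_real_, e2g = NA_real_,
                        t_dz_predicted = NA_real_,
                        h2g_diff = NA_real_, h2g_aug = NA_real_,
                        truncated = FALSE))
    }
    # DF transformation: divide by the zygosity's own proband mean, so each
    # group correlation is the scale-free regression-to-the-mean ratio
    k_mz <- mean(pz[elig & zyg == "MZ"])
    k_dz <- mean(pz[elig & zyg == "DZ"])
    cmz <- cz[elig & zyg == "MZ"] / k_mz
    cdz <- cz[elig & zyg == "DZ"] / k_dz
    t_mz <- mean(cmz)
    t_dz <- mean(cdz)
    # large-sample SEs treating the divisor as fixed
    t_mz_se <- stats::sd(cmz) / sqrt(n_mz)
    t_dz_se <- stats::sd(cdz) / sqrt(n_dz)
    gm <- df_group_model(t_mz, t_dz)
    # augmented DF regression on transformed scores (logged alternative)
    rel <- ifelse(zyg[elig] == "MZ", 1, 0.5)
    kk <- ifelse(zyg[elig] == "MZ", k_mz, k_dz)
    aug <- tryCatch(
      unname(stats::coef(stats::lm(I(cz[elig] / kk) ~ I(pz[elig] / kk) + rel))["rel"]),
      error = function(e) NA_real_)
    data.frame(label = cut$label, lo = cut$lo, hi = cut$hi,
               n_probands_mz = n_mz, n_probands_dz = n_dz,
               t_mz = t_mz, t_dz = t_dz, t_mz_se = t_mz_se, t_dz_se = t_dz_se,
               h2g = gm$h2g, e2g = gm$e2g,
               t_dz_predicted = gm$t_dz_predicted, h2g_diff = gm$h2g_diff,
               h2g_aug = aug, truncated = gm$truncated)
  })
  do.call(rbind, out)
}

#' @export
print.extremes_result <- function(x, ...) {
  cat(sprintf("<extremes_result> score mean = %.3f, SD = %.3f\n",
              attr(x, "mean"), attr(x, "sd")))
  cols <- intersect(c("label", "n_probands_mz", "n_probands_dz", "t_mz",
                      "t_dz", "h2g", "h2g_lower", "h2g_upper", "e2g"),
                    names(x))
  print(format(as.data.frame(x)[, cols], digits = 3), row.names = FALSE)
  invisible(x)
}

#' Genetic-continuity comparison of group and individual heritability
#'
#' Compares the DF group heritability at each proband threshold with the
#' individual-differences heritability from the classical twin model on the
#' same data.  The difference `h2g - h2` is bootstrapped jointly (the same
#' pair resamples feed both estimators), giving a percentile CI per
#' threshold; the verdict is "consistent with a shared etiology across the
#' continuum" when every CI covers zero.
#'
#' @param data a `family_dataset` containing twins.
#' @param cutoffs threshold table (see [default_cutoffs()]).
#' @param score score column.
#' @param n_boot joint bootstrap resamples (default 500).
#' @param conf_level interval coverage.
#' @param seed optional RNG seed.
#' @param ace,ext optional precomputed [intraclass_and_ace()] /
#'   [df_extremes()] fits for the point estimates (recomputed when NULL).
#' @return An object of class `continuity_report`: data frame with one row
#'   per threshold (`label`, `h2g`, `h2`, `diff`, `diff_lower`,
#'   `diff_upper`, `covers_zero`) and attribute `verdict`.
#' @export
continuity_report <- function(data, cutoffs = default_cutoffs(),
                              score = "sum_score", n_boot = 500L,
                              conf_level = 0.95, seed = NULL,
                              ace = NULL, ext = NULL) {
  tp <- twin_pair_table(data, score)
  mu <- mean(c(tp$y1, tp$y2)); sdv <- stats::sd(c(tp$y1, tp$y2))
  if (is.null(ace)) ace <- intraclass_and_ace(data, score, n_boot = 0)
  if (is.null(ext)) ext <- df_extremes(data, cutoffs, score, n_boot = 0)
  std <- function(d) data.frame(y1 = (d$y1 - mu) / sdv,
                                y2 = (d$y2 - mu) / sdv)
  diff_pt <- ext$h2g - ace$a2
  lo <- up <- rep(NA_real_, length(diff_pt))
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    imz <- which(tp$zygosity == "MZ"); idz <- which(tp$zygosity == "DZ")
    reps <- replicate(n_boot, {
      bi <- c(sample(imz, replace = TRUE), sample(idz, replace = TRUE))
      b <- tp[bi, ]
      h2 <- ace_point(std(b[b$zygosity == "MZ", ]),
                      std(b[b$zygosity == "DZ", ]),
                      force_model = ace$model)$a2
      bres <- df_extremes_point(b, cutoffs, mu, sdv, min_probands = 1L)
      bres$h2g - h2
    })
    reps <- matrix(reps, nrow = nrow(ext))
    alpha <- (1 - conf_level) / 2
    lo <- apply(reps, 1, stats::quantile, probs = alpha, na.rm = TRUE)
    up <- apply(reps, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE)
  }
  out <- data.frame(label = ext$label, h2g = ext$h2g, h2 = ace$a2,
                    diff = diff_pt, diff_lower = lo, diff_upper = up,
                    covers_zero = lo <= 0 & up >= 0)
  attr(out, "verdict") <- if (all(stats::na.omit(out$covers_zero)))
    "consistent with shared etiology" else "group and individual heritability differ"
  class(out) <- c("continuity_report", "data.frame")
  out
}

#' @export
print.continuity_report <- function(x, ...) {
  cat("<continuity_report>\n")
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  cat("verdict:", attr(x, "verdict"), "\n")
  invisible(x)
}
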