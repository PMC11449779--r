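#' Build the sibling-pair analysis table
#'
#' One row per full-sibling pair: the older sibling's exposure score, the
#' younger sibling's outcome score and the younger sibling's age.
#'
#' @param data a `family_dataset`.
#' @param outcome `"sum_score"` (observed diagnostic sum) or `"factor_score"`
#'   (standardized general-factor EAP score; requires `sol`).
#' @param sol a `bifactor_solution`, needed for `outcome = "factor_score"`.
#' @return data frame with columns `family_id`, `exposure`, `outcome`, `age`.
#' @export
sibling_pair_table <- function(data, outcome = c("sum_score", "factor_score"),
                               sol = NULL) {
  assert_family_dataset(data)
  outcome <- match.arg(outcome)
  sib <- data[data$relationship == "full_sibling", ]
  if (nrow(sib) == 0) stop("no full-sibling pairs in data")
  sc <- sum_score(sib)
  out_sc <- if (outcome == "factor_score") {
    if (is.null(sol)) stop("sol required for factor-score outcome")
    factor_scores(sib, sol)
  } else sc
  older <- sib$role == "older_sib"
  fam_o <- sib$family_id[older]
  idx <- match(fam_o, sib$family_id[!older])
  keep <- !is.na(idx)
  data.frame(family_id = fam_o[keep],
             exposure = sc[older][keep],
             outcome = out_sc[!older][idx[keep]],
             age = sib$age[!older][idx[keep]])
}

# Pool sparse top exposure levels downwards until every retained level has at
# least `floor_n` pairs.  Returns the capped level vector and the cap.
pool_levels <- function(lvl, floor_n) {
  cap <- max(lvl)
  repeat {
    if (cap <= min(lvl) + 1L) break
    if (sum(lvl >= cap) >= floor_n && sum(lvl == cap - 1L) >= floor_n) break
    cap <- cap - 1L
  }
  list(lvl = pmin(lvl, cap), cap = cap, pooled = cap < max(lvl))
}

#' Sibling familial-coaggregation regression with dummy-coded exposure
#'
#' Regresses the younger sibling's outcome on the older sibling's dummy-coded
#' diagnostic sum score (each level vs. the reference level 0), adjusting for
#' the younger sibling's age.  Coefficients are covariate-adjusted mean
#' differences per exposure level; standard errors are
#' heteroskedasticity-robust (HC1).  Exposure levels with fewer than
#' `min_level_n` pairs are pooled into the top bin.  A linear-by-linear trend
#' test and a lack-of-fit test against the linear-score model are attached
#' when at least three levels remain (see [trend_test()]).
#'
#' @param data a `family_dataset`.
#' @param outcome,sol see [sibling_pair_table()].
#' @param use_age adjust for the younger sibling's age (default TRUE).
#' @param min_level_n pooling floor for sparse exposure levels (default 30).
#' @param conf_level confidence level for the intervals.
#' @return An object of class `coaggregation_result`: list with `table`
#'   (level, n, beta, se, lower, upper), `trend` (`p_linear`,
#'   `p_lackoffit`, F statistics), `pooled_top`, `covariates`, `n_pairs`.
#' @export
dummy_regression <- function(data, outcome = "sum_score", sol = NULL,
                             use_age = TRUE, min_level_n = 30L,
                             conf_level = 0.95) {
  pd <- sibling_pair_table(data, outcome, sol)
  coagg_fit(pd, use_age = use_age, min_level_n = min_level_n,
            conf_level = conf_level, ordinal = TRUE)
}

# Shared fitting engine for dummy_regression and id_negative_control.
# `pd` has columns exposure (integer or factor), outcome, age.
coagg_fit <- function(pd, use_age, min_level_n, conf_level, ordinal) {
  if (is.numeric(pd$exposure)) {
    pool <- pool_levels(as.integer(pd$exposure), min_level_n)
    pd$level <- pool$lvl
    pooled <- pool$pooled
    if (pooled)
      message("exposure levels >= ", pool$cap, " pooled into the top bin")
    lev <- sort(unique(pd$level))
  } else {
    pd$level <- pd$exposure
    pooled <- FALSE
    lev <- levels(pd$exposure)
    lev <- lev[lev %in% unique(as.character(pd$exposure))]
  }
  if (!any(pd$level == lev[1]))
    stop("no pairs at the reference exposure level")
  if (length(lev) < 2) stop("need at least 2 exposure levels")
  pd$flevel <- factor(pd$level, levels = lev)
  fml <- if (use_age) outcome ~ flevel + age else outcome ~ flevel
  fit <- stats::lm(fml, data = pd)
  V <- sandwich::vcovHC(fit, type = "HC1")
  ct <- lmtest::coeftest(fit, vcov. = V)
  cf <- ct[grep("^flevel", rownames(ct)), , drop = FALSE]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    level = lev,
    n = as.integer(table(pd$flevel)[as.character(lev)]),
    beta = c(0, cf[, 1]),
    se = c(0, cf[, 2]),
    lower = c(0, cf[, 1] - zq * cf[, 2]),
    upper = c(0, cf[, 1] + zq * cf[, 2]),
    row.names = NULL)
  trend <- if (length(lev) >= 3) {
    scores <- if (ordinal && is.numeric(pd$level)) pd$level
              else as.integer(pd$flevel) - 1L
    trend_fit(pd, scores, use_age, m_dum = fit)
  } else NULL
  structure(list(table = tab, trend = trend, pooled_top = pooled,
                 covariates = if (use_age) "age" else character(0),
                 n_pairs = nrow(pd)),
            class = "coaggregation_result")
}

trend_fit <- function(pd, scores, use_age, m_dum = NULL) {
  pd$score_lin <- scores
  f_lin <- if (use_age) outcome ~ score_lin + age else outcome ~ score_lin
  f_dum <- if (use_age) outcome ~ flevel + age else outcome ~ flevel
  m_lin <- stats::lm(f_lin, data = pd)
  if (is.null(m_dum)) m_dum <- stats::lm(f_dum, data = pd)
  ct <- lmtest::coeftest(m_lin, vcov. = sandwich::vcovHC(m_lin, type = "HC1"))
  p_linear <- ct["score_lin", 4]
  an <- stats::anova(m_lin, m_dum)
  list(p_linear = unname(p_linear),
       slope = unname(ct["score_lin", 1]),
       p_lackoffit = an[["Pr(>F)"]][2],
       F_lackoffit = an[["F"]][2],
       df_lackoffit = an[["Df"]][2])
}

#' Linear-by-linear trend and lack-of-fit tests for an exposure gradient
#'
#' Two complementary tests of the shape of the exposure-outcome gradient:
#' `p_linear` tests the ordinal linear contrast (integer level scores) - a
#' small value indicates a positive (or negative) linear component;
#' `p_lackoffit` is the nested-F comparison of the saturated dummy-coded
#' model against the linear-score model - a small value indicates departure
#' from linearity.  Reporting both resolves the ambiguity in the customary
#' "linear-by-linear trend test" phrase, whose null is sometimes stated as
#' linearity and sometimes as its absence.
#'
#' @param data a `family_dataset`.
#' @inheritParams dummy_regression
#' @return list with `p_linear`, `slope`, `p_lackoffit`, `F_lackoffit`,
#'   `df_lackoffit`.
#' @export
trend_test <- function(data, outcome = "sum_score", sol = NULL,
                       use_age = TRUE, min_level_n = 30L) {
  res <- dummy_regression(data, outcome, sol, use_age, min_level_n)
  if (is.null(res$trend)) stop("need at least 3 exposure levels")
  res$trend
}

#' Intellectual-disability negative control
#'
#' Regresses the younger sibling's p sum score on the older sibling's
#' intellectual-disability severity class (none / mild / moderate /
#' severe-profound), age-adjusted, with integer class scores for the trend
#' test.  A decreasing mean difference with increasing severity - the
#' opposite of a shared-etiology gradient - is the expected negative-control
#' pattern, because severe ID is predominantly non-familial.
#'
#' @param data a `family_dataset` with populated `id_severity`.
#' @param use_age,conf_level see [dummy_regression()].
#' @return a `coaggregation_result` (levels are severity classes).
#' @export
id_negative_control <- function(data, use_age = TRUE, conf_level = 0.95) {
  assert_family_dataset(data)
  if (all(data$id_severity == "none"))
    stop("id_severity not populated; run simulate_id_negative_control first")
  sib <- data[data$relationship == "full_sibling", ]
  sc <- sum_score(sib)
  older <- sib$role == "older_sib"
  o <- data.frame(family_id = sib$family_id[older],
                  exposure = factor(sib$id_severity[older],
                                    levels = c("none", "mild", "moderate",
                                               "severe_profound")))
  y <- data.frame(family_id = sib$family_id[!older],
                  outcome = sc[!older], age = sib$age[!older])
  pd <- merge(o, y, by = "family_id")
  coagg_fit(pd, use_age = use_age, min_level_n = 1L,
            conf_level = conf_level, ordinal = FALSE)
}

#' @export
print.coaggregation_result <- function(x, ...) {
  cat(sprintf("<coaggregation_result> %d pairs, covariates: %s\n", x$n_pairs,
              paste(x$covariates, collapse = ", ") ))
  tab <- x$table
  tab$beta <- round(tab$beta, 3); tab$se <- round(tab$se, 4)
  tab$lower <- round(tab$lower, 3); tab$upper <- round(tab$upper, 3)
  print(tab)
  if (!is.null(x$trend))
    cat(sprintf("trend: p_linear = %.3g, p_lackoffit = %.3g\n",
                x$trend$p_linear, x$trend$p_lackoffit))
  invisible(x)
}

#' Apply the sensitivity-analysis filters
#'
#' Pairwise exclusion filters: a whole pair is removed when either member is
#' flagged.  Filters compose; retained and removed row counts are logged via
#' `message()`.
#'
#' @param data a `family_dataset`.
#' @param exclude_severe_id drop pairs in which at least one member has
#'   severe-profound intellectual disability.
#' @param age_min,age_max keep only pairs in which both members' ages fall in
#'   `[age_min, age_max]`.
#' @param condition_subset keep only these diagnosis columns (affects
#'   downstream sum scores and measurement fits).
#' @return the filtered `family_dataset`.
#' @export
apply_filters <- function(data, exclude_severe_id = FALSE, age_min = NULL,
                          age_max = NULL, condition_subset = NULL) {
  assert_family_dataset(data)
  n0 <- nrow(data)
  flag <- rep(FALSE, n0)
  if (exclude_severe_id)
    flag <- flag | data$id_severity == "severe_profound"
  if (!is.null(age_min)) flag <- flag | data$age < age_min
  if (!is.null(age_max)) flag <- flag | data$age > age_max
  bad_fam <- unique(data$family_id[flag])
  out <- data[!data$family_id %in% bad_fam, , drop = FALSE]
  if (!is.null(condition_subset)) {
    keep_dx <- paste0("dx_", condition_subset)
    miss <- setdiff(keep_dx, names(out))
    if (length(miss)) stop("unknown condition(s): ",
                           paste(sub("^dx_", "", miss), collapse = ", "))
    drop <- setdiff(dx_cols(out), keep_dx)
    out <- out[, setdiff(names(out), drop), drop = FALSE]
  }
  message(sprintf("filters retained %d of %d rows (%d pairs removed)",
                  nrow(out), n0, length(bad_fam)))
  class(out) <- c("family_dataset", "data.frame")
  out
}
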