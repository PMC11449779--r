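test_that("dummy-coded betas equal covariate-free group mean differences", {
  # level 0 mean 0.0, level 1 mean 0.5, level 2 mean 1.0
  older <- rep(c(0, 1, 2), each = 40)
  younger <- c(rep(0, 40), rep(c(0, 1), 20), rep(1, 40))
  fam <- make_pairs_dataset(older, younger)
  res <- dummy_regression(fam, use_age = FALSE, min_level_n = 10)
  expect_equal(res$table$beta, c(0, 0.5, 1.0), tolerance = 1e-12)
  # betas equal direct group-mean differences
  gm <- tapply(younger, older, mean)
  expect_equal(res$table$beta, as.numeric(gm - gm[1]), tolerance = 1e-12)
})

test_that("constant outcomes give zero betas", {
  fam <- make_pairs_dataset(rep(c(0, 1, 2), each = 40), rep(1, 120))
  res <- suppressWarnings(dummy_regression(fam, use_age = FALSE,
                                           min_level_n = 10))
  expect_equal(res$table$beta, c(0, 0, 0), tolerance = 1e-12)
})

test_that("exactly linear group means give lack-of-fit p = 1 and a decisive linear contrast", {
  older <- rep(c(0, 1, 2), each = 60)
  younger <- rep(c(0, 2, 1, 3, 2, 4), each = 30)  # means 1, 2, 3; within-sd > 0
  fam <- make_pairs_dataset(older, younger)
  res <- dummy_regression(fam, use_age = FALSE, min_level_n = 10)
  expect_equal(res$trend$p_lackoffit, 1, tolerance = 1e-9)
  expect_lt(res$trend$p_linear, 1e-10)
  expect_equal(res$trend$slope, 1, tolerance = 1e-9)
})

test_that("an inverted-U profile is detected by the lack-of-fit test", {
  set.seed(41)
  mu <- c(0, 0.5, 0.5, 0)
  older <- rep(0:3, each = 1000)
  noise <- rnorm(4000, sd = 0.5)
  pd <- data.frame(family_id = 1:4000, exposure = older,
                   outcome = rep(mu, each = 1000) + noise, age = 25)
  res <- pcontinuum:::coagg_fit(pd, use_age = FALSE, min_level_n = 10,
                                conf_level = 0.95, ordinal = TRUE)
  expect_lt(res$trend$p_lackoffit, 1e-3)
  # closed-form oracle for the expected F statistic: SS_lof / (2 sigma^2)
  # with group means (0,.5,.5,0) regressed on scores 0:3 -> per-group
  # deviations (mu - fitted) = (-0.25, .25, .25, -.25)
  f_expected <- (1000 * sum(rep(0.25^2, 4))) / (2 * 0.5^2)
  expect_lt(abs(res$trend$F_lackoffit - f_expected) / f_expected, 0.35)
})

test_that("permuted outcomes give calibrated (uniform) lack-of-fit p-values", {
  fam <- simulate_families(small_cfg(n_sib = 4000, n_mz = 0, n_dz = 0,
                                     seed = 43))
  pd <- sibling_pair_table(fam)
  set.seed(44)
  pvals <- replicate(150, {
    pd$outcome <- sample(pd$outcome)
    pcontinuum:::coagg_fit(pd, use_age = TRUE, min_level_n = 30,
                           conf_level = 0.95, ordinal = TRUE)$trend$p_lackoffit
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("sparse top exposure levels are pooled into the top bin", {
  fam <- simulate_families(small_cfg(n_sib = 20000, n_mz = 0, n_dz = 0,
                                     seed = 45))
  expect_message(res <- dummy_regression(fam, min_level_n = 30), "pooled")
  expect_true(all(res$table$n >= 30))
  expect_true(res$pooled_top)
})

test_that("ID negative control shows the attenuating severity gradient", {
  cfg <- small_cfg(n_sib = 400000, n_mz = 0, n_dz = 0, seed = 47)
  fam <- simulate_id_negative_control(cfg, simulate_families(cfg))
  res <- id_negative_control(fam)
  b <- setNames(res$table$beta, res$table$level)
  expect_gt(b[["mild"]], 0)
  expect_lt(res$table$lower[res$table$level == "mild"], b[["mild"]])
  expect_gt(res$table$lower[res$table$level == "mild"], 0)  # mild CI above 0
  # attenuation: mild exposure aggregates more than severe-profound
  expect_gt(b[["mild"]], b[["severe_profound"]])
  expect_gte(b[["mild"]], b[["moderate"]])
  # the non-linear (negative-control) shape is flagged
  expect_lt(res$trend$p_lackoffit, 0.01)
})

test_that("pairwise filters compose and match closed-form retention", {
  fam <- simulate_families(small_cfg(n_sib = 20000, n_mz = 0, n_dz = 0,
                                     seed = 49))
  expect_equal(nrow(suppressMessages(apply_filters(fam))), nrow(fam))
  # age window: both sibs must fall in [28, 34]; ages are iid uniform
  kept <- suppressMessages(apply_filters(fam, age_min = 28, age_max = 34))
  p_person <- (34 - 28) / (34.0 - 14.1)
  expect_lt(abs(nrow(kept) / nrow(fam) - p_person^2), 0.012)
  expect_true(all(kept$age >= 28 & kept$age <= 34))
  # severe-ID exclusion removes whole pairs
  fam$id_severity[1] <- "severe_profound"   # member 1 of family 1
  kept2 <- suppressMessages(apply_filters(fam, exclude_severe_id = TRUE))
  expect_false(any(kept2$family_id == fam$family_id[1]))
  expect_equal(nrow(kept2), nrow(fam) - 2)
  # condition subset drops diagnosis columns
  kept3 <- suppressMessages(apply_filters(fam, condition_subset =
                                            c("anxiety", "depression")))
  expect_equal(sort(grep("^dx_", names(kept3), value = TRUE)),
               c("dx_anxiety", "dx_depression"))
  expect_error(apply_filters(fam, condition_subset = "nonesuch"), "unknown")
})

test_that("homogeneous-mode sibling betas rise approximately in proportion to exposure", {
  fam <- simulate_families(small_cfg(n_sib = 100000, n_mz = 0, n_dz = 0,
                                     seed = 51))
  res <- suppressMessages(dummy_regression(fam))
  tab <- res$table[res$table$n >= 300, ]   # well-estimated levels
  expect_true(all(diff(tab$beta) > -0.05))          # monotone up to noise
  expect_gt(summary(lm(beta ~ level, data = tab))$r.squared, 0.85)
  expect_lt(res$trend$p_linear, 1e-6)
})
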