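test_that("double-entry ICC matches the analytic intraclass correlation", {
  set.seed(61)
  n <- 50000
  a <- rnorm(n, sd = sqrt(0.3))
  y1 <- a + rnorm(n, sd = sqrt(0.7))
  y2 <- a + rnorm(n, sd = sqrt(0.7))
  expect_lt(abs(pcontinuum:::icc_double_entry(y1, y2) - 0.3), 0.01)
})

test_that("independent twin pairs give a null heritability and e2 near 1", {
  set.seed(62)
  d <- make_twin_scores(matrix(rnorm(2 * 20000), ncol = 2),
                        matrix(rnorm(2 * 20000), ncol = 2))
  ace <- intraclass_and_ace(d, score = "score", n_boot = 0)
  expect_lt(abs(ace$r_mz), 0.02)
  expect_lt(ace$a2, 0.03)
  expect_gt(ace$e2, 0.95)
})

test_that("DZ correlation below half the MZ correlation forces the AE model", {
  set.seed(63)
  d <- make_twin_scores(rbvn_pairs(20000, 0.45), rbvn_pairs(20000, 0.14))
  ace <- intraclass_and_ace(d, score = "score", n_boot = 50, seed = 1)
  expect_identical(ace$model, "AE")
  expect_identical(ace$c2, 0)
  expect_lt(abs(ace$r_mz - 0.45), 0.02)
  expect_lt(abs(ace$r_dz - 0.14), 0.02)
  # AE maximum likelihood pools both zygosities
  expect_gt(ace$a2, 0.30); expect_lt(ace$a2, 0.45)
  expect_equal(ace$a2 + ace$e2, 1, tolerance = 1e-6)
  # bootstrap interval brackets the estimate
  expect_lte(ace$ci[1, "a2"], ace$a2)
  expect_gte(ace$ci[2, "a2"], ace$a2)
})

test_that("ACE parameters are recovered from untresholded liabilities", {
  cfg <- generator_config(n_sib_pairs = 0, n_mz_pairs = 20000,
                          n_dz_pairs = 20000,
                          ace_general = c(0.5, 0.2, 0.3), seed = 64)
  fam <- simulate_families(cfg)
  ace <- intraclass_and_ace(fam, score = "latent_general", n_boot = 0)
  expect_identical(ace$model, "ACE")
  expect_lt(abs(ace$a2 - 0.5), 0.03)
  expect_lt(abs(ace$c2 - 0.2), 0.03)
  expect_lt(abs(ace$e2 - 0.3), 0.03)
})

test_that("identical co-twin scores give group correlations of 1 and h2g = 1", {
  set.seed(65)
  y_mz <- rpois(3000, 0.5); y_dz <- rpois(6000, 0.5)
  d <- make_twin_scores(cbind(y_mz, y_mz), cbind(y_dz, y_dz))
  ext <- suppressWarnings(df_extremes(
    d, cutoffs = data.frame(label = "ge1", lo = 1, hi = Inf, scale = "raw"),
    score = "score", n_boot = 0))
  expect_equal(ext$t_mz, 1, tolerance = 1e-12)
  expect_equal(ext$t_dz, 1, tolerance = 1e-12)
  expect_equal(ext$h2g, 1, tolerance = 1e-12)
  expect_equal(ext$e2g, 0, tolerance = 1e-12)
})

test_that("published group correlations reproduce the worked-example estimates exactly", {
  ref <- read.csv(system.file("extdata", "register_group_correlations.csv",
                              package = "pcontinuum"))
  fits <- Map(df_group_model, ref$t_mz, ref$t_dz)
  h2g <- vapply(fits, `[[`, numeric(1), "h2g")
  e2g <- vapply(fits, `[[`, numeric(1), "e2g")
  expect_identical(h2g, c(0.44, 0.43, 0.42, 0.45))
  expect_identical(e2g, 1 - c(0.44, 0.43, 0.42, 0.45))
  # the 2(t_mz - t_dz) alternative is reported alongside
  alt <- vapply(fits, `[[`, numeric(1), "h2g_diff")
  expect_equal(alt, 2 * (ref$t_mz - ref$t_dz))
})

test_that("with a permissive cutoff the group correlation approaches the full-range correlation", {
  set.seed(66)
  d <- make_twin_scores(rbvn_pairs(40000, 0.4), rbvn_pairs(40000, 0.4))
  ext <- df_extremes(
    d, cutoffs = data.frame(label = "ge0", lo = 0, hi = Inf, scale = "sd"),
    score = "score", n_boot = 0)
  expect_lt(abs(ext$t_mz - 0.4), 0.03)
  expect_lt(abs(ext$t_dz - 0.4), 0.03)
})

test_that("thresholds with too few probands are skipped with a warning", {
  set.seed(67)
  d <- make_twin_scores(rbvn_pairs(200, 0.4), rbvn_pairs(200, 0.4))
  expect_warning(
    ext <- df_extremes(d, cutoffs = data.frame(label = "far", lo = 6,
                                               hi = Inf, scale = "sd"),
                       score = "score", n_boot = 0),
    "skipped")
  expect_true(is.na(ext$h2g))
})

test_that("group heritability tracks individual heritability under a continuous etiology", {
  cfg <- generator_config(n_sib_pairs = 0, n_mz_pairs = 20000,
                          n_dz_pairs = 20000, seed = 68)
  fam <- simulate_families(cfg)
  ace <- intraclass_and_ace(fam, n_boot = 0)
  ext <- suppressWarnings(df_extremes(fam, cutoffs = default_cutoffs("sd"),
                                      n_boot = 200, seed = 2))
  expect_lt(abs(ext$h2g[ext$label == "ge_2"] - ace$a2), 0.05)
  expect_true(all(ext$e2g + ext$h2g == 1, na.rm = TRUE))
  # bootstrap CIs bracket the point estimates
  ok <- !is.na(ext$h2g)
  expect_true(all(ext$h2g_lower[ok] <= ext$h2g[ok] + 1e-9))
  expect_true(all(ext$h2g_upper[ok] >= ext$h2g[ok] - 1e-9))
})

test_that("at register-study scale the homogeneous continuity verdict is affirmative", {
  cfg <- generator_config(n_sib_pairs = 0, n_mz_pairs = 5133,
                          n_dz_pairs = 12037, seed = 70)
  fam <- simulate_families(cfg)
  cont <- suppressWarnings(continuity_report(fam, n_boot = 200, seed = 5))
  expect_true(all(cont$covers_zero[!is.na(cont$diff_lower)]))
  expect_match(attr(cont, "verdict"), "consistent")
})

test_that("non-familial extreme shocks drive group heritability below individual heritability", {
  cfg <- generator_config(n_sib_pairs = 0, n_mz_pairs = 50000,
                          n_dz_pairs = 50000,
                          extreme_mode = "discontinuous", seed = 69)
  fam <- simulate_families(cfg)
  cont <- suppressWarnings(continuity_report(fam, n_boot = 100, seed = 4))
  top <- cont[cont$label == "ge4_profound", ]
  expect_lt(top$diff, 0)
  expect_lt(top$diff_upper, 0)       # significantly below
  expect_match(attr(cont, "verdict"), "differ")
})
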