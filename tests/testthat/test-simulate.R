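test_that("marginal prevalences match configuration and null loadings give no familiality", {
  p <- 10
  cfg <- generator_config(
    n_sib_pairs = 50000, n_mz_pairs = 0, n_dz_pairs = 0,
    loadings_general = rep(0, p),
    loadings_specific = matrix(0, p, 3),
    prevalences = rep(0.10, p), age_beta = 0, seed = 101)
  fam <- simulate_families(cfg)
  prev <- colMeans(fam[, grep("^dx_", names(fam))])
  se <- sqrt(0.1 * 0.9 / nrow(fam))
  expect_true(all(abs(prev - 0.10) < 3 * se + 1e-3))
  pd <- sibling_pair_table(fam)
  sib_cor <- cor(pd$exposure, pd$outcome)
  expect_lt(abs(sib_cor), 0.02)
})

test_that("latent cross-member correlations follow the configured ACE structure", {
  cfg <- generator_config(n_sib_pairs = 0, n_mz_pairs = 20000,
                          n_dz_pairs = 20000, ace_general = c(0.45, 0, 0.55),
                          seed = 7)
  fam <- simulate_families(cfg)
  tp <- twin_pair_table(fam, score = "latent_general")
  r <- tapply(seq_len(nrow(tp)), tp$zygosity,
              function(i) cor(tp$y1[i], tp$y2[i]))
  expect_lt(abs(r[["MZ"]] - 0.45), 0.02)
  expect_lt(abs(r[["DZ"]] - 0.225), 0.02)
  # MZ - DZ latent gap estimates half the additive variance
  expect_lt(abs((r[["MZ"]] - r[["DZ"]]) - 0.5 * 0.45), 0.03)
})

test_that("a perfectly heritable single condition yields the textbook tetrachoric pattern", {
  cfg <- generator_config(
    n_sib_pairs = 0, n_mz_pairs = 20000, n_dz_pairs = 20000,
    conditions = "trait",
    loadings_general = 0.999,
    loadings_specific = matrix(0, 1, 1),
    prevalences = 0.2, ace_general = c(1, 0, 0), age_beta = 0, seed = 13)
  fam <- simulate_families(cfg)
  tet_by_zyg <- function(rel) {
    d <- fam[fam$relationship == rel, ]
    i1 <- seq(1, nrow(d), 2)
    x <- d$dx_trait[i1]; y <- d$dx_trait[i1 + 1]
    tetrachoric_from_counts(sum(!x & !y), sum(!x & y), sum(x & !y),
                            sum(x & y))$rho
  }
  expect_gt(tet_by_zyg("MZ"), 0.95)
  expect_lt(abs(tet_by_zyg("DZ") - 0.5), 0.07)
})

test_that("generation is deterministic and rate-0 discontinuous mode equals homogeneous", {
  cfg <- small_cfg(seed = 42)
  expect_identical(simulate_families(cfg), simulate_families(cfg))
  cfg_d0 <- small_cfg(seed = 42, extreme_mode = "discontinuous",
                      discontinuity_rate = 0)
  expect_identical(simulate_families(cfg), simulate_families(cfg_d0))
  # positive rate changes the draw
  cfg_d <- small_cfg(seed = 42, extreme_mode = "discontinuous")
  expect_false(identical(simulate_families(cfg), simulate_families(cfg_d)))
})

test_that("default calibration yields a right-skewed sum score with mean in the register range", {
  cfg <- small_cfg(n_sib = 20000, n_mz = 2000, n_dz = 4000, seed = 3)
  fam <- simulate_families(cfg)
  sc <- sum_score(fam)
  expect_gt(mean(sc), 0.15)
  expect_lt(mean(sc), 0.30)
  skew <- mean(((sc - mean(sc)) / sd(sc))^3)
  expect_gt(skew, 1)          # strongly right-skewed
  expect_gt(sd(sc), mean(sc)) # overdispersed count-like scale
})

test_that("ages respect the configured range and the pair structure", {
  fam <- simulate_families(small_cfg(n_sib = 2000, n_mz = 500, n_dz = 500,
                                     seed = 5))
  expect_true(all(fam$age >= 14.1 & fam$age <= 34.0))
  sib <- fam[fam$relationship == "full_sibling", ]
  older <- sib$age[sib$role == "older_sib"]
  younger <- sib$age[sib$role == "younger_sib"]
  expect_true(all(older >= younger))
  tw <- fam[fam$relationship == "MZ", ]
  expect_equal(tw$age[tw$role == "twin1"], tw$age[tw$role == "twin2"])
  # every family has exactly two members with one relationship
  expect_true(all(table(fam$family_id) == 2))
  expect_true(all(tapply(fam$relationship, fam$family_id,
                         function(x) length(unique(x))) == 1))
})

test_that("ID severity bands anchor to normal tail integrals and configured prevalences", {
  # conceptual anchors: mass between 2/3.33/4.33 SD cuts of a standard normal
  expect_equal(pnorm(-2) - pnorm(-3.33), 0.02232, tolerance = 1e-3)
  expect_equal(pnorm(-3.33) - pnorm(-4.33), 4.27e-4, tolerance = 1e-2)
  expect_equal(pnorm(-4.33), 7.5e-6, tolerance = 1e-1)

  cfg <- small_cfg(n_sib = 100000, n_mz = 0, n_dz = 0, seed = 11)
  fam <- simulate_id_negative_control(cfg, simulate_families(cfg))
  tab <- table(fam$id_severity) / nrow(fam)
  idp <- cfg$id_params
  for (cl in names(idp$prevalence)) {
    se <- sqrt(idp$prevalence[[cl]] / nrow(fam))
    expect_lt(abs(tab[[cl]] - idp$prevalence[[cl]]), 4 * se + 2e-4)
  }
})

test_that("fully de-novo ID produces no sibling aggregation", {
  cfg <- small_cfg(n_sib = 150000, n_mz = 0, n_dz = 0, seed = 19,
                   id_params = list(familial_share = c(mild = 0, moderate = 0,
                                                       severe_profound = 0)))
  fam <- simulate_id_negative_control(cfg, simulate_families(cfg))
  res <- id_negative_control(fam, conf_level = 0.99)
  nonref <- res$table[res$table$level != "none", ]
  expect_true(all(nonref$lower <= 0 & nonref$upper >= 0))
  expect_true(all(abs(nonref$beta) < 0.1))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(n_sib_pairs = -1), "non-negative")
  expect_error(generator_config(n_sib_pairs = 0, n_mz_pairs = 0,
                                n_dz_pairs = 0), "positive total")
  expect_error(generator_config(loadings_general = rep(0.9, 10)),
               "communality")
  expect_error(generator_config(prevalences = rep(0.6, 10)), "prevalences")
  expect_error(generator_config(ace_general = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_warning(generator_config(
    id_params = list(prevalence = c(mild = 0.001, moderate = 0.002,
                                    severe_profound = 0.003))),
    "not strictly decreasing")
})

test_that("family CSV round-trips through disk", {
  fam <- simulate_families(small_cfg(n_sib = 200, n_mz = 50, n_dz = 50,
                                     seed = 2))
  path <- tempfile(fileext = ".csv")
  write_family_csv(fam, path)
  back <- read_family_csv(path)
  expect_equal(sum_score(back), sum_score(fam))
  expect_equal(back$relationship, fam$relationship)
  expect_equal(back$age, fam$age, tolerance = 1e-9)
})
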