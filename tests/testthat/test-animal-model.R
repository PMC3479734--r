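# Unit-level sampler checks; the heavier calibration suites (parameter
# recovery across families, prior recovery, null traits, chain quality)
# live in test-acceptance.R.

test_that("trait and MCMC specifications validate their invariants", {
  expect_error(trait_spec("SR_wB", "binary-logit",
                          random = c("additive", "permanent_individual")),
               "not identifiable")
  expect_error(mcmc_config(iterations = 100, burn_in = 200, seed = 1),
               "burn_in")
  expect_error(mcmc_config(seed = 1, thin = 0), "thin")
  expect_error(mcmc_config(), "seed")
  expect_error(prior_spec(nu = 0), "nu")
  pp <- mcmc_config(seed = 1, preset = "paper")
  expect_equal(pp$iterations, 3005000L)
  expect_equal(pp$thin, 3000L)
})

test_that("model specification files round-trip into fit configuration", {
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "traits:",
    "  - name: EPR_L",
    "    family: binomial-logit",
    "    fixed: [intercept, age_class, f]",
    "    random: [additive, year, permanent_individual]",
    "  - name: ARS_w",
    "    family: gaussian",
    "priors:",
    "  nu: 0.02",
    "mcmc:",
    "  iterations: 900",
    "  burn_in: 100",
    "  thin: 4",
    "  seed: 11"), tf)
  ms <- read_model_spec(tf)
  expect_length(ms$traits, 2L)
  expect_equal(ms$traits[[1]]$family, "binomial-logit")
  expect_setequal(ms$traits[[1]]$random,
                  c("additive", "year", "permanent_individual"))
  expect_equal(ms$priors$nu, 0.02)
  expect_equal(ms$mcmc$iterations, 900L)
  expect_equal(ms$mcmc$seed, 11L)
  expect_error(read_model_spec("/nonexistent.yaml"), "not found")
})

test_that("fitting errors early on inconsistent inputs", {
  sim <- small_sim(52, n_founder_pairs = 5, n_years = 3)
  tt <- build_trait_table(sim$female_years, sim$offspring)
  ped <- sim$pedigree
  # a phenotyped individual absent from the pedigree
  bad <- tt[tt$trait == "ARS_w", ]
  bad$individual_id[1] <- "GHOST"; bad$unit_id[1] <- "GHOST:1"
  class(bad) <- class(tt)
  expect_error(
    fit_animal_model(spec_ars(), bad, ped = ped,
                     mcmc = mcmc_config(iterations = 200, burn_in = 50,
                                        thin = 1, seed = 1)),
    "GHOST")
  expect_error(
    fit_animal_model(spec_ars(), tt, ped = NULL,
                     mcmc = mcmc_config(iterations = 200, burn_in = 50,
                                        thin = 1, seed = 1)),
    "pedigree is required")
})

test_that("identical data, priors, config and seed give identical draws", {
  sim <- small_sim(53, n_founder_pairs = 6, n_years = 4)
  st <- simulate_traits(sim$pedigree, "gaussian", G_A = 0.3, G_Y = 0.1,
                        G_R = 0.6, seed = 9)
  mc <- mcmc_config(iterations = 400, burn_in = 100, thin = 2, seed = 77)
  f1 <- fit_animal_model(gauss_spec(), st$data, ped = sim$pedigree, mcmc = mc)
  f2 <- fit_animal_model(gauss_spec(), st$data, ped = sim$pedigree, mcmc = mc)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_animal_model(gauss_spec(), st$data, ped = sim$pedigree,
                         mcmc = mcmc_config(iterations = 400, burn_in = 100,
                                            thin = 2, seed = 78))
  expect_false(identical(f3$draws, f1$draws))
})

test_that("fixed covariance elements never move; free draws respect PSD bounds", {
  sim <- small_sim(54, n_founder_pairs = 8, n_years = 5)
  tt <- build_trait_table(sim$female_years, sim$offspring)
  ped <- prune_pedigree(sim$pedigree,
                        unique(tt$individual_id))
  fit <- fit_animal_model(list(spec_epr(), spec_sr("binary")), tt, ped = ped,
                          mcmc = mcmc_config(iterations = 600, burn_in = 100,
                                             thin = 2, seed = 5))
  d <- fit$draws
  # binary residual fixed to 1, residual covariance fixed to 0
  expect_true(all(d[, "VR.SR_wB"] == 1))
  expect_true(all(d[, "covR.EPR_L:SR_wB"] == 0))
  # variances non-negative; within-block covariances bounded by the
  # geometric mean of the variances
  expect_true(all(d[, "VA.EPR_L"] >= 0))
  expect_true(all(abs(d[, "covA.EPR_L:SR_wB"]) <=
                    sqrt(d[, "VA.EPR_L"] * d[, "VA.SR_wB"]) + 1e-12))
  expect_true(all(abs(d[, "covY.EPR_L:SR_wB"]) <=
                    sqrt(d[, "VY.EPR_L"] * d[, "VY.SR_wB"]) + 1e-12))
  # latent MH acceptance adapted into a sane band
  expect_true(all(fit$acceptance[c("EPR_L", "SR_wB")] > 0.1 &
                    fit$acceptance[c("EPR_L", "SR_wB")] < 0.8))
})

test_that("bivariate fits impute missing responses instead of dropping rows", {
  sim <- small_sim(55, n_founder_pairs = 8, n_years = 5)
  fy <- sim$female_years
  expect_gt(sum(fy$ars == 0), 0)       # some breeding failures present
  tt <- build_trait_table(fy, NULL)
  ped <- prune_pedigree(sim$pedigree, unique(fy$female_id))
  fit <- fit_animal_model(list(spec_epr(), spec_ars()), tt, ped = ped,
                          mcmc = mcmc_config(iterations = 500, burn_in = 100,
                                             thin = 2, seed = 6))
  # every female-year contributes a record for both traits (EPR_L imputed
  # where ars = 0)
  expect_equal(fit$n_records, 2L * nrow(fy))
  expect_true(all(c("covA.EPR_L:ARS_w", "covPI.EPR_L:ARS_w",
                    "covY.EPR_L:ARS_w", "covR.EPR_L:ARS_w")
                  %in% colnames(fit$draws)))
})

test_that("posterior of a conjugate Gaussian mean matches the closed form", {
  # unrelated individuals, known residual variance, intercept-only model:
  # the exact posterior is N(sum(y)/(n + vr/1e8), vr/(n + vr/1e8))
  set.seed(60)
  n <- 50; vr <- 0.8; mu <- 1.3
  ped <- pedigree(data.frame(id = sprintf("u%02d", 1:n), dam = NA, sire = NA))
  y <- rnorm(n, mu, sqrt(vr))
  tt <- data.frame(individual_id = ped$id, unit_id = ped$id, year = 1L,
                   trait = "z", value = y, denom = NA_real_,
                   age_class = NA_character_, f = 0, sex = NA_character_)
  class(tt) <- c("trait_table", "data.frame")
  ts <- trait_spec("z", "gaussian", fixed = "intercept", random = character(0))
  fit <- fit_animal_model(
    ts, tt, ped = NULL,
    constraints = cov_structure(residual = list(value = matrix(vr),
                                                free = matrix(FALSE))),
    mcmc = mcmc_config(iterations = 2100, burn_in = 100, thin = 1, seed = 61))
  expect_true(all(fit$draws[, "VR.z"] == vr))
  b <- fit$draws[, "beta.z.(Intercept)"]
  prec <- n / vr + 1e-8
  post_mean <- sum(y) / vr / prec
  post_sd <- sqrt(1 / prec)
  expect_lt(abs(mean(b) - post_mean), 4 * post_sd / sqrt(length(b)))
  expect_lt(abs(sd(b) - post_sd), 0.15 * post_sd)
})

test_that("summaries of a real fit expose modes, intervals and diagnostics", {
  sim <- small_sim(56, n_founder_pairs = 6, n_years = 4)
  st <- simulate_traits(sim$pedigree, "gaussian", G_A = 0.5, G_Y = 0.1,
                        G_R = 0.5, seed = 62)
  fit <- fit_animal_model(gauss_spec(), st$data, ped = sim$pedigree,
                          mcmc = mcmc_config(iterations = 700, burn_in = 200,
                                             thin = 2, seed = 63))
  s <- summarize_posterior(fit)
  expect_true(all(s$l95 <= s$u95))
  expect_setequal(
    s$parameter,
    c("VA.trait1", "VY.trait1", "VR.trait1", "beta.trait1.(Intercept)"))
  expect_true(all(is.finite(s$mode)))
  h <- heritability(fit, "trait1")
  expect_true(all(h$draws >= 0 & h$draws <= 1))
})
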