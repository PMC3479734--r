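test_that("simulation is deterministic and emits valid, round-tripping files", {
  cfg <- sim_config(n_founder_pairs = 8, n_years = 5, seed = 71)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$female_years, s2$female_years)
  expect_identical(s1$offspring, s2$offspring)
  expect_identical(as.data.frame(s1$pedigree), as.data.frame(s2$pedigree))

  # generated pedigree passes validation (construction sorts + checks)
  expect_s3_class(s1$pedigree, "pedigree")
  # recorded offspring f equals the pedigree-derived inbreeding
  f <- inbreeding(s1$pedigree)
  expect_equal(unname(f[s1$offspring$offspring_id]), s1$offspring$f,
               tolerance = 1e-12)

  d <- withr::local_tempdir()
  write_sim_output(s1, d)
  ped2 <- read_pedigree(file.path(d, "pedigree.csv"))
  expect_equal(as.data.frame(ped2), as.data.frame(s1$pedigree))
  fy2 <- read.csv(file.path(d, "female_years.csv"),
                  colClasses = c(female_id = "character"))
  expect_equal(fy2, s1$female_years)
  truth <- jsonlite::read_json(file.path(d, "truth.json"))
  expect_equal(truth$realised$n_offspring, nrow(s1$offspring))
})

test_that("config validation rejects bad rates and non-PSD matrices", {
  expect_error(sim_config(epr_rate = 1.4, seed = 1), "epr_rate")
  G <- default_g <- eprqg:::default_G()$A
  G[1, 2] <- G[2, 1] <- 5          # breaks positive semi-definiteness
  expect_error(sim_config(G_A = G, seed = 1), "positive semi-definite")
  expect_error(sim_config(), "seed")
})

test_that("population extinction is reported with the failing year", {
  cfg <- sim_config(n_founder_pairs = 2, n_years = 30, adult_survival = 0.05,
                    recruitment_rate = 0.01, immigrants_per_year = 0,
                    seed = 72)
  expect_error(simulate_population(cfg), "extinct in year")
})

test_that("realised rates hit the calibration targets at large sample size", {
  cfg <- sim_config(n_founder_pairs = 45, n_years = 45, seed = 73)
  sim <- simulate_population(cfg)
  r <- sim$truth$realised
  expect_gt(r$n_offspring, 5000)
  expect_lt(abs(r$epo_proportion - 0.29), 0.02)
  expect_lt(abs(r$recruitment_rate - 0.195), 0.02)
  expect_lt(abs(r$mean_ars - 4.7), 0.35)

  # Mendelian-sampling deviations: var = V_A/2 scaled by parental f
  mc <- mendelian_check(sim$pedigree, sim$breeding_values[, "EPR_L"],
                        V_A = 1.198)
  expect_lt(abs(mc$ratio - 1), 0.1)
  mc3 <- mendelian_check(sim$pedigree, sim$breeding_values[, "SR"],
                         V_A = 0.405)
  expect_lt(abs(mc3$ratio - 1), 0.1)
  expect_error(mendelian_check(sim$pedigree, sim$breeding_values[, "EPR_L"],
                               1.198, min_n = 1e6), "too few")
})

test_that("founder breeding values reproduce the configured genetic covariance", {
  # 1,000 unrelated founders simulated directly on a founder-only pedigree
  ped <- pedigree(data.frame(id = sprintf("f%04d", 1:1000), dam = NA,
                             sire = NA))
  GA <- matrix(c(1.198, 0.087, 0.087, 0.016), 2)
  st <- simulate_traits(ped, c("gaussian", "gaussian"), G_A = GA,
                        G_Y = diag(0, 2), G_R = diag(c(0.5, 0.5)),
                        seed = 74)
  C <- cov(st$breeding_values)
  expect_lt(abs(C[1, 1] - GA[1, 1]), 0.15 * GA[1, 1])
  expect_lt(abs(C[2, 2] - GA[2, 2]), 0.15 * GA[2, 2])
  expect_lt(abs(C[1, 2] - GA[1, 2]), 0.15 * sqrt(GA[1, 1] * GA[2, 2]))
})

test_that("zero additive variance gives identical mid-parent offspring values", {
  sim <- small_sim(75, n_founder_pairs = 6, n_years = 4)
  st <- simulate_traits(sim$pedigree, "gaussian", G_A = 0, G_Y = 0.1,
                        G_R = 0.6, seed = 76)
  expect_true(all(st$breeding_values == 0))
})
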