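# End-to-end pipeline on a small simulated population with short chains;
# the point is structure, determinism and resumability, not posterior
# precision.

tiny_mcmc <- function(seed) mcmc_config(iterations = 700, burn_in = 200,
                                        thin = 5, seed = seed)

test_that("run_analysis produces the four model blocks and prediction tables", {
  out <- withr::local_tempdir()
  cfg <- run_config(sim = sim_config(n_founder_pairs = 8, n_years = 5,
                                     seed = 81),
                    outdir = out, mcmc = tiny_mcmc(810))
  rep1 <- run_analysis(cfg)

  expect_s3_class(rep1, "epr_report")
  expect_named(rep1$fits, c("epr_ars", "epr_srb", "epr_srg", "ars_srb"))
  expect_equal(length(unique(rep1$report_table$model)), 4L)
  # fixed cells rendered as such in the report table
  srb_row <- rep1$report_table[rep1$report_table$trait == "SR_wB", ][1, ]
  expect_match(srb_row$V_R, "fixed")
  expect_match(srb_row$cov_R, "fixed")
  # selection predictions: per-component plus the summed response
  expect_named(rep1$predictions, c("ARS_w", "SR_wB", "SR_wG", "summed"))
  expect_null(rep1$predictions$summed$ci95)  # separate fits: no CI
  expect_equal(rep1$predictions$summed$delta_A,
               rep1$predictions$ARS_w$delta_A +
                 rep1$predictions$SR_wG$delta_A)
  # observed-scale changes stay inside the logistic bounds
  p0 <- rep1$baseline_prop
  expect_true(all(rep1$observed_scale$observed_scale > -p0 &
                    rep1$observed_scale$observed_scale < 1 - p0))
  expect_true(all(file.exists(rep1$files)))
  # breeder's equation consistency
  expect_equal(rep1$breeders_equation$R,
               rep1$breeders_equation$h2 * rep1$breeders_equation$S)
})

test_that("cached chains make re-summarisation exact and reports reproducible", {
  out1 <- withr::local_tempdir()
  cfg1 <- run_config(sim = sim_config(n_founder_pairs = 8, n_years = 5,
                                      seed = 81),
                     outdir = out1, mcmc = tiny_mcmc(810))
  rep1 <- run_analysis(cfg1)

  # rerun in the same directory: fits come from cache, summaries identical
  cfg1b <- run_config(sim = sim_config(n_founder_pairs = 8, n_years = 5,
                                       seed = 81),
                      outdir = out1, mcmc = tiny_mcmc(810), overwrite = TRUE)
  rep1b <- run_analysis(cfg1b)
  expect_identical(rep1b$summaries, rep1$summaries)
  expect_identical(rep1b$predictions$ARS_w$draws, rep1$predictions$ARS_w$draws)

  # fresh directory, same seeds: identical report bytes
  out2 <- withr::local_tempdir()
  cfg2 <- run_config(sim = sim_config(n_founder_pairs = 8, n_years = 5,
                                      seed = 81),
                     outdir = out2, mcmc = tiny_mcmc(810))
  rep2 <- run_analysis(cfg2)
  expect_identical(readLines(rep2$files["predictions"]),
                   readLines(rep1$files["predictions"]))
  expect_identical(readLines(rep2$files["report"]),
                   readLines(rep1$files["report"]))

  # refusing to clobber existing outputs without the flag
  cfg3 <- run_config(sim = sim_config(n_founder_pairs = 8, n_years = 5,
                                      seed = 81),
                     outdir = out1, mcmc = tiny_mcmc(810))
  expect_error(run_analysis(cfg3), "overwrite")
})

test_that("missing input files are reported before any sampling", {
  expect_error(
    run_config(inputs = list(pedigree = "/nonexistent/ped.csv",
                             female_years = "/nonexistent/fy.csv",
                             offspring = "/nonexistent/off.csv"),
               outdir = withr::local_tempdir(), mcmc = tiny_mcmc(1)),
    "/nonexistent/ped.csv")
})

test_that("file-based inputs reproduce the simulated-input pipeline", {
  out <- withr::local_tempdir()
  sim <- simulate_population(sim_config(n_founder_pairs = 8, n_years = 5,
                                        seed = 81))
  ind <- file.path(out, "data")
  write_sim_output(sim, ind)
  cfg <- run_config(inputs = list(pedigree = file.path(ind, "pedigree.csv"),
                                  female_years = file.path(ind, "female_years.csv"),
                                  offspring = file.path(ind, "offspring.csv")),
                    outdir = file.path(out, "run"), mcmc = tiny_mcmc(810))
  rep_f <- run_analysis(cfg)
  expect_s3_class(rep_f, "epr_report")
  expect_equal(rep_f$rates$epo_proportion,
               sim$truth$realised$epo_proportion)
})
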