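mk_pred <- function(z, w, draws, chain = NULL) {
  if (!is.null(chain)) attr(draws, "chain_id") <- chain
  eprqg:::new_prediction(z, w, draws)
}

test_that("secondary theorem is the identity on the additive covariance chain", {
  d <- cbind("covA.EPR_L:ARS_w" = rnorm(200, 0.09, 0.05))
  fit <- structure(list(draws = d, tnames = c("EPR_L", "ARS_w"),
                        mcmc = list(seed = 1),
                        param_info = data.frame(name = colnames(d),
                                                kind = "covariance",
                                                free = TRUE)),
                   class = "epr_fit")
  p <- secondary_theorem(fit, "EPR_L", "ARS_w")
  expect_equal(as.numeric(p$draws), as.numeric(d[, 1]))
  s <- summarize_posterior(d)
  expect_equal(p$delta_A, s$mean)
  expect_equal(p$ci95, c(s$l95, s$u95))

  # all-zero covariance predicts no change
  fit$draws[, 1] <- 0
  expect_equal(secondary_theorem(fit, "EPR_L", "ARS_w")$delta_A, 0)
  expect_error(secondary_theorem(fit, "EPR_L", "SR_wB"), "no additive")
})

test_that("summed responses add component covariances", {
  # posterior-mean covariances with the two fitness components sum to 0.18
  p1 <- mk_pred("EPR_L", "ARS_w", rep(0.087, 150))
  p2 <- mk_pred("EPR_L", "SR_wG", rep(0.093, 150))
  ps <- sum_components(list(p1, p2))
  expect_equal(ps$delta_A, 0.180)
  # separate fits: no credible interval for the sum
  expect_null(ps$ci95)

  # aligned draws from one chain sum per draw and keep a CI
  set.seed(21)
  x <- rnorm(150, 0.1, 0.02)
  q1 <- mk_pred("EPR_L", "ARS_w", x, chain = "c1")
  q2 <- mk_pred("EPR_L", "SR_wG", -x, chain = "c1")
  qs <- sum_components(list(q1, q2))
  expect_equal(qs$delta_A, 0)
  expect_equal(qs$ci95, c(0, 0))

  expect_equal(sum_components(list(p1, mk_pred("EPR_L", "x", rep(0, 150))))$delta_A,
               p1$delta_A)
  expect_error(sum_components(list(p1, mk_pred("ARS_w", "w", rep(0, 150)))),
               "share the focal trait")
})

test_that("back-transformation maps liability change to proportion change", {
  # worked case: +0.087 liability at baseline 0.29; expected value from
  # hand arithmetic: 1/(1 + exp(log(71/29) - 0.087)) - 0.29
  expect_lt(abs(backtransform(0.087, 0.29) - 0.018229), 1e-5)
  expect_equal(round(backtransform(0.087, 0.29), 2), 0.02)
  expect_equal(backtransform(0, 0.4), 0)
  expect_error(backtransform(0.1, 0), "inside")
  expect_error(backtransform(0.1, 1), "inside")

  # strictly increasing, bounded in (-p0, 1 - p0), saturating
  p0 <- 0.29
  dl <- seq(-8, 8, by = 0.25)
  bt <- backtransform(dl, p0)
  expect_true(all(diff(bt) > 0))
  expect_true(all(bt > -p0 & bt < 1 - p0))
  expect_equal(backtransform(50, p0), 1 - p0, tolerance = 1e-8)

  # inverse-logit symmetry: plogis(-x) = 1 - plogis(x)
  x <- seq(-10, 10, by = 0.5)
  expect_equal(plogis(-x), 1 - plogis(x), tolerance = 1e-12)
  expect_equal(backtransform(x, 0.5), -backtransform(-x, 0.5),
               tolerance = 1e-12)
})

test_that("breeder's equation multiplies heritability and differential", {
  be <- breeders_equation(0.17, -0.03)
  expect_equal(be$R, -0.0051)
  expect_equal(round(be$R, 3), -0.005)
  expect_equal(breeders_equation(0.4, 0)$R, 0)
  expect_equal(breeders_equation(0, 2)$R, 0)
  expect_error(breeders_equation(1.3, 0.1), "0, 1")
  # bilinear
  expect_equal(breeders_equation(0.2, 0.3)$R + breeders_equation(0.2, 0.5)$R,
               breeders_equation(0.2, 0.8)$R)
})

test_that("selection differential recovers the generating residual covariance", {
  # two traits with year structure but no individual-level cross-trait
  # covariance: the posterior CI of cov_R should cover zero
  set.seed(31)
  n <- 250
  fy <- data.frame(female_id = sprintf("F%03d", seq_len(n)),
                   year = sample(1:6, n, replace = TRUE),
                   age_years = sample(1:5, n, replace = TRUE),
                   f = round(runif(n, 0, 0.2), 3), ars = 0, epo = 0)
  uy <- rnorm(6, 0, sqrt(0.1))
  fy$ars <- pmax(1L, as.integer(round(4.7 * (1 + uy[fy$year] + rnorm(n, 0, 0.4)))))
  lia <- -1 + rnorm(6, 0, 0.3)[fy$year] + rnorm(n, 0, 1)
  fy$epo <- rbinom(n, fy$ars, plogis(lia))
  tt <- build_trait_table(fy, NULL)
  sd0 <- selection_differential(tt, mcmc = mcmc_config(iterations = 2500,
                                                       burn_in = 500,
                                                       thin = 4, seed = 5))
  expect_lt(sd0$ci95[1], 0)
  expect_gt(sd0$ci95[2], 0)

  # induced negative residual covariance is detected as a negative
  # posterior mean in most replicates
  neg <- 0
  reps <- 10
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    e <- matrix(rnorm(2 * n), n) %*% chol(matrix(c(1, -0.35, -0.35, 0.16), 2))
    fy2 <- fy
    fy2$ars <- pmax(1L, as.integer(round(4.7 * (1 + e[, 2]))))
    fy2$epo <- rbinom(n, fy2$ars, plogis(-1 + e[, 1]))
    tt2 <- build_trait_table(fy2, NULL)
    sdn <- selection_differential(tt2, mcmc = mcmc_config(iterations = 1500,
                                                          burn_in = 300,
                                                          thin = 3,
                                                          seed = 600 + r))
    if (sdn$S < 0) neg <- neg + 1
  }
  expect_gte(neg, 9)
})
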