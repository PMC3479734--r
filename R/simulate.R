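## Synthetic island-population generator.
##
## Emulates a small, intensively monitored island songbird population with
## overlapping generations: social pairing each year, extra-pair paternity
## driven by a latent logit liability of the mother, annual reproductive
## success with year / permanent-individual / residual structure,
## recruitment as a binary threshold trait, inbreeding depression on all
## three traits, and occasional unrelated immigrants.  Kinship is tracked
## exactly among (potential) parents, so offspring inbreeding coefficients
## and Mendelian-sampling variances honour the realised pedigree.

sim_traits <- c("EPR_L", "ARS_w", "SR")

#' Simulation configuration
#'
#' Defaults reproduce the headline structure of a well-studied island
#' songbird system: mean annual reproductive success about 4.7 ringed
#' offspring, an extra-pair offspring proportion of 0.29, recruitment rate
#' 0.195, 1.1 immigrants per year, and (co)variance components on the
#' liability / relative-fitness scales taken from the posterior means of
#' the bivariate animal-model analyses of that system (trait order:
#' extra-pair liability, relative annual reproductive success, recruitment
#' liability).
#'
#' @param n_founder_pairs breeding pairs in year 1.
#' @param n_years number of breeding seasons.
#' @param mean_ars target mean ringed offspring per female-year.
#' @param epr_rate target marginal extra-pair offspring proportion.
#' @param recruitment_rate target marginal recruitment probability.
#' @param immigrants_per_year Poisson mean of yearly immigrant arrivals.
#' @param adult_survival yearly adult survival probability (chosen so the
#'   default population is roughly stationary).
#' @param max_pairs carrying capacity: at most this many social pairs breed
#'   in any year (surplus adults are non-breeding floaters).  The default
#'   matches the upper end of the island population's observed 15-45
#'   breeding pairs and keeps long simulations density-regulated.
#' @param G_A,G_Y,G_PI,G_R 3x3 (co)variance matrices of the additive
#'   genetic, year, permanent-individual and residual effects (the
#'   permanent-individual and residual rows for recruitment are zero and
#'   one respectively: a binary trait's residual is the unit liability
#'   noise).
#' @param beta_f inbreeding-depression slopes (liability / relative scale)
#'   per trait.
#' @param calibration_f mean inbreeding coefficient assumed when solving
#'   for the liability intercepts that hit the target rates (the long-run
#'   mean of the simulated population).
#' @param seed integer RNG seed (required).
#' @return object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_founder_pairs = 20, n_years = 10,
                       mean_ars = 4.7, epr_rate = 0.29,
                       recruitment_rate = 0.195,
                       immigrants_per_year = 1.1,
                       adult_survival = 0.6,
                       max_pairs = 45,
                       G_A = default_G()$A, G_Y = default_G()$Y,
                       G_PI = default_G()$PI, G_R = default_G()$R,
                       beta_f = c(EPR_L = -0.17, ARS_w = -1.07, SR = -8.04),
                       calibration_f = 0.05,
                       seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  for (nm in c("epr_rate", "recruitment_rate", "adult_survival")) {
    v <- get(nm)
    if (v < 0 || v > 1) stop(nm, " must be in [0, 1]")
  }
  for (nm in c("G_A", "G_Y", "G_PI", "G_R")) {
    G <- as.matrix(get(nm))
    if (!all(dim(G) == 3L)) stop(nm, " must be 3x3 (EPR_L, ARS_w, SR)")
    if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(nm, " is not positive semi-definite")
  }
  structure(list(n_founder_pairs = n_founder_pairs, n_years = n_years,
                 mean_ars = mean_ars, epr_rate = epr_rate,
                 recruitment_rate = recruitment_rate,
                 immigrants_per_year = immigrants_per_year,
                 adult_survival = adult_survival,
                 max_pairs = max_pairs,
                 G_A = as.matrix(G_A), G_Y = as.matrix(G_Y),
                 G_PI = as.matrix(G_PI), G_R = as.matrix(G_R),
                 beta_f = beta_f, calibration_f = calibration_f,
                 seed = as.integer(seed)),
            class = "sim_config")
}

default_G <- function() {
  tn <- sim_traits
  A <- matrix(c(1.198, 0.087, 0.160,
                0.087, 0.016, 0.025,
                0.160, 0.025, 0.405), 3, 3, dimnames = list(tn, tn))
  Y <- matrix(c(0.024, -0.011, 0.036,
                -0.011, 0.060, 0.033,
                0.036, 0.033, 0.744), 3, 3, dimnames = list(tn, tn))
  PI <- matrix(c(0.139, 0.018, 0,
                 0.018, 0.022, 0,
                 0, 0, 0), 3, 3, dimnames = list(tn, tn))
  R <- matrix(c(2.015, -0.105, 0,
                -0.105, 0.147, 0,
                0, 0, 1), 3, 3, dimnames = list(tn, tn))
  list(A = A, Y = Y, PI = PI, R = R)
}

## expected value of plogis(mu + sigma Z), Z standard normal
logit_normal_mean <- function(mu, sigma) {
  if (sigma == 0) return(stats::plogis(mu))
  stats::integrate(function(z) stats::plogis(mu + sigma * z) * stats::dnorm(z),
                   -Inf, Inf, rel.tol = 1e-9)$value
}

#' Solve for the logit intercept giving a target marginal rate
#'
#' One-dimensional root find for the intercept \code{mu} such that
#' \code{E[plogis(mu + offset + sigma Z)] = target} with Z standard normal
#' and total liability standard deviation \code{sigma}.
#'
#' @param target marginal rate in (0, 1).
#' @param total_var total liability variance around the intercept.
#' @param offset constant liability offset (e.g. the expected
#'   inbreeding-depression load).
#' @return the intercept.
#' @export
calibrate_logit_intercept <- function(target, total_var, offset = 0) {
  if (target <= 0 || target >= 1) stop("target rate must be in (0, 1)")
  s <- sqrt(total_var)
  stats::uniroot(function(mu) logit_normal_mean(mu + offset, s) - target,
                 c(-30, 30), tol = 1e-10)$root
}

rmvn <- function(n, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(Sigma))
  matrix(stats::rnorm(n * nrow(Sigma)), n) %*% t(L)
}

#' Simulate an island population with extra-pair paternity
#'
#' Runs the generative model described in \code{\link{sim_config}}.  Every
#' year surviving adults pair socially at random; each offspring of a
#' female is sired extra-pair with probability given by the inverse logit
#' of her extra-pair liability (intercept + breeding value + year +
#' permanent individual + residual + inbreeding depression); offspring
#' breeding values are mid-parent plus a Mendelian deviation with variance
#' \code{0.5 G_A (1 - (f_dam + f_sire)/2)}; recruitment is a binary
#' threshold on a liability including its inbreeding-depression load;
#' immigrants enter as unrelated founders.  Deterministic given the seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{"sim_output"}: list with \code{pedigree}
#'   (a \code{pedigree}), \code{female_years}, \code{offspring} (data
#'   frames in the package's input formats), \code{breeding_values}
#'   (matrix, all individuals x 3 traits) and \code{truth} (generating
#'   parameters, calibrated intercepts and realised rates).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config
  vtot <- function(tr) cfg$G_A[tr, tr] + cfg$G_Y[tr, tr] +
    cfg$G_PI[tr, tr] + cfg$G_R[tr, tr]
  mu_epr <- calibrate_logit_intercept(cfg$epr_rate, vtot(1),
                                      offset = cfg$beta_f[1] * cfg$calibration_f)
  mu_sr <- calibrate_logit_intercept(cfg$recruitment_rate, vtot(3),
                                     offset = cfg$beta_f[3] * cfg$calibration_f)

  ## Adult registry (founders, immigrants, recruits); kinship among
  ## (potential) parents is tracked exactly in K.  All accumulators are
  ## function-local, preallocated and doubled on demand: growing them
  ## element-wise (or holding them behind an environment accessor) would
  ## copy whole vectors or the kinship matrix per offspring and make long
  ## simulations quadratic in population size.
  K <- matrix(0, 512L, 512L)
  n_ad <- 0L
  ad_id <- character(512L); ad_sex <- character(512L)
  ad_f <- numeric(512L); ad_cohort <- integer(512L)
  ad_alive <- logical(512L); ad_imm <- logical(512L)
  bv_ad <- matrix(0, 512L, 3L)
  pi_ad <- matrix(0, 512L, 2L)     # EPR, ARS permanent effects
  ## every ringed individual (pedigree + breeding values)
  n_ped <- 0L
  ped_id <- character(1024L); ped_dam <- character(1024L)
  ped_sire <- character(1024L); ped_cohort <- integer(1024L)
  ped_imm <- logical(1024L)
  bv_all <- matrix(0, 1024L, 3L)
  n_fy <- 0L
  fy_id <- character(1024L); fy_year <- integer(1024L)
  fy_age <- integer(1024L); fy_f <- numeric(1024L)
  fy_ars <- integer(1024L); fy_epo <- integer(1024L)
  n_off <- 0L
  off_id <- character(1024L); off_year <- integer(1024L)
  off_sex <- character(1024L); off_f <- numeric(1024L)
  off_rec <- integer(1024L)
  imm_count <- 0L; off_count <- 0L

  ## founders enter before year 1; immigrants join later as new founders
  founder_queue <- list()
  for (i in seq_len(cfg$n_founder_pairs)) {
    founder_queue[[2L * i - 1L]] <- list(id = sprintf("F%03dM", i),
                                         sex = "male", cohort = 0L,
                                         imm = FALSE)
    founder_queue[[2L * i]] <- list(id = sprintf("F%03dF", i),
                                    sex = "female", cohort = 0L,
                                    imm = FALSE)
  }

  for (yr in c(0L, seq_len(cfg$n_years))) {
    ## ---- insert queued founders/immigrants --------------------------
    for (fd in founder_queue) {
      i <- n_ad + 1L
      while (i > nrow(K)) {
        old <- nrow(K)
        K2 <- matrix(0, 2L * old, 2L * old)
        K2[seq_len(old), seq_len(old)] <- K
        K <- K2
        bv_ad <- rbind(bv_ad, matrix(0, old, 3L))
        pi_ad <- rbind(pi_ad, matrix(0, old, 2L))
        length(ad_id) <- 2L * old; length(ad_sex) <- 2L * old
        length(ad_f) <- 2L * old; length(ad_cohort) <- 2L * old
        length(ad_alive) <- 2L * old; length(ad_imm) <- 2L * old
      }
      n_ad <- i
      bv <- drop(rmvn(1, cfg$G_A))
      ad_id[i] <- fd$id; ad_sex[i] <- fd$sex; ad_f[i] <- 0
      ad_cohort[i] <- fd$cohort; ad_alive[i] <- TRUE; ad_imm[i] <- fd$imm
      bv_ad[i, ] <- bv
      pi_ad[i, ] <- drop(rmvn(1, cfg$G_PI[1:2, 1:2]))
      K[i, i] <- 0.5
      j <- n_ped + 1L
      if (j > nrow(bv_all)) {
        old <- nrow(bv_all)
        bv_all <- rbind(bv_all, matrix(0, old, 3L))
        length(ped_id) <- 2L * old; length(ped_dam) <- 2L * old
        length(ped_sire) <- 2L * old; length(ped_cohort) <- 2L * old
        length(ped_imm) <- 2L * old
      }
      n_ped <- j
      ped_id[j] <- fd$id; ped_dam[j] <- NA_character_
      ped_sire[j] <- NA_character_
      ped_cohort[j] <- fd$cohort; ped_imm[j] <- fd$imm
      bv_all[j, ] <- bv
    }
    founder_queue <- list()
    if (yr == 0L) next

    ## ---- one breeding season ----------------------------------------
    live <- which(ad_alive[seq_len(n_ad)])
    fem <- live[ad_sex[live] == "female"]
    mal <- live[ad_sex[live] == "male"]
    if (length(fem) < 1L || length(mal) < 1L)
      stop("population went extinct in year ", yr)
    u_y <- drop(rmvn(1, cfg$G_Y))
    npair <- min(length(fem), length(mal), cfg$max_pairs)
    fpick <- if (length(fem) > 1L) sample(fem, npair) else fem
    mpick <- if (length(mal) > 1L) sample(mal, npair) else mal

    ## stabilising regulation: fitness components are heritable and under
    ## selection, so without compensation their means (and, through the
    ## genetic covariances, the extra-pair rate) would drift across
    ## generations.  The intercepts track the breeder pool's mean genetic
    ## / permanent / inbreeding load each year, keeping the marginal rates
    ## at their configured targets while leaving within-year variance and
    ## all individual-level (co)variances untouched.
    comp_epr <- mean(bv_ad[fpick, 1] + pi_ad[fpick, 1]) +
      cfg$beta_f[1] * (mean(ad_f[fpick]) - cfg$calibration_f)
    comp_ars <- mean(bv_ad[fpick, 2] + pi_ad[fpick, 2]) +
      cfg$beta_f[2] * mean(ad_f[fpick])
    mu_epr_y <- mu_epr - comp_epr
    mu_ars_y <- 1 - comp_ars

    recruits <- list()   # enter the adult pool at the end of the year
    cohort <- list()     # this year's offspring; recruitment drawn below

    for (p in seq_len(npair)) {
      fi <- fpick[p]; mi <- mpick[p]
      f_fem <- ad_f[fi]
      e_fy <- drop(rmvn(1, cfg$G_R[1:2, 1:2]))
      age <- yr - ad_cohort[fi]

      ars_lat <- mu_ars_y + bv_ad[fi, 2] + pi_ad[fi, 2] + u_y[2] +
        cfg$beta_f[2] * f_fem + e_fy[2]
      ars <- max(0L, as.integer(round(ars_lat * cfg$mean_ars)))

      epr_lia <- mu_epr_y + bv_ad[fi, 1] + pi_ad[fi, 1] + u_y[1] +
        cfg$beta_f[1] * f_fem + e_fy[1]
      p_ep <- stats::plogis(epr_lia)

      epo <- 0L
      if (ars > 0L) {
        for (o in seq_len(ars)) {
          off_count <- off_count + 1L
          oid <- sprintf("O%05d", off_count)
          extra <- stats::runif(1) < p_ep && length(mal) > 1L
          si <- if (extra) sample(setdiff(mal, mi), 1L) else mi
          if (extra) epo <- epo + 1L
          f_off <- K[fi, si]
          d_ms <- 0.5 * (1 - (ad_f[fi] + ad_f[si]) / 2)
          bv_o <- 0.5 * (bv_ad[fi, ] + bv_ad[si, ]) +
            drop(rmvn(1, d_ms * cfg$G_A))
          sex_o <- if (stats::runif(1) < 0.5) "female" else "male"
          j <- n_ped + 1L
          if (j > nrow(bv_all)) {
            old <- nrow(bv_all)
            bv_all <- rbind(bv_all, matrix(0, old, 3L))
            length(ped_id) <- 2L * old; length(ped_dam) <- 2L * old
            length(ped_sire) <- 2L * old; length(ped_cohort) <- 2L * old
            length(ped_imm) <- 2L * old
          }
          n_ped <- j
          ped_id[j] <- oid; ped_dam[j] <- ad_id[fi]; ped_sire[j] <- ad_id[si]
          ped_cohort[j] <- yr; ped_imm[j] <- FALSE
          bv_all[j, ] <- bv_o
          k <- n_off + 1L
          if (k > length(off_id)) {
            old <- length(off_id)
            length(off_id) <- 2L * old; length(off_year) <- 2L * old
            length(off_sex) <- 2L * old; length(off_f) <- 2L * old
            length(off_rec) <- 2L * old
          }
          n_off <- k
          off_id[k] <- oid; off_year[k] <- yr; off_sex[k] <- sex_o
          off_f[k] <- f_off; off_rec[k] <- NA_integer_
          cohort[[length(cohort) + 1L]] <-
            list(row = k, sex = sex_o, f = f_off, dam = fi, sire = si,
                 bv = bv_o)
        }
      }
      ## phenotype records for native females only (immigrant females are
      ## excluded from the analysis data, as in the study population)
      if (!ad_imm[fi]) {
        k <- n_fy + 1L
        if (k > length(fy_id)) {
          old <- length(fy_id)
          length(fy_id) <- 2L * old; length(fy_year) <- 2L * old
          length(fy_age) <- 2L * old; length(fy_f) <- 2L * old
          length(fy_ars) <- 2L * old; length(fy_epo) <- 2L * old
        }
        n_fy <- k
        fy_id[k] <- ad_id[fi]; fy_year[k] <- yr; fy_age[k] <- age
        fy_f[k] <- f_fem; fy_ars[k] <- ars; fy_epo[k] <- epo
      }
    }

    ## Recruitment, drawn after the whole cohort exists.  Fitness
    ## components are heritable and under selection, so the cohort's mean
    ## genetic and inbreeding load drifts across generations; the
    ## intercept is re-centred on the realised cohort load (stabilising
    ## regulation) so the marginal recruitment rate stays at its target
    ## while within-cohort variation and all individual-level
    ## (co)variances are untouched.
    if (length(cohort)) {
      sys <- vapply(cohort, function(oc) oc$bv[3] + cfg$beta_f[3] * oc$f, 1)
      mu_sr_y <- mu_sr + cfg$beta_f[3] * cfg$calibration_f - mean(sys)
      for (ci in seq_along(cohort)) {
        oc <- cohort[[ci]]
        sr_lia <- mu_sr_y + sys[ci] + u_y[3] +
          stats::rnorm(1, 0, sqrt(cfg$G_R[3, 3]))
        rec <- stats::runif(1) < stats::plogis(sr_lia)
        off_rec[oc$row] <- as.integer(rec)
        if (rec)
          recruits[[length(recruits) + 1L]] <-
            list(id = off_id[oc$row], sex = oc$sex, f = oc$f,
                 dam = oc$dam, sire = oc$sire, bv = oc$bv)
      }
    }

    ## adult survival, then recruitment into the pool and immigration
    ad_alive[live] <- stats::runif(length(live)) < cfg$adult_survival
    for (rc in recruits) {
      nprev <- n_ad
      krow <- 0.5 * (K[rc$dam, seq_len(nprev)] + K[rc$sire, seq_len(nprev)])
      i <- n_ad + 1L
      while (i > nrow(K)) {
        old <- nrow(K)
        K2 <- matrix(0, 2L * old, 2L * old)
        K2[seq_len(old), seq_len(old)] <- K
        K <- K2
        bv_ad <- rbind(bv_ad, matrix(0, old, 3L))
        pi_ad <- rbind(pi_ad, matrix(0, old, 2L))
        length(ad_id) <- 2L * old; length(ad_sex) <- 2L * old
        length(ad_f) <- 2L * old; length(ad_cohort) <- 2L * old
        length(ad_alive) <- 2L * old; length(ad_imm) <- 2L * old
      }
      n_ad <- i
      ad_id[i] <- rc$id; ad_sex[i] <- rc$sex; ad_f[i] <- rc$f
      ad_cohort[i] <- yr; ad_alive[i] <- TRUE; ad_imm[i] <- FALSE
      bv_ad[i, ] <- rc$bv
      pi_ad[i, ] <- drop(rmvn(1, cfg$G_PI[1:2, 1:2]))
      K[i, seq_len(nprev)] <- krow
      K[seq_len(nprev), i] <- krow
      K[i, i] <- 0.5 * (1 + rc$f)
    }
    n_imm <- stats::rpois(1, cfg$immigrants_per_year)
    for (kk in seq_len(n_imm)) {
      imm_count <- imm_count + 1L
      founder_queue[[length(founder_queue) + 1L]] <-
        list(id = sprintf("I%03d", imm_count),
             sex = if (stats::runif(1) < 0.5) "female" else "male",
             cohort = yr, imm = TRUE)
    }
  }

  np <- n_ped
  ped_df <- data.frame(id = ped_id[seq_len(np)],
                       dam = ped_dam[seq_len(np)],
                       sire = ped_sire[seq_len(np)],
                       cohort = ped_cohort[seq_len(np)],
                       immigrant = ped_imm[seq_len(np)],
                       stringsAsFactors = FALSE)
  bv_mat <- bv_all[seq_len(np), , drop = FALSE]
  dimnames(bv_mat) <- list(ped_df$id, sim_traits)
  if (n_fy == 0L) stop("no female-year records generated")
  sq <- seq_len(n_fy)
  fy <- data.frame(female_id = fy_id[sq], year = fy_year[sq],
                   age_years = fy_age[sq], f = fy_f[sq],
                   ars = fy_ars[sq], epo = fy_epo[sq],
                   stringsAsFactors = FALSE)
  sq <- seq_len(n_off)
  off <- data.frame(offspring_id = off_id[sq],
                    cohort_year = off_year[sq], sex = off_sex[sq],
                    f = off_f[sq], recruited = off_rec[sq],
                    stringsAsFactors = FALSE)
  pedo <- pedigree(ped_df)

  truth <- list(config = unclass(cfg)[setdiff(names(unclass(cfg)), "seed")],
                seed = cfg$seed,
                intercepts = list(EPR_L = mu_epr, SR = mu_sr),
                realised = list(
                  n_individuals = nrow(ped_df),
                  n_female_years = nrow(fy),
                  n_offspring = nrow(off),
                  mean_ars = mean(fy$ars),
                  epo_proportion = sum(fy$epo) / max(1, sum(fy$ars)),
                  recruitment_rate = mean(off$recruited),
                  mean_f_offspring = mean(off$f)))
  structure(list(pedigree = pedo, female_years = fy, offspring = off,
                 breeding_values = bv_mat, truth = truth),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  r <- x$truth$realised
  cat("Simulated population:", r$n_individuals, "individuals,",
      r$n_female_years, "female-years,", r$n_offspring, "offspring\n")
  cat(sprintf("  mean ARS %.2f | EPO proportion %.3f | recruitment %.3f\n",
              r$mean_ars, r$epo_proportion, r$recruitment_rate))
  invisible(x)
}

#' Write simulation output in the package's input formats
#'
#' Emits \code{pedigree.csv}, \code{female_years.csv},
#' \code{offspring.csv} and \code{truth.json} (the generating parameters).
#' The files round-trip through \code{\link{read_pedigree}} and
#' \code{\link{utils::read.csv}}.
#'
#' @param sim a \code{sim_output}.
#' @param dir output directory (created if needed).
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.csv"))
  utils::write.csv(sim$female_years, file.path(dir, "female_years.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$offspring, file.path(dir, "offspring.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Mendelian-sampling diagnostic for simulated breeding values
#'
#' Checks the generator against quantitative-genetic theory: among
#' offspring with both parents known, the variance of the deviation of the
#' offspring breeding value from the mid-parent value should equal
#' \code{0.5 V_A (1 - mean((f_dam + f_sire)/2))}.
#'
#' @param ped a \code{pedigree}.
#' @param breeding_values named vector (or single-column matrix rowed by
#'   id) of breeding values for one trait.
#' @param V_A generating additive variance of the trait.
#' @param min_n minimum number of usable offspring.
#' @return list with \code{n}, \code{deviation_var}, \code{expected}
#'   (theory value) and \code{ratio}.
#' @export
mendelian_check <- function(ped, breeding_values, V_A, min_n = 500L) {
  if (is.matrix(breeding_values)) {
    bv <- breeding_values[, 1]; names(bv) <- rownames(breeding_values)
  } else bv <- breeding_values
  both <- !is.na(ped$dam) & !is.na(ped$sire)
  ids <- ped$id[both]
  ok <- ids %in% names(bv) & ped$dam[both] %in% names(bv) &
    ped$sire[both] %in% names(bv)
  ids <- ids[ok]
  if (length(ids) < min_n)
    stop("too few offspring with both parents and breeding values (",
         length(ids), " < ", min_n, ")")
  dam <- ped$dam[match(ids, ped$id)]; sire <- ped$sire[match(ids, ped$id)]
  ## parental f only; restrict the relationship algebra to the parents and
  ## their ancestors rather than the (much larger) full offspring table
  f <- inbreeding(prune_pedigree(ped, unique(c(dam, sire))))
  dev <- bv[ids] - 0.5 * (bv[dam] + bv[sire])
  expected <- 0.5 * V_A * (1 - mean((f[dam] + f[sire]) / 2))
  v <- stats::var(dev)
  list(n = length(ids), deviation_var = v, expected = expected,
       ratio = if (expected > 0) v / expected else NA_real_)
}

#' Simulate traits on a fixed pedigree
#'
#' Controlled generator for parameter-recovery and chain-quality studies:
#' given a pedigree and generating (co)variance matrices, draws breeding
#' values down the pedigree (Mendelian-sampling variance
#' \code{d_i G_A} with \code{d_i} the usual inbreeding-adjusted
#' coefficient), year effects, permanent-individual effects and residuals,
#' and emits a \code{trait_table} for one or two traits.
#'
#' @param ped a sorted \code{pedigree}.
#' @param families character vector (length 1 or 2) of trait families as in
#'   \code{\link{trait_spec}}.
#' @param G_A,G_Y,G_PI,G_R generating (co)variance matrices (T x T;
#'   scalars accepted for T = 1).  \code{G_PI} is only used when
#'   \code{records_per_individual > 1}.
#' @param names_ trait names.
#' @param n_years number of year levels; each record is assigned a year
#'   uniformly at random.
#' @param records_per_individual repeated records per individual (units
#'   become individual-year pairs).
#' @param means fixed intercepts per trait.
#' @param beta_f inbreeding-depression slopes per trait.
#' @param size binomial denominator (per record) for binomial traits.
#' @param seed integer RNG seed (required).
#' @return list with \code{data} (a \code{trait_table}), \code{truth}
#'   (generating values) and \code{breeding_values}.
#' @export
simulate_traits <- function(ped, families = "gaussian",
                            G_A = 0.3, G_Y = 0.1, G_PI = 0, G_R = 0.6,
                            names_ = NULL, n_years = 6,
                            records_per_individual = 1L,
                            means = 0, beta_f = 0, size = 5L, seed) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  check_sorted_ped(ped)
  set.seed(seed)
  T_ <- length(families)
  ## scalars become diagonal fill; matrices pass through
  GA <- if (is.matrix(G_A)) G_A else diag(rep(G_A, length.out = T_), T_)
  GY <- if (is.matrix(G_Y)) G_Y else diag(rep(G_Y, length.out = T_), T_)
  GP <- if (is.matrix(G_PI)) G_PI else diag(rep(G_PI, length.out = T_), T_)
  GR <- if (is.matrix(G_R)) G_R else diag(rep(G_R, length.out = T_), T_)
  if (is.null(names_))
    names_ <- paste0("trait", seq_len(T_))
  means <- rep(means, length.out = T_)
  beta_f <- rep(beta_f, length.out = T_)

  n <- nrow(ped)
  f <- inbreeding(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  bv <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    d <- idx[ped$dam[i]]; s <- idx[ped$sire[i]]
    if (!is.na(d) && !is.na(s)) {
      di <- 0.5 * (1 - (f[d] + f[s]) / 2)
      bv[i, ] <- 0.5 * (bv[d, ] + bv[s, ]) + drop(rmvn(1, di * GA))
    } else if (!is.na(d) || !is.na(s)) {
      p <- if (is.na(d)) s else d
      bv[i, ] <- 0.5 * bv[p, ] + drop(rmvn(1, (0.75 - 0.25 * f[p]) * GA))
    } else {
      bv[i, ] <- drop(rmvn(1, GA))
    }
  }
  rownames(bv) <- ped$id

  uy <- rmvn(n_years, GY)
  pe <- if (records_per_individual > 1L) rmvn(n, GP) else matrix(0, n, T_)
  rows <- list()
  for (rep_i in seq_len(records_per_individual)) {
    yr <- sample.int(n_years, n, replace = TRUE)
    ee <- rmvn(n, GR)
    unit <- if (records_per_individual > 1L)
      paste(ped$id, rep_i, sep = ":") else ped$id
    for (t in seq_len(T_)) {
      lat <- means[t] + bv[, t] + pe[, t] + uy[yr, t] + beta_f[t] * f + ee[, t]
      fam <- families[t]
      if (fam == "gaussian") {
        val <- lat; den <- NA_real_
      } else if (fam == "binomial-logit") {
        val <- stats::rbinom(n, size, stats::plogis(lat)); den <- size
      } else {
        val <- stats::rbinom(n, 1L, stats::plogis(lat)); den <- 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ped$id, unit_id = unit, year = yr,
        trait = names_[t], value = as.numeric(val), denom = den,
        age_class = NA_character_, f = unname(f), sex = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  list(data = out,
       truth = list(G_A = GA, G_Y = GY, G_PI = GP, G_R = GR,
                    means = means, beta_f = beta_f, families = families,
                    names = names_),
       breeding_values = bv, year_effects = uy,
       permanent_effects = pe)
}
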