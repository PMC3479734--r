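#' Configuration for a full analysis run
#'
#' Either \code{sim} (a \code{\link{sim_config}}) or \code{inputs} (paths
#' to \code{pedigree}, \code{female_years} and \code{offspring} CSV files)
#' must be supplied.  All stochastic stages derive their seeds from the
#' seed of \code{mcmc}; re-running with identical configuration reproduces
#' the report exactly.
#'
#' @param sim a \code{sim_config}, or \code{NULL} when reading files.
#' @param inputs named list of file paths (\code{pedigree},
#'   \code{female_years}, \code{offspring}), or \code{NULL}.
#' @param outdir output directory; fitted chains are cached there and
#'   reused on re-runs, so a run is resumable per stage.
#' @param mcmc an \code{\link{mcmc_config}} applied to every model fit.
#' @param priors a \code{\link{prior_spec}}.
#' @param baseline_prop baseline extra-pair proportion for the
#'   observed-scale back-transformation; default is the observed EPO
#'   proportion of the data.
#' @param overwrite allow replacing existing report files.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(sim = NULL, inputs = NULL, outdir, mcmc,
                       priors = prior_spec(), baseline_prop = NULL,
                       overwrite = FALSE) {
  if (is.null(sim) == is.null(inputs))
    stop("supply exactly one of 'sim' or 'inputs'")
  if (!inherits(mcmc, "mcmc_config")) stop("mcmc must be an mcmc_config()")
  if (!is.null(inputs)) {
    need <- c("pedigree", "female_years", "offspring")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("inputs missing path for: ", miss[1L])
    for (nm in need)
      if (!file.exists(inputs[[nm]]))
        stop("input file not found: ", inputs[[nm]])
  }
  structure(list(sim = sim, inputs = inputs, outdir = outdir, mcmc = mcmc,
                 priors = priors, baseline_prop = baseline_prop,
                 overwrite = overwrite),
            class = "run_config")
}

derive_mcmc <- function(mcmc, offset) {
  mcmc_config(iterations = mcmc$iterations, burn_in = mcmc$burn_in,
              thin = mcmc$thin, seed = mcmc$seed + offset,
              preset = mcmc$preset)
}

## fit with on-disk caching; cached chains make the pipeline resumable and
## cached re-summarisation equals fresh summarisation exactly
cached_fit <- function(path, expr) {
  if (file.exists(path)) return(readRDS(path))
  fit <- expr
  saveRDS(fit, path)
  fit
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> build trait tables -> prune pedigrees -> fit the
#' pairwise bivariate animal models (extra-pair liability with relative
#' annual reproductive success, with recruitment in both codings, and the
#' two fitness components with each other) -> fit the
#' phenotypic-differential model -> summarise and predict selection
#' responses.  Writes a posterior-summary report shaped like the standard
#' (co)variance-component table (fixed cells rendered as \code{"1 (fixed)"}
#' / \code{"0 (fixed)"}) and a selection-prediction table.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose print per-stage progress.
#' @return object of class \code{"epr_report"}: list with \code{fits},
#'   \code{summaries}, \code{heritability}, \code{predictions},
#'   \code{selection_differential}, \code{rates}, \code{report_table} and
#'   \code{files}.
#' @export
run_analysis <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)

  say("stage: data")
  if (!is.null(config$sim)) {
    sim <- simulate_population(config$sim)
    ped <- sim$pedigree
    fy <- sim$female_years
    off <- sim$offspring
  } else {
    ped <- read_pedigree(config$inputs$pedigree)
    fy <- utils::read.csv(config$inputs$female_years,
                          stringsAsFactors = FALSE,
                          colClasses = c(female_id = "character"))
    off <- utils::read.csv(config$inputs$offspring,
                           stringsAsFactors = FALSE,
                           colClasses = c(offspring_id = "character"))
  }
  tt <- build_trait_table(fy, off, sr_coding = "both")
  rates <- observed_rates(fy, off)
  baseline <- if (is.null(config$baseline_prop)) rates$epo_proportion
              else config$baseline_prop

  females <- unique(fy$female_id)
  offs <- unique(off$offspring_id)
  ped_f <- prune_pedigree(ped, females)
  ped_fo <- prune_pedigree(ped, c(females, offs))

  models <- list(
    epr_ars = list(traits = list(spec_epr(), spec_ars()), ped = ped_f,
                   off = 1L),
    epr_srb = list(traits = list(spec_epr(), spec_sr("binary")), ped = ped_fo,
                   off = 2L),
    epr_srg = list(traits = list(spec_epr(), spec_sr("gaussian")), ped = ped_fo,
                   off = 3L),
    ars_srb = list(traits = list(spec_ars(), spec_sr("binary")), ped = ped_fo,
                   off = 4L))

  fits <- list()
  for (nm in names(models)) {
    say("stage: fit ", nm)
    m <- models[[nm]]
    fits[[nm]] <- cached_fit(
      file.path(config$outdir, paste0("fit_", nm, ".rds")),
      fit_animal_model(m$traits, tt, ped = m$ped, priors = config$priors,
                       mcmc = derive_mcmc(config$mcmc, m$off),
                       verbose = verbose))
  }

  say("stage: phenotypic selection differential")
  sdiff <- cached_fit(
    file.path(config$outdir, "fit_sdiff.rds"),
    selection_differential(tt, mcmc = derive_mcmc(config$mcmc, 5L),
                           priors = config$priors, verbose = verbose))

  say("stage: summaries and predictions")
  summaries <- lapply(fits, summarize_posterior,
                      min_draws = min(100L, nrow(fits[[1]]$draws)))
  h2 <- list(
    EPR_L = heritability(fits$epr_ars, "EPR_L"),
    ARS_w = heritability(fits$epr_ars, "ARS_w"),
    SR_wB = heritability(fits$epr_srb, "SR_wB"),
    SR_wG = heritability(fits$epr_srg, "SR_wG"))

  pred_ars <- secondary_theorem(fits$epr_ars, "EPR_L", "ARS_w")
  pred_srb <- secondary_theorem(fits$epr_srb, "EPR_L", "SR_wB")
  pred_srg <- secondary_theorem(fits$epr_srg, "EPR_L", "SR_wG")
  pred_sum <- sum_components(list(pred_ars, pred_srg))
  preds <- list(ARS_w = pred_ars, SR_wB = pred_srb, SR_wG = pred_srg,
                summed = pred_sum)
  obs_scale <- data.frame(
    component = names(preds),
    delta_A = vapply(preds, `[[`, 1, "delta_A"),
    observed_scale = vapply(preds, function(p)
      backtransform(p$delta_A, baseline), 1),
    stringsAsFactors = FALSE)

  be <- breeders_equation(h2$EPR_L$summary$mean, sdiff$S)

  report <- report_table(fits, h2)
  files <- write_report_files(config, report, preds, obs_scale, be, sdiff)

  structure(list(fits = fits, summaries = summaries, heritability = h2,
                 predictions = preds, observed_scale = obs_scale,
                 selection_differential = sdiff,
                 breeders_equation = be, rates = rates,
                 baseline_prop = baseline, report_table = report,
                 files = files),
            class = "epr_report")
}

fmt_ci <- function(m, lo, hi) sprintf("%.3f (%.3f to %.3f)", m, lo, hi)

## one block of the report per model, one row per trait; fixed elements
## are rendered as "<value> (fixed)".  h2 is recomputed per model so each
## block's heritability matches its own chain.
report_table <- function(fits, h2 = NULL) {
  out <- list()
  for (nm in names(fits)) {
    fit <- fits[[nm]]
    sm <- summarize_posterior(fit, min_draws = 1L)
    pin <- fit$param_info
    cell <- function(pname) {
      i <- match(pname, sm$parameter)
      if (is.na(i)) return("-")
      j <- match(pname, pin$name)
      if (!pin$free[j]) return(sprintf("%g (fixed)", sm$mean[i]))
      fmt_ci(sm$mean[i], sm$l95[i], sm$u95[i])
    }
    other <- rev(fit$tnames)
    for (k in seq_along(fit$tnames)) {
      tr <- fit$tnames[k]
      h <- tryCatch(heritability(fit, tr), error = function(e) NULL)
      hcell <- if (!is.null(h))
        fmt_ci(h$summary$mean, h$summary$l95, h$summary$u95) else "-"
      out[[length(out) + 1L]] <- data.frame(
        model = nm, trait = tr,
        V_A = cell(paste0("VA.", tr)),
        V_PI = cell(paste0("VPI.", tr)),
        V_Y = cell(paste0("VY.", tr)),
        V_R = cell(paste0("VR.", tr)),
        h2 = hcell,
        beta_f = cell(paste0("beta.", tr, ".f")),
        cov_A = cov_cell(sm, pin, "A", tr, other[k]),
        cov_PI = cov_cell(sm, pin, "PI", tr, other[k]),
        cov_Y = cov_cell(sm, pin, "Y", tr, other[k]),
        cov_R = cov_cell(sm, pin, "R", tr, other[k]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

cov_cell <- function(sm, pin, tag, t1, t2) {
  cand <- paste0("cov", tag, ".", c(paste0(t1, ":", t2), paste0(t2, ":", t1)))
  hit <- cand[cand %in% sm$parameter]
  if (!length(hit)) return("-")
  i <- match(hit[1L], sm$parameter); j <- match(hit[1L], pin$name)
  if (!pin$free[j]) return(sprintf("%g (fixed)", sm$mean[i]))
  fmt_ci(sm$mean[i], sm$l95[i], sm$u95[i])
}

write_report_files <- function(config, report, preds, obs_scale, be, sdiff) {
  paths <- c(report = file.path(config$outdir, "posterior_table.csv"),
             predictions = file.path(config$outdir, "selection_predictions.csv"),
             breeders = file.path(config$outdir, "breeders_equation.csv"))
  exists <- file.exists(paths)
  if (any(exists) && !config$overwrite)
    stop("output exists (use overwrite = TRUE): ", paths[exists][1L])
  utils::write.csv(report, paths["report"], row.names = FALSE)
  ptab <- data.frame(
    z = vapply(preds, `[[`, "", "z"),
    w = vapply(preds, `[[`, "", "w"),
    delta_A = vapply(preds, `[[`, 1, "delta_A"),
    l95 = vapply(preds, function(p) if (is.null(p$ci95)) NA_real_ else p$ci95[1], 1),
    u95 = vapply(preds, function(p) if (is.null(p$ci95)) NA_real_ else p$ci95[2], 1),
    observed_scale = obs_scale$observed_scale,
    stringsAsFactors = FALSE)
  utils::write.csv(ptab, paths["predictions"], row.names = FALSE)
  btab <- data.frame(h2 = be$h2, S = be$S, R = be$R,
                     S_l95 = sdiff$ci95[1], S_u95 = sdiff$ci95[2])
  utils::write.csv(btab, paths["breeders"], row.names = FALSE)
  paths
}

#' @export
print.epr_report <- function(x, ...) {
  cat("Analysis report:", length(x$fits), "animal-model fits +",
      "phenotypic-differential model\n")
  cat(sprintf("  observed rates: mean ARS %.2f, EPO proportion %.3f%s\n",
              x$rates$mean_ars, x$rates$epo_proportion,
              if (!is.null(x$rates$recruitment_rate))
                sprintf(", recruitment %.3f", x$rates$recruitment_rate) else ""))
  for (nm in names(x$predictions)) {
    p <- x$predictions[[nm]]
    cat(sprintf("  delta_A(%s | %s) = %.4f%s\n", p$z, p$w, p$delta_A,
                if (!is.null(p$ci95)) sprintf(" (%.3f to %.3f)",
                                              p$ci95[1], p$ci95[2]) else ""))
  }
  cat(sprintf("  breeder's equation: R = %.3f x %.4f = %.5f\n",
              x$breeders_equation$h2, x$breeders_equation$S,
              x$breeders_equation$R))
  invisible(x)
}
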