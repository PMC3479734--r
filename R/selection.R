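#' Predicted response to selection via the secondary theorem of selection
#'
#' The per-generation change in mean breeding value of a trait z equals its
#' additive genetic covariance with relative fitness w:
#' \code{delta_A = cov_A(w, z)}.  The prediction is therefore the identity
#' map on the posterior of that covariance; the summary equals the model's
#' own summary of the same draws.
#'
#' @param fit an \code{epr_fit} containing the additive covariance between
#'   \code{z} and \code{w}.
#' @param z focal trait name (e.g. \code{"EPR_L"}).
#' @param w fitness-component trait name (e.g. \code{"ARS_w"}).
#' @return object of class \code{"selection_prediction"}: list with
#'   \code{z}, \code{w}, \code{draws}, \code{delta_A} (posterior mean),
#'   \code{ci95}.
#' @export
secondary_theorem <- function(fit, z, w) {
  draws <- covariance_draws(fit, "additive", z, w)
  attr(draws, "chain_id") <- paste(fit$mcmc$seed,
                                   paste(fit$tnames, collapse = ","),
                                   nrow(fit$draws), sep = "|")
  new_prediction(z, w, draws)
}

new_prediction <- function(z, w, draws, delta = NULL, ci = NULL) {
  if (!is.null(draws)) {
    delta <- mean(draws)
    ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  structure(list(z = z, w = w, draws = draws, delta_A = delta, ci95 = ci),
            class = "selection_prediction")
}

#' @export
print.selection_prediction <- function(x, ...) {
  cat(sprintf("Predicted response of %s to selection through %s:\n",
              x$z, x$w))
  cat(sprintf("  delta_A = %.4f", x$delta_A))
  if (!is.null(x$ci95))
    cat(sprintf("  (95%% CI %.4f to %.4f)", x$ci95[1], x$ci95[2]))
  else cat("  (95% CI unavailable: summed across separate fits)")
  cat("\n")
  invisible(x)
}

#' Sum predicted responses over fitness components
#'
#' Selection through multiplicative fitness components adds, so the
#' combined predicted response is the sum of the per-component additive
#' genetic covariances.  When all predictions carry aligned draws from a
#' single model's chain the sum is computed per draw and keeps a credible
#' interval; across separate fits the means are summed and the interval is
#' reported as unavailable.
#'
#' @param predictions list of \code{selection_prediction} objects sharing
#'   the same focal trait.
#' @return a \code{selection_prediction} for the summed response; the
#'   \code{w} slot concatenates the component names.
#' @export
sum_components <- function(predictions) {
  zs <- unique(vapply(predictions, `[[`, "", "z"))
  if (length(zs) != 1L)
    stop("predictions being summed must share the focal trait (got: ",
         paste(zs, collapse = ", "), ")")
  ws <- paste(vapply(predictions, `[[`, "", "w"), collapse = "+")
  dr <- lapply(predictions, `[[`, "draws")
  aligned <- all(!vapply(dr, is.null, TRUE)) &&
    length(unique(vapply(dr, length, 1L))) == 1L &&
    length(predictions) > 1L && attr_same_chain(predictions)
  if (aligned) {
    new_prediction(zs, ws, Reduce(`+`, dr))
  } else {
    delta <- sum(vapply(predictions, `[[`, 1, "delta_A"))
    new_prediction(zs, ws, NULL, delta = delta, ci = NULL)
  }
}

## draws are per-draw summable only when they come from one chain; callers
## mark this by fitting both covariances in a single model.  Separate fits
## have independent draw indices, so the per-draw sum would be meaningless.
attr_same_chain <- function(predictions) {
  ids <- lapply(predictions, function(p) attr(p$draws, "chain_id"))
  if (any(vapply(ids, is.null, TRUE))) return(FALSE)
  length(unique(unlist(ids))) == 1L
}

#' Back-transform a liability-scale response to the observed scale
#'
#' Converts a predicted change on the logit-liability scale into a change
#' in the expected proportion at a baseline:
#' \code{plogis(qlogis(p0) + delta) - p0}.  Strictly increasing in
#' \code{delta} and bounded in \code{(-p0, 1 - p0)}.
#'
#' @param delta_liability change on the liability (logit) scale.
#' @param baseline_prop baseline proportion in (0, 1); for extra-pair
#'   reproduction the observed mean EPO proportion.
#' @return change in the expected proportion.
#' @export
backtransform <- function(delta_liability, baseline_prop) {
  if (any(baseline_prop <= 0) || any(baseline_prop >= 1))
    stop("baseline proportion must be strictly inside (0, 1)")
  stats::plogis(stats::qlogis(baseline_prop) + delta_liability) - baseline_prop
}

#' Breeder's equation
#'
#' Predicted response \code{R = h2 * S}, with S the phenotypic selection
#' differential (phenotypic covariance between trait and relative fitness).
#'
#' @param h2 heritability in [0, 1].
#' @param S selection differential.
#' @return list with \code{h2}, \code{S} and \code{R}.
#' @export
breeders_equation <- function(h2, S) {
  if (any(h2 < 0) || any(h2 > 1)) stop("h2 must be in [0, 1]")
  list(h2 = h2, S = S, R = h2 * S)
}

#' Phenotypic selection differential from a bivariate mixed model
#'
#' Estimates the phenotypic covariance cov_P between extra-pair liability
#' and a Gaussian fitness component as the residual covariance of a
#' bivariate mixed model with random year effects and fixed age and
#' inbreeding effects but no additive genetic term, restricted to units
#' where both traits are observed (female-years with at least one ringed
#' offspring).
#'
#' @param data a \code{trait_table} containing the two traits.
#' @param z binomial focal trait name (default \code{"EPR_L"}).
#' @param w Gaussian fitness component name (default \code{"ARS_w"}).
#' @param mcmc an \code{\link{mcmc_config}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param verbose passed through to the sampler.
#' @return list with \code{draws} (residual-covariance posterior),
#'   \code{S} (posterior mean), \code{ci95} and the underlying \code{fit}.
#' @export
selection_differential <- function(data, z = "EPR_L", w = "ARS_w",
                                   mcmc, priors = prior_spec(),
                                   verbose = FALSE) {
  data <- as.data.frame(data)
  zu <- data$unit_id[data$trait == z]
  keep <- data$trait %in% c(z, w) & data$unit_id %in% zu
  sub <- data[keep, , drop = FALSE]
  class(sub) <- c("trait_table", "data.frame")
  ts <- list(
    trait_spec(z, "binomial-logit", fixed = c("intercept", "age_class", "f"),
               random = "year"),
    trait_spec(w, "gaussian", fixed = c("intercept", "age_class", "f"),
               random = "year"))
  fit <- fit_animal_model(ts, sub, ped = NULL, priors = priors, mcmc = mcmc,
                          verbose = verbose)
  draws <- covariance_draws(fit, "residual", z, w)
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  list(draws = draws, S = mean(draws), ci95 = ci, fit = fit)
}
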