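#' Read a model specification file
#'
#' Builds trait specifications, priors and MCMC settings from a YAML file,
#' so an analysis can be configured without writing R code.  Layout:
#'
#' \preformatted{
#' traits:
#'   - name: EPR_L
#'     family: binomial-logit
#'     fixed: [intercept, age_class, f]
#'     random: [additive, year, permanent_individual]
#'   - name: ARS_w
#'     family: gaussian
#'     fixed: [intercept, age_class, f]
#'     random: [additive, year, permanent_individual]
#' priors:
#'   V: 1
#'   nu: 0.002
#' mcmc:
#'   preset: desk        # or iterations/burn_in/thin
#'   seed: 42
#' }
#'
#' @param path YAML file path.
#' @return list with \code{traits} (list of \code{trait_spec}),
#'   \code{priors} (\code{prior_spec}) and \code{mcmc}
#'   (\code{mcmc_config}).
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("model specification file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$traits)) stop("model specification needs a 'traits' block")
  traits <- lapply(y$traits, function(tr) {
    trait_spec(tr$name, tr$family,
               fixed = if (is.null(tr$fixed)) c("intercept", "f")
                       else unlist(tr$fixed),
               random = if (is.null(tr$random)) c("additive", "year")
                        else unlist(tr$random))
  })
  pr <- y$priors
  priors <- prior_spec(
    V = if (is.null(pr$V)) 1 else pr$V,
    nu = if (is.null(pr$nu)) 0.002 else pr$nu,
    fixed_var = if (is.null(pr$fixed_var)) 1e8 else pr$fixed_var)
  mc <- y$mcmc
  if (is.null(mc$seed)) stop("model specification must give mcmc: seed")
  mcmc <- mcmc_config(iterations = mc$iterations, burn_in = mc$burn_in,
                      thin = mc$thin, seed = mc$seed,
                      preset = if (is.null(mc$preset)) "desk" else mc$preset)
  list(traits = traits, priors = priors, mcmc = mcmc)
}
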