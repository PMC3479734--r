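#' Trait specification for animal models
#'
#' Describes how one trait enters the model: its error family, fixed-effect
#' covariates and random terms.  Threshold traits (binomial/binary with a
#' logit link) are fitted on a latent liability scale; Gaussian traits on
#' the observed scale.
#'
#' @param name trait name; must match the \code{trait} column of the trait
#'   table (e.g. \code{"EPR_L"}, \code{"ARS_w"}, \code{"SR_wB"},
#'   \code{"SR_wG"}).
#' @param family \code{"gaussian"}, \code{"binomial-logit"} (count out of a
#'   per-record denominator) or \code{"binary-logit"} (single 0/1 record).
#' @param fixed character subset of \code{c("intercept", "age_class", "f",
#'   "sex")}.
#' @param random character subset of \code{c("additive", "year",
#'   "permanent_individual")}.  Binary traits observed once per individual
#'   cannot declare \code{permanent_individual} (it is confounded with the
#'   fixed-to-one residual).
#' @return object of class \code{"trait_spec"}.
#' @export
trait_spec <- function(name,
                       family = c("gaussian", "binomial-logit", "binary-logit"),
                       fixed = c("intercept", "f"),
                       random = c("additive", "year")) {
  family <- match.arg(family)
  fixed <- match.arg(fixed, c("intercept", "age_class", "f", "sex"),
                     several.ok = TRUE)
  random <- if (length(random))
    match.arg(random, c("additive", "year", "permanent_individual"),
              several.ok = TRUE) else character(0)
  if (family == "binary-logit" && "permanent_individual" %in% random)
    stop("permanent-individual variance is not identifiable for a ",
         "single-observation binary trait")
  structure(list(name = name, family = family, fixed = fixed,
                 random = random), class = "trait_spec")
}

#' Default trait specifications for the study traits
#'
#' Convenience constructors matching the standard model structure: female
#' extra-pair liability (binomial, age + inbreeding fixed effects,
#' additive + year + permanent-individual random effects), relative annual
#' reproductive success (Gaussian, same structure) and survival to
#' recruitment (binary or Gaussian relative fitness, sex + inbreeding fixed
#' effects, additive + year).
#'
#' @return a \code{trait_spec}.
#' @export
spec_epr <- function() {
  trait_spec("EPR_L", "binomial-logit",
             fixed = c("intercept", "age_class", "f"),
             random = c("additive", "year", "permanent_individual"))
}

#' @rdname spec_epr
#' @export
spec_ars <- function() {
  trait_spec("ARS_w", "gaussian",
             fixed = c("intercept", "age_class", "f"),
             random = c("additive", "year", "permanent_individual"))
}

#' @rdname spec_epr
#' @param coding \code{"binary"} for the liability-scale threshold coding,
#'   \code{"gaussian"} for relative fitness on the observed scale.
#' @export
spec_sr <- function(coding = c("binary", "gaussian")) {
  coding <- match.arg(coding)
  trait_spec(if (coding == "binary") "SR_wB" else "SR_wG",
             if (coding == "binary") "binary-logit" else "gaussian",
             fixed = c("intercept", "sex", "f"),
             random = c("additive", "year"))
}

#' Prior specification
#'
#' Fixed effects get independent normal priors with mean zero and large
#' variance.  Each (co)variance component gets an inverse-Wishart prior
#' parameterised by a limit variance matrix V and a degree of belief nu
#' (scale matrix \code{nu * V}, degrees of freedom \code{nu}); prior
#' covariances are zero.  The defaults (V = identity, nu = 0.002) are only
#' weakly informative.
#'
#' @param V scalar or matrix limit variance (default 1, i.e. identity).
#' @param nu degree of belief, > 0.
#' @param fixed_var prior variance of fixed-effect coefficients.
#' @param components optional named list overriding \code{V}/\code{nu} per
#'   component (\code{additive}, \code{year}, \code{permanent_individual},
#'   \code{residual}), each a list with elements \code{V} and/or \code{nu}.
#' @return object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(V = 1, nu = 0.002, fixed_var = 1e8,
                       components = list()) {
  if (nu <= 0) stop("degree of belief nu must be > 0")
  if (any(diag(as.matrix(V)) <= 0)) stop("limit variance must be > 0")
  structure(list(V = V, nu = nu, fixed_var = fixed_var,
                 components = components), class = "prior_spec")
}

prior_for_component <- function(priors, component, dim) {
  ov <- priors$components[[component]]
  V <- if (!is.null(ov$V)) ov$V else priors$V
  nu <- if (!is.null(ov$nu)) ov$nu else priors$nu
  V <- if (length(V) == 1L) diag(as.numeric(V), dim) else as.matrix(V)
  if (!all(dim(V) == dim)) stop("prior V has wrong dimension for ", component)
  list(S0 = nu * V, nu = nu)
}

#' MCMC configuration
#'
#' The \code{"desk"} preset (55,000 iterations, burn-in 5,000, thinning 50)
#' keeps runs at interactive scale; the \code{"paper"} preset (3,005,000 /
#' 5,000 / 3,000) reproduces the full-length chains used for the published
#' analyses.  A seed is mandatory: every fit is bit-reproducible.
#'
#' @param iterations,burn_in,thin chain length controls; overrides the
#'   preset when given.
#' @param seed integer RNG seed (required).
#' @param preset \code{"desk"} or \code{"paper"}.
#' @return object of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(iterations = NULL, burn_in = NULL, thin = NULL,
                        seed, preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  def <- switch(preset,
                desk = list(iterations = 55000L, burn_in = 5000L, thin = 50L),
                paper = list(iterations = 3005000L, burn_in = 5000L, thin = 3000L))
  if (missing(seed)) stop("an explicit RNG seed is required")
  it <- as.integer(if (is.null(iterations)) def$iterations else iterations)
  bi <- as.integer(if (is.null(burn_in)) def$burn_in else burn_in)
  th <- as.integer(if (is.null(thin)) def$thin else thin)
  if (bi >= it) stop("burn_in must be smaller than iterations")
  if (th < 1L) stop("thin must be >= 1")
  structure(list(iterations = it, burn_in = bi, thin = th,
                 seed = as.integer(seed), preset = preset),
            class = "mcmc_config")
}

#' Covariance-structure constraints
#'
#' Per-component masks marking each element of a traits-by-traits
#' (co)variance block as free or fixed at a value.  \code{NULL} components
#' get the model defaults: everything free except (i) the residual variance
#' of a binary-logit trait, fixed to 1 by convention, and (ii) residual
#' covariances that are not identifiable, fixed to 0 — between any pair
#' involving a binary trait, and between traits whose records never share
#' an observational unit (e.g. a trait observed only on recruited females
#' and recruitment itself).
#'
#' @param residual,additive,year,permanent_individual each \code{NULL} or a
#'   list with \code{value} (numeric matrix of fixed values / starting
#'   values) and \code{free} (logical matrix).
#' @return object of class \code{"cov_structure"}.
#' @export
cov_structure <- function(residual = NULL, additive = NULL, year = NULL,
                          permanent_individual = NULL) {
  structure(list(residual = residual, additive = additive, year = year,
                 permanent_individual = permanent_individual),
            class = "cov_structure")
}
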