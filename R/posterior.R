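#' Sample autocorrelation of a chain
#'
#' @param chain numeric vector of (thinned) draws.
#' @param lag positive integer lag, smaller than the chain length.
#' @return autocorrelation in [-1, 1]; 0 by convention for a constant
#'   chain.
#' @export
autocorrelation <- function(chain, lag = 1L) {
  n <- length(chain)
  if (lag < 1L || lag >= n) stop("lag must be in [1, length(chain) - 1]")
  a <- chain[seq_len(n - lag)]
  b <- chain[seq_len(n - lag) + lag]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

## kernel-density mode; variance chains are reflected at zero so boundary
## mass is not smeared into negative values
density_mode <- function(x, lower_bound = NULL) {
  if (stats::sd(x) == 0) return(x[1])
  if (!is.null(lower_bound)) {
    d <- stats::density(c(x, 2 * lower_bound - x))
    keep <- d$x >= lower_bound
    d$x <- d$x[keep]; d$y <- 2 * d$y[keep]
  } else d <- stats::density(x)
  d$x[which.max(d$y)]
}

## ratio of density at zero to density at the mode, for chains bounded
## below by zero; large values mean the posterior is not separated from 0
density_near_zero <- function(x) {
  if (stats::sd(x) == 0) return(if (abs(x[1]) < .Machine$double.eps) 1 else 0)
  d <- stats::density(c(x, -x))
  keep <- d$x >= 0
  dx <- d$x[keep]; dy <- 2 * d$y[keep]
  dy[which.min(dx)] / max(dy)
}

#' Posterior summary
#'
#' Posterior mean, equal-tailed 95\% credible interval, kernel-density mode
#' (with reflection at zero for variance parameters), lag-1 autocorrelation
#' of the thinned chain and, for variances, a density-near-zero diagnostic:
#' the ratio of posterior density at zero to density at the mode, with
#' \code{near_zero = TRUE} when that ratio exceeds 0.5 (the posterior is
#' "not separated from zero").
#'
#' @param object an \code{epr_fit} or a matrix of draws (columns are
#'   parameters).
#' @param params optional character vector selecting parameters.
#' @param min_draws minimum number of retained draws required.
#' @param interval \code{"equal-tailed"} (default; 2.5/97.5 quantiles) or
#'   \code{"hpd"} (highest posterior density, the narrowest window holding
#'   95\% of draws — better calibrated for boundary-bounded, skewed
#'   variance posteriors).
#' @param ... unused.
#' @return data frame with one row per parameter: \code{mean},
#'   \code{l95}, \code{u95}, \code{mode}, \code{lag1}, \code{dz},
#'   \code{near_zero}.
#' @export
summarize_posterior <- function(object, params = NULL, min_draws = 100L,
                                interval = c("equal-tailed", "hpd")) {
  interval <- match.arg(interval)
  if (inherits(object, "epr_fit")) {
    draws <- object$draws
    kinds <- object$param_info$kind[match(colnames(draws), object$param_info$name)]
  } else {
    draws <- as.matrix(object)
    if (is.null(colnames(draws)))
      colnames(draws) <- paste0("param", seq_len(ncol(draws)))
    kinds <- rep("unknown", ncol(draws))
  }
  if (!is.null(params)) {
    miss <- setdiff(params, colnames(draws))
    if (length(miss)) stop("unknown parameter: ", miss[1L])
    kinds <- kinds[match(params, colnames(draws))]
    draws <- draws[, params, drop = FALSE]
  }
  if (nrow(draws) < min_draws)
    stop("too few retained draws (", nrow(draws), " < ", min_draws, ")")
  out <- lapply(seq_len(ncol(draws)), function(j) {
    x <- draws[, j]
    is_var <- kinds[j] == "variance"
    ci <- if (interval == "hpd") hpd_interval(x)
          else unname(stats::quantile(x, c(0.025, 0.975)))
    dz <- if (is_var) density_near_zero(x) else NA_real_
    data.frame(parameter = colnames(draws)[j], mean = mean(x),
               l95 = ci[1], u95 = ci[2],
               mode = density_mode(x, lower_bound = if (is_var) 0 else NULL),
               lag1 = autocorrelation(x, 1L),
               dz = dz,
               near_zero = if (is_var) dz > 0.5 else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname summarize_posterior
#' @export
summary.epr_fit <- function(object, ...) summarize_posterior(object, ...)

## narrowest window containing a fraction p of the sorted draws
hpd_interval <- function(x, p = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(p * n))
  if (k >= n) return(range(x))
  w <- x[(k + 1L):n] - x[seq_len(n - k)]
  i <- which.min(w)
  c(x[i], x[i + k])
}

#' Liability- or observed-scale heritability
#'
#' Per-draw heritability \code{h2 = V_A / (V_A + V_PI + V_Y + V_R)} for
#' Gaussian traits, with the logit link variance \code{pi^2/3} added to the
#' denominator for binomial and binary (threshold) traits; components the
#' model does not include are omitted.  The summary is the mean (and CI) of
#' the per-draw ratios, not the ratio of posterior means.
#'
#' @param fit an \code{epr_fit}.
#' @param trait trait name.
#' @return list with \code{draws} (per-draw h2) and \code{summary}
#'   (posterior mean, 95\% CI, mode, lag-1 autocorrelation).
#' @export
heritability <- function(fit, trait) {
  stopifnot(inherits(fit, "epr_fit"))
  ti <- match(trait, fit$tnames)
  if (is.na(ti)) stop("trait not in fit: ", trait)
  fam <- fit$families[ti]
  num <- var_col(fit, "A", trait)
  if (is.null(num)) stop("no additive variance for trait ", trait)
  denom <- num
  for (tag in c("PI", "Y", "R")) {
    v <- var_col(fit, tag, trait)
    if (!is.null(v)) denom <- denom + v
  }
  if (fam %in% c(FAMILY_BINOM, FAMILY_BINARY)) denom <- denom + pi^2 / 3
  if (any(denom == 0)) stop("zero total variance in a draw")
  h2 <- num / denom
  ci <- unname(stats::quantile(h2, c(0.025, 0.975)))
  list(draws = h2,
       summary = data.frame(parameter = paste0("h2.", trait),
                            mean = mean(h2), l95 = ci[1], u95 = ci[2],
                            mode = density_mode(h2, lower_bound = 0),
                            lag1 = autocorrelation(h2, 1L),
                            stringsAsFactors = FALSE))
}

var_col <- function(fit, tag, trait) {
  nm <- paste0("V", tag, ".", trait)
  if (nm %in% colnames(fit$draws)) fit$draws[, nm] else NULL
}

#' Extract covariance draws between two traits
#'
#' @param fit an \code{epr_fit}.
#' @param component one of \code{"additive"}, \code{"year"},
#'   \code{"permanent_individual"}, \code{"residual"}.
#' @param t1,t2 trait names (order-free).
#' @return numeric vector of draws.
#' @export
covariance_draws <- function(fit, component, t1, t2) {
  tag <- comp_tags[[component]]
  cand <- paste0("cov", tag, ".", c(paste0(t1, ":", t2), paste0(t2, ":", t1)))
  hit <- cand[cand %in% colnames(fit$draws)]
  if (!length(hit))
    stop("no ", component, " covariance between ", t1, " and ", t2,
         " in this fit")
  fit$draws[, hit[1L]]
}

#' Write posterior draws / summaries as CSV
#'
#' Draws go out tidy (\code{draw}, \code{parameter}, \code{value});
#' summaries as one row per parameter.
#'
#' @param fit an \code{epr_fit}.
#' @param path output file.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  out <- data.frame(draw = rep(seq_len(nrow(d)), ncol(d)),
                    parameter = rep(colnames(d), each = nrow(d)),
                    value = as.vector(d))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
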