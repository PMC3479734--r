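#' Relative fitness
#'
#' Divides fitness-component values by the population mean, either across
#' all years (default; resulting mean is exactly 1) or within each year.
#' For a binary component such as survival to recruitment the result is 0
#' or 1/mean, the relative fitness of a binary trait.
#'
#' @param values non-negative numeric fitness measurements.
#' @param mode \code{"across-year"} (default) or \code{"year-specific"}.
#' @param years integer years, required for year-specific mode.
#' @return numeric vector of relative fitness values.
#' @export
relative_fitness <- function(values, mode = c("across-year", "year-specific"),
                             years = NULL) {
  mode <- match.arg(mode)
  if (any(values < 0, na.rm = TRUE)) stop("fitness values must be non-negative")
  if (mode == "across-year") {
    m <- mean(values, na.rm = TRUE)
    if (!is.finite(m) || m <= 0) stop("reference mean is zero; cannot relativise")
    values / m
  } else {
    if (is.null(years)) stop("year-specific mode needs 'years'")
    if (length(years) != length(values)) stop("'years' length mismatch")
    m <- tapply(values, years, mean, na.rm = TRUE)
    if (any(m <= 0)) stop("a year-specific mean is zero; cannot relativise")
    values / unname(m[as.character(years)])
  }
}

#' Age classes for female reproductive traits
#'
#' Ages are grouped into three categories: 1 year, 2-3 years, and more than
#' 3 years.
#'
#' @param age_years integer age(s), at least 1.
#' @return factor with levels \code{class1}, \code{class2}, \code{class3}.
#' @export
age_class <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 1))
    stop("age must be >= 1 year")
  cls <- cut(age_years, breaks = c(0, 1, 3, Inf),
             labels = c("class1", "class2", "class3"))
  factor(cls, levels = c("class1", "class2", "class3"))
}

#' Validate female-year records
#'
#' @param x data frame with columns \code{female_id}, \code{year},
#'   \code{age_years}, \code{f}, \code{ars} (ringed offspring count) and
#'   \code{epo} (extra-pair offspring count).
#' @return the validated data frame.
#' @keywords internal
validate_female_years <- function(x) {
  need <- c("female_id", "year", "age_years", "f", "ars", "epo")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("female-year table missing column: ", miss[1L])
  if (any(x$ars < 0) || any(x$epo < 0)) stop("counts must be non-negative")
  bad <- which(x$epo > x$ars)
  if (length(bad))
    stop("epo exceeds ars for female ", x$female_id[bad[1L]],
         " in year ", x$year[bad[1L]])
  if (any(x$age_years < 1)) stop("female age must be >= 1")
  x
}

validate_offspring <- function(x) {
  need <- c("offspring_id", "cohort_year", "sex", "f", "recruited")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("offspring table missing column: ", miss[1L])
  if (!all(x$recruited %in% c(0, 1))) stop("recruited must be 0/1")
  if (!all(x$sex %in% c("female", "male"))) stop("sex must be 'female'/'male'")
  x
}

#' Build the long trait table for animal-model fitting
#'
#' Turns female-year and offspring records into the long per-trait table the
#' sampler consumes.  Trait codings:
#' \describe{
#'   \item{EPR_L}{female liability to produce an extra-pair rather than a
#'     within-pair offspring; binomial response \code{epo} with denominator
#'     \code{ars}.  Rows are emitted only for female-years with
#'     \code{ars > 0}: breeding failures carry no information about the
#'     EPO/WPO split.}
#'   \item{ARS_w}{relative annual reproductive success (ringed offspring per
#'     year divided by the across-year mean); Gaussian, emitted for all
#'     female-years including \code{ars = 0}.}
#'   \item{SR_wB}{survival to recruitment as a binary (0/1) threshold trait.}
#'   \item{SR_wG}{survival to recruitment as relative fitness on the
#'     observed scale: 0 or 1/mean(recruited), Gaussian.}
#' }
#' Grouping year is the breeding year for EPR_L and ARS_w and the natal
#' (cohort) year for SR; the residual-pairing unit is the female-year for
#' EPR_L/ARS_w and the offspring for SR.
#'
#' @param female_years data frame of female-year records (see
#'   \code{\link{validate_female_years}} for columns).
#' @param offspring data frame of offspring records, or \code{NULL}.
#' @param sr_coding \code{"binary"} (SR_wB), \code{"gaussian"} (SR_wG) or
#'   \code{"both"}.
#' @param rel_mode relative-fitness mode, see \code{\link{relative_fitness}}.
#' @return a \code{trait_table}: data frame with columns
#'   \code{individual_id}, \code{unit_id}, \code{year}, \code{trait},
#'   \code{value}, \code{denom}, \code{age_class}, \code{f}, \code{sex}.
#' @export
build_trait_table <- function(female_years, offspring = NULL,
                              sr_coding = c("both", "binary", "gaussian"),
                              rel_mode = "across-year") {
  sr_coding <- match.arg(sr_coding)
  rows <- list()
  if (!is.null(female_years) && nrow(female_years)) {
    fy <- validate_female_years(female_years)
    unit <- paste(fy$female_id, fy$year, sep = ":")
    acl <- age_class(fy$age_years)
    has_brood <- fy$ars > 0
    if (any(has_brood)) {
      rows$epr <- data.frame(
        individual_id = fy$female_id[has_brood],
        unit_id = unit[has_brood], year = fy$year[has_brood],
        trait = "EPR_L", value = as.numeric(fy$epo[has_brood]),
        denom = as.numeric(fy$ars[has_brood]),
        age_class = as.character(acl[has_brood]), f = fy$f[has_brood],
        sex = NA_character_, stringsAsFactors = FALSE)
    }
    rows$ars <- data.frame(
      individual_id = fy$female_id, unit_id = unit, year = fy$year,
      trait = "ARS_w",
      value = relative_fitness(fy$ars, mode = rel_mode, years = fy$year),
      denom = NA_real_, age_class = as.character(acl), f = fy$f,
      sex = NA_character_, stringsAsFactors = FALSE)
  }
  if (!is.null(offspring) && nrow(offspring)) {
    os <- validate_offspring(offspring)
    base <- data.frame(
      individual_id = os$offspring_id, unit_id = os$offspring_id,
      year = os$cohort_year, trait = NA_character_, value = NA_real_,
      denom = NA_real_, age_class = NA_character_, f = os$f,
      sex = os$sex, stringsAsFactors = FALSE)
    if (sr_coding %in% c("both", "binary")) {
      b <- base; b$trait <- "SR_wB"; b$value <- as.numeric(os$recruited)
      b$denom <- 1
      rows$srb <- b
    }
    if (sr_coding %in% c("both", "gaussian")) {
      g <- base; g$trait <- "SR_wG"
      g$value <- relative_fitness(os$recruited, mode = rel_mode,
                                  years = os$cohort_year)
      rows$srg <- g
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}

#' @rdname build_trait_table
#' @param path file path for reading/writing a trait table as CSV.
#' @export
write_trait_table <- function(x, path) {
  stopifnot(inherits(x, "trait_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname build_trait_table
#' @param x a \code{trait_table}.
#' @export
read_trait_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(individual_id = "character",
                                        unit_id = "character",
                                        trait = "character",
                                        age_class = "character",
                                        sex = "character"))
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Observed population rates
#'
#' Summary rates of the raw phenotype tables: mean and variance of ARS, the
#' overall EPO proportion among ringed offspring of observed female-years,
#' and the recruitment rate (with counts).
#'
#' @inheritParams build_trait_table
#' @return list with \code{mean_ars}, \code{var_ars}, \code{epo_proportion},
#'   \code{recruitment_rate}, \code{n_offspring}, \code{n_recruits}.
#' @export
observed_rates <- function(female_years, offspring = NULL) {
  fy <- validate_female_years(female_years)
  out <- list(mean_ars = mean(fy$ars), var_ars = stats::var(fy$ars),
              epo_proportion = sum(fy$epo) / sum(fy$ars))
  if (!is.null(offspring) && nrow(offspring)) {
    os <- validate_offspring(offspring)
    out$n_offspring <- nrow(os)
    out$n_recruits <- sum(os$recruited)
    out$recruitment_rate <- mean(os$recruited)
  }
  out
}
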