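## Bayesian animal models for mixed Gaussian / logit-liability traits.
##
## The sampler is a Gibbs scheme on the latent-Gaussian representation:
## every record (unit x trait) carries a value l on the model scale --
## the observed response for Gaussian traits, a latent liability for
## binomial/binary (logit) traits, and an imputed draw for missing
## responses.  Conditional on l the model is an ordinary Gaussian mixed
## model, so location effects (fixed effects, breeding values, year and
## permanent-individual effects) are drawn jointly from their multivariate
## normal full conditional via the dense mixed-model equations; free
## (co)variance blocks are drawn from conditional inverse-Wisharts;
## liabilities are updated by per-record random-walk Metropolis-Hastings
## with proposal scales adapted during burn-in.

FAMILY_GAUSS <- 0L; FAMILY_BINOM <- 1L; FAMILY_BINARY <- 2L
TYPE_OBS <- 0L; TYPE_LATENT <- 1L; TYPE_MISSING <- 2L

comp_tags <- c(additive = "A", year = "Y", permanent_individual = "PI",
               residual = "R")

#' Fit a Bayesian animal model
#'
#' Fits a univariate or bivariate animal model by MCMC.  Gaussian traits
#' are modelled on the observed scale; binomial and binary traits as
#' threshold traits on a latent logit-liability scale (binomial traits get
#' an estimated per-record overdispersion residual; binary traits have
#' residual variance fixed to 1 by convention).  Random effects: additive
#' genetic (covariance proportional to the pedigree relationship matrix),
#' year, and permanent individual.  In bivariate models the free
#' (co)variance blocks are 2x2 and records missing one response (for
#' example extra-pair liability in a year with no ringed offspring) are
#' imputed inside the sampler rather than dropped.
#'
#' @param traits a \code{trait_spec} or list of one or two of them.
#' @param data a \code{trait_table} (see \code{\link{build_trait_table}}).
#' @param ped sorted \code{pedigree}, required when any trait declares the
#'   \code{additive} random term; it should already be pruned to phenotyped
#'   individuals and their ancestors.
#' @param constraints a \code{\link{cov_structure}}; \code{NULL} components
#'   get model defaults.
#' @param priors a \code{\link{prior_spec}}.
#' @param mcmc an \code{\link{mcmc_config}} (carries the mandatory seed).
#' @param verbose print progress every 1,000 iterations.
#' @return an object of class \code{"epr_fit"} with elements
#'   \code{draws} (matrix, one column per parameter), \code{param_info},
#'   \code{traits}, \code{acceptance} (latent MH rates per trait),
#'   \code{mcmc}, \code{priors}.
#' @export
fit_animal_model <- function(traits, data, ped = NULL,
                             constraints = cov_structure(),
                             priors = prior_spec(), mcmc,
                             verbose = FALSE) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  if (!length(traits) %in% 1:2)
    stop("only univariate and bivariate models are supported")
  if (!inherits(mcmc, "mcmc_config")) stop("mcmc must be an mcmc_config()")
  prep <- prepare_model(traits, data, ped, constraints)
  run_gibbs(prep, priors, mcmc, verbose)
}

## ---------------------------------------------------------------------
## model preparation

prepare_model <- function(traits, data, ped, constraints) {
  T_ <- length(traits)
  tnames <- vapply(traits, `[[`, "", "name")
  if (anyDuplicated(tnames)) stop("duplicate trait names")
  fams <- vapply(traits, `[[`, "", "family")
  fam_code <- c(gaussian = FAMILY_GAUSS, `binomial-logit` = FAMILY_BINOM,
                `binary-logit` = FAMILY_BINARY)[fams]

  data <- as.data.frame(data)
  rows_t <- lapply(tnames, function(nm) data[data$trait == nm, , drop = FALSE])
  for (t in seq_len(T_)) {
    if (!nrow(rows_t[[t]])) stop("no records for trait: ", tnames[t])
    if (fam_code[t] == FAMILY_BINOM && any(rows_t[[t]]$denom < 1, na.rm = TRUE))
      stop("binomial trait needs denominator >= 1: ", tnames[t])
  }

  need_ped <- any(vapply(traits, function(s) "additive" %in% s$random, TRUE))
  if (need_ped) {
    if (is.null(ped)) stop("a pedigree is required for the additive term")
    check_sorted_ped(ped)
    phen <- unique(unlist(lapply(rows_t, function(x) x$individual_id)))
    missing_ids <- setdiff(phen, ped$id)
    if (length(missing_ids))
      stop("phenotyped individual missing from pedigree: ", missing_ids[1L])
  }

  ## resolve residual constraint before augmentation (freeness of cov_R
  ## decides which missing cells must be created)
  overlap <- matrix(TRUE, T_, T_)
  if (T_ == 2L)
    overlap[1, 2] <- overlap[2, 1] <-
      length(intersect(rows_t[[1]]$unit_id, rows_t[[2]]$unit_id)) > 0L
  resid <- resolve_block(constraints$residual, T_, default_residual(fam_code, overlap))

  ## augmented long row table: one row per (unit, trait) cell
  cells <- do.call(rbind, lapply(seq_len(T_), function(t) {
    x <- rows_t[[t]]
    data.frame(trait = t, unit = x$unit_id, indiv = x$individual_id,
               year = as.character(x$year), y = x$value,
               size = ifelse(is.na(x$denom), 1, x$denom),
               age_class = x$age_class, f = x$f, sex = x$sex,
               stringsAsFactors = FALSE)
  }))
  if (T_ == 2L) {
    for (t in 1:2) {
      o <- 3L - t
      if (resid$free[t, o]) {
        lack <- setdiff(cells$unit[cells$trait == o], cells$unit[cells$trait == t])
        if (length(lack)) {
          src <- cells[cells$trait == o & cells$unit %in% lack, , drop = FALSE]
          src <- src[!duplicated(src$unit), , drop = FALSE]
          src$trait <- t; src$y <- NA_real_; src$size <- 1
          cells <- rbind(cells, src)
        }
      }
    }
  }
  dupcell <- duplicated(paste(cells$trait, cells$unit))
  if (any(dupcell))
    stop("duplicate record for unit ", cells$unit[dupcell][1L])
  cells$type <- ifelse(is.na(cells$y), TYPE_MISSING,
                       ifelse(fam_code[cells$trait] == FAMILY_GAUSS,
                              TYPE_OBS, TYPE_LATENT))

  ## parameter layout ---------------------------------------------------
  Xs <- lapply(seq_len(T_), function(t)
    fixed_design(traits[[t]], cells[cells$trait == t, , drop = FALSE]))
  layout <- list(); P <- 0L
  layout$beta <- vector("list", T_)
  for (t in seq_len(T_)) {
    p <- ncol(Xs[[t]])
    layout$beta[[t]] <- P + seq_len(p); P <- P + p
  }
  a_traits <- which(vapply(traits, function(s) "additive" %in% s$random, TRUE))
  y_traits <- which(vapply(traits, function(s) "year" %in% s$random, TRUE))
  p_traits <- which(vapply(traits, function(s) "permanent_individual" %in% s$random, TRUE))
  q <- if (length(a_traits)) nrow(ped) else 0L
  layout$a <- list()
  for (t in a_traits) { layout$a[[as.character(t)]] <- P + seq_len(q); P <- P + q }
  ylev <- sort(unique(cells$year[cells$trait %in% y_traits]))
  layout$y <- list()
  for (t in y_traits) { layout$y[[as.character(t)]] <- P + seq_along(ylev); P <- P + length(ylev) }
  plev <- sort(unique(cells$indiv[cells$trait %in% p_traits]))
  layout$pi <- list()
  for (t in p_traits) { layout$pi[[as.character(t)]] <- P + seq_along(plev); P <- P + length(plev) }

  ## dense design, filled per trait
  W <- matrix(0, nrow(cells), P)
  for (t in seq_len(T_)) {
    r <- which(cells$trait == t)
    W[r, layout$beta[[t]]] <- Xs[[t]]
    if (t %in% a_traits)
      W[cbind(r, layout$a[[as.character(t)]][match(cells$indiv[r], ped$id)])] <- 1
    if (t %in% y_traits)
      W[cbind(r, layout$y[[as.character(t)]][match(cells$year[r], ylev)])] <- 1
    if (t %in% p_traits)
      W[cbind(r, layout$pi[[as.character(t)]][match(cells$indiv[r], plev)])] <- 1
  }

  ## residual grouping by unit pattern ----------------------------------
  pat <- tapply(cells$trait, cells$unit, function(x) paste(sort(unique(x)), collapse = ","))
  groups <- list()
  for (key in unique(pat)) {
    units_g <- names(pat)[pat == key]
    tg <- as.integer(strsplit(key, ",")[[1]])
    rows_gt <- lapply(tg, function(t) {
      r <- which(cells$trait == t & cells$unit %in% units_g)
      r[match(units_g, cells$unit[r])]
    })
    names(rows_gt) <- as.character(tg)
    Wg <- lapply(rows_gt, function(r) W[r, , drop = FALSE])
    CP <- list()
    for (i in seq_along(tg)) for (j in seq_along(tg)) {
      if (i <= j) CP[[paste(i, j)]] <- crossprod(Wg[[i]], Wg[[j]])
    }
    groups[[key]] <- list(traits = tg, units = units_g, rows = rows_gt,
                          W = Wg, CP = CP)
  }

  if (all(resid$free) && T_ == 2L) {
    full <- vapply(groups, function(g) length(g$traits) == T_, TRUE)
    if (!all(full))
      stop("free residual covariance requires every unit to carry both traits")
  }

  comps <- list()
  if (length(a_traits))
    comps$additive <- list(traits = a_traits, n = q,
                           block = resolve_block(constraints$additive,
                                                 length(a_traits), NULL))
  if (length(y_traits))
    comps$year <- list(traits = y_traits, n = length(ylev),
                       block = resolve_block(constraints$year,
                                             length(y_traits), NULL))
  if (length(p_traits))
    comps$permanent_individual <- list(traits = p_traits, n = length(plev),
                                       block = resolve_block(constraints$permanent_individual,
                                                             length(p_traits), NULL))
  comps$residual <- list(traits = seq_len(T_), n = NA, block = resid)

  Ainv_m <- if (length(a_traits)) ainverse(ped) else NULL

  ## bookkeeping for the joint scale moves: for each non-residual
  ## component and trait, where its effect enters each residual group
  scale_info <- list()
  for (nm in setdiff(names(comps), "residual")) {
    cm <- comps[[nm]]
    levmap <- switch(nm,
      additive = function(r) match(cells$indiv[r], ped$id),
      year = function(r) match(cells$year[r], ylev),
      permanent_individual = function(r) match(cells$indiv[r], plev))
    per_trait <- list()
    for (ti in seq_along(cm$traits)) {
      t <- cm$traits[ti]
      hits <- list()
      for (key in names(groups)) {
        g <- groups[[key]]
        il <- match(t, g$traits)
        if (!is.na(il))
          hits[[length(hits) + 1L]] <- list(gid = key, il = il,
                                            idx = levmap(g$rows[[il]]))
      }
      per_trait[[ti]] <- hits
    }
    scale_info[[nm]] <- per_trait
  }

  list(traits = traits, tnames = tnames, fam = fam_code, T = T_,
       scale_info = scale_info,
       cells = cells, layout = layout, P = P, groups = groups,
       comps = comps, Ainv = Ainv_m, ped = ped,
       Xnames = lapply(Xs, colnames),
       a_traits = a_traits, y_traits = y_traits, p_traits = p_traits,
       ylev = ylev, plev = plev)
}

## design matrix for the declared fixed effects; reference levels are
## age class 1 and female sex
fixed_design <- function(spec, cells_t) {
  cols <- list()
  if ("intercept" %in% spec$fixed) cols[["(Intercept)"]] <- rep(1, nrow(cells_t))
  if ("age_class" %in% spec$fixed) {
    ac <- cells_t$age_class
    cols[["age_class2"]] <- as.numeric(!is.na(ac) & ac == "class2")
    cols[["age_class3"]] <- as.numeric(!is.na(ac) & ac == "class3")
  }
  if ("f" %in% spec$fixed) {
    fv <- cells_t$f
    if (anyNA(fv)) stop("missing inbreeding coefficient for trait ", spec$name)
    cols[["f"]] <- fv
  }
  if ("sex" %in% spec$fixed) {
    sx <- cells_t$sex
    cols[["sexM"]] <- as.numeric(!is.na(sx) & sx == "male")
  }
  if (!length(cols)) stop("trait ", spec$name, " declares no fixed effects")
  do.call(cbind, cols)
}

default_residual <- function(fam_code, overlap) {
  T_ <- length(fam_code)
  value <- diag(1, T_); free <- matrix(TRUE, T_, T_)
  for (t in seq_len(T_)) {
    if (fam_code[t] == FAMILY_BINARY) { value[t, t] <- 1; free[t, t] <- FALSE }
  }
  if (T_ == 2L) {
    ok <- all(fam_code != FAMILY_BINARY) && overlap[1, 2]
    if (!ok) { value[1, 2] <- value[2, 1] <- 0; free[1, 2] <- free[2, 1] <- FALSE }
  }
  list(value = value, free = free)
}

## normalise a user/default constraint block; classify its update rule
resolve_block <- function(user, dim, default) {
  if (is.null(user)) {
    blk <- if (is.null(default))
      list(value = diag(1, dim), free = matrix(TRUE, dim, dim)) else default
  } else {
    blk <- list(value = as.matrix(user$value), free = as.matrix(user$free))
    if (!all(dim(blk$value) == dim) || !all(dim(blk$free) == dim))
      stop("constraint block has wrong dimension")
    if (!isSymmetric(blk$value) || !isSymmetric(blk$free))
      stop("constraint block must be symmetric")
  }
  off <- row(blk$free) != col(blk$free)
  blk$kind <- if (!any(blk$free)) "fixed"
  else if (all(blk$free)) "full"
  else if (!any(blk$free[off]) && all(blk$value[off & !blk$free] == 0)) "diag"
  else stop("unsupported covariance constraint pattern (free off-diagonals ",
            "must come with free diagonals, fixed off-diagonals must be 0)")
  blk
}

## ---------------------------------------------------------------------
## sampling helpers

riwish <- function(df, S) {
  p <- nrow(S)
  if (p == 1L) return(matrix(S[1, 1] / stats::rchisq(1, df), 1, 1))
  W <- stats::rWishart(1, df, chol2inv(chol(S)))[, , 1]
  V <- chol2inv(chol(W))
  (V + t(V)) / 2
}

## log(1 + exp(x)), stable
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## conditional inverse-Wishart update of one (co)variance block
update_block <- function(blk, S, n, prior) {
  if (blk$kind == "fixed") return(blk$value)
  if (blk$kind == "full") {
    return(riwish(prior$nu + n, prior$S0 + S))
  }
  ## diag: independent scalar inverse-Wishart per free variance
  out <- blk$value
  for (t in seq_len(nrow(out))) {
    if (blk$free[t, t])
      out[t, t] <- (prior$S0[t, t] + S[t, t]) / stats::rchisq(1, prior$nu + n[t])
  }
  out
}

## ---------------------------------------------------------------------
## the Gibbs sampler

run_gibbs <- function(prep, priors, mcmc, verbose = FALSE) {
  set.seed(mcmc$seed)
  T_ <- prep$T; P <- prep$P
  cells <- prep$cells; layout <- prep$layout; groups <- prep$groups

  comp_priors <- lapply(names(prep$comps), function(nm)
    prior_for_component(priors, nm, length(prep$comps[[nm]]$traits)))
  names(comp_priors) <- names(prep$comps)

  ## state
  theta <- numeric(P)
  l <- cells$y
  lat <- which(cells$type == TYPE_LATENT)
  l[lat] <- stats::qlogis((cells$y[lat] + 0.5) / (cells$size[lat] + 1))
  l[cells$type == TYPE_MISSING] <- 0
  ## free variances start at the empirical model-scale variance of the
  ## trait split evenly across its components; far-off starting values
  ## (e.g. a fixed 1) would need long burn-ins on slow-mixing variance
  ## chains
  v_emp <- vapply(seq_len(T_), function(t) {
    x <- l[cells$trait == t & cells$type != TYPE_MISSING]
    v <- if (length(x) > 1L) stats::var(x) else 1
    max(v, 1e-3)
  }, 1)
  n_comp_t <- vapply(seq_len(T_), function(t)
    sum(vapply(prep$comps, function(cm) t %in% cm$traits, TRUE)), 1L)
  Sigma <- lapply(prep$comps, function(cm) {
    G <- cm$block$value
    for (i in seq_along(cm$traits)) {
      t <- cm$traits[i]
      if (cm$block$free[i, i]) G[i, i] <- v_emp[t] / n_comp_t[t]
    }
    G
  })
  prop_sd <- rep(1, T_)
  acc_n <- acc_k <- numeric(T_)
  acc_n_tot <- acc_k_tot <- numeric(T_)
  ## scale-move proposal scales, one per (component, trait)
  sc_tau <- lapply(prep$scale_info, function(pt) rep(0.3, length(pt)))
  sc_n <- sc_k <- lapply(prep$scale_info, function(pt) numeric(length(pt)))
  layout_of <- c(additive = "a", year = "y", permanent_individual = "pi")

  ## residual bookkeeping: rows per trait (for diag updates), full groups
  rows_trait <- lapply(seq_len(T_), function(t) which(cells$trait == t))
  full_groups <- names(groups)[vapply(groups, function(g) length(g$traits) == T_, TRUE)]

  n_draws <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  pinfo <- param_table(prep)
  draws <- matrix(NA_real_, n_draws, nrow(pinfo),
                  dimnames = list(NULL, pinfo$name))
  drow <- 0L

  eta <- numeric(nrow(cells))
  bidx <- unlist(layout$beta)

  for (iter in seq_len(mcmc$iterations)) {
    ## residual precision per group
    SR <- Sigma$residual
    Rinv <- lapply(groups, function(g) {
      Sg <- SR[g$traits, g$traits, drop = FALSE]
      chol2inv(chol(Sg))
    })

    ## --- location effects: C theta = rhs -----------------------------
    C <- matrix(0, P, P)
    rhs <- numeric(P)
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]; Ri <- Rinv[[gi]]
      ng <- length(g$traits)
      for (i in seq_len(ng)) {
        m <- numeric(length(g$units))
        for (j in seq_len(ng)) {
          key <- if (i <= j) paste(i, j) else paste(j, i)
          CPij <- if (i <= j) g$CP[[key]] else t(g$CP[[key]])
          C <- C + Ri[i, j] * CPij
          m <- m + Ri[i, j] * l[g$rows[[j]]]
        }
        rhs <- rhs + drop(crossprod(g$W[[i]], m))
      }
    }
    bdi <- cbind(bidx, bidx)
    C[bdi] <- C[bdi] + 1 / priors$fixed_var
    if (length(prep$a_traits)) {
      Gi <- chol2inv(chol(Sigma$additive))
      at <- as.character(prep$a_traits)
      for (i in seq_along(at)) for (j in seq_along(at)) {
        ii <- layout$a[[at[i]]]; jj <- layout$a[[at[j]]]
        if (Gi[i, j] != 0 || i == j)
          C[ii, jj] <- C[ii, jj] + Gi[i, j] * prep$Ainv
      }
    }
    if (length(prep$y_traits)) {
      Gi <- chol2inv(chol(Sigma$year))
      yt <- as.character(prep$y_traits)
      for (i in seq_along(yt)) for (j in seq_along(yt)) {
        idx <- cbind(layout$y[[yt[i]]], layout$y[[yt[j]]])
        C[idx] <- C[idx] + Gi[i, j]
      }
    }
    if (length(prep$p_traits)) {
      Gi <- chol2inv(chol(Sigma$permanent_individual))
      pt <- as.character(prep$p_traits)
      for (i in seq_along(pt)) for (j in seq_along(pt)) {
        idx <- cbind(layout$pi[[pt[i]]], layout$pi[[pt[j]]])
        C[idx] <- C[idx] + Gi[i, j]
      }
    }
    U <- tryCatch(chol(C), error = function(e)
      stop("chain diverged (non-positive-definite equations) at iteration ",
           iter, call. = FALSE))
    theta <- backsolve(U, backsolve(U, rhs, transpose = TRUE)) +
      backsolve(U, stats::rnorm(P))
    if (!all(is.finite(theta)))
      stop("chain diverged (non-finite state) at iteration ", iter)

    ## --- linear predictor and latent updates --------------------------
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (i in seq_along(g$traits))
        eta[g$rows[[i]]] <- drop(g$W[[i]] %*% theta)
    }
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      for (i in seq_along(g$traits)) {
        t <- g$traits[i]
        r <- g$rows[[i]]
        if (length(g$traits) == 2L) {
          o <- 3L - i
          ro <- g$rows[[o]]
          to <- g$traits[o]
          svv <- SR[t, t]; svo <- SR[t, to]; soo <- SR[to, to]
          cmean <- eta[r] + (svo / soo) * (l[ro] - eta[ro])
          cvar <- svv - svo^2 / soo
        } else {
          cmean <- eta[r]
          cvar <- SR[t, t]
        }
        ty <- cells$type[r]
        im <- which(ty == TYPE_MISSING)
        if (length(im))
          l[r[im]] <- stats::rnorm(length(im), cmean[im], sqrt(cvar))
        il <- which(ty == TYPE_LATENT)
        if (length(il)) {
          rr <- r[il]
          cur <- l[rr]
          prop <- cur + stats::rnorm(length(rr), 0, prop_sd[t])
          yv <- cells$y[rr]; nv <- cells$size[rr]
          mcur <- cmean[il]
          logr <- (yv * prop - nv * log1pexp(prop)) -
                  (yv * cur - nv * log1pexp(cur)) -
                  (prop - mcur)^2 / (2 * cvar) + (cur - mcur)^2 / (2 * cvar)
          acc <- log(stats::runif(length(rr))) < logr
          l[rr][acc] <- prop[acc]
          acc_n[t] <- acc_n[t] + length(rr); acc_k[t] <- acc_k[t] + sum(acc)
          acc_n_tot[t] <- acc_n_tot[t] + length(rr)
          acc_k_tot[t] <- acc_k_tot[t] + sum(acc)
        }
      }
    }
    if (iter <= mcmc$burn_in && iter %% 100L == 0L) {
      for (t in seq_len(T_)) {
        if (acc_n[t] > 0) {
          rate <- acc_k[t] / acc_n[t]
          prop_sd[t] <- min(10, max(0.05, prop_sd[t] * exp(rate - 0.35)))
        }
      }
      acc_n[] <- 0; acc_k[] <- 0
    }

    ## --- (co)variance components --------------------------------------
    if (length(prep$a_traits)) {
      M <- vapply(as.character(prep$a_traits), function(k) theta[layout$a[[k]]],
                  numeric(length(layout$a[[1]])))
      M <- matrix(M, ncol = length(prep$a_traits))
      S <- crossprod(M, prep$Ainv %*% M)
      nlev <- if (prep$comps$additive$block$kind == "full") nrow(M)
              else rep(nrow(M), ncol(M))
      Sigma$additive <- update_block(prep$comps$additive$block, S, nlev,
                                     comp_priors$additive)
    }
    if (length(prep$y_traits)) {
      M <- vapply(as.character(prep$y_traits), function(k) theta[layout$y[[k]]],
                  numeric(length(prep$ylev)))
      M <- matrix(M, ncol = length(prep$y_traits))
      S <- crossprod(M)
      nlev <- if (prep$comps$year$block$kind == "full") nrow(M)
              else rep(nrow(M), ncol(M))
      Sigma$year <- update_block(prep$comps$year$block, S, nlev,
                                 comp_priors$year)
    }
    if (length(prep$p_traits)) {
      M <- vapply(as.character(prep$p_traits), function(k) theta[layout$pi[[k]]],
                  numeric(length(prep$plev)))
      M <- matrix(M, ncol = length(prep$p_traits))
      S <- crossprod(M)
      nlev <- if (prep$comps$permanent_individual$block$kind == "full") nrow(M)
              else rep(nrow(M), ncol(M))
      Sigma$permanent_individual <-
        update_block(prep$comps$permanent_individual$block, S, nlev,
                     comp_priors$permanent_individual)
    }
    rblk <- prep$comps$residual$block
    if (rblk$kind != "fixed") {
      if (rblk$kind == "full" && T_ == 2L) {
        E <- do.call(cbind, lapply(seq_len(T_), function(i) {
          unlist(lapply(full_groups, function(k)
            l[groups[[k]]$rows[[i]]] - eta[groups[[k]]$rows[[i]]]))
        }))
        Sigma$residual <- update_block(rblk, crossprod(E), nrow(E),
                                       comp_priors$residual)
      } else if (rblk$kind == "full" && T_ == 1L) {
        e <- l - eta
        Sigma$residual <- update_block(rblk, matrix(sum(e^2), 1, 1),
                                       length(e), comp_priors$residual)
      } else {
        S <- diag(0, T_); nvec <- numeric(T_)
        for (t in seq_len(T_)) {
          e <- l[rows_trait[[t]]] - eta[rows_trait[[t]]]
          S[t, t] <- sum(e^2); nvec[t] <- length(e)
        }
        Sigma$residual <- update_block(rblk, S, nvec, comp_priors$residual)
      }
    }

    ## --- joint scale moves --------------------------------------------
    ## Metropolis move rescaling one component-trait's effects and its
    ## (co)variance row/column together: eff' = s eff, G'[t, ] = s G[t, ]
    ## (diagonal s^2).  The Gaussian effect-prior normalisation cancels
    ## against the Jacobian, leaving the likelihood change, -nu log s and
    ## the inverse-Wishart trace term.  Decorrelates variance components
    ## from their effect vectors without altering the prior.
    SRc <- Sigma$residual
    for (sweep in 1:2) for (nm in names(prep$scale_info)) {
      cm <- prep$comps[[nm]]
      G <- Sigma[[nm]]
      pr <- comp_priors[[nm]]
      for (ti in seq_along(cm$traits)) {
        if (!cm$block$free[ti, ti]) next
        cols <- layout[[layout_of[[nm]]]][[as.character(cm$traits[ti])]]
        s <- exp(stats::rnorm(1, 0, sc_tau[[nm]][ti]))
        eff <- theta[cols]
        dlik <- 0
        deltas <- vector("list", length(prep$scale_info[[nm]][[ti]]))
        for (hi in seq_along(prep$scale_info[[nm]][[ti]])) {
          h <- prep$scale_info[[nm]][[ti]][[hi]]
          g <- groups[[h$gid]]
          Sg <- SRc[g$traits, g$traits, drop = FALSE]
          Ri <- chol2inv(chol(Sg))
          r <- g$rows[[h$il]]
          dl <- (s - 1) * eff[h$idx]
          for (j in seq_along(g$traits)) {
            ej <- l[g$rows[[j]]] - eta[g$rows[[j]]]
            dlik <- dlik + Ri[h$il, j] * sum(dl * ej)
          }
          dlik <- dlik - 0.5 * Ri[h$il, h$il] * sum(dl^2)
          deltas[[hi]] <- list(rows = r, dl = dl)
        }
        Gp <- G
        Gp[ti, ] <- s * Gp[ti, ]; Gp[, ti] <- s * Gp[, ti]
        dtr <- sum(diag(pr$S0 %*% chol2inv(chol(Gp)))) -
               sum(diag(pr$S0 %*% chol2inv(chol(G))))
        logr <- dlik - pr$nu * log(s) - 0.5 * dtr
        sc_n[[nm]][ti] <- sc_n[[nm]][ti] + 1
        if (log(stats::runif(1)) < logr) {
          sc_k[[nm]][ti] <- sc_k[[nm]][ti] + 1
          theta[cols] <- s * eff
          G <- Gp
          for (d in deltas) eta[d$rows] <- eta[d$rows] + d$dl
        }
      }
      Sigma[[nm]] <- G
    }
    if (iter <= mcmc$burn_in && iter %% 100L == 0L) {
      for (nm in names(sc_tau)) {
        rate <- ifelse(sc_n[[nm]] > 0, sc_k[[nm]] / pmax(sc_n[[nm]], 1), 0.44)
        sc_tau[[nm]] <- pmin(3, pmax(0.02, sc_tau[[nm]] * exp(rate - 0.44)))
        sc_n[[nm]][] <- 0; sc_k[[nm]][] <- 0
      }
    }

    ## --- record -------------------------------------------------------
    if (iter > mcmc$burn_in && (iter - mcmc$burn_in) %% mcmc$thin == 0L) {
      drow <- drow + 1L
      draws[drow, ] <- collect_draw(prep, Sigma, theta)
    }
    if (verbose && iter %% 1000L == 0L)
      message("iteration ", iter, " / ", mcmc$iterations,
              if (any(acc_n_tot > 0))
                paste0("  (MH acceptance ",
                       paste(sprintf("%s: %.2f", prep$tnames[acc_n_tot > 0],
                                     (acc_k_tot / pmax(acc_n_tot, 1))[acc_n_tot > 0]),
                             collapse = ", "), ")") else "")
  }

  draws <- draws[seq_len(drow), , drop = FALSE]
  acc <- ifelse(acc_n_tot > 0, acc_k_tot / acc_n_tot, NA_real_)
  names(acc) <- prep$tnames
  structure(list(draws = draws, param_info = pinfo, traits = prep$traits,
                 tnames = prep$tnames, families = prep$fam,
                 components = lapply(prep$comps, function(cm)
                   list(traits = prep$tnames[cm$traits], block = cm$block)),
                 acceptance = acc, proposal_sd = prop_sd,
                 mcmc = mcmc, priors = priors,
                 n_records = nrow(prep$cells)),
            class = "epr_fit")
}

## one row of the draws matrix: free and fixed (co)variance elements,
## then fixed-effect coefficients
param_table <- function(prep) {
  rows <- list()
  for (nm in names(prep$comps)) {
    cm <- prep$comps[[nm]]; tag <- comp_tags[[nm]]
    tn <- prep$tnames[cm$traits]
    for (i in seq_along(tn)) for (j in i:length(tn)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = if (i == j) paste0("V", tag, ".", tn[i])
               else paste0("cov", tag, ".", tn[i], ":", tn[j]),
        kind = if (i == j) "variance" else "covariance",
        component = nm, trait1 = tn[i], trait2 = tn[j],
        free = cm$block$free[i, j], stringsAsFactors = FALSE)
    }
  }
  for (t in seq_len(prep$T)) {
    for (cn in prep$Xnames[[t]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("beta.", prep$tnames[t], ".", cn), kind = "beta",
        component = "fixed", trait1 = prep$tnames[t], trait2 = NA,
        free = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

collect_draw <- function(prep, Sigma, theta) {
  out <- numeric(0)
  for (nm in names(prep$comps)) {
    G <- Sigma[[nm]]
    d <- nrow(G)
    for (i in seq_len(d)) for (j in i:d) out <- c(out, G[i, j])
  }
  for (t in seq_len(prep$T)) out <- c(out, theta[prep$layout$beta[[t]]])
  out
}

#' @export
print.epr_fit <- function(x, ...) {
  cat("Bayesian animal model fit:",
      paste(x$tnames, collapse = " x "), "\n")
  cat("  ", nrow(x$draws), "retained draws (", x$mcmc$iterations,
      "iterations, burn-in", x$mcmc$burn_in, ", thin", x$mcmc$thin, ")\n")
  if (any(!is.na(x$acceptance)))
    cat("  latent MH acceptance:",
        paste(sprintf("%s %.2f", names(x$acceptance)[!is.na(x$acceptance)],
                      x$acceptance[!is.na(x$acceptance)]), collapse = ", "), "\n")
  invisible(x)
}
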