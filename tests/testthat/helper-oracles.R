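# Independent oracles and fixture builders, kept free of the package's own
# relationship algebra so they can check it.

# Recursive kinship by the textbook definition:
#   k(x, x) = (1 + k(dam_x, sire_x)) / 2
#   k(x, y) = (k(dam_x, y) + k(sire_x, y)) / 2   when x is sorted after y
# with unknown parents contributing 0.
oracle_kinship <- function(ped_df) {
  n <- nrow(ped_df)
  pos <- seq_len(n); names(pos) <- ped_df$id
  dam <- unname(pos[ped_df$dam]); sire <- unname(pos[ped_df$sire])
  K <- matrix(0, n, n, dimnames = list(ped_df$id, ped_df$id))
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i == j) {
      fd <- if (is.na(dam[i]) || is.na(sire[i])) 0 else K[dam[i], sire[i]]
      return((1 + fd) / 2)
    }
    a <- max(i, j); b <- min(i, j)
    ((if (is.na(dam[a])) 0 else K[dam[a], b]) +
     (if (is.na(sire[a])) 0 else K[sire[a], b])) / 2
  }
  for (i in seq_len(n)) for (j in seq_len(i)) {
    K[i, j] <- K[j, i] <- kin(i, j)
  }
  K
}

# Random sorted pedigree: each individual draws two distinct earlier
# parents with probability p_parents (else founder); sexes ignored.
random_pedigree_df <- function(n, p_parents = 0.7) {
  id <- sprintf("i%03d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > 2 && stats::runif(1) < p_parents) {
      pr <- sample(i - 1L, 2L)
      dam[i] <- id[pr[1]]; sire[i] <- id[pr[2]]
    }
  }
  data.frame(id = id, dam = dam, sire = sire, stringsAsFactors = FALSE)
}

# small study-shaped population used by several fitting tests
small_sim <- function(seed, n_founder_pairs = 10, n_years = 6) {
  simulate_population(sim_config(n_founder_pairs = n_founder_pairs,
                                 n_years = n_years, seed = seed))
}

gauss_spec <- function(name = "trait1", random = c("additive", "year"))
  trait_spec(name, "gaussian", fixed = "intercept", random = random)
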