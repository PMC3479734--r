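#' Pedigree construction and validation
#'
#' Build a validated, topologically sorted pedigree from a data frame.
#' Unknown parents may be encoded as \code{NA}, \code{0} or the empty
#' string; all three dialects are normalised to \code{NA}.  Records are
#' reordered so that every parent precedes its offspring, which the
#' relationship algebra (\code{\link{additive_relationship}},
#' \code{\link{ainverse}}) requires.
#'
#' @param x data frame with columns \code{id}, \code{dam}, \code{sire} and
#'   optionally \code{cohort} (integer year) and \code{immigrant} (0/1).
#' @param add_founders if \code{TRUE}, parents that appear only in the
#'   \code{dam}/\code{sire} columns are silently added as founder records;
#'   if \code{FALSE} (default) such parents are an error.
#' @return an object of class \code{"pedigree"}: a data frame with columns
#'   \code{id}, \code{dam}, \code{sire}, \code{cohort}, \code{immigrant},
#'   sorted parents-before-offspring.
#' @seealso \code{\link{read_pedigree}}, \code{\link{inbreeding}}
#' @export
pedigree <- function(x, add_founders = FALSE) {
  x <- as.data.frame(x)
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns 'id', 'dam', 'sire'")
  id <- as.character(x$id)
  dam <- normalise_parent(x$dam)
  sire <- normalise_parent(x$sire)
  cohort <- if ("cohort" %in% names(x)) as.integer(x$cohort) else rep(NA_integer_, length(id))
  immigrant <- if ("immigrant" %in% names(x)) as.integer(x$immigrant) %in% 1L else rep(FALSE, length(id))

  if (anyNA(id) || any(id == ""))
    stop("missing individual id in pedigree")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("duplicate pedigree id: ", dup[1L])

  known <- unique(c(dam, sire))
  known <- known[!is.na(known)]
  orphan <- setdiff(known, id)
  if (length(orphan)) {
    if (!add_founders)
      stop("parent id not present as an individual: ", orphan[1L],
           " (use add_founders = TRUE to create founder records)")
    extra <- data.frame(id = orphan, dam = NA_character_, sire = NA_character_,
                        cohort = NA_integer_, immigrant = FALSE,
                        stringsAsFactors = FALSE)
    id <- c(id, extra$id); dam <- c(dam, extra$dam); sire <- c(sire, extra$sire)
    cohort <- c(cohort, extra$cohort); immigrant <- c(immigrant, extra$immigrant)
  }

  ord <- ped_toposort(id, dam, sire)
  out <- data.frame(id = id, dam = dam, sire = sire, cohort = cohort,
                    immigrant = immigrant, stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

normalise_parent <- function(p) {
  p <- as.character(p)
  p[!is.na(p) & (p == "" | p == "0" | toupper(p) == "NA")] <- NA_character_
  p
}

## Topological order via generation depth (founders 0, otherwise
## 1 + max over parents), computed by iterative DFS with cycle detection.
## Ties are broken by id, so the sorted order is a canonical function of
## the pedigree, not of the row order on disk.
ped_toposort <- function(id, dam, sire) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  pd <- unname(idx[dam]); ps <- unname(idx[sire])   # NA where unknown
  depth <- rep(NA_integer_, n)
  state <- integer(n)                               # 0 new, 1 open, 2 done
  for (root in seq_len(n)) {
    if (state[root] == 2L) next
    stack <- root
    while (length(stack)) {
      j <- stack[length(stack)]
      if (state[j] == 2L) { stack <- stack[-length(stack)]; next }
      parents <- unique(c(pd[j], ps[j])); parents <- parents[!is.na(parents)]
      pending <- parents[state[parents] != 2L]
      if (state[j] == 0L) {
        state[j] <- 1L
        if (any(state[pending] == 1L))
          stop("pedigree contains a cycle involving individual: ", id[j])
        if (length(pending)) { stack <- c(stack, pending); next }
      } else if (length(pending)) {
        ## revisiting an open node whose parents are still open: cycle
        stop("pedigree contains a cycle involving individual: ", id[j])
      }
      depth[j] <- if (length(parents)) 1L + max(depth[parents]) else 0L
      state[j] <- 2L
      stack <- stack[-length(stack)]
    }
  }
  order(depth, id)
}

#' Read or write a pedigree file
#'
#' Pedigree files are CSV with header columns \code{id}, \code{dam},
#' \code{sire} and optionally \code{cohort} and \code{immigrant} (0/1).
#' Unknown parents may be written as \code{NA}, \code{0} or left empty;
#' \code{write_pedigree} emits \code{NA}.
#'
#' @param path file path.
#' @param add_founders passed to \code{\link{pedigree}}.
#' @return \code{read_pedigree}: a sorted \code{pedigree} object.
#' @export
read_pedigree <- function(path, add_founders = FALSE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  pedigree(x, add_founders = add_founders)
}

#' @rdname read_pedigree
#' @param ped a \code{pedigree} object.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- as.data.frame(ped)
  out$immigrant <- as.integer(out$immigrant)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      sum(is.na(x$dam) & is.na(x$sire)), "founders,",
      sum(x$immigrant), "immigrants\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Additive genetic relationship matrix
#'
#' Computes the numerator relationship matrix A by the tabular (recursive)
#' method, honouring inbreeding: \code{A[i,i] = 1 + f_i} where \code{f_i}
#' is the kinship between i's parents, and \code{A = 2 K} where K is the
#' kinship matrix.  Individuals with one known parent are treated as having
#' an unrelated, non-inbred unknown parent.
#'
#' @param ped a sorted \code{pedigree} object.
#' @return dense symmetric matrix with dimnames equal to the pedigree ids.
#' @export
additive_relationship <- function(ped) {
  check_sorted_ped(ped)
  n <- nrow(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  pd <- unname(idx[ped$dam]); ps <- unname(idx[ped$sire])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    d <- pd[i]; s <- ps[i]
    f <- if (!is.na(d) && !is.na(s)) 0.5 * A[d, s] else 0
    A[i, i] <- 1 + f
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(d)) rel <- rel + 0.5 * A[j, d]
      if (!is.na(s)) rel <- rel + 0.5 * A[j, s]
      A[j, i] <- rel
      A[i, j] <- rel
    }
  }
  A
}

#' Kinship matrix
#'
#' Pairwise kinship coefficients k (probability of identity by descent of
#' randomly drawn alleles), equal to half the additive relationship:
#' \code{K = A / 2}, with self-kinship \code{(1 + f)/2}.
#'
#' @inheritParams additive_relationship
#' @return dense symmetric matrix of kinship coefficients.
#' @export
kinship_matrix <- function(ped) additive_relationship(ped) / 2

#' Inbreeding coefficients
#'
#' \code{f_i} equals the kinship between i's parents; \code{f = 0} for
#' founders, immigrants and any individual with an unknown parent
#' (immigrants are treated as unrelated to all natives).
#'
#' @inheritParams additive_relationship
#' @return named numeric vector of inbreeding coefficients, in pedigree
#'   order.
#' @export
inbreeding <- function(ped) {
  check_sorted_ped(ped)
  A <- additive_relationship(ped)
  f <- diag(A) - 1
  names(f) <- ped$id
  f
}

#' Inverse of the additive relationship matrix
#'
#' Direct construction of A-inverse from the pedigree by Henderson's rules
#' with Quaas's inbreeding adjustment: each individual contributes
#' \code{1/d_i} to the Mendelian-sampling diagonal, where
#' \code{d_i = 0.5 - 0.25 (f_dam + f_sire)} (both parents known),
#' \code{0.75 - 0.25 f_parent} (one known) or 1 (founder).
#'
#' @inheritParams additive_relationship
#' @param f optional precomputed inbreeding vector in pedigree order.
#' @return dense symmetric matrix, the exact inverse of
#'   \code{\link{additive_relationship}(ped)}.
#' @export
ainverse <- function(ped, f = NULL) {
  check_sorted_ped(ped)
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  idx <- seq_len(n); names(idx) <- ped$id
  pd <- unname(idx[ped$dam]); ps <- unname(idx[ped$sire])
  Ai <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    d <- pd[i]; s <- ps[i]
    if (!is.na(d) && !is.na(s)) {
      dm <- 0.5 - 0.25 * (f[d] + f[s])
    } else if (!is.na(d) || !is.na(s)) {
      p <- if (is.na(d)) s else d
      dm <- 0.75 - 0.25 * f[p]
    } else {
      dm <- 1
    }
    w <- 1 / dm
    Ai[i, i] <- Ai[i, i] + w
    for (p in c(d, s)) {
      if (!is.na(p)) {
        Ai[i, p] <- Ai[i, p] - 0.5 * w
        Ai[p, i] <- Ai[p, i] - 0.5 * w
      }
    }
    if (!is.na(d)) Ai[d, d] <- Ai[d, d] + 0.25 * w
    if (!is.na(s)) Ai[s, s] <- Ai[s, s] + 0.25 * w
    if (!is.na(d) && !is.na(s)) {
      Ai[d, s] <- Ai[d, s] + 0.25 * w
      Ai[s, d] <- Ai[s, d] + 0.25 * w
    }
  }
  Ai
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Retains exactly the union of the given individuals and all their known
#' ancestors.  Pairwise relationships among retained individuals are
#' unchanged by pruning.
#'
#' @inheritParams additive_relationship
#' @param phenotyped_ids character vector of ids with phenotypic data; must
#'   all be present in the pedigree.
#' @return a \code{pedigree} object containing the retained records.
#' @export
prune_pedigree <- function(ped, phenotyped_ids) {
  check_sorted_ped(ped)
  phenotyped_ids <- unique(as.character(phenotyped_ids))
  unknown <- setdiff(phenotyped_ids, ped$id)
  if (length(unknown))
    stop("phenotyped id not in pedigree: ", unknown[1L])
  idx <- seq_len(nrow(ped)); names(idx) <- ped$id
  keep <- logical(nrow(ped))
  keep[idx[phenotyped_ids]] <- TRUE
  ## sorted order: walking from the bottom up marks all ancestors
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      for (p in c(ped$dam[i], ped$sire[i]))
        if (!is.na(p)) keep[idx[[p]]] <- TRUE
    }
  }
  out <- as.data.frame(ped)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Summary statistics of pairwise kinship
#'
#' Mean, median, inter-quartile range, range and percentage of zeros of the
#' kinship coefficient over all unordered off-diagonal pairs among a set of
#' individuals.
#'
#' @param K kinship matrix (see \code{\link{kinship_matrix}}).
#' @param ids subset of rownames of \code{K}; defaults to all.
#' @return list with elements \code{n}, \code{n_pairs}, \code{mean},
#'   \code{median}, \code{iqr} (length-2), \code{range} (length-2) and
#'   \code{pct_zero}.
#' @export
kinship_summary <- function(K, ids = rownames(K)) {
  ids <- as.character(ids)
  missing_ids <- setdiff(ids, rownames(K))
  if (length(missing_ids))
    stop("id not in kinship matrix: ", missing_ids[1L])
  if (length(ids) < 2L)
    stop("kinship summary needs at least two individuals")
  Ks <- K[ids, ids, drop = FALSE]
  k <- Ks[upper.tri(Ks)]
  list(n = length(ids), n_pairs = length(k),
       mean = mean(k), median = stats::median(k),
       iqr = unname(stats::quantile(k, c(0.25, 0.75))),
       range = range(k), pct_zero = 100 * mean(k == 0))
}

#' Expected fraction of correct pedigree links under unmodelled paternity
#'
#' With maternal links always correct and each paternal link wrong with
#' probability equal to the extra-pair rate, the expected proportion of
#' correct parent-offspring links is \code{(1 + (1 - epr_rate))/2}.
#'
#' @param epr_rate extra-pair offspring proportion in [0, 1].
#' @return expected proportion of correct links.
#' @export
expected_link_correctness <- function(epr_rate) {
  if (!is.numeric(epr_rate) || any(epr_rate < 0) || any(epr_rate > 1))
    stop("epr_rate must be in [0, 1]")
  (1 + (1 - epr_rate)) / 2
}

check_sorted_ped <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("not a 'pedigree' object; use pedigree() or read_pedigree()")
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  pd <- pos[ped$dam]; ps <- pos[ped$sire]
  bad <- which((!is.na(pd) & pd >= pos) | (!is.na(ps) & ps >= pos))
  if (length(bad))
    stop("pedigree not sorted parents-before-offspring at individual: ",
         ped$id[bad[1L]])
  invisible(TRUE)
}
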