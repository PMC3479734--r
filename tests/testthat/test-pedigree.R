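test_that("pedigree construction validates, normalises and sorts", {
  p <- pedigree(data.frame(id = c("C", "A", "B"), dam = c("A", NA, ""),
                           sire = c("B", "0", NA)))
  expect_equal(nrow(p), 3L)
  expect_equal(p$id, c("A", "B", "C"))      # C sorted after its parents
  expect_true(all(is.na(p$dam[1:2])))

  # reading a file with offspring listed before parents gives same order
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dam,sire", "C,A,B", "B,,", "A,,"), tf)
  expect_equal(read_pedigree(tf)$id, c("A", "B", "C"))

  expect_error(pedigree(data.frame(id = c("A", "A"), dam = NA, sire = NA)),
               "duplicate")
  expect_error(pedigree(data.frame(id = "C", dam = "C", sire = NA)), "cycle")
  expect_error(pedigree(data.frame(id = "C", dam = "X", sire = NA)),
               "not present")
  # explicit founder creation on request
  p2 <- pedigree(data.frame(id = "C", dam = "X", sire = NA),
                 add_founders = TRUE)
  expect_setequal(p2$id, c("C", "X"))
})

test_that("pedigree files round-trip", {
  p <- pedigree(data.frame(id = c("A", "B", "C"), dam = c(NA, NA, "A"),
                           sire = c(NA, NA, "B"), cohort = c(1, 1, 2),
                           immigrant = c(0, 1, 0)))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(p, tf)
  p2 <- read_pedigree(tf)
  expect_equal(as.data.frame(p2), as.data.frame(p))
})

test_that("additive relationship matches textbook cases", {
  trio <- pedigree(data.frame(id = c("P1", "P2", "O"), dam = c(NA, NA, "P1"),
                              sire = c(NA, NA, "P2")))
  A <- additive_relationship(trio)
  expect_equal(A["P1", "O"], 0.5)
  expect_equal(A["P1", "P2"], 0)

  sibs <- pedigree(data.frame(id = c("P1", "P2", "S1", "S2"),
                              dam = c(NA, NA, "P1", "P1"),
                              sire = c(NA, NA, "P2", "P2")))
  expect_equal(additive_relationship(sibs)["S1", "S2"], 0.5)

  # offspring of a full-sib mating: f = 0.25
  inc <- pedigree(data.frame(id = c("P1", "P2", "S1", "S2", "X"),
                             dam = c(NA, NA, "P1", "P1", "S1"),
                             sire = c(NA, NA, "P2", "P2", "S2")))
  expect_equal(additive_relationship(inc)["X", "X"], 1.25)
  expect_equal(unname(inbreeding(inc)["X"]), 0.25)
})

test_that("A equals twice the recursive-kinship oracle on random pedigrees", {
  set.seed(401)
  for (rep in 1:50) {
    df <- random_pedigree_df(sample(20:100, 1))
    ped <- pedigree(df)
    A <- additive_relationship(ped)
    K <- oracle_kinship(as.data.frame(ped))
    expect_equal(A, 2 * K, tolerance = 1e-12)
  }
})

test_that("A is PSD, diag(A) - 1 is the inbreeding vector, and ainverse inverts A", {
  set.seed(402)
  for (rep in 1:8) {
    ped <- pedigree(random_pedigree_df(sample(50:200, 1)))
    A <- additive_relationship(ped)
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
    expect_equal(unname(diag(A) - 1), unname(inbreeding(ped)))
    Ai <- ainverse(ped)
    expect_lt(max(abs(Ai %*% A - diag(nrow(A)))), 1e-8)
  }
})

test_that("inbreeding follows the kinship of the parents", {
  # offspring of paternal half-sibs: f = 0.125
  hs <- pedigree(data.frame(id = c("S", "D1", "D2", "H1", "H2", "X"),
                            dam = c(NA, NA, NA, "D1", "D2", "H1"),
                            sire = c(NA, NA, NA, "S", "S", "H2")))
  expect_equal(unname(inbreeding(hs)["X"]), 0.125)

  # immigrant x native pairing: offspring f = 0 (immigrants unrelated)
  im <- pedigree(data.frame(id = c("N1", "N2", "NK", "I", "X"),
                            dam = c(NA, NA, "N1", NA, "NK"),
                            sire = c(NA, NA, "N2", NA, "I"),
                            immigrant = c(0, 0, 0, 1, 0)))
  expect_equal(unname(inbreeding(im)["X"]), 0)
  # founders have f = 0
  expect_equal(unname(inbreeding(im)[c("N1", "I")]), c(0, 0))
})

test_that("pruning keeps phenotyped individuals plus ancestors and preserves relationships", {
  trio <- pedigree(data.frame(id = c("A", "B", "C", "D"),
                              dam = c(NA, NA, "A", NA),
                              sire = c(NA, NA, "B", NA)))
  pr <- prune_pedigree(trio, "C")
  expect_setequal(pr$id, c("A", "B", "C"))   # unrelated D dropped
  expect_error(prune_pedigree(trio, "Z"), "not in pedigree")

  set.seed(403)
  ped <- pedigree(random_pedigree_df(80))
  keep <- sample(ped$id, 25)
  sub <- prune_pedigree(ped, keep)
  A_full <- additive_relationship(ped)
  A_sub <- additive_relationship(sub)
  expect_equal(A_sub, A_full[sub$id, sub$id])
})

test_that("kinship summary statistics match brute-force enumeration", {
  trio <- pedigree(data.frame(id = c("A", "B", "C"), dam = c(NA, NA, "A"),
                              sire = c(NA, NA, "B")))
  K <- kinship_matrix(trio)
  s <- kinship_summary(K)
  expect_equal(s$mean, mean(c(0, 0.25, 0.25)))
  expect_equal(s$pct_zero, 100 / 3)

  founders <- pedigree(data.frame(id = c("A", "B", "C"), dam = NA, sire = NA))
  s0 <- kinship_summary(kinship_matrix(founders))
  expect_equal(s0$mean, 0)
  expect_equal(s0$pct_zero, 100)
  expect_error(kinship_summary(K, "A"), "two individuals")

  set.seed(404)
  ped <- pedigree(random_pedigree_df(60))
  K <- kinship_matrix(ped)
  s <- kinship_summary(K)
  # brute force over all unordered pairs
  vals <- c()
  for (i in 1:59) for (j in (i + 1):60) vals <- c(vals, K[i, j])
  expect_equal(s$mean, mean(vals))
  expect_equal(s$median, median(vals))
  expect_equal(s$range, range(vals))
  expect_equal(s$n_pairs, length(vals))
})

test_that("expected link correctness averages maternal and paternal accuracy", {
  expect_equal(expected_link_correctness(0.29), 0.855)
  expect_equal(expected_link_correctness(0), 1)
  expect_equal(expected_link_correctness(1), 0.5)
  expect_error(expected_link_correctness(1.2), "0, 1")
})
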