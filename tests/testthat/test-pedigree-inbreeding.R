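test_that("inbreeding matches textbook and oracle-derived values", {
  ped <- fullsib_ped()
  f <- inbreeding_ml(ped)
  expect_equal(f[["x"]], 0.25)            # full-sib mating
  expect_equal(unname(f[c("s", "d", "a", "b")]), rep(0, 4))  # founders/sibs
  # sire x daughter, dam unrelated: oracle gives a_{sire,daughter} = 0.5
  ped2 <- pedigree(c("3", "4", "5", "6"), c("0", "0", "3", "3"),
                   c("0", "0", "4", "5"))
  A <- relationship_matrix(ped2)
  expect_equal(A["3", "5"], 0.5)
  expect_equal(inbreeding_ml(ped2)[["6"]], 0.5 * A["3", "5"])
})

test_that("tabular relationship matrix reproduces the classic small cases", {
  A <- relationship_matrix(trio_ped())
  expect_equal(unname(A),
               matrix(c(1, 0, .5, 0, 1, .5, .5, .5, 1), 3))
  # full-sib pair related 0.5; their offspring has a_ii = 1.25
  A2 <- relationship_matrix(fullsib_ped())
  expect_equal(A2["a", "b"], 0.5)
  expect_equal(A2["x", "x"], 1.25)
  expect_true(isSymmetric(A2))
  ev <- eigen(A2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_error(relationship_matrix(trio_ped(), cap = 2L), "cap")
})

test_that("Meuwissen-Luo equals the tabular diagonal on random pedigrees", {
  for (seed in 1:25) {
    ped <- random_ped(sample(20:120, 1), p_known = stats::runif(1, 0.4, 0.95),
                      seed = seed)
    expect_lt(max(abs(inbreeding_ml(ped) - (diag(relationship_matrix(ped)) - 1))),
              1e-12)
  }
})

test_that("input order never changes F", {
  set.seed(99)
  ped <- random_ped(60, seed = 99)
  raw <- data.frame(id = ped$id, sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam))
  for (k in 1:5) {
    sh <- raw[sample(nrow(raw)), ]
    ped2 <- pedigree(sh$id, sh$sire, sh$dam)
    expect_equal(inbreeding_ml(ped2)[ped$id], inbreeding_ml(ped)[ped$id])
  }
})

test_that("average relatedness matches dense row sums and dilutes correctly", {
  # single founder alone: a_11 = 1, n = 1 -> AR = 0.5
  expect_equal(unname(average_relatedness(pedigree("1", "0", "0"))), 0.5)
  # trio: offspring row sum (0.5 + 0.5 + 1)/6
  expect_equal(average_relatedness(trio_ped())[["3"]], 1 / 3)
  for (seed in 1:10) {
    ped <- random_ped(50, seed = seed)
    A <- relationship_matrix(ped)
    expect_equal(average_relatedness(ped), rowSums(A) / (2 * nrow(ped)),
                 tolerance = 1e-12)
  }
  # adding an unrelated founder lowers every other animal's AR
  ped <- fullsib_ped()
  ar1 <- average_relatedness(ped)
  ped2 <- pedigree(c(ped$id, "lone"),
                   c(ifelse(is.na(ped$sire), "0", ped$sire), "0"),
                   c(ifelse(is.na(ped$dam), "0", ped$dam), "0"))
  ar2 <- average_relatedness(ped2)
  expect_true(all(ar2[ped$id] < ar1[ped$id]))
})

test_that("individual dF and Ne follow the closed form", {
  expect_equal(individual_delta_f(0, 5)$delta_f, 0)        # F = 0
  expect_equal(individual_delta_f(0.25, 2)$delta_f, 0.25)  # exponent 1
  # mean dF = 0.0053 -> Ne = 1/(2 * 0.0053) = 94.3396...
  r <- individual_delta_f(rep(1 - (1 - 0.0053)^4, 3), rep(5, 3))
  expect_equal(r$mean_delta_f, 0.0053, tolerance = 1e-12)
  expect_equal(r$ne, 94.33962, tolerance = 1e-6)
  # animals with EqG <= 1 are excluded; all excluded -> NA sentinel
  r2 <- individual_delta_f(c(0.1, 0), c(0.5, 1))
  expect_true(is.na(r2$ne) && r2$n_used == 0 && r2$n_excluded == 2)
  # include_all mode averages zeros in
  r3 <- individual_delta_f(c(0.25, 0), c(2, 1), include_all = TRUE)
  expect_equal(r3$mean_delta_f, 0.125)
})

test_that("pedigree_inbreeding summary is internally consistent", {
  ped <- fullsib_ped()
  res <- pedigree_inbreeding(ped)
  expect_equal(res$summary$mean_f, 0.05)           # one of five has F = 0.25
  expect_equal(res$summary$pct_inbred, 20)
  expect_equal(res$summary$mean_f_inbred, 0.25)
  # reference run: per-animal values identical to the full run
  ref <- c("x", "a")
  res_ref <- pedigree_inbreeding(ped, ref = ref)
  expect_equal(res_ref$table$f, res$table$f[match(ref, res$table$id)])
  expect_equal(res_ref$summary$n, 2)
})
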