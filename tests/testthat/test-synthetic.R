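test_that("full-sib line reproduces the textbook F series", {
  cfg <- sim_config(mating_scheme = "full_sib_line", n_founders = 2,
                    n_generations = 3, offspring_per_mating = 3, seed = 1)
  sim <- simulate_pedigree(cfg)
  byg <- aggregate(f_true ~ generation, sim$truth, unique)
  expect_equal(byg$f_true, c(0, 0, 0.25, 0.375))
})

test_that("released pedigree round-trips through the loader when complete", {
  cfg <- sim_config(n_founders = 10, n_generations = 3,
                    p_missing_parent = 0, seed = 2)
  sim <- simulate_pedigree(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(sim$ped, f)
  ped2 <- load_pedigree(f, id_col = "id", sire_col = "sire",
                        dam_col = "dam", sex_col = "sex",
                        year_col = "birth_year")
  expect_equal(ped2[, c("id", "sire", "dam", "sire_idx", "dam_idx")],
               sim$ped[, c("id", "sire", "dam", "sire_idx", "dam_idx")],
               ignore_attr = TRUE)
})

test_that("missing-parent erasure happens after truth is recorded", {
  cfg <- sim_config(n_founders = 12, n_generations = 4,
                    p_missing_parent = 0.3, seed = 3)
  sim <- simulate_pedigree(cfg)
  expect_gt(sum(is.na(sim$ped$sire)) + sum(is.na(sim$ped$dam)),
            sum(is.na(sim$ped_complete$sire)) + sum(is.na(sim$ped_complete$dam)))
  # truth F comes from the complete pedigree
  expect_equal(sim$truth$f_true,
               unname(inbreeding_ml(sim$ped_complete)[sim$truth$id]))
})

test_that("sire bottleneck produces Fa < Fe in the final generation", {
  cfg <- sim_config(mating_scheme = "sire_bottleneck", n_founders = 16,
                    n_generations = 3, offspring_per_mating = 2, seed = 4)
  sim <- simulate_pedigree(cfg)
  last <- sim$truth$id[sim$truth$generation == max(sim$truth$generation)]
  go <- gene_origin_summary(sim$ped, ref = last)
  expect_lt(go$fa, go$fe)
})

test_that("infeasible schemes error", {
  expect_error(sim_config(n_founders = 1, seed = 1) |> simulate_pedigree(),
               "infeasible|male")
  expect_error(sim_config(mating_scheme = "full_sib_line", n_founders = 2,
                          offspring_per_mating = 1, seed = 1) |>
                 simulate_pedigree(), "offspring_per_mating")
  expect_error(sim_config(), "seed")
})

test_that("gene dropping realizes the expected autozygosity", {
  # forced selfing: expectation 1/2
  ped <- pedigree(c("f", "x"), c("0", "f"), c("0", "f"))
  cfg <- sim_config(n_chromosomes = 20, snps_per_chromosome = 10,
                    chromosome_length = 1e8, seed = 6)
  gd <- gene_drop(ped, cfg)
  a <- gd$truth$autozygosity[gd$truth$id == "x"]
  # 20 chromosomes of 1 Morgan: generous Monte-Carlo band
  expect_lt(abs(a - 0.5), 0.25)
  expect_equal(sum(gd$founder_origin["x", ]), 1)
  # half-known parents are rejected
  bad <- pedigree(c("s", "x"), c("0", "s"), c("0", "0"))
  expect_error(gene_drop(bad, cfg), "complete")
})

test_that("independent full-sib families average to pedigree F", {
  fam <- family_cohort_ped(60, n_off = 1L)
  cfg <- sim_config(n_chromosomes = 3, snps_per_chromosome = 10,
                    chromosome_length = 1e8, seed = 7)
  gd <- gene_drop(fam$ped, cfg, keep = fam$gen2[1])
  auto <- gd$truth$autozygosity[match(fam$gen2, gd$truth$id)]
  se <- sd(auto) / sqrt(length(auto))
  expect_lt(abs(mean(auto) - 0.25), 3 * se + 1e-9)
  # non-inbred sibs have zero autozygosity by construction
  expect_equal(max(gd$truth$autozygosity[match(fam$gen1, gd$truth$id)]), 0)
})

test_that("founder-only populations show no IBD: FROH ~ 0, FGRM centered", {
  founder_ped <- pedigree(paste0("f", 1:120), rep("0", 120), rep("0", 120))
  cfg <- sim_config(n_chromosomes = 2, snps_per_chromosome = 600,
                    chromosome_length = 6e7, seed = 8)
  gd <- gene_drop(founder_ped, cfg)
  expect_equal(max(gd$truth$autozygosity), 0)
  segs <- detect_roh(gd$panel)
  fr <- froh(segs, gd$panel)
  expect_lt(mean(fr$froh$froh), 0.01)
  g <- grm_yang(gd$panel)
  expect_lt(abs(mean(g$fgrm)), 3 * sd(g$fgrm) / sqrt(120) + 0.02)
})

test_that("the same seed gives byte-identical outputs", {
  cfg <- sim_config(n_founders = 8, n_generations = 2, n_chromosomes = 1,
                    snps_per_chromosome = 50, seed = 99)
  s1 <- simulate_pedigree(cfg); s2 <- simulate_pedigree(cfg)
  expect_identical(s1$ped, s2$ped)
  g1 <- gene_drop(s1$ped_complete, cfg); g2 <- gene_drop(s2$ped_complete, cfg)
  expect_identical(g1$panel$geno, g2$panel$geno)
  expect_identical(g1$truth, g2$truth)
})

test_that("gene-dropped founder-origin fractions agree with expected q", {
  cfg <- sim_config(mating_scheme = "random", n_founders = 10,
                    n_generations = 2, n_chromosomes = 4,
                    snps_per_chromosome = 10, seed = 12)
  sim <- simulate_pedigree(cfg)
  last <- sim$truth$id[sim$truth$generation == 2]
  gd <- gene_drop(sim$ped_complete, cfg, keep = last[1])
  realized <- colMeans(gd$founder_origin[last, , drop = FALSE])
  fc <- founder_contributions(sim$ped_complete, last)
  q <- setNames(fc$q$q, fc$q$id)[names(realized)]
  q[is.na(q)] <- 0
  # loose 3-SE-style band: realized fractions fluctuate around expectation
  expect_lt(max(abs(realized - q)), 0.1)
  expect_gt(cor(realized, q), 0.8)
})
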