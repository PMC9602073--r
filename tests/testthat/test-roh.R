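hom_panel <- function(pos, g = NULL, animals = 1L) {
  m <- length(pos)
  if (is.null(g)) g <- matrix(2L, animals, m)
  rownames(g) <- paste0("a", seq_len(nrow(g)))
  genotype_panel(g, data.frame(chr = "1", snp = paste0("s", seq_len(m)),
                               pos = pos))
}

test_that("sliding-window detection handles the canonical hand cases", {
  # 30 SNP spaced 100 kb, all homozygous -> one 2.9 Mb run
  p1 <- hom_panel(seq(1, by = 1e5, length.out = 30))
  s1 <- detect_roh(p1)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$length, 2900001)
  expect_equal(s1$n_snp, 30L)

  # a 1.5 Mb gap between SNP 15 and 16 splits into two 1.4 Mb runs
  pos2 <- c(seq(1, by = 1e5, length.out = 15),
            seq(1.4e6 + 1.5e6, by = 1e5, length.out = 15))
  s2 <- detect_roh(hom_panel(pos2))
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$length, rep(1400001, 2))

  # 8 homozygous SNP spanning 0.7 Mb: shorter than min_length AND a window
  expect_equal(nrow(detect_roh(hom_panel(seq(1, by = 1e5, length.out = 8)))),
               0L)

  # heterozygotes break runs at the default 0 allowance
  g <- matrix(2L, 1, 45); g[1, 23] <- 1L
  s4 <- detect_roh(hom_panel(seq(1, by = 1e5, length.out = 45), g))
  expect_equal(nrow(s4), 2L)
  expect_true(all(s4$n_snp == 22L))

  # chromosomes with < window_snp SNPs are skipped with a log
  few <- hom_panel(seq(1, by = 1e5, length.out = 10))
  s5 <- detect_roh(few)
  expect_equal(attr(s5, "skipped_chromosomes"), "1")
})

test_that("every reported segment satisfies every parameter constraint", {
  set.seed(101)
  params <- roh_params()
  for (k in 1:10) {
    panel <- random_panel(4, 60, p_het = 0.08, p_miss = 0.05)
    segs <- detect_roh(panel, params)
    if (!nrow(segs)) next
    expect_true(all(segs$length >= params$min_length))
    expect_true(all(segs$n_snp >= params$min_snp_in_run))
    expect_true(all(segs$n_snp / segs$length >= params$min_density))
    for (r in seq_len(nrow(segs))) {
      jx <- panel$map$pos >= segs$start[r] & panel$map$pos <= segs$end[r]
      expect_true(all(diff(panel$map$pos[jx]) <= params$max_gap))
    }
  }
})

test_that("detector equals the brute-force enumerator on small panels", {
  set.seed(202)
  params <- roh_params()
  for (k in 1:60) {
    panel <- random_panel(2, sample(20:50, 1), p_het = runif(1, 0.02, 0.3),
                          p_miss = runif(1, 0, 0.08))
    expect_equal(sorted_segs(detect_roh(panel, params)),
                 sorted_segs(roh_bruteforce(panel, params)))
  }
})

test_that("froh follows the span convention and the worked arithmetic", {
  # fully homozygous animal -> froh = 1
  p <- hom_panel(seq(1, by = 1e5, length.out = 30))
  fr <- froh(detect_roh(p), p)
  expect_equal(fr$froh$froh, 1)
  # runs {1.5, 3, 20} Mb on a 100 Mb autosome
  map <- data.frame(chr = "1", snp = c("a", "b"), pos = c(1, 1e8))
  panel <- genotype_panel(matrix(c(2L, 2L), 1, 2,
                                 dimnames = list("x", NULL)), map)
  segs <- data.frame(animal = "x", chr = "1",
                     start = c(1, 1e7, 5e7),
                     end = c(1, 1e7, 5e7) + c(1.5e6, 3e6, 2e7) - 1,
                     length = c(1.5e6, 3e6, 2e7),
                     n_snp = c(30L, 60L, 400L), stringsAsFactors = FALSE)
  fr2 <- froh(segs, panel)
  expect_equal(fr2$froh$froh, 0.245)
  expect_equal(fr2$froh$froh_4mb, 0.20)
  ct <- roh_class_table(segs)
  expect_equal(ct$n[ct$class %in% c("1-2 Mb", "2-4 Mb", ">16 Mb")],
               c(1L, 1L, 1L))
  # no ROH -> froh = 0
  fr3 <- froh(segs[0, ], panel)
  expect_equal(fr3$froh$froh, 0)
})

test_that("length classes use lower-inclusive half-open bins", {
  seg <- data.frame(animal = "x", chr = "1", start = 1, end = 2e6,
                    length = 2e6, n_snp = 40L)
  ct <- roh_class_table(seg)
  expect_equal(ct$n[ct$class == "2-4 Mb"], 1L)
  expect_equal(ct$n[ct$class == "1-2 Mb"], 0L)
  expect_equal(ct$n[ct$class == "Total"], 1L)
})

test_that("froh is monotone non-increasing in the length threshold", {
  set.seed(303)
  for (k in 1:5) {
    panel <- random_panel(6, 80, p_het = 0.05, p_miss = 0.03)
    fr <- froh(detect_roh(panel), panel)
    cols <- as.matrix(fr$froh[, paste0("froh_", c(1, 2, 4, 8, 16), "mb")])
    expect_true(all(cols[, -1] <= cols[, -ncol(cols)] + 1e-12))
    expect_true(all(fr$froh$froh >= 0 & fr$froh$froh <= 1))
  }
})

test_that("island incidence uses a strict 50% threshold", {
  # 4 animals; 3 share a homozygous block, 1 is heterozygous there
  pos <- seq(1, by = 1e5, length.out = 40)
  g <- matrix(2L, 4, 40)
  g[4, ] <- 1L
  panel <- hom_panel(pos, g)
  segs <- detect_roh(panel)
  isl <- roh_islands(segs, panel, threshold = 50)
  expect_equal(unique(isl$incidence$pct), 75)
  expect_equal(nrow(isl$islands), 1L)
  expect_equal(isl$islands$n_snp, 40L)
  # exactly 50% is NOT an island member
  g2 <- matrix(2L, 4, 40); g2[3:4, ] <- 1L
  segs2 <- detect_roh(hom_panel(pos, g2))
  isl2 <- roh_islands(segs2, hom_panel(pos, g2), threshold = 50)
  expect_equal(unique(isl2$incidence$pct), 50)
  expect_equal(nrow(isl2$islands), 0L)
})

test_that("island annotation joins overlapping intervals", {
  isl <- data.frame(chr = "1", start = 1e6, end = 2e6, n_snp = 10L,
                    max_pct = 80)
  feats <- data.frame(chr = c("1", "1", "2"),
                      start = c(1.5e6, 3e6, 1e6),
                      end = c(2.5e6, 4e6, 2e6),
                      name = c("GENE1", "GENE2", "GENE3"))
  out <- annotate_islands(isl, feats)
  expect_equal(out$features, "GENE1")
})
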