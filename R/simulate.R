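#' Simulation configuration
#'
#' Describes a discrete-generation pedigree and the genome dropped through
#' it. Defaults emulate a mid-20th-century closed nucleus herd at a scale
#' convenient for testing: founder cohort from 1956, ~7-year generation
#' spacing, a handful of 100-Mb autosomes at medium SNP density, uniform
#' recombination at 1 cM/Mb and founder allele frequencies drawn uniformly
#' on [0.05, 0.5].
#'
#' @param n_founders founder cohort size (split evenly male/female).
#' @param n_generations number of offspring generations.
#' @param offspring_per_mating offspring per mating pair.
#' @param mating_scheme one of `"random"`, `"circular"`, `"full_sib_line"`,
#'   `"sire_bottleneck"`.
#' @param p_missing_parent probability that a parent link is erased from the
#'   released pedigree (truth is recorded on the complete pedigree first).
#' @param birth_year_start founder birth year.
#' @param year_spacing years between generations.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length genome layout
#'   (length in bp).
#' @param founder_maf function(n) returning n founder allele frequencies.
#' @param recomb_rate recombination rate in cM/Mb (default 1).
#' @param p_missing_geno per-genotype missingness rate injected into the
#'   emitted panel.
#' @param seed integer seed; mandatory for reproducibility.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 40L, n_generations = 6L,
                       offspring_per_mating = 2L,
                       mating_scheme = c("random", "circular",
                                         "full_sib_line", "sire_bottleneck"),
                       p_missing_parent = 0,
                       birth_year_start = 1956L, year_spacing = 7L,
                       n_chromosomes = 5L, snps_per_chromosome = 1000L,
                       chromosome_length = 1e8,
                       founder_maf = function(n) stats::runif(n, 0.05, 0.5),
                       recomb_rate = 1, p_missing_geno = 0, seed) {
  mating_scheme <- match.arg(mating_scheme)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_founders >= 1, n_generations >= 1, offspring_per_mating >= 1,
            p_missing_parent >= 0, p_missing_parent <= 1,
            n_chromosomes >= 1, snps_per_chromosome >= 1,
            chromosome_length >= 1, recomb_rate >= 0,
            p_missing_geno >= 0, p_missing_geno <= 1)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 offspring_per_mating = as.integer(offspring_per_mating),
                 mating_scheme = mating_scheme,
                 p_missing_parent = p_missing_parent,
                 birth_year_start = as.integer(birth_year_start),
                 year_spacing = as.integer(year_spacing),
                 n_chromosomes = as.integer(n_chromosomes),
                 snps_per_chromosome = as.integer(snps_per_chromosome),
                 chromosome_length = chromosome_length,
                 founder_maf = founder_maf, recomb_rate = recomb_rate,
                 p_missing_geno = p_missing_geno, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a discrete-generation pedigree with known inbreeding
#'
#' Builds the mating structure of `cfg$mating_scheme`, records the true
#' per-animal inbreeding coefficient on the *complete* pedigree, then
#' optionally erases parent links at rate `p_missing_parent` to emulate
#' incomplete herd books. Birth years are assigned by generation.
#'
#' Schemes: `random` mates every dam to a random sire of the previous
#' generation; `circular` mates male i to female i+1 (mod k); each produces
#' `offspring_per_mating` offspring per mating. `full_sib_line` propagates a
#' single repeated full-sib mating (the textbook F series 0, 0.25, 0.375,
#' ...); `sire_bottleneck` mates the founder generation randomly and from
#' the second generation on uses a single sire over all dams, so the
#' bottleneck ancestor stands out against a diverse founder background
#' (effective number of ancestors < effective number of founders).
#'
#' @param cfg a [sim_config()].
#' @return list with `ped` (released pedigree, possibly with erased links),
#'   `ped_complete`, `truth` (data.frame id, generation, f_true) and `cfg`.
#' @export
simulate_pedigree <- function(cfg) {
  set.seed(cfg$seed)
  nf <- cfg$n_founders
  sexes0 <- rep(c("male", "female"), length.out = nf)
  id <- paste0("g0_", seq_len(nf))
  sire <- rep(NA_character_, nf); dam <- rep(NA_character_, nf)
  sex <- sexes0; gen <- rep(0L, nf)
  prev_ids <- id; prev_sex <- sex
  opm <- cfg$offspring_per_mating
  for (g in seq_len(cfg$n_generations)) {
    males <- prev_ids[prev_sex == "male"]
    females <- prev_ids[prev_sex == "female"]
    if (!length(males) || !length(females))
      stop("mating scheme infeasible: generation ", g,
           " has no ", if (!length(males)) "males" else "females")
    matings <- switch(cfg$mating_scheme,
      random = {
        if (length(males) < 1L || length(females) < 1L)
          stop("random mating needs at least one male and one female")
        data.frame(sire = sample(males, length(females), replace = TRUE),
                   dam = females, stringsAsFactors = FALSE)
      },
      circular = {
        k <- min(length(males), length(females))
        data.frame(sire = males[seq_len(k)],
                   dam = females[c(seq_len(k)[-1], 1L)],
                   stringsAsFactors = FALSE)
      },
      full_sib_line = {
        if (opm < 2L)
          stop("full_sib_line needs offspring_per_mating >= 2")
        data.frame(sire = males[1L], dam = females[1L],
                   stringsAsFactors = FALSE)
      },
      sire_bottleneck = {
        ## random founder matings first, then one sire serves all dams:
        ## the bottleneck stands out against a diverse founder background
        if (g == 1L)
          data.frame(sire = sample(males, length(females), replace = TRUE),
                     dam = females, stringsAsFactors = FALSE)
        else
          data.frame(sire = sample(males, 1L), dam = females,
                     stringsAsFactors = FALSE)
      })
    noff <- nrow(matings) * opm
    oid <- paste0("g", g, "_", seq_len(noff))
    osex <- rep(c("male", "female"), length.out = noff)
    id <- c(id, oid)
    sire <- c(sire, rep(matings$sire, each = opm))
    dam <- c(dam, rep(matings$dam, each = opm))
    sex <- c(sex, osex)
    gen <- c(gen, rep(g, noff))
    prev_ids <- oid; prev_sex <- osex
  }
  years <- cfg$birth_year_start + gen * cfg$year_spacing
  ped_complete <- pedigree(id = id,
                           sire = ifelse(is.na(sire), "0", sire),
                           dam = ifelse(is.na(dam), "0", dam),
                           sex = sex, birth_year = years)
  f_true <- inbreeding_ml(ped_complete)
  truth <- data.frame(id = id, generation = gen,
                      f_true = unname(f_true[id]), stringsAsFactors = FALSE)
  ## erase parent links after truth has been recorded
  sire_rel <- sire; dam_rel <- dam
  if (cfg$p_missing_parent > 0) {
    drop_s <- stats::runif(length(sire)) < cfg$p_missing_parent
    drop_d <- stats::runif(length(dam)) < cfg$p_missing_parent
    sire_rel[drop_s] <- NA_character_
    dam_rel[drop_d] <- NA_character_
  }
  ped <- pedigree(id = id, sire = ifelse(is.na(sire_rel), "0", sire_rel),
                  dam = ifelse(is.na(dam_rel), "0", dam_rel),
                  sex = sex, birth_year = years)
  list(ped = ped, ped_complete = ped_complete, truth = truth, cfg = cfg)
}

## ---- segment-based gene dropping -------------------------------------

## a haplotype is list(brk = segment end positions (last = L), lab = founder
## haplotype labels); segment k covers (brk[k-1], brk[k]] with brk[0] = 0.

.hap_slice <- function(h, a, b) {
  brk <- h$brk
  i <- findInterval(a, brk) + 1L          # segment holding (a, ...]
  j <- findInterval(b, brk, left.open = TRUE) + 1L  # segment holding b
  ends <- if (j > i) c(brk[i:(j - 1L)], b) else b
  list(brk = ends, lab = h$lab[i:j])
}

.hap_merge <- function(brk, lab) {
  n <- length(lab)
  if (n <= 1L) return(list(brk = brk, lab = lab))
  keep <- c(lab[-1L] != lab[-n], TRUE)
  list(brk = brk[keep], lab = lab[keep])
}

.meiosis <- function(h1, h2, L, morgans) {
  nx <- stats::rpois(1L, morgans)
  cur <- if (stats::runif(1L) < 0.5) 1L else 2L
  if (nx == 0L) return(if (cur == 1L) h1 else h2)
  x <- sort(stats::runif(nx, 0, L))
  bounds <- c(0, x, L)
  brk <- numeric(0); lab <- integer(0)
  haps <- list(h1, h2)
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    if (b > a) {
      sl <- .hap_slice(haps[[cur]], a, b)
      brk <- c(brk, sl$brk); lab <- c(lab, sl$lab)
    }
    cur <- 3L - cur
  }
  .hap_merge(brk, lab)
}

.shared_length <- function(h1, h2) {
  b <- sort(unique(c(h1$brk, h2$brk)))
  a <- c(0, b[-length(b)])
  l1 <- h1$lab[findInterval(a, h1$brk) + 1L]
  l2 <- h2$lab[findInterval(a, h2$brk) + 1L]
  sum((b - a)[l1 == l2])
}

#' Drop labeled founder genomes through a complete pedigree
#'
#' Every founder receives two uniquely labeled chromosomes; transmission to
#' offspring applies crossovers as a Poisson process along the chromosome
#' (Haldane model, no interference) at `recomb_rate` cM/Mb. The realized
#' autozygosity of an animal is the fraction of its diploid genome where
#' both haplotypes carry the same founder-haplotype label — the
#' identity-by-descent ground truth that pedigree F only predicts in
#' expectation. SNP alleles are painted onto founder haplotypes from
#' per-SNP frequencies drawn from `cfg$founder_maf`, giving a genotype
#' panel whose homozygous stretches arise mechanistically from IBD.
#'
#' @param ped a complete [pedigree()] (founders excepted, both parents of
#'   every animal must be known).
#' @param cfg a [sim_config()] (genome layout, recombination, seed).
#' @param keep optional character vector of animal ids to emit in the panel
#'   (default: all animals).
#' @return list with `panel` (a [genotype_panel()]), `truth` (data.frame
#'   `id`, `autozygosity`), `founder_origin` (animals x founders matrix of
#'   realized genome fractions) and `cfg`.
#' @export
gene_drop <- function(ped, cfg, keep = ped$id) {
  s <- ped$sire_idx; d <- ped$dam_idx
  half <- (s == 0L) != (d == 0L)
  if (any(half))
    stop("gene_drop needs a complete pedigree; animals with exactly one ",
         "known parent: ", paste(ped$id[half][1:min(3, sum(half))],
                                 collapse = ", "))
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  fndr <- s == 0L & d == 0L
  fid <- cumsum(fndr)                      # founder serial number
  L <- cfg$chromosome_length
  morgans <- L * 1e-6 * cfg$recomb_rate / 100
  nchr <- cfg$n_chromosomes
  m <- cfg$snps_per_chromosome
  keep_idx <- match(keep, ped$id)
  if (anyNA(keep_idx)) stop("keep ids not in pedigree")
  nf <- sum(fndr)
  auto_len <- numeric(n)
  origin_len <- matrix(0, n, nf, dimnames = list(ped$id, ped$id[fndr]))
  geno <- matrix(0L, length(keep_idx), nchr * m,
                 dimnames = list(ped$id[keep_idx], NULL))
  map <- NULL
  for (ch in seq_len(nchr)) {
    pos <- sort(sample.int(L - 1L, m)) # distinct, < L
    p <- cfg$founder_maf(m)
    alle <- matrix(stats::rbinom(2L * nf * m, 1L, rep(p, each = 2L * nf)),
                   nrow = 2L * nf)
    haps <- vector("list", n)
    for (i in seq_len(n)) {
      if (fndr[i]) {
        k <- fid[i]
        haps[[i]] <- list(list(brk = L, lab = 2L * k - 1L),
                          list(brk = L, lab = 2L * k))
      } else {
        hp <- .meiosis(haps[[s[i]]][[1L]], haps[[s[i]]][[2L]], L, morgans)
        hm <- .meiosis(haps[[d[i]]][[1L]], haps[[d[i]]][[2L]], L, morgans)
        haps[[i]] <- list(hp, hm)
      }
      h <- haps[[i]]
      auto_len[i] <- auto_len[i] + .shared_length(h[[1L]], h[[2L]])
      for (hh in h) {
        lens <- diff(c(0, hh$brk))
        fo <- (hh$lab + 1L) %/% 2L        # founder serial from hap label
        tl <- tapply(lens, fo, sum)
        origin_len[i, as.integer(names(tl))] <-
          origin_len[i, as.integer(names(tl))] + tl
      }
    }
    for (kk in seq_along(keep_idx)) {
      h <- haps[[keep_idx[kk]]]
      a1 <- alle[cbind(h[[1L]]$lab[findInterval(pos, h[[1L]]$brk,
                                                left.open = TRUE) + 1L],
                       seq_len(m))]
      a2 <- alle[cbind(h[[2L]]$lab[findInterval(pos, h[[2L]]$brk,
                                                left.open = TRUE) + 1L],
                       seq_len(m))]
      geno[kk, ((ch - 1L) * m + 1L):(ch * m)] <- a1 + a2
    }
    map <- rbind(map, data.frame(chr = as.character(ch),
                                 snp = paste0("snp", ch, "_", seq_len(m)),
                                 pos = pos, stringsAsFactors = FALSE))
  }
  if (cfg$p_missing_geno > 0)
    geno[stats::runif(length(geno)) < cfg$p_missing_geno] <- NA_integer_
  colnames(geno) <- map$snp
  panel <- genotype_panel(geno, map)
  list(panel = panel,
       truth = data.frame(id = ped$id,
                          autozygosity = auto_len / (nchr * L),
                          stringsAsFactors = FALSE),
       founder_origin = origin_len / (2 * nchr * L),
       cfg = cfg)
}

#' Monte-Carlo single-locus gene dropping
#'
#' Drops one unlinked locus through the pedigree `n_rep` times and tallies,
#' over a reference set, the fraction of sampled alleles originating from
#' each founder (or phantom parent side). The estimates converge to the
#' expected founder contributions q of [founder_contributions()], providing
#' an independent Monte-Carlo check.
#'
#' @param ped a [pedigree()].
#' @param ref reference ids (default all animals).
#' @param n_rep number of independent drops (default 10000).
#' @param seed RNG seed.
#' @return data.frame `id`, `q_hat`, `se` sorted by decreasing `q_hat`.
#' @export
gene_drop_loci <- function(ped, ref = ped$id, n_rep = 10000L, seed = 1L) {
  set.seed(seed)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  O1 <- matrix(0L, n, n_rep); O2 <- matrix(0L, n, n_rep)
  for (i in seq_len(n)) {
    if (s[i] > 0L) {
      u <- stats::runif(n_rep) < 0.5
      O1[i, ] <- ifelse(u, O1[s[i], ], O2[s[i], ])
    } else O1[i, ] <- if (d[i] == 0L) i else n + i       # founder / phantom sire
    if (d[i] > 0L) {
      u <- stats::runif(n_rep) < 0.5
      O2[i, ] <- ifelse(u, O1[d[i], ], O2[d[i], ])
    } else O2[i, ] <- if (s[i] == 0L) i else 2L * n + i  # founder / phantom dam
  }
  ref_idx <- match(ref, ped$id)
  if (anyNA(ref_idx)) stop("reference id(s) not in pedigree")
  lab <- rbind(O1[ref_idx, , drop = FALSE], O2[ref_idx, , drop = FALSE])
  codes <- sort(unique(as.vector(lab)))
  pid <- .phantom_ids(ped)
  ids <- ifelse(codes <= n, ped$id[pmin(codes, n)],
                ifelse(codes <= 2L * n, pid[1L, pmax(codes - n, 1L)],
                       pid[2L, pmax(codes - 2L * n, 1L)]))
  ## per-replicate contribution fractions give an honest SE (alleles within
  ## a replicate are correlated through shared transmissions)
  q_hat <- se <- numeric(length(codes))
  for (k in seq_along(codes)) {
    per_rep <- colMeans(lab == codes[k])
    q_hat[k] <- mean(per_rep)
    se[k] <- stats::sd(per_rep) / sqrt(n_rep)
  }
  out <- data.frame(id = ids, q_hat = q_hat, se = se,
                    stringsAsFactors = FALSE)
  out[order(-out$q_hat), , drop = FALSE]
}
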