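# Pedigree builders -------------------------------------------------------

trio_ped <- function() {
  pedigree(id = c("1", "2", "3"), sire = c("0", "0", "1"),
           dam = c("0", "0", "2"))
}

# founders s,d; full sibs a,b; x = a x b (F = 0.25)
fullsib_ped <- function() {
  pedigree(c("s", "d", "a", "b", "x"), c("0", "0", "s", "s", "a"),
           c("0", "0", "d", "d", "b"))
}

# bottleneck: founders 1,2 -> son 3; 3 x founder dams 4,5 -> ref {6,7}
bottleneck_ped <- function() {
  pedigree(as.character(1:7), c("0", "0", "1", "0", "0", "3", "3"),
           c("0", "0", "2", "0", "0", "4", "5"))
}

# random valid pedigree: each animal may draw parents among earlier animals
random_ped <- function(n, p_known = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i > 1 && stats::runif(1) < p_known)
      sire[i] <- as.character(sample.int(i - 1L, 1L))
    if (i > 1 && stats::runif(1) < p_known)
      dam[i] <- as.character(sample.int(i - 1L, 1L))
  }
  pedigree(as.character(seq_len(n)), sire, dam)
}

# nfam independent full-sib families: founders A,B; sibs S,D; n_off inbred
# offspring X (F = 0.25 each); returns the pedigree and the cohort id sets
family_cohort_ped <- function(nfam, n_off = 2L) {
  id <- sire <- dam <- character(0)
  for (k in seq_len(nfam)) {
    a <- paste0("A", k); b <- paste0("B", k)
    s <- paste0("S", k); d <- paste0("D", k)
    x <- paste0("X", k, "_", seq_len(n_off))
    id <- c(id, a, b, s, d, x)
    sire <- c(sire, "0", "0", a, a, rep(s, n_off))
    dam <- c(dam, "0", "0", b, b, rep(d, n_off))
  }
  list(ped = pedigree(id, sire, dam),
       gen1 = c(outer(c("S", "D"), seq_len(nfam), paste0)),
       gen2 = unlist(lapply(seq_len(nfam), function(k)
         paste0("X", k, "_", seq_len(n_off)))),
       family_of = function(ids) sub("^[SDX]([0-9]+).*$", "\\1", ids))
}

# Independent oracles ------------------------------------------------------

# ancestral closure by repeated upward traversal over raw id links
closure_oracle <- function(ped, ref) {
  cur <- unique(ref)
  repeat {
    par <- unique(stats::na.omit(c(ped$sire[ped$id %in% cur],
                                   ped$dam[ped$id %in% cur])))
    nxt <- unique(c(cur, par))
    if (length(nxt) == length(cur)) return(sort(cur))
    cur <- nxt
  }
}

# brute-force ROH enumeration: a SNP is in-run iff it lies in at least one
# window of window_snp consecutive SNPs with <= max_het het (here asserted
# with the detector's max_het) and <= max_miss missing; then maximal
# stretches, split at gaps, and the same min_snp/length/density filters,
# all re-implemented with plain loops.
roh_bruteforce <- function(panel, params) {
  map <- panel$map
  out <- list()
  for (ch in unique(map$chr)) {
    jx <- which(map$chr == ch)
    pos <- map$pos[jx]
    m <- length(jx)
    w <- params$window_snp
    if (m < w) next
    for (a in seq_len(nrow(panel$geno))) {
      g <- panel$geno[a, jx]
      inrun <- logical(m)
      for (st in seq_len(m - w + 1L)) {
        win <- g[st:(st + w - 1L)]
        if (sum(win == 1L, na.rm = TRUE) <= params$max_het_in_window &&
            sum(is.na(win)) <= params$max_miss_in_window)
          inrun[st:(st + w - 1L)] <- TRUE
      }
      i <- 1L
      while (i <= m) {
        if (!inrun[i]) { i <- i + 1L; next }
        j <- i
        while (j < m && inrun[j + 1L] && pos[j + 1L] - pos[j] <= params$max_gap)
          j <- j + 1L
        np <- j - i + 1L
        len <- pos[j] - pos[i] + 1
        if (np >= params$min_snp_in_run && len >= params$min_length &&
            np / len >= params$min_density)
          out[[length(out) + 1L]] <- data.frame(
            animal = rownames(panel$geno)[a], chr = ch, start = pos[i],
            end = pos[j], length = len, n_snp = np,
            stringsAsFactors = FALSE)
        i <- j + 1L
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(animal = character(0), chr = character(0), start = numeric(0),
               end = numeric(0), length = numeric(0), n_snp = integer(0))
}

# random small genotype panel for detector-vs-oracle comparisons; spacing
# mixes ~60 kb steps with occasional > 1 Mb gaps to exercise the split rule
random_panel <- function(n_animals, n_snp, p_het = 0.25, p_miss = 0.03) {
  gaps <- sample(c(6e4, 1.2e5, 1.4e6), n_snp, replace = TRUE,
                 prob = c(0.75, 0.2, 0.05))
  pos <- cumsum(gaps)
  g <- matrix(sample(c(0L, 1L, 2L, NA),  n_animals * n_snp, replace = TRUE,
                     prob = c((1 - p_het - p_miss) / 2, p_het,
                              (1 - p_het - p_miss) / 2, p_miss)),
              n_animals, n_snp,
              dimnames = list(paste0("a", seq_len(n_animals)), NULL))
  genotype_panel(g, data.frame(chr = "1", snp = paste0("s", seq_len(n_snp)),
                               pos = pos))
}

sorted_segs <- function(x) {
  x <- as.data.frame(x)[, c("animal", "chr", "start", "end", "n_snp")]
  x <- x[order(x$animal, x$chr, x$start), , drop = FALSE]
  rownames(x) <- NULL
  x
}
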