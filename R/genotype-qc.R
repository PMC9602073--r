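#' Genotype panel container
#'
#' A `genotype_panel` couples an animal-by-SNP dosage matrix, coded as the
#' count of the A1 allele (`0`, `1`, `2`, `NA` = missing), with its SNP map
#' (chromosome, base-pair position, alleles) and a QC log.
#'
#' @param geno integer/numeric matrix, animals in rows (rownames = animal
#'   ids), SNPs in columns (colnames = SNP ids), values in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `snp`, `chr` (character), `pos`
#'   (1-based bp), and optionally `a1`, `a2`.
#' @param qc_log list of QC bookkeeping entries.
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(geno, map, qc_log = list()) {
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(map))
    stop("geno has ", ncol(geno), " SNPs but map has ", nrow(map), " rows")
  bad <- !(geno %in% c(0, 1, 2) | is.na(geno))
  if (any(bad)) stop("genotypes must be coded 0/1/2/NA")
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("animal", seq_len(nrow(geno)))
  map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  if (is.null(colnames(geno))) colnames(geno) <- map$snp
  structure(list(geno = geno, map = map, qc_log = qc_log),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$geno), "animals x", ncol(x$geno), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s)\n")
  if (length(x$qc_log)) cat("QC steps applied:", length(x$qc_log), "\n")
  invisible(x)
}

## ---- PLINK text (PED/MAP) and binary (BED/BIM/FAM) readers/writers ----

#' Read SNP genotypes in PLINK format
#'
#' Reads either text `PED`/`MAP` or binary `BED`/`BIM`/`FAM` (SNP-major,
#' magic bytes `0x6c 0x1b 0x01`) files into a [genotype_panel()]. Dosages
#' count the A1 allele (in BED files, A1 is column 5 of the BIM). In PED
#' files A1 is the first non-missing allele encountered for each SNP;
#' SNPs with more than two alleles are dropped with a log entry.
#'
#' @param prefix path prefix: `prefix.bed`/`.bim`/`.fam` is preferred when
#'   present, else `prefix.ped`/`.map`.
#' @details In PED text files allele identity is not declared, so A1 is
#'   assigned deterministically as the alphabetically first observed allele
#'   of each SNP; [write_plink()] uses alleles `A`/`B`, which makes
#'   text round trips dosage-stable whenever both alleles (or only `A`)
#'   are observed.
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  if (file.exists(paste0(prefix, ".bed"))) .read_bed(prefix)
  else if (file.exists(paste0(prefix, ".ped"))) .read_ped(prefix)
  else stop("no PLINK fileset found at prefix: ", prefix)
}

.read_ped <- function(prefix) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  m <- utils::read.table(mapf, colClasses = "character",
                         stringsAsFactors = FALSE)
  map <- data.frame(chr = m[[1]], snp = m[[2]], pos = as.integer(m[[4]]),
                    stringsAsFactors = FALSE)
  lines <- readLines(pedf, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nsnp <- nrow(map)
  nan <- length(toks)
  want <- 6L + 2L * nsnp
  lens <- lengths(toks)
  if (any(lens != want))
    stop("PED/MAP dimensions inconsistent: expected ", want,
         " fields per line, found ", paste(unique(lens), collapse = "/"))
  ids <- vapply(toks, `[`, character(1), 2L)
  A <- matrix(unlist(lapply(toks, `[`, 7L:want)), nrow = nan, byrow = TRUE)
  a1col <- A[, seq(1L, 2L * nsnp, by = 2L), drop = FALSE]
  a2col <- A[, seq(2L, 2L * nsnp, by = 2L), drop = FALSE]
  geno <- matrix(NA_integer_, nan, nsnp, dimnames = list(ids, map$snp))
  a1 <- a2 <- rep(NA_character_, nsnp)
  multi <- logical(nsnp)
  for (j in seq_len(nsnp)) {
    al <- c(a1col[, j], a2col[, j])
    miss <- al == "0"
    obs <- sort(unique(al[!miss]))       # deterministic: alphabetical A1
    if (length(obs) > 2L) { multi[j] <- TRUE; next }
    a1[j] <- if (length(obs)) obs[1L] else NA_character_
    a2[j] <- if (length(obs) > 1L) obs[2L] else NA_character_
    ok <- !(a1col[, j] == "0" | a2col[, j] == "0")
    geno[ok, j] <- (a1col[ok, j] == a1[j]) + (a2col[ok, j] == a1[j])
  }
  map$a1 <- a1; map$a2 <- a2
  log <- list()
  if (any(multi))
    log$multiallelic_dropped <- list(n = sum(multi), snps = map$snp[multi])
  genotype_panel(geno[, !multi, drop = FALSE], map[!multi, , drop = FALSE],
                 qc_log = log)
}

.read_bed <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"), colClasses = "character",
                           stringsAsFactors = FALSE)
  map <- data.frame(chr = bim[[1]], snp = bim[[2]], pos = as.integer(bim[[4]]),
                    a1 = bim[[5]], a2 = bim[[6]], stringsAsFactors = FALSE)
  fam <- utils::read.table(paste0(prefix, ".fam"), colClasses = "character",
                           stringsAsFactors = FALSE)
  ids <- fam[[2]]
  nan <- length(ids); nsnp <- nrow(map)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3L + ceiling(nan / 4) * nsnp)
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", prefix, ".bed")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major BED files are supported")
  body <- raw[-(1:3)]
  bpp <- ceiling(nan / 4)
  if (length(body) != bpp * nsnp)
    stop("BED size inconsistent with FAM/BIM dimensions")
  ## decode 2-bit genotypes, LSB first: 00 hom A1 (2), 01 missing,
  ## 10 het (1), 11 hom A2 (0)
  ints <- as.integer(body)
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  dim(codes) <- c(4L * bpp, nsnp)
  codes <- codes[seq_len(nan), , drop = FALSE]
  geno <- matrix(NA_integer_, nan, nsnp, dimnames = list(ids, map$snp))
  geno[codes == 0L] <- 2L
  geno[codes == 2L] <- 1L
  geno[codes == 3L] <- 0L
  genotype_panel(geno, map)
}

#' Write a genotype panel in PLINK format
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @param format `"bed"` (binary, SNP-major) or `"ped"` (text).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  map <- panel$map
  if (is.null(map$a1)) { map$a1 <- "A"; map$a2 <- "B" }
  map$a2[is.na(map$a2)] <- "B"
  geno <- panel$geno
  ids <- rownames(geno)
  if (format == "ped") {
    mapout <- data.frame(map$chr, map$snp, 0, map$pos)
    utils::write.table(mapout, paste0(prefix, ".map"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    con <- file(paste0(prefix, ".ped"), "w")
    on.exit(close(con))
    for (i in seq_len(nrow(geno))) {
      g <- geno[i, ]
      al1 <- ifelse(is.na(g), "0", ifelse(g >= 1, map$a1, map$a2))
      al2 <- ifelse(is.na(g), "0", ifelse(g == 2, map$a1, map$a2))
      writeLines(paste(c(ids[i], ids[i], "0", "0", "0", "-9",
                         as.vector(rbind(al1, al2))), collapse = " "), con)
    }
  } else {
    utils::write.table(data.frame(map$chr, map$snp, 0, map$pos, map$a1,
                                  map$a2),
                       paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(ids, ids, 0, 0, 0, -9),
                       paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    nan <- nrow(geno); nsnp <- ncol(geno); bpp <- ceiling(nan / 4)
    codes <- matrix(1L, 4L * bpp, nsnp)          # 01 = missing padding
    gm <- geno
    cd <- matrix(1L, nan, nsnp)
    cd[gm == 2L] <- 0L
    cd[gm == 1L] <- 2L
    cd[gm == 0L] <- 3L
    codes[seq_len(nan), ] <- cd
    b <- codes[seq(1, 4 * bpp, by = 4), , drop = FALSE] +
      4L * codes[seq(2, 4 * bpp, by = 4), , drop = FALSE] +
      16L * codes[seq(3, 4 * bpp, by = 4), , drop = FALSE] +
      64L * codes[seq(4, 4 * bpp, by = 4), , drop = FALSE]
    writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), as.raw(as.vector(b))),
             paste0(prefix, ".bed"))
  }
  invisible(prefix)
}

#' Apply study-style genotype quality control
#'
#' Filters, in order: (1) SNPs not on an autosome (chromosome token outside
#' `1..n_autosomes`) or unmapped (position missing or 0); (2) SNPs with call
#' rate below `snp_cr`; (3) animals with call rate below `animal_cr`. No
#' minor-allele-frequency filter is applied: monomorphic SNPs are retained
#' on purpose, since homozygosity itself is the signal of interest in a
#' single-population study. Counts removed at each step are appended to the
#' panel's `qc_log`. The operation is idempotent.
#'
#' @param panel a [genotype_panel()].
#' @param snp_cr minimum SNP call rate (default 0.90).
#' @param animal_cr minimum animal call rate (default 0.90).
#' @param n_autosomes autosome count (default 29, cattle).
#' @return filtered [genotype_panel()] with updated `qc_log`.
#' @export
apply_qc <- function(panel, snp_cr = 0.90, animal_cr = 0.90,
                     n_autosomes = 29L) {
  geno <- panel$geno; map <- panel$map
  chr_num <- suppressWarnings(as.integer(map$chr))
  auto <- !is.na(chr_num) & chr_num >= 1L & chr_num <= n_autosomes &
    !is.na(map$pos) & map$pos > 0L
  n_nonauto <- sum(!auto)
  geno <- geno[, auto, drop = FALSE]; map <- map[auto, , drop = FALSE]
  cr_snp <- colMeans(!is.na(geno))
  keep_snp <- cr_snp >= snp_cr
  n_lowcr_snp <- sum(!keep_snp)
  geno <- geno[, keep_snp, drop = FALSE]; map <- map[keep_snp, , drop = FALSE]
  if (ncol(geno) == 0L) stop("no SNPs left after QC")
  cr_an <- rowMeans(!is.na(geno))
  keep_an <- cr_an >= animal_cr
  n_lowcr_an <- sum(!keep_an)
  geno <- geno[keep_an, , drop = FALSE]
  if (nrow(geno) == 0L) stop("no animals left after QC")
  ## sort by chromosome then position
  o <- order(as.integer(map$chr), map$pos)
  map <- map[o, , drop = FALSE]; geno <- geno[, o, drop = FALSE]
  rownames(map) <- NULL
  log <- c(panel$qc_log,
           list(qc = list(snp_nonautosomal_or_unmapped = n_nonauto,
                          snp_low_call_rate = n_lowcr_snp,
                          animal_low_call_rate = n_lowcr_an,
                          snp_kept = ncol(geno), animal_kept = nrow(geno),
                          snp_cr = snp_cr, animal_cr = animal_cr)))
  genotype_panel(geno, map, qc_log = log)
}
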