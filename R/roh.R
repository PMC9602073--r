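#' Parameters for sliding-window ROH detection
#'
#' Defaults follow common medium-density cattle practice: 20-SNP sliding
#' windows, a minimum density of 1 SNP per 1000 kb, a maximum gap between
#' consecutive SNPs of 1 Mb and a minimum run length of 1 Mb. The per-window
#' heterozygote/missing allowances, the window-coverage threshold and the
#' minimum SNP count per run are the conventional detector defaults (0 het,
#' 1 missing, 0.05, 15) and are all exposed here.
#'
#' Note on `window_coverage_threshold`: a SNP is declared in-run when the
#' fraction of homozygous windows among the windows containing it is **at
#' least** the threshold. With 20-SNP windows the default 0.05 therefore
#' means "contained in at least one homozygous window", which is also the
#' semantics of the brute-force enumeration used to validate the detector.
#'
#' @param window_snp window size in SNPs (20).
#' @param min_density minimum SNP density of a run, SNPs per bp (default
#'   1/1e6, i.e. 1 SNP per 1000 kb).
#' @param max_gap maximum gap between consecutive SNPs inside a run, bp (1e6).
#' @param min_length minimum run length, bp (1e6).
#' @param max_het_in_window heterozygous calls allowed per window (0).
#' @param max_miss_in_window missing calls allowed per window (1).
#' @param min_snp_in_run minimum SNPs per run (15).
#' @param window_coverage_threshold in-run coverage fraction (0.05).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 20L, min_density = 1 / 1e6,
                       max_gap = 1e6, min_length = 1e6,
                       max_het_in_window = 0L, max_miss_in_window = 1L,
                       min_snp_in_run = 15L,
                       window_coverage_threshold = 0.05) {
  stopifnot(window_snp >= 1, min_density > 0, max_gap > 0, min_length >= 1,
            max_het_in_window >= 0, max_miss_in_window >= 0,
            min_snp_in_run >= 1, window_coverage_threshold > 0)
  structure(list(window_snp = as.integer(window_snp),
                 min_density = min_density, max_gap = max_gap,
                 min_length = min_length,
                 max_het_in_window = as.integer(max_het_in_window),
                 max_miss_in_window = as.integer(max_miss_in_window),
                 min_snp_in_run = as.integer(min_snp_in_run),
                 window_coverage_threshold = window_coverage_threshold),
            class = "roh_params")
}

## in-run flags for one animal on one chromosome (sliding-window rule)
.snp_in_run <- function(g, params) {
  m <- length(g)
  w <- params$window_snp
  if (m < w) return(NULL)
  het <- as.numeric(!is.na(g) & g == 1L)
  mis <- as.numeric(is.na(g))
  nw <- m - w + 1L
  cs_het <- c(0, cumsum(het)); cs_mis <- c(0, cumsum(mis))
  win_het <- cs_het[(w + 1):(m + 1)] - cs_het[1:nw]
  win_mis <- cs_mis[(w + 1):(m + 1)] - cs_mis[1:nw]
  homwin <- win_het <= params$max_het_in_window &
    win_mis <= params$max_miss_in_window
  H <- c(0, cumsum(homwin))
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  nhom <- H[hi + 1L] - H[lo]
  ntot <- hi - lo + 1L
  nhom / ntot >= params$window_coverage_threshold
}

## turn an in-run logical vector + positions into filtered segments
.runs_from_flags <- function(inrun, pos, params) {
  if (is.null(inrun) || !any(inrun)) return(NULL)
  r <- rle(inrun)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    ix <- starts[k]:ends[k]
    ## split at gaps larger than max_gap before filtering
    gaps <- diff(pos[ix])
    cut <- which(gaps > params$max_gap)
    pieces <- split(ix, findInterval(seq_along(ix), cut + 1L) + 1L)
    for (pc in pieces) {
      np <- length(pc)
      if (np < params$min_snp_in_run) next
      st <- pos[pc[1L]]; en <- pos[pc[np]]
      len <- en - st + 1
      if (len < params$min_length) next
      if (np / len < params$min_density) next
      out[[length(out) + 1L]] <- c(start = st, end = en, n_snp = np)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect runs of homozygosity by the sliding-window method
#'
#' For each animal and chromosome, a window of `window_snp` consecutive SNPs
#' slides one SNP at a time; a window is homozygous when it contains at most
#' `max_het_in_window` heterozygotes and `max_miss_in_window` missing calls.
#' Each SNP is flagged in-run when the fraction of homozygous windows among
#' those containing it reaches `window_coverage_threshold` (see
#' [roh_params()]). Maximal stretches of in-run SNPs are split at
#' consecutive-SNP gaps larger than `max_gap` and then filtered on
#' `min_snp_in_run`, `min_length` and `min_density`. Chromosomes with fewer
#' SNPs than one window are skipped (recorded in the attribute
#' `skipped_chromosomes`).
#'
#' @param panel a QC'd [genotype_panel()], map sorted by (chromosome, bp).
#' @param params an [roh_params()] object.
#' @return data.frame of class `roh_set` with columns `animal`, `chr`,
#'   `start`, `end`, `length` (= end - start + 1), `n_snp`.
#' @export
detect_roh <- function(panel, params = roh_params()) {
  map <- panel$map
  geno <- panel$geno
  chrs <- unique(map$chr)
  skipped <- character(0)
  segs <- list()
  for (ch in chrs) {
    jx <- which(map$chr == ch)
    if (is.unsorted(map$pos[jx]))
      stop("map not sorted by position on chromosome ", ch)
    if (length(jx) < params$window_snp) { skipped <- c(skipped, ch); next }
    pos <- map$pos[jx]
    for (a in seq_len(nrow(geno))) {
      flags <- .snp_in_run(geno[a, jx], params)
      runs <- .runs_from_flags(flags, pos, params)
      if (!is.null(runs))
        segs[[length(segs) + 1L]] <- data.frame(
          animal = rownames(geno)[a], chr = ch, start = runs[, "start"],
          end = runs[, "end"],
          length = runs[, "end"] - runs[, "start"] + 1,
          n_snp = as.integer(runs[, "n_snp"]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(animal = character(0), chr = character(0),
               start = numeric(0), end = numeric(0), length = numeric(0),
               n_snp = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped_chromosomes") <- skipped
  attr(out, "params") <- params
  class(out) <- c("roh_set", "data.frame")
  out
}

## autosome length convention: SNP-covered span (first to last SNP, +1)
.chr_lengths <- function(map) {
  vapply(split(map$pos, map$chr),
         function(p) max(p) - min(p) + 1, numeric(1))
}

#' Genomic inbreeding from runs of homozygosity
#'
#' `FROH = L_ROH / L_AUT`, with `L_ROH` the summed length of an animal's
#' runs and `L_AUT` the SNP-covered autosome span (first-to-last SNP per
#' chromosome, summed) — the convention under which a fully homozygous
#' animal attains FROH = 1. Also returns per-chromosome FROH and FROH
#' restricted to runs of at least 1/2/4/8/16 Mb.
#'
#' @param segments an `roh_set` from [detect_roh()].
#' @param panel the [genotype_panel()] the segments came from (defines
#'   L_AUT and the animal set; animals without runs get FROH = 0).
#' @param min_lengths_mb length thresholds in Mb for the FROH>x columns.
#' @return list with `froh`: data.frame (animal, froh, froh_1mb, ...),
#'   `froh_chr`: animal x chromosome matrix, `l_aut`, `chr_lengths`.
#' @export
froh <- function(segments, panel, min_lengths_mb = c(1, 2, 4, 8, 16)) {
  map <- panel$map
  animals <- rownames(panel$geno)
  chrl <- .chr_lengths(map)
  l_aut <- sum(chrl)
  base <- stats::setNames(numeric(length(animals)), animals)
  cols <- lapply(min_lengths_mb, function(th) {
    keep <- segments$length >= th * 1e6
    v <- base
    if (any(keep)) {
      s <- tapply(segments$length[keep], segments$animal[keep], sum)
      v[names(s)] <- s
    }
    v / l_aut
  })
  names(cols) <- paste0("froh_", min_lengths_mb, "mb")
  vall <- base
  if (nrow(segments)) {
    s <- tapply(segments$length, segments$animal, sum)
    vall[names(s)] <- s
  }
  tab <- data.frame(animal = animals, froh = unname(vall / l_aut),
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) tab[[nm]] <- unname(cols[[nm]])
  fchr <- matrix(0, length(animals), length(chrl),
                 dimnames = list(animals, names(chrl)))
  if (nrow(segments)) {
    agg <- stats::aggregate(length ~ animal + chr, data = segments, FUN = sum)
    fchr[cbind(agg$animal, agg$chr)] <- agg$length
  }
  fchr <- sweep(fchr, 2L, chrl, "/")
  list(froh = tab, froh_chr = fchr, l_aut = l_aut, chr_lengths = chrl)
}

#' ROH length-class table
#'
#' Counts and mean lengths (Mb and SNPs) of runs in the half-open,
#' lower-inclusive classes [1,2), [2,4), [4,8), [8,16), [16, Inf) Mb, plus
#' a totals row.
#'
#' @param segments an `roh_set` from [detect_roh()].
#' @param breaks_mb class breakpoints in Mb.
#' @return data.frame with columns `class`, `n`, `mean_mb`, `sd_mb`,
#'   `mean_snp`, `sd_snp`.
#' @export
roh_class_table <- function(segments, breaks_mb = c(1, 2, 4, 8, 16)) {
  br <- c(breaks_mb * 1e6, Inf)
  labs <- c(paste0(breaks_mb[-length(breaks_mb)], "-",
                   breaks_mb[-1], " Mb"),
            paste0(">", breaks_mb[length(breaks_mb)], " Mb"))
  cl <- cut(segments$length, breaks = br, labels = labs, right = FALSE)
  row1 <- function(ix, lab) data.frame(
    class = lab, n = length(ix),
    mean_mb = if (length(ix)) mean(segments$length[ix]) / 1e6 else NA_real_,
    sd_mb = if (length(ix) > 1) stats::sd(segments$length[ix]) / 1e6 else NA_real_,
    mean_snp = if (length(ix)) mean(segments$n_snp[ix]) else NA_real_,
    sd_snp = if (length(ix) > 1) stats::sd(segments$n_snp[ix]) else NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_along(labs), function(k)
    row1(which(as.integer(cl) == k), labs[k])))
  out <- rbind(out, row1(seq_len(nrow(segments)), "Total"))
  rownames(out) <- NULL
  out
}

#' SNP incidence in ROH and island calling
#'
#' For every SNP, the incidence is the percentage of animals whose detected
#' runs cover that SNP. Islands — candidate selection signatures — are
#' maximal stretches of consecutive SNPs (within a chromosome) whose
#' incidence is strictly greater than `threshold` percent.
#'
#' @param segments an `roh_set` from [detect_roh()].
#' @param panel the source [genotype_panel()] (defines the SNP set and the
#'   animal count in the denominator).
#' @param threshold incidence threshold in percent (default 50; strict
#'   comparison, so exactly 50% is not an island member).
#' @return list with `incidence`: data.frame (chr, pos, snp, pct), and
#'   `islands`: data.frame (chr, start, end, n_snp, max_pct).
#' @export
roh_islands <- function(segments, panel, threshold = 50) {
  map <- panel$map
  n_animals <- nrow(panel$geno)
  count <- numeric(nrow(map))
  if (nrow(segments)) {
    for (ch in unique(segments$chr)) {
      jx <- which(map$chr == ch)
      pos <- map$pos[jx]
      sub <- segments[segments$chr == ch, , drop = FALSE]
      for (k in seq_len(nrow(sub))) {
        lo <- findInterval(sub$start[k] - 1, pos) + 1L
        hi <- findInterval(sub$end[k], pos)
        if (hi >= lo) count[jx[lo:hi]] <- count[jx[lo:hi]] + 1
      }
    }
  }
  pct <- 100 * count / n_animals
  inc <- data.frame(chr = map$chr, pos = map$pos, snp = map$snp, pct = pct,
                    stringsAsFactors = FALSE)
  islands <- list()
  for (ch in unique(map$chr)) {
    jx <- which(map$chr == ch)
    flag <- pct[jx] > threshold
    if (!any(flag)) next
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      ix <- jx[starts[k]:ends[k]]
      islands[[length(islands) + 1L]] <- data.frame(
        chr = ch, start = map$pos[ix[1L]], end = map$pos[ix[length(ix)]],
        n_snp = length(ix), max_pct = max(pct[ix]), stringsAsFactors = FALSE)
    }
  }
  islands <- if (length(islands)) do.call(rbind, islands) else
    data.frame(chr = character(0), start = numeric(0), end = numeric(0),
               n_snp = integer(0), max_pct = numeric(0),
               stringsAsFactors = FALSE)
  rownames(islands) <- NULL
  list(incidence = inc, islands = islands)
}

#' Annotate islands with user-supplied intervals
#'
#' Coordinate-overlap join of island intervals against a gene/feature
#' interval table (e.g. read from a BED file): a feature is attached to an
#' island when the two intervals overlap by at least one bp.
#'
#' @param islands island data.frame from [roh_islands()].
#' @param features data.frame with columns `chr`, `start`, `end`, `name`.
#' @return `islands` with an added `features` column (comma-separated names).
#' @export
annotate_islands <- function(islands, features) {
  stopifnot(all(c("chr", "start", "end", "name") %in% names(features)))
  islands$features <- vapply(seq_len(nrow(islands)), function(k) {
    hit <- features$chr == islands$chr[k] &
      features$start <= islands$end[k] & features$end >= islands$start[k]
    paste(features$name[hit], collapse = ",")
  }, character(1))
  islands
}

#' Read a minimal BED interval file
#'
#' Three to four columns: chrom, start (0-based), end (exclusive), name.
#' Coordinates are converted to 1-based inclusive.
#' @param path BED file path.
#' @return data.frame with `chr`, `start`, `end`, `name`.
#' @export
read_bed_intervals <- function(path) {
  b <- utils::read.table(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  data.frame(chr = b[[1]], start = as.numeric(b[[2]]) + 1,
             end = as.numeric(b[[3]]),
             name = if (ncol(b) >= 4) b[[4]] else paste0("iv", seq_len(nrow(b))),
             stringsAsFactors = FALSE)
}
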