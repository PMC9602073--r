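#' Equivalent complete generations
#'
#' `EqG_i = sum over known ancestors j of (1/2)^n_j`, with `n_j` the number
#' of generations separating animal i from ancestor j (each ancestor counted
#' once per distinct path). Equivalently, by recursion over parents:
#' `EqG_i = sum over known parents p of 0.5 * (1 + EqG_p)`. A fully known
#' g-generation pedigree gives exactly g; founders give 0.
#'
#' @param ped a [pedigree()].
#' @return numeric vector named by animal id.
#' @export
equivalent_generations <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  eqg <- numeric(n)
  for (i in seq_len(n)) {
    v <- 0
    if (s[i] > 0L) v <- v + 0.5 * (1 + eqg[s[i]])
    if (d[i] > 0L) v <- v + 0.5 * (1 + eqg[d[i]])
    eqg[i] <- v
  }
  names(eqg) <- ped$id
  eqg
}

#' Maximum and complete generations traced
#'
#' `maxg` is the length of the longest known ancestor path; `comg` is the
#' largest g such that all `2^g` ancestors at depth g are known. Founders
#' have both equal to 0, and `comg <= eqg <= maxg` always holds.
#'
#' @param ped a [pedigree()].
#' @return data.frame with columns `id`, `maxg`, `comg`.
#' @export
generations_traced <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  maxg <- integer(n); comg <- integer(n)
  for (i in seq_len(n)) {
    ms <- if (s[i] > 0L) maxg[s[i]] + 1L else 0L
    md <- if (d[i] > 0L) maxg[d[i]] + 1L else 0L
    maxg[i] <- max(ms, md)
    comg[i] <- if (s[i] > 0L && d[i] > 0L)
      1L + min(comg[s[i]], comg[d[i]]) else 0L
  }
  data.frame(id = ped$id, maxg = maxg, comg = comg, stringsAsFactors = FALSE)
}

## known-ancestor counts per depth: K[i, g] = number of known ancestors of
## animal i at depth g (depth 1 = parents); slots, not distinct animals.
.known_by_depth <- function(ped, depth) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  K <- matrix(0, n, depth)
  for (i in seq_len(n)) {
    k1 <- (s[i] > 0L) + (d[i] > 0L)
    K[i, 1] <- k1
    if (depth > 1) {
      row <- numeric(depth - 1)
      if (s[i] > 0L) row <- row + K[s[i], seq_len(depth - 1)]
      if (d[i] > 0L) row <- row + K[d[i], seq_len(depth - 1)]
      K[i, 2:depth] <- row
    }
  }
  K
}

#' Pedigree completeness index
#'
#' MacCluer-style completeness: for each parental line L (sire, dam) the
#' line completeness to depth d is
#' `C_L(d) = (1/d) * sum_{g=1..d} known(L, g) / 2^(g-1)`, where `known(L, g)`
#' counts known ancestors of that line in ascending generation g (generation
#' 1 is the parent itself). The per-animal index is the harmonic mean
#' `PCI(d) = 2 C_s C_d / (C_s + C_d)`, defined as 0 when either line is
#' fully unknown — so PCI is 0 whenever a parent is missing, regardless of
#' how complete the other side is.
#'
#' @param ped a [pedigree()].
#' @param depth maximum ascending generation D (default 5).
#' @return list with `pci`: animals x depth matrix (rownames = ids), and
#'   `mean_by_depth`: population mean PCI per depth 1..D.
#' @export
completeness_index <- function(ped, depth = 5L) {
  stopifnot(depth >= 1L)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  K <- .known_by_depth(ped, depth)          # used for ancestors-of-parent
  pci <- matrix(0, n, depth,
                dimnames = list(ped$id, paste0("g", seq_len(depth))))
  w <- 0.5^(0:(depth - 1))                  # 1/2^(g-1)
  lineC <- function(p, dd) {
    ## completeness of one parental line to depth dd
    if (p == 0L) return(0)
    kn <- c(1, if (dd > 1) K[p, seq_len(dd - 1)] else NULL)
    sum(kn * w[seq_len(dd)]) / dd
  }
  for (i in seq_len(n)) {
    for (dd in seq_len(depth)) {
      cs <- lineC(s[i], dd)
      cd <- lineC(d[i], dd)
      pci[i, dd] <- if (cs > 0 && cd > 0) 2 * cs * cd / (cs + cd) else 0
    }
  }
  list(pci = pci, mean_by_depth = colMeans(pci))
}

#' Generation intervals by the four selection paths
#'
#' The generation interval is the parent's average age when progeny that
#' were themselves kept for reproduction were born. A (parent, offspring)
#' pair is counted on a path only when the offspring has recorded progeny;
#' the role of the offspring (used as a sire vs. as a dam) determines the
#' path: sire-sire (LSS), sire-dam (LSD), dam-sire (LDS), dam-dam (LDD).
#' Pairs with a missing birth year on either side are skipped and counted
#' in `n_skipped`.
#'
#' @param ped a [pedigree()] with birth years.
#' @param weighted if `TRUE` (default) the overall mean is the count-weighted
#'   mean over the four paths (the "Total" row convention of study tables);
#'   if `FALSE` it is the plain (LSS + LSD + LDS + LDD) / 4.
#' @return list with `paths`: data.frame (path, n, mean, se), `overall`:
#'   overall mean interval in years, `n_total`, `n_skipped`.
#' @export
generation_intervals <- function(ped, weighted = TRUE) {
  n <- nrow(ped)
  used_as_sire <- ped$id %in% ped$sire
  used_as_dam <- ped$id %in% ped$dam
  yr <- ped$birth_year
  paths <- list(LSS = NULL, LSD = NULL, LDS = NULL, LDD = NULL)
  n_skipped <- 0L
  add <- function(pp, parent_i, off_i) {
    if (is.na(yr[parent_i]) || is.na(yr[off_i])) {
      n_skipped <<- n_skipped + 1L
      return(invisible())
    }
    paths[[pp]] <<- c(paths[[pp]], yr[off_i] - yr[parent_i])
  }
  for (o in seq_len(n)) {
    si <- ped$sire_idx[o]; di <- ped$dam_idx[o]
    if (used_as_sire[o]) {
      if (si > 0L) add("LSS", si, o)
      if (di > 0L) add("LDS", di, o)
    }
    if (used_as_dam[o]) {
      if (si > 0L) add("LSD", si, o)
      if (di > 0L) add("LDD", di, o)
    }
  }
  tab <- data.frame(
    path = names(paths),
    n = vapply(paths, length, integer(1)),
    mean = vapply(paths, function(x) if (length(x)) mean(x) else NA_real_,
                  numeric(1)),
    se = vapply(paths, function(x) if (length(x) > 1)
      stats::sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  overall <- overall_generation_interval(tab$n, tab$mean, weighted = weighted)
  list(paths = tab, overall = overall, n_total = sum(tab$n),
       n_skipped = n_skipped)
}

#' Overall generation interval from per-path counts and means
#'
#' Combines the four selection-path summaries into one overall interval:
#' count-weighted mean `sum(n_p mean_p) / sum(n_p)` (the "Total" row of
#' published interval tables) or the unweighted four-path mean.
#'
#' @param n integer vector of per-path pair counts.
#' @param mean numeric vector of per-path mean intervals (years).
#' @param weighted use the count-weighted mean? Default `TRUE`.
#' @return overall mean interval in years (NA if no pairs).
#' @export
overall_generation_interval <- function(n, mean, weighted = TRUE) {
  ok <- !is.na(mean) & n > 0
  if (!any(ok)) return(NA_real_)
  if (weighted) sum(n[ok] * mean[ok]) / sum(n[ok]) else mean(mean[ok])
}

#' Mean inbreeding and relatedness by generation class
#'
#' Groups animals by complete (`comg`) or maximum (`maxg`) generations
#' traced and returns mean F and AR per class — the data behind the usual
#' "evolution of F and AR across generations" figure.
#'
#' @param ped a [pedigree()].
#' @param by `"comg"` or `"maxg"`.
#' @return data.frame with columns `generation`, `n`, `mean_f`, `mean_ar`.
#' @export
f_by_generation <- function(ped, by = c("comg", "maxg")) {
  by <- match.arg(by)
  f <- inbreeding_ml(ped)
  ar <- average_relatedness(ped, f)
  g <- generations_traced(ped)[[by]]
  agg <- lapply(split(seq_len(nrow(ped)), g), function(ix)
    c(n = length(ix), mean_f = mean(f[ix]), mean_ar = mean(ar[ix])))
  out <- data.frame(generation = as.integer(names(agg)),
                    do.call(rbind, agg))
  rownames(out) <- NULL
  out
}
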