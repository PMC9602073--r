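#' Pedigree inbreeding coefficients (Meuwissen-Luo algorithm)
#'
#' Computes per-animal inbreeding coefficients F — the probability that the
#' two alleles at a locus are identical by descent — without materializing
#' the numerator relationship matrix A. The algorithm traces, for each
#' animal, the ancestor contributions of the L matrix of the `A = L D L'`
#' decomposition and accumulates `a_ii = sum_j L_ij^2 D_j`, so memory is
#' linear in pedigree size. Results are identical (to machine precision) to
#' `diag(A) - 1` of the tabular method, see [relationship_matrix()].
#'
#' @param ped a [pedigree()].
#' @return numeric vector of F in `[0, 1]`, named by animal id. Founders and
#'   animals with an unknown parent have F = 0.
#' @examples
#' ped <- pedigree(c("s","d","a","b","x"), c("0","0","s","s","a"),
#'                 c("0","0","d","d","b"))
#' inbreeding_ml(ped)["x"]  # full-sib mating: 0.25
#' @export
inbreeding_ml <- function(ped) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  f <- numeric(n)
  dv <- numeric(n)            # within-family (Mendelian) variance D_j
  L <- numeric(n)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fpar <- function(k) if (k == 0L) -1 else f[k]
  for (i in seq_len(n)) {
    dv[i] <- 0.5 - 0.25 * (fpar(s[i]) + fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) next  # F = 0 when a parent is unknown
    key <- paste0(s[i], "_", d[i])
    hit <- cache[[key]]
    if (!is.null(hit)) { f[i] <- hit; next }
    L[i] <- 1
    a <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      a <- a + lj * lj * dv[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      L[j] <- 0
    }
    f[i] <- a - 1
    cache[[key]] <- f[i]
  }
  names(f) <- ped$id
  f
}

#' Numerator relationship matrix by the tabular method (test oracle)
#'
#' Builds the dense additive relationship matrix A with the recurrences
#' `a_ii = 1 + 0.5 a_{sd}` and `a_ij = 0.5 (a_{j,s(i)} + a_{j,d(i)})`.
#' Quadratic memory; intended as an independent oracle for small pedigrees
#' and for exact average-relatedness checks.
#'
#' @param ped a [pedigree()].
#' @param cap refuse pedigrees larger than this (default 5000); use the
#'   indirect algorithms ([inbreeding_ml()], [average_relatedness()]) above it.
#' @return symmetric `n x n` matrix with animal ids as dimnames.
#' @export
relationship_matrix <- function(ped, cap = 5000L) {
  n <- nrow(ped)
  if (n > cap)
    stop("pedigree has ", n, " animals (> cap = ", cap,
         "); use inbreeding_ml()/average_relatedness() instead")
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    row <- numeric(n)
    if (s[i] > 0L) row <- row + 0.5 * A[, s[i]]
    if (d[i] > 0L) row <- row + 0.5 * A[, d[i]]
    A[i, ] <- row
    A[, i] <- row
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

#' Average relatedness coefficients
#'
#' AR_i is the probability that an allele randomly sampled from the whole
#' pedigree population traces back to animal i: the mean of row i of the
#' numerator relationship matrix divided by 2, i.e.
#' `AR_i = (sum_j a_ij) / (2 n)`. Computed indirectly (Colleau-style gene
#' flow through the `A = T D T'` decomposition) in linear memory; equal to
#' the dense row sums of [relationship_matrix()] to machine precision.
#'
#' @param ped a [pedigree()].
#' @param f optional precomputed [inbreeding_ml()] result (recomputed if
#'   missing).
#' @return numeric vector of AR in `[0, 1]`, named by animal id.
#' @export
average_relatedness <- function(ped, f = NULL) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  if (is.null(f)) f <- inbreeding_ml(ped)
  fpar <- function(k) if (k == 0L) -1 else f[[k]]
  dv <- vapply(seq_len(n), function(i) 0.5 - 0.25 * (fpar(s[i]) + fpar(d[i])),
               numeric(1))
  ## A %*% 1 = T D T' 1 : back-propagate v = T' 1, scale, then drop down
  v <- rep(1, n)
  for (i in n:1) {
    if (s[i] > 0L) v[s[i]] <- v[s[i]] + 0.5 * v[i]
    if (d[i] > 0L) v[d[i]] <- v[d[i]] + 0.5 * v[i]
  }
  u <- dv * v
  rs <- numeric(n)
  for (i in seq_len(n)) {
    rs[i] <- u[i] +
      (if (s[i] > 0L) 0.5 * rs[s[i]] else 0) +
      (if (d[i] > 0L) 0.5 * rs[d[i]] else 0)
  }
  ar <- rs / (2 * n)
  names(ar) <- ped$id
  ar
}

#' Individual rate of inbreeding and realized effective population size
#'
#' The individual increase in inbreeding scales F by pedigree depth:
#' `dF_i = 1 - (1 - F_i)^(1 / (EqG_i - 1))`, defined for animals with
#' equivalent complete generations EqG > 1. The realized effective
#' population size is `Ne = 1 / (2 mean(dF))`.
#'
#' @param f per-animal inbreeding coefficients ([inbreeding_ml()]).
#' @param eqg per-animal equivalent complete generations
#'   ([equivalent_generations()]), same order as `f`.
#' @param include_all if `TRUE`, average dF over all animals (excluded
#'   animals contribute dF = 0); default `FALSE` averages only over animals
#'   with EqG > 1.
#' @return list with `delta_f` (per-animal, NA where EqG <= 1), `mean_delta_f`,
#'   `ne` (NA if no animal qualifies), `n_used`, `n_excluded`.
#' @export
individual_delta_f <- function(f, eqg, include_all = FALSE) {
  stopifnot(length(f) == length(eqg))
  ok <- eqg > 1
  df <- rep(NA_real_, length(f))
  df[ok] <- 1 - (1 - f[ok])^(1 / (eqg[ok] - 1))
  m <- if (include_all) {
    if (length(f)) mean(ifelse(is.na(df), 0, df)) else NA_real_
  } else if (any(ok)) mean(df[ok]) else NA_real_
  ne <- if (!is.na(m) && m > 0) 1 / (2 * m) else NA_real_
  list(delta_f = df, mean_delta_f = m, ne = ne,
       n_used = sum(ok), n_excluded = sum(!ok))
}

#' Pedigree inbreeding summary table
#'
#' Convenience wrapper combining [inbreeding_ml()], [average_relatedness()],
#' [equivalent_generations()], [generations_traced()] and
#' [individual_delta_f()] into a per-animal table plus the scalar summary
#' a diversity study reports: mean F, percentage of inbred animals
#' (F > 1e-12), mean F of the inbred, mean AR, mean EqG/MaxG, mean dF and Ne.
#'
#' @param ped a [pedigree()].
#' @param ref optional character vector of reference-population ids; the
#'   per-animal table is then restricted to (and the summary computed over)
#'   those animals, while AR keeps its whole-pedigree definition.
#' @return list with `table` (data.frame) and `summary` (named list).
#' @export
pedigree_inbreeding <- function(ped, ref = NULL) {
  f <- inbreeding_ml(ped)
  ar <- average_relatedness(ped, f)
  eqg <- equivalent_generations(ped)
  gt <- generations_traced(ped)
  dfres <- individual_delta_f(f, eqg)
  tab <- data.frame(id = ped$id, f = unname(f), ar = unname(ar),
                    eqg = unname(eqg), maxg = gt$maxg, comg = gt$comg,
                    delta_f = unname(dfres$delta_f),
                    stringsAsFactors = FALSE)
  if (!is.null(ref)) {
    bad <- setdiff(ref, ped$id)
    if (length(bad))
      stop("reference id(s) not in pedigree: ", paste(bad, collapse = ", "))
    tab <- tab[match(ref, tab$id), , drop = FALSE]
    rownames(tab) <- NULL
    dfres <- individual_delta_f(tab$f, tab$eqg)
  }
  inbred <- tab$f > 1e-12
  list(table = tab,
       summary = list(
         n = nrow(tab),
         mean_f = mean(tab$f),
         pct_inbred = 100 * mean(inbred),
         mean_f_inbred = if (any(inbred)) mean(tab$f[inbred]) else NA_real_,
         mean_ar = mean(tab$ar),
         mean_eqg = mean(tab$eqg),
         mean_maxg = mean(tab$maxg),
         mean_delta_f = dfres$mean_delta_f,
         ne = dfres$ne,
         n_delta_f_used = dfres$n_used))
}
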