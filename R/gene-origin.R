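## Probability-of-gene-origin machinery.
##
## Gene flow is traced upward from the reference population: each reference
## animal starts with weight 1/|ref|, a non-blocked animal passes half of the
## weight reaching it to each parent, and weight is absorbed at founders, at
## phantom founders (an unknown parent side of a non-founder) and at blocked
## ("already selected") ancestors. Absorbed weight at a node is exactly the
## expected fraction of the reference genome originating there and not
## already explained by a blocked ancestor.

## Returns list(arrive, absorbed_founder, phantom) where
##   arrive[i]  = weight reaching node i from reference descendants
##                (excluding its own start weight),
##   absorbed[i]= weight absorbed at i (founder self weight included),
##   phantom    = 2 x n matrix of weight absorbed at the phantom sire/dam
##                side of animal i.
.gene_flow <- function(ped, ref_idx, blocked = integer(0)) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  isblk <- logical(n); isblk[blocked] <- TRUE
  start <- numeric(n)
  w0 <- 1 / length(ref_idx)
  for (i in ref_idx) start[i] <- start[i] + w0
  arrive <- numeric(n)
  absorbed <- numeric(n)
  phantom <- matrix(0, 2L, n)
  for (i in n:1) {
    tot <- start[i] + arrive[i]
    if (tot == 0) next
    fndr <- s[i] == 0L && d[i] == 0L
    if (fndr) {                 # founders absorb everything reaching them
      absorbed[i] <- absorbed[i] + tot
      next
    }
    if (isblk[i]) {
      ## a selected ancestor absorbs the flow arriving from reference
      ## descendants, but its own reference start weight (if any) still
      ## needs explaining by its ancestors and keeps flowing upward
      absorbed[i] <- absorbed[i] + arrive[i]
      if (start[i] == 0) next
      tot <- start[i]
    }
    half <- tot / 2
    if (s[i] > 0L) arrive[s[i]] <- arrive[s[i]] + half
    else phantom[1L, i] <- phantom[1L, i] + half
    if (d[i] > 0L) arrive[d[i]] <- arrive[d[i]] + half
    else phantom[2L, i] <- phantom[2L, i] + half
  }
  list(arrive = arrive, absorbed = absorbed, phantom = phantom)
}

.phantom_ids <- function(ped) {
  rbind(paste0("phantom_sire:", ped$id), paste0("phantom_dam:", ped$id))
}

## fraction of each animal's own genome originating from the blocked
## (already selected) ancestors — real nodes or selected phantom parent
## sides — in the pedigree where blocked ancestors' parents are severed;
## downward recursion in topological order.
.explained_fraction <- function(ped, blocked, frozen_phantom = list()) {
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  frac <- numeric(n)
  isblk <- logical(n); isblk[blocked] <- TRUE
  ph <- matrix(FALSE, 2L, n)
  for (fz in frozen_phantom) ph[fz[1L], fz[2L]] <- TRUE
  for (i in seq_len(n)) {
    if (isblk[i]) { frac[i] <- 1; next }
    v <- 0
    if (s[i] > 0L) v <- v + 0.5 * frac[s[i]] else if (ph[1L, i]) v <- v + 0.5
    if (d[i] > 0L) v <- v + 0.5 * frac[d[i]] else if (ph[2L, i]) v <- v + 0.5
    frac[i] <- v
  }
  frac
}

#' Founder contributions and effective number of founders
#'
#' The expected proportional genetic contribution q of every founder to a
#' reference population is obtained by tracing gene flow upward from the
#' reference animals (half of an animal's weight to each parent). Founders
#' are animals with both parents unknown; an animal with exactly one unknown
#' parent contributes a distinct *phantom founder* for that side, which
#' keeps `sum(q) = 1`. The effective number of founders is Lacy's
#' `Fe = 1 / sum(q^2)`: the number of equally contributing founders that
#' would produce the observed diversity.
#'
#' @param ped a [pedigree()].
#' @param ref character vector of reference ids; default all animals.
#' @return list with `q`: data.frame (id, q, phantom flag) of positive
#'   contributions sorted decreasing, and `fe`.
#' @export
founder_contributions <- function(ped, ref = ped$id) {
  ref_idx <- match(ref, ped$id)
  if (anyNA(ref_idx))
    stop("reference id(s) not in pedigree: ",
         paste(ref[is.na(ref_idx)], collapse = ", "))
  if (!length(ref_idx)) stop("reference population is empty")
  gf <- .gene_flow(ped, ref_idx)
  pid <- .phantom_ids(ped)
  ids <- c(ped$id, pid[1L, ], pid[2L, ])
  q <- c(gf$absorbed, gf$phantom[1L, ], gf$phantom[2L, ])
  ph <- c(rep(FALSE, nrow(ped)), rep(TRUE, 2L * nrow(ped)))
  keep <- q > 0
  o <- order(-q[keep])
  tab <- data.frame(id = ids[keep][o], q = q[keep][o],
                    phantom = ph[keep][o], stringsAsFactors = FALSE)
  list(q = tab, fe = 1 / sum(tab$q^2))
}

#' Marginal ancestor contributions and effective number of ancestors
#'
#' Boichard's iterative procedure: at each round every candidate ancestor's
#' expected contribution to the reference population is computed
#' *conditional on the ancestors already selected* (gene flow stops at
#' selected ancestors, whose contribution is frozen at its selection-time
#' value and whose parent links are effectively severed); the candidate with
#' the largest contribution is selected and its marginal contribution p
#' recorded. The effective number of ancestors is `Fa = 1 / sum(p^2)` over
#' all extracted ancestors; bottlenecks make Fa smaller than Fe. `n_half`
#' is the minimum number of selected ancestors whose cumulative marginal
#' contribution reaches 50%.
#'
#' Candidates are real ancestors of the reference animals (including
#' founders that are themselves reference members) and phantom founders for
#' unknown parent sides, so the residual unexplained fraction converges to
#' zero. Ties on the maximum are broken by the smallest internal
#' (topological) index.
#'
#' @param ped a [pedigree()].
#' @param ref character vector of reference ids; default all animals.
#' @param max_ancestors stop after this many selections (default: no limit).
#' @param tol stop when the residual unexplained fraction drops below this
#'   (default 1e-10).
#' @return list with `p`: data.frame (id, p, cumulative, phantom) in
#'   selection order, `fa`, `n_half`, `residual`.
#' @export
ancestor_contributions <- function(ped, ref = ped$id, max_ancestors = Inf,
                                   tol = 1e-10) {
  ref_idx <- match(ref, ped$id)
  if (anyNA(ref_idx))
    stop("reference id(s) not in pedigree: ",
         paste(ref[is.na(ref_idx)], collapse = ", "))
  if (!length(ref_idx)) stop("reference population is empty")
  n <- nrow(ped)
  pid <- .phantom_ids(ped)
  blocked <- integer(0)
  sel_id <- character(0); sel_p <- numeric(0); sel_ph <- logical(0)
  ## frozen phantom contributions: once a phantom side is "selected" its
  ## value is fixed; represented by remembering (animal, side).
  sel_phantom <- matrix(numeric(0), nrow = 2)  # rows: side, animal index
  frozen_phantom <- list()
  explained <- 0
  repeat {
    if (length(sel_p) >= max_ancestors) break
    gf <- .gene_flow(ped, ref_idx, blocked)
    ## candidate values: weight reaching the node without passing a selected
    ## ancestor, discounted by the fraction of the node's own genome already
    ## explained by selected ancestors (avoids double counting when a
    ## descendant of a selected ancestor is extracted later)
    fndr <- ped$sire_idx == 0L & ped$dam_idx == 0L
    cand <- gf$arrive
    cand[fndr] <- gf$absorbed[fndr]          # includes own ref start weight
    cand <- cand * (1 - .explained_fraction(ped, blocked, frozen_phantom))
    cand[blocked] <- -Inf                    # already selected
    ph <- gf$phantom                         # 2 x n
    for (fz in frozen_phantom) ph[fz[1L], fz[2L]] <- -Inf
    best_real <- if (n) which.max(cand) else integer(0)
    bv_real <- if (length(best_real)) cand[best_real] else -Inf
    bv_ph <- suppressWarnings(max(ph))
    residual <- 1 - explained
    if (max(bv_real, bv_ph, -Inf) <= 0 || residual < tol) break
    if (bv_real >= bv_ph) {                  # real ancestors win ties
      sel_id <- c(sel_id, ped$id[best_real])
      sel_p <- c(sel_p, bv_real)
      sel_ph <- c(sel_ph, FALSE)
      blocked <- c(blocked, best_real)
      explained <- explained + bv_real
    } else {
      ## column-major scan: earliest animal wins ties, sire side before dam
      k <- which(ph == bv_ph, arr.ind = TRUE)[1L, ]
      sel_id <- c(sel_id, pid[k[1L], k[2L]])
      sel_p <- c(sel_p, bv_ph)
      sel_ph <- c(sel_ph, TRUE)
      frozen_phantom <- c(frozen_phantom, list(k))
      explained <- explained + bv_ph
    }
  }
  cum <- cumsum(sel_p)
  n_half <- if (any(cum >= 0.5)) which(cum >= 0.5)[1L] else NA_integer_
  list(p = data.frame(id = sel_id, p = sel_p, cumulative = cum,
                      phantom = sel_ph, stringsAsFactors = FALSE),
       fa = if (length(sel_p)) 1 / sum(sel_p^2) else NA_real_,
       n_half = n_half,
       residual = 1 - sum(sel_p))
}

#' Gene-origin summary
#'
#' Runs [founder_contributions()] and [ancestor_contributions()] and
#' returns the headline scalars: Fe, Fa, Fa/Fe and the number of ancestors
#' explaining 50% of the diversity.
#'
#' @inheritParams ancestor_contributions
#' @return named list `fe`, `fa`, `fa_fe_ratio`, `n_half`, `n_founders`.
#' @export
gene_origin_summary <- function(ped, ref = ped$id, max_ancestors = Inf) {
  fc <- founder_contributions(ped, ref)
  ac <- ancestor_contributions(ped, ref, max_ancestors = max_ancestors)
  list(fe = fc$fe, fa = ac$fa, fa_fe_ratio = ac$fa / fc$fe,
       n_half = ac$n_half, n_founders = nrow(fc$q))
}
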