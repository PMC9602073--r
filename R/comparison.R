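#' Assemble the estimator table for correlation analysis
#'
#' Joins pedigree inbreeding (FPED), GRM inbreeding (FGRM) and the FROH
#' columns by animal id. Animals missing any estimator are dropped
#' (listwise deletion); the number kept is reported by
#' [inbreeding_correlations()].
#'
#' @param fped named numeric vector (names = animal ids), or NULL.
#' @param fgrm named numeric vector, or NULL.
#' @param froh_table the `froh` data.frame from [froh()], or NULL.
#' @return data.frame, one row per animal with all estimators present.
#' @export
estimator_table <- function(fped = NULL, fgrm = NULL, froh_table = NULL) {
  parts <- list()
  if (!is.null(fped))
    parts$fped <- data.frame(animal = names(fped), fped = unname(fped),
                             stringsAsFactors = FALSE)
  if (!is.null(fgrm))
    parts$fgrm <- data.frame(animal = names(fgrm), fgrm = unname(fgrm),
                             stringsAsFactors = FALSE)
  if (!is.null(froh_table)) parts$froh <- froh_table
  if (!length(parts)) stop("no estimators supplied")
  out <- Reduce(function(a, b) merge(a, b, by = "animal"), parts)
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Pairwise Pearson correlations among inbreeding estimators
#'
#' Pearson r for every estimator pair, with two-sided p-values from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom and the
#' usual significance codes (`ns`, `*`, `**`, `***` at 0.05 / 0.01 / 0.001).
#' No multiple-testing correction is applied. Zero-variance columns yield
#' NA correlations with a warning.
#'
#' @param m data.frame or matrix of per-animal estimator columns (an
#'   `animal` id column, if present, is dropped).
#' @return list with `r`, `p`, `stars` matrices and `n`.
#' @export
inbreeding_correlations <- function(m) {
  if (is.data.frame(m) && "animal" %in% names(m))
    m <- m[, setdiff(names(m), "animal"), drop = FALSE]
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least two estimator columns")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) stop("need at least 3 complete observations")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance column(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(m))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA
  stars <- matrix(cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                      labels = c("***", "**", "*", "ns")),
                  ncol(m), dimnames = dimnames(r))
  diag(stars) <- ""
  list(r = r, p = p, stars = stars, n = n)
}

#' Write a publication-style correlation table
#'
#' Correlations above the diagonal, significance codes below.
#' @param cc result of [inbreeding_correlations()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlation_table <- function(cc, path) {
  k <- ncol(cc$r)
  out <- matrix("", k, k, dimnames = dimnames(cc$r))
  out[upper.tri(out)] <- sprintf("%.2f", cc$r[upper.tri(cc$r)])
  out[lower.tri(out)] <- as.character(cc$stars[lower.tri(cc$stars)])
  utils::write.csv(as.data.frame(out), path)
  invisible(path)
}
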