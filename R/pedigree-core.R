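#' Construct a validated, topologically ordered pedigree
#'
#' Builds a `pedigree` object from parallel vectors of animal, sire and dam
#' identifiers. Identifiers are opaque strings; unknown parents are coded by
#' any value in `unknown`. Parents that appear only in the sire/dam columns
#' are materialized as founder records (missing sex and birth year), matching
#' how herd-book extracts behave. Records are re-ordered so that every parent
#' precedes its offspring; all downstream recursions rely on that order.
#'
#' @param id character vector of animal identifiers (unique, nonempty).
#' @param sire,dam character vectors of parent identifiers (same length as
#'   `id`), with unknown parents coded as in `unknown`.
#' @param sex optional vector with values `"male"`, `"female"` or
#'   `"unknown"` (`1`/`2`/`M`/`F` tokens are normalized).
#' @param birth_year optional integer vector of birth years (NA = missing).
#' @param unknown character vector of codes denoting an unknown parent.
#'   Default `c("0", "", "NA")`.
#' @return A `pedigree`: a data.frame with columns `id`, `sire`, `dam`
#'   (`NA` = unknown), `sex`, `birth_year`, and internal integer columns
#'   `sire_idx`/`dam_idx` (row index of the parent, `0` = unknown), sorted
#'   topologically.
#' @examples
#' ped <- pedigree(id = c("1", "2", "3"), sire = c("0", "0", "1"),
#'                 dam = c("0", "0", "2"))
#' founders(ped)
#' @export
pedigree <- function(id, sire, dam, sex = NULL, birth_year = NULL,
                     unknown = c("0", "", "NA")) {
  id   <- trimws(as.character(id))
  sire <- trimws(as.character(sire))
  dam  <- trimws(as.character(dam))
  n0 <- length(id)
  if (length(sire) != n0 || length(dam) != n0)
    stop("id, sire and dam must have the same length")
  if (any(id %in% c(unknown, NA)) || any(!nzchar(id)))
    stop("animal ids must be nonempty and distinct from the unknown-parent code")
  if (anyDuplicated(id))
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sire[sire %in% unknown | is.na(sire)] <- NA_character_
  dam[dam %in% unknown | is.na(dam)] <- NA_character_
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("animal(s) recorded as their own parent: ",
         paste(id[self], collapse = ", "))

  sex <- if (is.null(sex)) rep("unknown", n0) else .normalize_sex(sex)
  birth_year <- if (is.null(birth_year)) rep(NA_integer_, n0)
                else suppressWarnings(as.integer(birth_year))

  ## materialize parents that have no record of their own as founders
  ghosts <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
  if (length(ghosts)) {
    id <- c(id, ghosts)
    sire <- c(sire, rep(NA_character_, length(ghosts)))
    dam <- c(dam, rep(NA_character_, length(ghosts)))
    sex <- c(sex, rep("unknown", length(ghosts)))
    birth_year <- c(birth_year, rep(NA_integer_, length(ghosts)))
  }
  n <- length(id)
  si <- match(sire, id); si[is.na(si)] <- 0L
  di <- match(dam, id);  di[is.na(di)] <- 0L

  ord <- .topo_order(si, di, id)
  rnk <- integer(n); rnk[ord] <- seq_len(n)
  si2 <- si[ord]; si2[si2 > 0L] <- rnk[si2[si2 > 0L]]
  di2 <- di[ord]; di2[di2 > 0L] <- rnk[di2[di2 > 0L]]
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord],
                    sex = sex[ord], birth_year = birth_year[ord],
                    sire_idx = as.integer(si2), dam_idx = as.integer(di2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1")] <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  out
}

## Kahn topological sort (parents before offspring); names a cycle member on
## failure. Operates on 0-coded parent index vectors in input order.
.topo_order <- function(si, di, id) {
  n <- length(si)
  nchild <- integer(n)
  deps <- cbind(si, di)
  indeg <- (si != 0L) + (di != 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in deps[i, ]) if (p != 0L) children[[p]] <- c(children[[p]], i)
  }
  ord <- integer(n)
  k <- 0L
  queue <- which(indeg == 0L)
  ord[seq_along(queue)] <- queue
  k <- length(queue)
  head <- 1L
  while (head <= k) {
    v <- ord[head]; head <- head + 1L
    for (c in children[[v]]) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) { k <- k + 1L; ord[k] <- c }
    }
  }
  if (k < n) {
    stuck <- setdiff(seq_len(n), ord[seq_len(k)])
    stop("pedigree contains a cycle (animal is its own ancestor); ",
         "involved animal: ", id[stuck[1L]])
  }
  ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x), "animals,", sum(is_founder(x)), "founders\n")
  utils::head(as.data.frame(x)[, c("id", "sire", "dam", "sex", "birth_year")])
}

#' Founder indicator and founder ids
#'
#' A founder is an animal with both parents unknown.
#' @param ped a [pedigree()].
#' @return `is_founder`: logical vector along the pedigree rows;
#'   `founders`: character vector of founder ids.
#' @export
is_founder <- function(ped) ped$sire_idx == 0L & ped$dam_idx == 0L

#' @rdname is_founder
#' @export
founders <- function(ped) ped$id[is_founder(ped)]

#' Read a pedigree file
#'
#' Reads a CSV or whitespace-delimited pedigree table and returns a
#' validated [pedigree()]. Column names (or positions) for the id, sire, dam,
#' sex and birth-year fields are configurable, as is the unknown-parent code.
#'
#' @param path path to the pedigree file.
#' @param sep field separator; `""` (default) means any whitespace for `.txt`
#'   files and `","` for `.csv` files.
#' @param id_col,sire_col,dam_col column names or 1-based positions.
#' @param sex_col,year_col optional column names/positions (`NULL` to skip).
#' @param unknown unknown-parent codes, see [pedigree()].
#' @param header does the file carry a header line? Default `TRUE`.
#' @return a [pedigree()].
#' @export
load_pedigree <- function(path, sep = NULL, id_col = 1, sire_col = 2,
                          dam_col = 3, sex_col = NULL, year_col = NULL,
                          unknown = c("0", "", "NA"), header = TRUE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = header,
                           colClasses = "character", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(col) {
    if (is.null(col)) return(NULL)
    if (is.character(col)) {
      if (!col %in% names(tab)) stop("column not found: ", col)
      tab[[col]]
    } else tab[[as.integer(col)]]
  }
  pedigree(id = pick(id_col), sire = pick(sire_col), dam = pick(dam_col),
           sex = pick(sex_col), birth_year = pick(year_col),
           unknown = unknown)
}

#' Write a pedigree to a CSV file
#'
#' Inverse of [load_pedigree()]; unknown parents are written as `"0"`.
#' @param ped a [pedigree()].
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(id = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = ped$sex, birth_year = ped$birth_year)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a pedigree to the ancestral closure of a reference population
#'
#' Returns the sub-pedigree containing the reference animals plus all their
#' traceable ancestors, topologically sorted. Per-animal statistics of the
#' reference animals are identical in the restricted and the full pedigree,
#' so the closure is used for efficiency when only reference-population
#' statistics are needed.
#'
#' @param ped a [pedigree()].
#' @param ref character vector of reference-animal ids (must exist in `ped`).
#' @return a [pedigree()] containing the closure.
#' @export
restrict_to_reference <- function(ped, ref) {
  ref <- unique(as.character(ref))
  bad <- setdiff(ref, ped$id)
  if (length(bad))
    stop("reference id(s) not in pedigree: ", paste(bad, collapse = ", "))
  keep <- logical(nrow(ped))
  keep[match(ref, ped$id)] <- TRUE
  ## sweep from youngest to oldest: offspring mark their parents
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (ped$sire_idx[i] > 0L) keep[ped$sire_idx[i]] <- TRUE
      if (ped$dam_idx[i] > 0L) keep[ped$dam_idx[i]] <- TRUE
    }
  }
  pedigree(id = ped$id[keep],
           sire = ifelse(is.na(ped$sire[keep]), "0", ped$sire[keep]),
           dam = ifelse(is.na(ped$dam[keep]), "0", ped$dam[keep]),
           sex = ped$sex[keep], birth_year = ped$birth_year[keep])
}

#' Read a reference-population id list
#'
#' One id per line; blank lines and `#` comments ignored.
#' @param path file path.
#' @param ped optional [pedigree()] to validate the ids against.
#' @return character vector of ids.
#' @export
load_reference_ids <- function(path, ped = NULL) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(sub("#.*$", "", ids))
  ids <- ids[nzchar(ids)]
  if (!is.null(ped)) {
    bad <- setdiff(ids, ped$id)
    if (length(bad))
      stop("reference id(s) not in pedigree: ", paste(bad, collapse = ", "))
  }
  ids
}
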