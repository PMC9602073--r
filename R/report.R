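## Study-style report bundles. Every CSV carries a provenance header
## (comment lines starting with '#') recording the parameters of the run,
## so identical configs reproduce identical files.

.write_csv_prov <- function(df, path, prov) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(prov))
    writeLines(paste0("# ", nm, "=", prov[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.prov <- function(...) {
  x <- list(...)
  lapply(x, function(v) paste(format(v, trim = TRUE), collapse = ","))
}

#' Run the pedigree analysis bundle
#'
#' Loads (or accepts) a pedigree, computes inbreeding, average relatedness,
#' depth metrics, individual inbreeding rates and realized Ne, generation
#' intervals and the probability-of-gene-origin parameters, and writes the
#' study-style outputs: a per-animal CSV, a summary JSON, mean F/AR by
#' generation class, the mean completeness-index curve, the four-path
#' generation-interval table and the ranked ancestor table. When a
#' reference population is given, all summaries are additionally produced
#' for it (per-animal values are identical in full and restricted runs).
#'
#' @param ped a [pedigree()] or a path readable by [load_pedigree()].
#' @param out_dir output directory (created if needed).
#' @param ref optional reference ids (character vector or path to an id
#'   list, one per line).
#' @param pci_depth completeness-index depth (default 5).
#' @return invisibly, a list with all computed pieces.
#' @export
run_pedigree <- function(ped, out_dir, ref = NULL, pci_depth = 5L) {
  if (is.character(ped)) ped <- load_pedigree(ped)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(ref) && length(ref) == 1L && file.exists(ref))
    ref <- load_reference_ids(ref, ped)
  prov <- .prov(n_animals = nrow(ped), n_founders = sum(is_founder(ped)),
                reference_n = if (is.null(ref)) 0L else length(ref),
                pci_depth = pci_depth)

  pin <- pedigree_inbreeding(ped)
  gi <- generation_intervals(ped)
  pci <- completeness_index(ped, depth = pci_depth)
  go <- gene_origin_summary(ped)
  fgen <- f_by_generation(ped, by = "comg")
  fgen_max <- f_by_generation(ped, by = "maxg")

  .write_csv_prov(pin$table, file.path(out_dir, "per_animal.csv"), prov)
  .write_csv_prov(gi$paths, file.path(out_dir, "generation_intervals.csv"),
                  prov)
  .write_csv_prov(data.frame(depth = seq_len(pci_depth),
                             mean_pci = pci$mean_by_depth),
                  file.path(out_dir, "pci_by_depth.csv"), prov)
  .write_csv_prov(fgen, file.path(out_dir, "f_by_comg.csv"), prov)
  .write_csv_prov(fgen_max, file.path(out_dir, "f_by_maxg.csv"), prov)
  ac <- ancestor_contributions(ped)
  .write_csv_prov(ac$p, file.path(out_dir, "ancestor_contributions.csv"),
                  prov)

  summary <- c(pin$summary,
               list(gi_overall = gi$overall, gi_n = gi$n_total,
                    fe = go$fe, fa = go$fa, fa_fe_ratio = go$fa_fe_ratio,
                    n_half = go$n_half))
  out <- list(inbreeding = pin, generation_intervals = gi, pci = pci,
              gene_origin = go, summary = summary)

  if (!is.null(ref)) {
    pin_ref <- pedigree_inbreeding(ped, ref = ref)
    go_ref <- gene_origin_summary(ped, ref = ref)
    pci_ref <- completeness_index(restrict_to_reference(ped, ref),
                                  depth = pci_depth)
    pci_ref_mean <- colMeans(pci_ref$pci[ref, , drop = FALSE])
    .write_csv_prov(pin_ref$table,
                    file.path(out_dir, "per_animal_reference.csv"), prov)
    .write_csv_prov(data.frame(depth = seq_len(pci_depth),
                               mean_pci = pci_ref_mean),
                    file.path(out_dir, "pci_by_depth_reference.csv"), prov)
    summary$reference <- c(pin_ref$summary,
                           list(fe = go_ref$fe, fa = go_ref$fa,
                                fa_fe_ratio = go_ref$fa_fe_ratio,
                                n_half = go_ref$n_half))
    out$reference <- list(inbreeding = pin_ref, gene_origin = go_ref)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  out$summary <- summary
  invisible(out)
}

#' Run the genomic analysis bundle
#'
#' Applies quality control, computes Yang-GRM inbreeding, detects runs of
#' homozygosity, and writes FGRM/FROH per-animal tables, the genomic
#' inbreeding summary, the ROH length-class table, per-chromosome FROH,
#' the SNP-incidence track, island calls (CSV and BED) and — when a
#' pedigree is supplied — the estimator correlation matrix.
#'
#' @param panel a [genotype_panel()] or a PLINK prefix for [read_plink()].
#' @param out_dir output directory.
#' @param ped optional [pedigree()] (or path) for the FPED column of the
#'   estimator comparison.
#' @param params an [roh_params()].
#' @param qc apply [apply_qc()] first? Default `TRUE`.
#' @param snp_cr,animal_cr,n_autosomes QC settings.
#' @param island_threshold incidence threshold in percent (default 50).
#' @param gene_intervals optional path to a BED file of features for island
#'   annotation.
#' @return invisibly, a list with all computed pieces.
#' @export
run_genomic <- function(panel, out_dir, ped = NULL, params = roh_params(),
                        qc = TRUE, snp_cr = 0.90, animal_cr = 0.90,
                        n_autosomes = 29L, island_threshold = 50,
                        gene_intervals = NULL) {
  if (is.character(panel)) panel <- read_plink(panel)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (qc) panel <- apply_qc(panel, snp_cr, animal_cr, n_autosomes)
  prov <- .prov(n_animals = nrow(panel$geno), n_snp = ncol(panel$geno),
                window_snp = params$window_snp,
                min_length = params$min_length, max_gap = params$max_gap,
                min_density = params$min_density,
                max_het_in_window = params$max_het_in_window,
                max_miss_in_window = params$max_miss_in_window,
                min_snp_in_run = params$min_snp_in_run,
                coverage_threshold = params$window_coverage_threshold,
                island_threshold = island_threshold)

  g <- grm_yang(panel)
  segs <- detect_roh(panel, params)
  fr <- froh(segs, panel)
  isl <- roh_islands(segs, panel, threshold = island_threshold)

  .write_csv_prov(data.frame(animal = names(g$fgrm), fgrm = unname(g$fgrm)),
                  file.path(out_dir, "fgrm.csv"), prov)
  write_grm(g$g, file.path(out_dir, "grm"))
  .write_csv_prov(fr$froh, file.path(out_dir, "froh.csv"), prov)
  .write_csv_prov(as.data.frame(segs), file.path(out_dir, "roh_segments.csv"),
                  prov)
  .write_csv_prov(roh_class_table(segs),
                  file.path(out_dir, "roh_class_table.csv"), prov)
  .write_csv_prov(data.frame(chr = colnames(fr$froh_chr),
                             mean_froh = colMeans(fr$froh_chr)),
                  file.path(out_dir, "froh_by_chromosome.csv"), prov)
  utils::write.table(isl$incidence, file.path(out_dir, "snp_incidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  islands <- isl$islands
  if (!is.null(gene_intervals) && nrow(islands))
    islands <- annotate_islands(islands, read_bed_intervals(gene_intervals))
  .write_csv_prov(islands, file.path(out_dir, "roh_islands.csv"), prov)
  if (nrow(islands))
    utils::write.table(data.frame(islands$chr, islands$start - 1,
                                  islands$end),
                       file.path(out_dir, "roh_islands.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

  tab2 <- do.call(rbind, lapply(
    c("fgrm", grep("^froh", names(fr$froh), value = TRUE)),
    function(nm) {
      v <- if (nm == "fgrm") g$fgrm else fr$froh[[nm]]
      data.frame(estimator = nm, as.data.frame(inbreeding_pct_summary(v)))
    }))
  .write_csv_prov(tab2, file.path(out_dir, "genomic_inbreeding_summary.csv"),
                  prov)

  out <- list(panel = panel, grm = g, segments = segs, froh = fr,
              islands = islands, incidence = isl$incidence, summary = tab2)
  if (!is.null(ped)) {
    if (is.character(ped)) ped <- load_pedigree(ped)
    common <- intersect(rownames(panel$geno), ped$id)
    if (length(common) >= 3) {
      fped <- inbreeding_ml(ped)[common]
      et <- estimator_table(fped = fped, fgrm = g$fgrm,
                            froh_table = fr$froh)
      cc <- inbreeding_correlations(et)
      write_correlation_table(cc, file.path(out_dir, "correlations.csv"))
      out$correlations <- cc
    }
  }
  invisible(out)
}
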