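#' Run the full orientation-bias analysis report
#'
#' Executes the complete pipeline on a genome + mutation catalog: gene
#' orientation classification, CDS and promoter assignment, per-gene
#' frequencies, CD-versus-HO comparison tables for the standard gene
#' subsets (all genes, minus tRNA and ribosomal, highly expressed and its
#' exclusion variants, essential, tRNA), correlation tables against CDS
#' length and expression, conditional rates, the transition placement
#' (strand-asymmetry) summary, the mononucleotide-run census, the tRNA
#' hotspot decomposition, and the -10 element scan. One Benjamini-Hochberg
#' pass is applied across every p-value the run emits.
#'
#' @param genome A [genome_annotation()] (categories/TPM columns used when
#'   present).
#' @param catalog A `mutation_catalog`.
#' @param meta Experiment metadata (per-line generations).
#' @param out_dir Optional directory; when given, tables are written as TSV
#'   plus a JSON manifest.
#' @param hotspot_ids Gene ids treated as declared indel hotspots in the
#'   tRNA decomposition (default: genes tagged "hotspot").
#' @return Object of class `ori_report`: list of all tables and summaries.
#' @export
run_report <- function(genome, catalog, meta, out_dir = NULL,
                       hotspot_ids = NULL) {
  orientation <- classify_orientation(genome)
  cds <- assign_to_cds(catalog, genome)
  freq <- frequency_per_cds(merge_gene_info(cds$gene_counts, genome))
  promoters <- assign_to_promoters(catalog, genome)
  runs <- find_runs(genome$sequence, min_len = 5L)
  run_assignment <- assign_indels_to_runs(catalog, runs)
  census <- run_census(genome$sequence)

  if (is.null(hotspot_ids)) {
    hotspot_ids <- select_category(genome$genes, "hotspot")$gene_ids
  }
  trna <- select_category(genome$genes, "tRNA")
  ribosomal <- select_category(genome$genes, "ribosomal")
  essential <- select_category(genome$genes, "essential")

  comparisons <- list(comparison_table(freq, subset_name = "all_genes"))
  excl <- union(trna$gene_ids, ribosomal$gene_ids)
  if (length(excl)) {
    sub <- structure(list(name = "minus_trna_ribosomal",
                          gene_ids = setdiff(freq$gene_id, excl)),
                     class = "gene_subset")
    comparisons <- c(comparisons, list(comparison_table(freq, sub)))
  }
  he <- NULL
  if (any(is.finite(freq$tpm_lag) | is.finite(freq$tpm_log) |
          is.finite(freq$tpm_stat))) {
    he <- select_highly_expressed(freq)
    comparisons <- c(comparisons, list(comparison_table(freq, he)))
    if (length(excl)) {
      sub <- structure(list(name = "highly_expressed_minus_trna_ribosomal",
                            gene_ids = setdiff(he$gene_ids, excl)),
                       class = "gene_subset")
      comparisons <- c(comparisons, list(comparison_table(freq, sub)))
    }
    if (length(trna$gene_ids)) {
      sub <- structure(list(name = "highly_expressed_minus_trna",
                            gene_ids = setdiff(he$gene_ids, trna$gene_ids)),
                       class = "gene_subset")
      comparisons <- c(comparisons, list(comparison_table(freq, sub)))
    }
  }
  if (length(essential$gene_ids)) {
    comparisons <- c(comparisons, list(comparison_table(freq, essential)))
  }
  if (length(trna$gene_ids)) {
    comparisons <- c(comparisons, list(comparison_table(freq, trna)))
    if (length(hotspot_ids)) {
      sub <- structure(list(name = "trna_minus_hotspots",
                            gene_ids = setdiff(trna$gene_ids, hotspot_ids)),
                       class = "gene_subset")
      comparisons <- c(comparisons, list(comparison_table(freq, sub)))
    }
  }
  comparison <- do.call(rbind, comparisons)

  # promoter CD-vs-HO comparison on per-promoter counts
  prom_comparison <- NULL
  if (nrow(promoters) > 0) {
    pf <- promoters
    pf$orientation <- promoters$orientation
    pf$gene_id <- promoters$promoter_id
    pm <- c(n_bps = "BPSs/promoter", n_indel = "Indels/promoter")
    prom_comparison <- comparison_table(pf, metrics = pm,
                                        subset_name = "promoters")
  }

  correlations <- list(correlation_table(freq, "cds_length",
                                         subset_name = "all_genes"))
  for (ph in c("tpm_lag", "tpm_log", "tpm_stat")) {
    if (any(is.finite(freq[[ph]]) & freq[[ph]] > 0)) {
      correlations <- c(correlations, list(
        correlation_table(freq, ph, subset_name = "all_genes")))
    }
  }
  correlation <- do.call(rbind, correlations)

  rates <- rate_table(catalog, genome, meta)
  placement <- placement_summary(catalog, genome, meta, freq)
  trna_report <- trna_decomposition(freq, trna, hotspot_ids,
                                    run_assignment, cds$assignments)
  minus10 <- scan_minus10(catalog, genome)

  tabs <- list(comparison = comparison, correlation = correlation)
  if (!is.null(prom_comparison)) tabs$prom_comparison <- prom_comparison
  tabs <- adjust_report(tabs)
  family_size <- attr(tabs, "family_size")

  report <- structure(list(
    orientation = orientation,
    partition = partition_counts(genome),
    gene_freq = freq,
    promoters = promoters,
    comparison = tabs$comparison,
    prom_comparison = tabs$prom_comparison,
    correlation = tabs$correlation,
    rates = rates,
    placement = placement,
    runs = runs, run_census = census,
    run_assignment = run_assignment,
    trna = trna_report,
    minus10 = minus10,
    n_intergenic = cds$n_intergenic, n_multi = cds$n_multi,
    bh_family_size = family_size,
    highly_expressed = he), class = "ori_report")

  if (!is.null(out_dir)) write_report(report, genome, out_dir)
  report
}

merge_gene_info <- function(gene_counts, genome) {
  g <- genome$genes
  idx <- match(gene_counts$gene_id, g$gene_id)
  for (col in c("name", "categories", "tpm_lag", "tpm_log", "tpm_stat")) {
    gene_counts[[col]] <- g[[col]][idx]
  }
  gene_counts
}

#' @export
print.ori_report <- function(x, ...) {
  cat("Orientation-bias analysis report\n")
  cat(sprintf("  genes: %d CD, %d HO\n", x$partition[["n_CD"]],
              x$partition[["n_HO"]]))
  cat(sprintf("  mutations: %d in CDSs (+%d intergenic), BH family of %d\n",
              sum(x$gene_freq$n_bps) + sum(x$gene_freq$n_indel),
              x$n_intergenic, x$bh_family_size))
  cat("\nCD vs HO comparisons:\n")
  print(x$comparison)
  invisible(x)
}

#' Write an analysis report to TSV files + manifest
#'
#' @param report An `ori_report`.
#' @param genome The [genome_annotation()] used.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, genome, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    as.data.frame(x), file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(report$comparison, "comparison_cd_ho.tsv")
  wt(report$correlation, "correlations.tsv")
  if (!is.null(report$prom_comparison)) {
    wt(report$prom_comparison, "promoter_comparison.tsv")
  }
  wt(report$gene_freq, "gene_counts.tsv")
  wt(report$promoters, "promoter_counts.tsv")
  wt(report$rates, "rates.tsv")
  wt(report$placement$placement, "placement.tsv")
  wt(report$run_census, "run_census.tsv")
  if (nrow(report$minus10) > 0) wt(report$minus10, "minus10_hits.tsv")
  write_runs_bed(report$runs, genome, file.path(out_dir, "runs.bed"))
  manifest <- list(genome_id = genome$genome_id,
                   genome_length = genome$length,
                   n_cd = unname(report$partition[["n_CD"]]),
                   n_ho = unname(report$partition[["n_HO"]]),
                   n_intergenic = report$n_intergenic,
                   n_multi = report$n_multi,
                   bh_family_size = report$bh_family_size,
                   package_version = as.character(
                     utils::packageVersion("oriconflict")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
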