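#' Select highly expressed genes
#'
#' A gene is highly expressed when its log10(TPM) in at least one growth
#' phase (lag, log, stationary) is at or above one standard deviation above
#' the mean log10(TPM) for that phase; the `all_phases` variant requires the
#' criterion in every phase. Phase means and SDs are computed over genes
#' with TPM > 0 by default (genes with zero TPM can never be selected).
#'
#' @param genes Gene table with `gene_id`, `tpm_lag`, `tpm_log`, `tpm_stat`.
#' @param mode "any_phase" (default) or "all_phases".
#' @param include_zero Include zero-TPM genes when computing phase means/SDs
#'   (as log10 of a half-minimum pseudocount)? Default FALSE.
#' @param n_sd Number of SDs above the mean (default 1).
#' @return Object of class `gene_subset`: list with `name`, `gene_ids`, and
#'   `thresholds` (per-phase mean, sd, cutoff).
#' @export
select_highly_expressed <- function(genes, mode = c("any_phase", "all_phases"),
                                    include_zero = FALSE, n_sd = 1) {
  mode <- match.arg(mode)
  phases <- c("tpm_lag", "tpm_log", "tpm_stat")
  if (!any(phases %in% names(genes))) stop("no TPM columns in gene table")
  crit <- matrix(FALSE, nrow(genes), length(phases))
  thr <- data.frame(phase = phases, mean = NA_real_, sd = NA_real_,
                    cutoff = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(phases)) {
    tpm <- genes[[phases[i]]]
    if (is.null(tpm)) next
    pos <- is.finite(tpm) & tpm > 0
    if (!any(pos)) next
    ltpm <- rep(NA_real_, length(tpm))
    ltpm[pos] <- log10(tpm[pos])
    base <- if (include_zero) {
      pseudo <- min(tpm[pos]) / 2
      log10(pmax(ifelse(is.finite(tpm), tpm, 0), pseudo))
    } else ltpm[pos]
    m <- mean(base); s <- stats::sd(base)
    if (is.na(s) || s == 0) {
      warning("degenerate (zero-variance) TPM table for ", phases[i])
      next
    }
    thr$mean[i] <- m; thr$sd[i] <- s; thr$cutoff[i] <- m + n_sd * s
    crit[, i] <- !is.na(ltpm) & ltpm >= m + n_sd * s
  }
  if (all(is.na(thr$cutoff))) stop("all-zero TPM table")
  sel <- if (mode == "any_phase") rowSums(crit) > 0 else
    rowSums(crit) == sum(!is.na(thr$cutoff))
  structure(list(name = paste0("highly_expressed_", mode),
                 gene_ids = genes$gene_id[sel], thresholds = thr),
            class = "gene_subset")
}

#' Define a gene subset by category tags
#'
#' @param genes Gene table with `gene_id` and `categories`
#'   (semicolon-joined tags).
#' @param category Tag to select (e.g. "tRNA", "essential").
#' @param name Subset name (defaults to the category).
#' @param exclude Character vector of gene_ids to drop.
#' @return A `gene_subset`.
#' @export
select_category <- function(genes, category, name = category,
                            exclude = character(0)) {
  tags <- strsplit(ifelse(is.na(genes$categories), "", genes$categories), ";")
  sel <- vapply(tags, function(t) category %in% t, logical(1))
  ids <- setdiff(genes$gene_id[sel], exclude)
  structure(list(name = name, gene_ids = ids,
                 definition = list(category = category, exclude = exclude)),
            class = "gene_subset")
}

#' @export
print.gene_subset <- function(x, ...) {
  cat(sprintf("Gene subset '%s': %d genes\n", x$name, length(x$gene_ids)))
  invisible(x)
}

metric_columns <- function() {
  c(bps_per_cds = "BPSs/CDS", bps_per_nt_k = "BPSs/CDS/nt (10^3)",
    indel_per_cds = "Indels/CDS", indel_per_nt_k = "Indels/CDS/nt (10^3)")
}

#' Codirectional versus head-on comparison table
#'
#' For each metric, summarizes all genes of a subset and the CD and HO
#' orientation classes: means, SDs, the percent excess of the HO mean over
#' the CD mean (delta_HO, from unrounded means), a pooled-variance Student's
#' t p-value and a Mann-Whitney p-value, both two-tailed and unadjusted
#' (Benjamini-Hochberg adjustment is applied once per report run across all
#' emitted p-values, see [adjust_report()]). An empty orientation class
#' yields a row with missing statistics and a flag.
#'
#' @param freq Per-gene frequency table from [frequency_per_cds()] (must
#'   include an `orientation` column).
#' @param subset Optional `gene_subset` (default: all genes).
#' @param metrics Named character vector of metric columns to summarize
#'   (default the four standard per-CDS metrics).
#' @param subset_name Label for the output rows.
#' @return `data.frame` of class `comparison_table`, one row per metric:
#'   counts, means, SDs, `delta_ho`, `p_t`, `p_mw`, `flag`.
#' @export
comparison_table <- function(freq, subset = NULL, metrics = metric_columns(),
                             subset_name = NULL) {
  if (!is.null(subset)) {
    if (is.null(subset_name)) subset_name <- subset$name
    freq <- freq[freq$gene_id %in% subset$gene_ids, , drop = FALSE]
  }
  if (is.null(subset_name)) subset_name <- "all_genes"
  rows <- lapply(names(metrics), function(col) {
    v <- freq[[col]]
    cd <- v[freq$orientation == "CD"]
    ho <- v[freq$orientation == "HO"]
    flag <- NA_character_
    if (length(cd) == 0 || length(ho) == 0) flag <- "empty_class"
    mean_cd <- if (length(cd)) mean(cd) else NA_real_
    mean_ho <- if (length(ho)) mean(ho) else NA_real_
    delta <- if (!is.na(mean_cd) && mean_cd > 0 && !is.na(mean_ho)) {
      100 * (mean_ho / mean_cd - 1)
    } else NA_real_
    p_t <- p_mw <- NA_real_
    if (is.na(flag)) {
      p_t <- two_sample_t(cd, ho)$p_raw
      p_mw <- mann_whitney(cd, ho)$p_raw
    }
    data.frame(subset_name = subset_name, metric = unname(metrics[col]),
               metric_col = col,
               n_all = length(v), n_cd = length(cd), n_ho = length(ho),
               mean_all = mean(v), sd_all = stats::sd(v),
               mean_cd = mean_cd,
               sd_cd = if (length(cd) > 1) stats::sd(cd) else NA_real_,
               mean_ho = mean_ho,
               sd_ho = if (length(ho) > 1) stats::sd(ho) else NA_real_,
               delta_ho = delta, p_t = p_t, p_mw = p_mw,
               p_t_adj = NA_real_, p_mw_adj = NA_real_,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  show <- df[, c("subset_name", "metric", "mean_cd", "mean_ho", "delta_ho",
                 "p_t", "p_mw")]
  show$mean_cd <- round(show$mean_cd, digits)
  show$mean_ho <- round(show$mean_ho, digits)
  show$delta_ho <- round(show$delta_ho)
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' Confidence interval for the HO/CD percent excess
#'
#' Delta-method interval for `100 * (mean_ho / mean_cd - 1)` using the
#' standard errors of the two class means.
#'
#' @param cd,ho Per-gene metric values in the two orientation classes.
#' @param conf Confidence level (default 0.95).
#' @return list: `delta_ho`, `ci_low`, `ci_high`.
#' @export
delta_ho_ci <- function(cd, ho, conf = 0.95) {
  m1 <- mean(cd); m2 <- mean(ho)
  se1 <- stats::sd(cd) / sqrt(length(cd))
  se2 <- stats::sd(ho) / sqrt(length(ho))
  if (m1 <= 0) stop("CD mean must be positive for a ratio interval")
  ratio <- m2 / m1
  se_ratio <- abs(ratio) * sqrt(se2^2 / m2^2 + se1^2 / m1^2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(delta_ho = 100 * (ratio - 1),
       ci_low = 100 * (ratio - z * se_ratio - 1),
       ci_high = 100 * (ratio + z * se_ratio - 1))
}

#' Correlation table against a gene-level predictor
#'
#' Pearson and Spearman correlations of per-gene mutation metrics with CDS
#' length or a log10(TPM) expression phase, for all genes of a subset and
#' within each orientation class. TPM predictors are log10-transformed;
#' genes with zero or missing TPM are dropped for those predictors.
#'
#' @param freq Per-gene frequency table (needs `orientation` plus the
#'   predictor source columns).
#' @param predictor One of "cds_length", "tpm_lag", "tpm_log", "tpm_stat".
#' @param subset Optional `gene_subset`.
#' @param metrics Metric columns to correlate (default BPSs/CDS and
#'   indels/CDS).
#' @param subset_name Label for output rows.
#' @return `data.frame`: one row per metric x orientation with `rho_pearson`,
#'   `p_pearson`, `rho_spearman`, `p_spearman`, adjusted columns filled by
#'   [adjust_report()].
#' @export
correlation_table <- function(freq, predictor = "cds_length", subset = NULL,
                              metrics = c(bps_per_cds = "BPSs/CDS",
                                          indel_per_cds = "Indels/CDS"),
                              subset_name = NULL) {
  stopifnot(predictor %in% c("cds_length", "tpm_lag", "tpm_log", "tpm_stat"))
  if (!is.null(subset)) {
    if (is.null(subset_name)) subset_name <- subset$name
    freq <- freq[freq$gene_id %in% subset$gene_ids, , drop = FALSE]
  }
  if (is.null(subset_name)) subset_name <- "all_genes"
  pv <- freq[[predictor]]
  if (startsWith(predictor, "tpm")) {
    keep <- is.finite(pv) & pv > 0
    freq <- freq[keep, , drop = FALSE]
    pv <- log10(pv[keep])
  }
  groups <- list(All = rep(TRUE, nrow(freq)),
                 CD = freq$orientation == "CD",
                 HO = freq$orientation == "HO")
  rows <- list()
  for (col in names(metrics)) {
    for (gname in names(groups)) {
      sel <- groups[[gname]]
      x <- pv[sel]; y <- freq[[col]][sel]
      pe <- cor_stat(x, y, "pearson")
      sp <- cor_stat(x, y, "spearman")
      rows[[length(rows) + 1L]] <- data.frame(
        subset_name = subset_name, predictor = predictor,
        metric = unname(metrics[col]), metric_col = col, group = gname,
        n = sum(sel), rho_pearson = pe$statistic, p_pearson = pe$p_raw,
        rho_spearman = sp$statistic, p_spearman = sp$p_raw,
        p_pearson_adj = NA_real_, p_spearman_adj = NA_real_,
        flag = ifelse(is.na(pe$flag), NA_character_, pe$flag),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Apply one Benjamini-Hochberg pass across a report run
#'
#' Gathers every raw p-value column (`p_t`, `p_mw`, `p_pearson`,
#' `p_spearman`, `p_F`) across the supplied tables into a single family,
#' adjusts once, and writes the `*_adj` columns back. With a single
#' comparison the adjusted value equals the raw value.
#'
#' @param tables Named list of report tables.
#' @param method "BH" (default) or "holm".
#' @return The list of tables with adjusted columns filled; attribute
#'   `family_size` records the number of p-values adjusted together.
#' @export
adjust_report <- function(tables, method = "BH") {
  pairs <- list(c("p_t", "p_t_adj"), c("p_mw", "p_mw_adj"),
                c("p_pearson", "p_pearson_adj"),
                c("p_spearman", "p_spearman_adj"), c("p_F", "p_F_adj"))
  slots <- list(); raw <- numeric(0)
  for (tn in names(tables)) {
    tab <- tables[[tn]]
    for (pr in pairs) {
      if (pr[1] %in% names(tab)) {
        idx <- which(!is.na(tab[[pr[1]]]))
        if (length(idx)) {
          slots[[length(slots) + 1L]] <- list(tn = tn, col = pr, idx = idx,
                                              off = length(raw))
          raw <- c(raw, tab[[pr[1]]][idx])
        }
      }
    }
  }
  adj <- benjamini_hochberg(raw, method = method)
  for (s in slots) {
    tab <- tables[[s$tn]]
    if (!(s$col[2] %in% names(tab))) tab[[s$col[2]]] <- NA_real_
    tab[[s$col[2]]][s$idx] <- adj[s$off + seq_along(s$idx)]
    tables[[s$tn]] <- tab
  }
  attr(tables, "family_size") <- length(raw)
  tables
}

#' Decompose tRNA-gene mutation counts around declared hotspot genes
#'
#' Reports per-tRNA BPS and indel counts; totals with and without the
#' declared hotspot genes; a chi-square homogeneity test of indel counts
#' across the hotspot genes (are the homologues equally mutable?); the naive
#' HO/CD mean indel ratio with and without the hotspots; and the fraction of
#' tRNA indels attributable to mononucleotide runs.
#'
#' @param freq Per-gene frequency table.
#' @param trna_subset `gene_subset` of tRNA genes.
#' @param hotspot_ids Gene ids of the declared hotspot homologues.
#' @param run_assignment Optional output of [assign_indels_to_runs()]
#'   restricted to tRNA indels, used for the run-attribution fraction.
#' @param assignments Optional mutation-to-gene `assignments` table from
#'   [assign_to_cds()] (needed with `run_assignment`).
#' @return list: `per_gene`, `total_indels`, `hotspot_indels`,
#'   `chisq_homogeneity` (statistic, df, p), `ho_cd_ratio`,
#'   `ho_cd_ratio_minus_hotspots`, `run_fraction`.
#' @export
trna_decomposition <- function(freq, trna_subset, hotspot_ids = character(0),
                               run_assignment = NULL, assignments = NULL) {
  tr <- freq[freq$gene_id %in% trna_subset$gene_ids, , drop = FALSE]
  if (nrow(tr) == 0) {
    return(list(per_gene = tr, total_indels = 0L, hotspot_indels = 0L,
                chisq_homogeneity = NULL, ho_cd_ratio = NA_real_,
                ho_cd_ratio_minus_hotspots = NA_real_,
                run_fraction = NA_real_))
  }
  per_gene <- tr[, c("gene_id", "orientation", "cds_length", "n_bps",
                     "n_indel")]
  hot <- tr[tr$gene_id %in% hotspot_ids, , drop = FALSE]
  chisq <- NULL
  if (nrow(hot) >= 2 && sum(hot$n_indel) > 0) {
    ct <- suppressWarnings(stats::chisq.test(hot$n_indel))
    chisq <- list(statistic = unname(ct$statistic),
                  df = unname(ct$parameter), p = ct$p.value)
  }
  ratio_of <- function(d) {
    cd <- d$n_indel[d$orientation == "CD"]
    ho <- d$n_indel[d$orientation == "HO"]
    if (length(cd) == 0 || length(ho) == 0 || mean(cd) == 0) return(NA_real_)
    mean(ho) / mean(cd)
  }
  run_fraction <- NA_real_
  if (!is.null(run_assignment) && !is.null(assignments)) {
    tr_muts <- assignments$mutation_id[assignments$gene_id %in%
                                         trna_subset$gene_ids]
    mp <- run_assignment$mapping
    mp <- mp[mp$mutation_id %in% tr_muts, , drop = FALSE]
    if (nrow(mp) > 0) run_fraction <- mean(!is.na(mp$run_id))
  }
  list(per_gene = per_gene,
       total_indels = sum(tr$n_indel),
       hotspot_indels = sum(hot$n_indel),
       chisq_homogeneity = chisq,
       ho_cd_ratio = ratio_of(tr),
       ho_cd_ratio_minus_hotspots = ratio_of(
         tr[!(tr$gene_id %in% hotspot_ids), , drop = FALSE]),
       run_fraction = run_fraction)
}

#' Transition placement summary (strand-asymmetry analysis)
#'
#' Genome-wide, transitions are split by the placement of the informative
#' base (A for A·T, C for G·C) on the lagging- (LGST) versus leading-strand
#' (LDST) template, and the per-placement conditional rates and their ratio
#' are estimated, with a 95% interval for the ratio obtained from the
#' conditional binomial split of the two Poisson counts. Per-CDS transition
#' frequencies are additionally summarized by gene orientation with box
#' statistics and t / Mann-Whitney tests, the form in which such asymmetry
#' is usually displayed.
#'
#' @param catalog A `mutation_catalog`.
#' @param genome A [genome_annotation()].
#' @param meta Experiment metadata.
#' @param freq Optional per-gene frequency table (from
#'   [frequency_per_cds()]); when supplied the orientation-level summary is
#'   included.
#' @return list with `placement` (per pair class: counts, targets, rates,
#'   `ratio`, `ratio_ci_low`, `ratio_ci_high`) and `by_orientation`
#'   (per-CDS frequency summaries with box stats and tests), plus
#'   `placement_counts` (the 4-class count vector).
#' @export
placement_summary <- function(catalog, genome, meta, freq = NULL) {
  gens <- total_exposure(meta)
  ts <- catalog[!is.na(catalog$change_class) &
                  catalog$change_class == "transition", , drop = FALSE]
  placement <- classify_transition_placement(ts, genome)
  counts <- table(factor(placement,
                         levels = c("A_on_LGST", "A_on_LDST",
                                    "C_on_LGST", "C_on_LDST")))
  tg <- nt_targets(genome)
  row_for <- function(base) {
    lg <- counts[[paste0(base, "_on_LGST")]]
    ld <- counts[[paste0(base, "_on_LDST")]]
    nt_lg <- tg[[paste0(base, "_on_LGST")]]
    nt_ld <- tg[[paste0(base, "_on_LDST")]]
    r_lg <- conditional_rate(lg, gens, nt_lg)
    r_ld <- conditional_rate(ld, gens, nt_ld)
    if (lg + ld > 0 && ld > 0) {
      bt <- stats::binom.test(lg, lg + ld)
      ci <- bt$conf.int / (1 - bt$conf.int) * (nt_ld / nt_lg)
      ratio <- (lg / nt_lg) / (ld / nt_ld)
    } else {
      ci <- c(NA_real_, NA_real_); ratio <- NA_real_
    }
    data.frame(pair_class = if (base == "A") "AT" else "GC",
               informative_base = base,
               n_lgst = lg, n_ldst = ld, nt_lgst = nt_lg, nt_ldst = nt_ld,
               rate_lgst = r_lg$rate, rate_ldst = r_ld$rate,
               ratio = ratio, ratio_ci_low = ci[1], ratio_ci_high = ci[2],
               stringsAsFactors = FALSE)
  }
  placement_tab <- rbind(row_for("A"), row_for("C"))

  by_orientation <- NULL
  if (!is.null(freq)) {
    by_orientation <- lapply(c(at = "n_ts_at", gc = "n_ts_gc"), function(col) {
      cd <- freq[[col]][freq$orientation == "CD"]
      ho <- freq[[col]][freq$orientation == "HO"]
      list(box_cd = box_stats(cd), box_ho = box_stats(ho),
           p_t = two_sample_t(cd, ho)$p_raw,
           p_mw = mann_whitney(cd, ho)$p_raw)
    })
  }
  list(placement = placement_tab,
       placement_counts = stats::setNames(as.integer(counts), names(counts)),
       by_orientation = by_orientation)
}
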