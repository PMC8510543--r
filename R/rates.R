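#' Per-CDS mutation frequencies
#'
#' Adds per-gene frequency columns to a gene count table: mutations per CDS,
#' per CDS per nucleotide, and the x10^3-scaled per-nucleotide value used in
#' reports.
#'
#' @param gene_counts `gene_counts` table from [assign_to_cds()] (needs
#'   `n_bps`, `n_indel`, `cds_length`).
#' @return The input with added columns `bps_per_cds`, `bps_per_nt`,
#'   `bps_per_nt_k`, `indel_per_cds`, `indel_per_nt`, `indel_per_nt_k`, and
#'   analogous `*_per_nt_k` columns for the transition/transversion classes.
#' @export
frequency_per_cds <- function(gene_counts) {
  if (any(gene_counts$cds_length <= 0)) stop("zero-length CDS")
  x <- gene_counts
  x$bps_per_cds <- x$n_bps
  x$bps_per_nt <- x$n_bps / x$cds_length
  x$bps_per_nt_k <- 1e3 * x$bps_per_nt
  x$indel_per_cds <- x$n_indel
  x$indel_per_nt <- x$n_indel / x$cds_length
  x$indel_per_nt_k <- 1e3 * x$indel_per_nt
  for (cls in c("ts_at", "ts_gc", "tv_at", "tv_gc")) {
    n <- x[[paste0("n_", cls)]]
    if (!is.null(n)) {
      x[[paste0(cls, "_per_cds")]] <- n
      x[[paste0(cls, "_per_nt_k")]] <- 1e3 * n / x$cds_length
    }
  }
  x
}

#' Mean mutations per CDS from a count and a number of CDSs
#'
#' The worked-example arithmetic behind summary table entries such as
#' "mean BPSs/CDS": a total mutation count divided by the number of coding
#' sequences carrying it.
#'
#' @param n_mutations Total mutation count.
#' @param n_cds Number of CDSs.
#' @return Mean mutations per CDS.
#' @export
per_cds_mean <- function(n_mutations, n_cds) {
  stopifnot(n_cds > 0)
  n_mutations / n_cds
}

#' Conditional per-generation, per-nucleotide mutation rate
#'
#' The rate of a mutation class is its count divided by the product of total
#' line-generations and the number of eligible nucleotides (for pair-class
#' rates, base pairs of that class: an A·T pair counts once regardless of
#' strand). The 95% confidence limits are the exact (Garwood) Poisson
#' interval on the count, divided by the same exposure:
#' `[qchisq(alpha/2, 2k)/2, qchisq(1 - alpha/2, 2k + 2)/2] / exposure`.
#'
#' @param count Mutation count (non-negative integer).
#' @param generations Total line-generations.
#' @param nt_target Number of eligible nucleotides (or base pairs).
#' @param conf Confidence level (default 0.95).
#' @return Object of class `rate_estimate`: list with `count`,
#'   `generations`, `nt_target`, `rate`, `ci_low`, `ci_high`, `conf`.
#' @export
conditional_rate <- function(count, generations, nt_target, conf = 0.95) {
  if (generations <= 0 || nt_target <= 0) stop("exposure must be positive")
  if (count < 0) stop("count must be non-negative")
  exposure <- generations * nt_target
  alpha <- 1 - conf
  lo <- if (count == 0) 0 else stats::qchisq(alpha / 2, 2 * count) / 2
  hi <- stats::qchisq(1 - alpha / 2, 2 * count + 2) / 2
  structure(list(count = count, generations = generations,
                 nt_target = nt_target, rate = count / exposure,
                 ci_low = lo / exposure, ci_high = hi / exposure,
                 conf = conf),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(
    "rate %.3g per generation per nt (%d events / %.3g gen x %.3g nt)\n",
    x$rate, x$count, x$generations, x$nt_target))
  cat(sprintf("  %.0f%% CI [%.3g, %.3g]\n", 100 * x$conf, x$ci_low, x$ci_high))
  invisible(x)
}

#' Percent change between two rates
#'
#' `100 * (rate_a - rate_b) / rate_b`; report tables round this to the
#' nearest integer percent.
#'
#' @param rate_a,rate_b Rates on the same scale; `rate_b > 0`.
#' @return Percent change (numeric, unrounded).
#' @export
rate_delta <- function(rate_a, rate_b) {
  if (any(rate_b == 0)) stop("reference rate must be nonzero")
  100 * (rate_a - rate_b) / rate_b
}

#' Genome-wide nucleotide targets by class and template placement
#'
#' Counts base pairs of each pair class (an A·T pair once, whichever strand
#' shows the A) and, within each class, how many have the informative base
#' (A or C) on the lagging- versus leading-strand template. These are the
#' denominators for conditional rates and placement-asymmetry ratios.
#'
#' @param genome A [genome_annotation()].
#' @param positions Optional integer vector restricting the census (e.g. CDS
#'   positions only); default all positions.
#' @return Named numeric vector: `AT`, `GC`, `A_on_LGST`, `A_on_LDST`,
#'   `C_on_LGST`, `C_on_LDST`.
#' @export
nt_targets <- function(genome, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(genome$length)
  bases <- strsplit(genome$sequence, "", fixed = TRUE)[[1]][positions]
  repl <- classify_replichore(positions, genome)
  # template role of the forward strand at each position
  fwd_tmpl <- ifelse(repl == "right", "LGST", "LDST")
  at <- bases %in% c("A", "T")
  # A on forward strand iff base is A; else A on reverse strand, whose
  # template role is the opposite of the forward strand's
  a_tmpl <- ifelse(bases == "A", fwd_tmpl,
            ifelse(fwd_tmpl == "LGST", "LDST", "LGST"))
  c_tmpl <- ifelse(bases == "C", fwd_tmpl,
            ifelse(fwd_tmpl == "LGST", "LDST", "LGST"))
  c(AT = sum(at), GC = sum(!at),
    A_on_LGST = sum(at & a_tmpl == "LGST"),
    A_on_LDST = sum(at & a_tmpl == "LDST"),
    C_on_LGST = sum(!at & c_tmpl == "LGST"),
    C_on_LDST = sum(!at & c_tmpl == "LDST"))
}

#' Conditional rate table for the standard mutation classes
#'
#' @param catalog A `mutation_catalog`.
#' @param genome A [genome_annotation()].
#' @param meta Experiment metadata (per-line generations).
#' @param scope Label recorded in the output (default "genome").
#' @return `data.frame` with one row per class (`bps`, `indel`, `ts_at`,
#'   `ts_gc`, `tv_at`, `tv_gc`): count, exposure components, rate, and 95%
#'   confidence limits.
#' @export
rate_table <- function(catalog, genome, meta, scope = "genome") {
  gens <- total_exposure(meta)
  tg <- nt_targets(genome)
  classes <- list(
    bps = list(n = sum(catalog$kind == "BPS"), nt = genome$length),
    indel = list(n = sum(catalog$kind != "BPS"), nt = genome$length),
    ts_at = list(n = sum(catalog$kind == "BPS" &
                           catalog$change_class == "transition" &
                           catalog$pair_class == "AT"), nt = tg[["AT"]]),
    ts_gc = list(n = sum(catalog$kind == "BPS" &
                           catalog$change_class == "transition" &
                           catalog$pair_class == "GC"), nt = tg[["GC"]]),
    tv_at = list(n = sum(catalog$kind == "BPS" &
                           catalog$change_class == "transversion" &
                           catalog$pair_class == "AT"), nt = tg[["AT"]]),
    tv_gc = list(n = sum(catalog$kind == "BPS" &
                           catalog$change_class == "transversion" &
                           catalog$pair_class == "GC"), nt = tg[["GC"]]))
  rows <- lapply(names(classes), function(nm) {
    cl <- classes[[nm]]
    r <- conditional_rate(cl$n, gens, cl$nt)
    data.frame(scope = scope, class = nm, count = cl$n, generations = gens,
               nt_target = cl$nt, rate = r$rate, ci_low = r$ci_low,
               ci_high = r$ci_high, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
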