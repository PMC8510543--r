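#' Configuration for the synthetic mutation-accumulation generator
#'
#' Defaults describe a desk-scale analogue of a mismatch-repair-deficient
#' bacterial MA study: a 500 kb circular genome at 50% GC with 500
#' non-overlapping genes (~55% codirectional with replication, CDS lengths
#' roughly normal around 900 nt), 200 independent lines propagated for 1,000
#' generations each, transition rates of order 1e-8 per base pair per
#' generation with a 2-fold lagging-strand-template placement bias, rare
#' transversions, and an indel rate that grows exponentially with
#' mononucleotide-run length.
#'
#' Scenario presets:
#' \describe{
#'   \item{null}{No placement bias (`strand_bias_rho = 1`), no hotspots: the
#'     negative-control genome in which CD and HO genes are exchangeable.}
#'   \item{strand_bias}{Placement bias `rho = 2` (the defaults).}
#'   \item{trna_artifact}{Additionally plants four identical short
#'     "tRNA-like" genes, each carrying an 8 bp and a 5 bp G·C run, three
#'     head-on and one codirectional, labels an E. coli-like tRNA cohort
#'     (51 CD + 31 HO ordinary members), forces the hotspot genes into the
#'     top expression stratum, and raises the run-indel scale
#'     (`indel_mu0 = 2e-7`) so the hotspots accumulate tens of indels at
#'     the default exposure.}
#'   \item{expression_coupled}{Scales each gene's BPS rate by
#'     `exp(expr_beta * z)` where `z` is the gene's standardized mean
#'     log10(TPM) (`expr_beta = 0.5`), to exercise the correlation
#'     machinery.}
#' }
#'
#' @param scenario One of "null", "strand_bias", "trna_artifact",
#'   "expression_coupled".
#' @param seed Integer seed; every generator call derives its stream from it.
#' @param genome_length,gc_content,n_genes,cd_fraction Genome geometry.
#' @param gene_length_mean,gene_length_sd,gene_length_min CDS length model
#'   (truncated normal, nt).
#' @param n_lines,generations_per_line MA design.
#' @param mu_ts_AT,mu_ts_GC Transition rates per base pair per generation at
#'   LDST placement of the informative base; multiplied by
#'   `strand_bias_rho` when that base is on the LGST.
#' @param strand_bias_rho LGST/LDST transition rate ratio.
#' @param mu_tv Transversion rate per base pair per generation.
#' @param indel_mu0,indel_b,indel_l0 Run-indel model: a run of length l
#'   mutates at `indel_mu0 * indel_b^(l - indel_l0)` per generation.
#' @param indel_run_cap Run length at which the exponential growth
#'   saturates (default 8); without a cap a single long natural run would
#'   dominate the whole catalog.
#' @param indel_bg Background (non-run) indel rate per nt per generation.
#' @param tpm_mu,tpm_sd,tpm_gene_sd Expression model: per-phase log10(TPM)
#'   is `N(tpm_mu, tpm_sd)` plus a per-gene effect `N(0, tpm_gene_sd)`.
#' @param expr_beta Expression coupling of BPS rates (0 = none).
#' @return Object of class `sim_config` (a list of the above).
#' @export
sim_config <- function(scenario = c("null", "strand_bias", "trna_artifact",
                                    "expression_coupled"),
                       seed = 1L,
                       genome_length = 500000L, gc_content = 0.5,
                       n_genes = 500L, cd_fraction = 0.55,
                       gene_length_mean = 900, gene_length_sd = 300,
                       gene_length_min = 120L,
                       n_lines = 200L, generations_per_line = 1000,
                       mu_ts_AT = 1.2e-8, mu_ts_GC = 6e-9,
                       strand_bias_rho = 2, mu_tv = 1e-9,
                       indel_mu0 = 1e-9, indel_b = 10, indel_l0 = 5,
                       indel_run_cap = 8L, indel_bg = 5e-11,
                       tpm_mu = 1.3, tpm_sd = 0.5, tpm_gene_sd = 0.3,
                       expr_beta = 0) {
  scenario <- match.arg(scenario)
  cfg <- as.list(environment())
  if (scenario == "null") cfg$strand_bias_rho <- 1
  if (scenario == "trna_artifact") cfg$indel_mu0 <- 2e-7
  if (scenario == "expression_coupled") cfg$expr_beta <- 0.5
  stopifnot(cfg$strand_bias_rho > 0, cfg$cd_fraction >= 0,
            cfg$cd_fraction <= 1,
            all(c(cfg$mu_ts_AT, cfg$mu_ts_GC, cfg$mu_tv, cfg$indel_mu0,
                  cfg$indel_bg) >= 0))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config [%s]: %d bp genome, %d genes, %d lines x %g gen\n",
              x$scenario, x$genome_length, x$n_genes, x$n_lines,
              x$generations_per_line))
  invisible(x)
}

# gene-sense sequence of the planted hotspot gene: 120 nt with one 8 bp and
# one 5 bp G.C run (C-runs on the gene sense strand), no other run >= 4
hotspot_gene_sequence <- function() {
  paste0("ATGACGTACGTACCCCCCCCTAGTACGATCGATACGTAGCTAGCATGCAT",
         "GACTGCACCCCCTGATCGTACGTGCATGCATACGATCGTAGCATGCGTAC",
         "GATCAGTCATGCAGTCGTAA")
}

rev_comp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Generate a synthetic circular genome with annotation
#'
#' Draws a random sequence at the configured GC content, places
#' non-overlapping genes around the circle (gaps distributed randomly, so
#' placement is uniform in expectation), chooses each gene's strand so that
#' it is codirectional with replication with probability `cd_fraction`, and
#' puts a promoter TSS 25 nt upstream of each CDS. Under the
#' `trna_artifact` scenario, four genes become identical "tRNA-like"
#' hotspot genes (named leuP/leuQ/leuV head-on and leuT codirectional) and
#' a cohort of ordinary genes is labeled tRNA (51 CD + 31 HO).
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A [genome_annotation()]. Hotspot gene ids (if any) are in
#'   attribute `hotspot_ids`.
#' @export
generate_genome <- function(config, seed = config$seed) {
  set.seed(seed)
  L <- config$genome_length
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq_chars <- sample(names(p), L, replace = TRUE, prob = p)

  ng <- config$n_genes
  lens <- integer(0)
  while (length(lens) < ng) {
    draw <- round(stats::rnorm(ng, config$gene_length_mean,
                               config$gene_length_sd))
    lens <- c(lens, draw[draw >= config$gene_length_min])
  }
  lens <- as.integer(lens[seq_len(ng)])
  total <- sum(lens)
  if (total > 0.95 * L) {
    stop("infeasible packing: genes occupy >95% of the genome")
  }
  gap_total <- L - total
  w <- stats::rexp(ng)
  gaps <- floor(gap_total * w / sum(w))
  gaps[1] <- gaps[1] + (gap_total - sum(gaps))  # keep the circle exact
  starts <- integer(ng); pos <- 1L
  for (i in seq_len(ng)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  ends <- starts + lens - 1L

  genes <- data.frame(gene_id = sprintf("g%04d", seq_len(ng)),
                      name = sprintf("g%04d", seq_len(ng)),
                      start = starts, end = ends, strand = "+",
                      stringsAsFactors = FALSE)
  # strand choice targets the CD fraction: decide CD/HO per gene, then set
  # the strand that realizes it given the replichore of the midpoint
  mid <- circular_midpoint(starts, lens, L)
  half <- ((1L - 1L + L %/% 2L) %% L) + 1L
  repl_right <- ((mid - 1L) %% L) < ((half - 1L) %% L)
  want_cd <- stats::runif(ng) < config$cd_fraction
  genes$strand <- ifelse(want_cd == repl_right, "+", "-")

  categories <- rep("", ng)
  hotspot_ids <- character(0)
  if (config$scenario == "trna_artifact") {
    hseq <- hotspot_gene_sequence()
    hlen <- nchar(hseq)
    is_ho <- (genes$strand == "+") != repl_right
    # hotspot genes must sit well inside a replichore so that shrinking the
    # CDS to the hotspot length cannot move the midpoint across a boundary
    margin <- 5000L
    boundary_dist <- pmin((mid - 1L) %% L, (1L - mid) %% L,
                          (mid - half) %% L, (half - mid) %% L)
    interior <- boundary_dist > margin
    ho_idx <- which(is_ho & interior)
    cd_idx <- which(!is_ho & interior)
    stopifnot(length(ho_idx) >= 34, length(cd_idx) >= 52)
    hot <- c(ho_idx[1:3], cd_idx[1])
    for (k in seq_along(hot)) {
      i <- hot[k]
      genes$end[i] <- genes$start[i] + hlen - 1L  # shrink to hotspot length
      s <- if (genes$strand[i] == "+") hseq else rev_comp(hseq)
      seq_chars[genes$start[i]:genes$end[i]] <- strsplit(s, "")[[1]]
    }
    genes$name[hot] <- c("leuP", "leuQ", "leuV", "leuT")
    hotspot_ids <- genes$gene_id[hot]
    # ordinary tRNA cohort (E. coli-like 51 CD + 31 HO split), restricted to
    # genes free of long (>= 7 nt) runs: most real tRNAs lack long runs, and
    # a long natural run inside a cohort gene would be its own hotspot
    run_free <- vapply(seq_len(ng), function(i) {
      if (i %in% hot) return(FALSE)
      s <- paste(seq_chars[genes$start[i]:genes$end[i]], collapse = "")
      nrow(find_runs(s, min_len = 7L)) == 0
    }, logical(1))
    cd_pool <- setdiff(which(!is_ho & run_free), hot)
    ho_pool <- setdiff(which(is_ho & run_free), hot)
    stopifnot(length(cd_pool) >= 51, length(ho_pool) >= 31)
    ordinary <- c(cd_pool[1:51], ho_pool[1:31])
    categories[c(hot, ordinary)] <- "tRNA"
    categories[hot] <- "tRNA;hotspot"
  }
  genes$categories <- categories

  promoters <- data.frame(
    promoter_id = sprintf("p%04d", seq_len(ng)),
    tss_pos = ifelse(genes$strand == "+",
                     ((genes$start - 25L - 1L) %% L) + 1L,
                     ((genes$end + 25L - 1L) %% L) + 1L),
    strand = genes$strand, gene_id = genes$gene_id,
    stringsAsFactors = FALSE)

  g <- genome_annotation(paste(seq_chars, collapse = ""), genes, promoters,
                         origin_pos = 1L, genome_id = "sim_chr")
  attr(g, "hotspot_ids") <- hotspot_ids
  g
}

#' Generate a synthetic expression table
#'
#' Per-phase log10(TPM) values are drawn from a normal distribution with a
#' shared per-gene random effect, so the three phases are correlated as in
#' real transcriptomes. Hotspot genes (tRNA-like homologues) are forced
#' into the top expression stratum of every phase.
#'
#' @param genome A [generate_genome()] result.
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed + 1` when given.
#' @return The genome with `tpm_lag`, `tpm_log`, `tpm_stat` columns filled
#'   in `genome$genes`.
#' @export
generate_expression <- function(genome, config, seed = config$seed + 1L) {
  set.seed(seed)
  ng <- nrow(genome$genes)
  gene_eff <- stats::rnorm(ng, 0, config$tpm_gene_sd)
  for (phase in c("tpm_lag", "tpm_log", "tpm_stat")) {
    l <- stats::rnorm(ng, config$tpm_mu, config$tpm_sd) + gene_eff
    hot <- genome$genes$gene_id %in% attr(genome, "hotspot_ids")
    l[hot] <- config$tpm_mu + 2.5 * config$tpm_sd
    genome$genes[[phase]] <- 10^l
  }
  genome
}

# per-position transition rate vector and ref/alt assignment (internal)
transition_site_rates <- function(genome, config, gene_mult = NULL) {
  bases <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  pos <- seq_len(genome$length)
  repl_right <- classify_replichore(pos, genome) == "right"
  fwd_lgst <- repl_right  # forward strand is the LGST on the right replichore
  at <- bases %in% c("A", "T")
  # is the informative base (A or C) on the LGST at this site?
  carrier_fwd <- bases %in% c("A", "C")
  carrier_lgst <- ifelse(carrier_fwd, fwd_lgst, !fwd_lgst)
  rate <- ifelse(at, config$mu_ts_AT, config$mu_ts_GC) *
    ifelse(carrier_lgst, config$strand_bias_rho, 1)
  if (!is.null(gene_mult)) rate <- rate * gene_mult
  alt <- c(A = "G", G = "A", C = "T", T = "C")[bases]
  list(rate = rate, ref = bases, alt = unname(alt))
}

#' Simulate a mutation catalog over a synthetic genome
#'
#' Mutation counts are Poisson with exposure equal to the summed line
#' generations (MA designs minimize selection, so accumulation totals are
#' treated as selectively neutral). Transitions arise per base pair at the
#' configured class rate times the placement bias when the informative base
#' (A or C) lies on the lagging-strand template; transversions arise
#' uniformly; each mononucleotide run of length l gains or loses one base
#' (left-normalized to the run start) at rate `indel_mu0 *
#' indel_b^(l - indel_l0)`; non-run sites get the background indel rate.
#' Every event is assigned to a line in proportion to its generations, and
#' repeated hits at one site are recorded as separate rows.
#'
#' @param genome A [generate_genome()] (with expression if
#'   `config$expr_beta != 0`).
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed + 2` when given.
#' @return list with `catalog` (a validated `mutation_catalog`) and `meta`
#'   (per-line experiment metadata).
#' @export
simulate_mutations <- function(genome, config, seed = config$seed + 2L) {
  set.seed(seed)
  L <- genome$length
  gens <- config$n_lines * config$generations_per_line
  lines <- sprintf("L%03d", seq_len(config$n_lines))

  gene_mult <- NULL
  if (config$expr_beta != 0) {
    g <- genome$genes
    ltpm <- rowMeans(log10(cbind(g$tpm_lag, g$tpm_log, g$tpm_stat)),
                     na.rm = TRUE)
    if (all(is.finite(ltpm)) && stats::sd(ltpm) > 0) {
      z <- (ltpm - mean(ltpm)) / stats::sd(ltpm)
      gene_mult <- rep(1, L)
      for (i in seq_len(nrow(g))) {
        span <- if (g$wraps_origin[i]) c(g$start[i]:L, 1:g$end[i]) else
          g$start[i]:g$end[i]
        gene_mult[span] <- exp(config$expr_beta * z[i])
      }
    }
  }

  ts <- transition_site_rates(genome, config, gene_mult)
  if (max(ts$rate) > 1) stop("per-site transition rate exceeds 1 per generation")
  n_ts <- stats::rpois(1, sum(ts$rate) * gens)
  ts_pos <- if (n_ts > 0) {
    sample.int(L, n_ts, replace = TRUE, prob = ts$rate)
  } else integer(0)

  n_tv <- stats::rpois(1, config$mu_tv * L * gens)
  tv_pos <- if (n_tv > 0) sample.int(L, n_tv, replace = TRUE) else integer(0)
  tv_ref <- strsplit(genome$sequence, "", fixed = TRUE)[[1]][tv_pos]
  tv_choices <- list(A = c("C", "T"), C = c("A", "G"),
                     G = c("C", "T"), T = c("A", "G"))
  tv_alt <- vapply(tv_ref, function(b)
    sample(tv_choices[[b]], 1L), "", USE.NAMES = FALSE)

  runs <- find_runs(genome$sequence, min_len = 2L)
  eff_len <- pmin(runs$run_len, config$indel_run_cap)
  run_rate <- config$indel_mu0 * config$indel_b^(eff_len - config$indel_l0)
  n_run_events <- stats::rpois(nrow(runs), run_rate * gens)
  run_idx <- rep(seq_len(nrow(runs)), n_run_events)
  run_ins <- stats::runif(length(run_idx)) < 0.5

  in_run <- logical(L)
  if (nrow(runs) > 0) {
    in_run[unlist(mapply(seq, runs$start, runs$end, SIMPLIFY = FALSE))] <- TRUE
  }
  n_bg <- stats::rpois(1, config$indel_bg * sum(!in_run) * gens)
  bg_pos <- sample(which(!in_run), min(n_bg, sum(!in_run)), replace = TRUE)
  bg_ins <- stats::runif(length(bg_pos)) < 0.5
  bg_base <- strsplit(genome$sequence, "", fixed = TRUE)[[1]][bg_pos]

  rows <- list()
  if (n_ts > 0) {
    rows$ts <- data.frame(pos = ts_pos, ref = ts$ref[ts_pos],
                          alt = ts$alt[ts_pos], stringsAsFactors = FALSE)
  }
  if (n_tv > 0) {
    rows$tv <- data.frame(pos = tv_pos, ref = tv_ref, alt = tv_alt,
                          stringsAsFactors = FALSE)
  }
  if (length(run_idx) > 0) {
    rows$run <- data.frame(pos = runs$start[run_idx],
                           ref = ifelse(run_ins, "", runs$base[run_idx]),
                           alt = ifelse(run_ins, runs$base[run_idx], ""),
                           stringsAsFactors = FALSE)
  }
  if (length(bg_pos) > 0) {
    rows$bg <- data.frame(pos = bg_pos,
                          ref = ifelse(bg_ins, "", bg_base),
                          alt = ifelse(bg_ins, bg_base, ""),
                          stringsAsFactors = FALSE)
  }
  muts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  n <- nrow(muts)
  muts$experiment_id <- rep("sim", n)
  muts$line_id <- if (n > 0) sample(lines, n, replace = TRUE) else character(0)
  muts$mutation_id <- if (n > 0) sprintf("sim%06d", seq_len(n)) else character(0)

  meta <- data.frame(experiment_id = "sim", line_id = lines,
                     generations = config$generations_per_line,
                     genotype_tags = "MMR_minus", stringsAsFactors = FALSE)
  list(catalog = mutation_catalog(muts, genome), meta = meta)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: genome, expression table, and mutation catalog for a
#' scenario, all derived from one seed.
#'
#' @param config A [sim_config()].
#' @return list: `genome` (annotation with TPM columns), `catalog`, `meta`,
#'   `hotspot_ids`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- generate_genome(config)
  genome <- generate_expression(genome, config)
  sim <- simulate_mutations(genome, config)
  list(genome = genome, catalog = sim$catalog, meta = sim$meta,
       hotspot_ids = attr(genome, "hotspot_ids"), config = config)
}

#' Write a synthetic dataset to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `gene_meta.tsv`, `mutations.tsv`,
#' `experiments.tsv`, and `manifest.json` into a directory.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(dataset$genome, dir)
  write_catalog(dataset$catalog, file.path(dir, "mutations.tsv"))
  utils::write.table(dataset$meta, file.path(dir, "experiments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(scenario = dataset$config$scenario,
                   seed = dataset$config$seed,
                   genome_length = dataset$genome$length,
                   n_genes = nrow(dataset$genome$genes),
                   n_mutations = nrow(dataset$catalog),
                   hotspot_ids = dataset$hotspot_ids)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
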