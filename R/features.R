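#' Assign mutations to gene coding sequences
#'
#' Every mutation is assigned to each CDS whose interval contains its
#' position (for indels, the position of the first affected base after
#' left-normalization). Mutations inside no CDS are flagged intergenic;
#' mutations inside several overlapping CDSs increment each of them, and the
#' number of such multi-assigned mutations is reported, so counts are
#' conserved: unique + multi + intergenic = catalog size.
#'
#' Per-gene transition counts are additionally split by the placement of the
#' mutated purine/pyrimidine: whether the A (A·T transitions) or the C (G·C
#' transitions) sits on the lagging-strand template (LGST) or the
#' leading-strand template (LDST) — see [classify_transition_placement()].
#'
#' @param catalog A `mutation_catalog`.
#' @param genome A [genome_annotation()].
#' @return list with elements:
#'   \describe{
#'     \item{gene_counts}{`data.frame`, one row per gene: `n_bps`, `n_indel`,
#'       `n_ts_at`, `n_ts_gc`, `n_tv_at`, `n_tv_gc`, `n_a_lgst`, `n_a_ldst`,
#'       `n_c_lgst`, `n_c_ldst`, plus `cds_length` and orientation columns.}
#'     \item{assignments}{`data.frame` mapping `mutation_id` to `gene_id`
#'       (one row per hit; intergenic mutations absent).}
#'     \item{n_intergenic,n_multi}{Bookkeeping counts.}
#'   }
#' @export
assign_to_cds <- function(catalog, genome) {
  g <- genome$genes
  ori <- classify_orientation(genome)
  L <- genome$length

  # split wrapped genes into two linear segments for interval overlap
  seg_gene <- rep(seq_len(nrow(g)), ifelse(g$wraps_origin, 2L, 1L))
  seg_start <- integer(0); seg_end <- integer(0)
  if (nrow(g) > 0) {
    seg_start <- unlist(mapply(function(s, e, w) if (w) c(s, 1L) else s,
                               g$start, g$end, g$wraps_origin))
    seg_end <- unlist(mapply(function(s, e, w) if (w) c(L, e) else e,
                             g$start, g$end, g$wraps_origin))
  }
  q <- IRanges::IRanges(start = catalog$pos, width = 1L)
  s <- IRanges::IRanges(start = seg_start, end = seg_end)
  hits <- IRanges::findOverlaps(q, s)
  mut_idx <- S4Vectors::queryHits(hits)
  gene_idx <- seg_gene[S4Vectors::subjectHits(hits)]

  assignments <- data.frame(mutation_id = catalog$mutation_id[mut_idx],
                            gene_id = g$gene_id[gene_idx],
                            stringsAsFactors = FALSE)
  hits_per_mut <- tabulate(mut_idx, nbins = nrow(catalog))
  n_intergenic <- sum(hits_per_mut == 0L)
  n_multi <- sum(hits_per_mut > 1L)

  ng <- nrow(g)
  cnt <- function(keep) tabulate(gene_idx[keep[mut_idx]], nbins = ng)
  is_bps <- catalog$kind == "BPS"
  is_ts <- !is.na(catalog$change_class) & catalog$change_class == "transition"
  is_tv <- !is.na(catalog$change_class) & catalog$change_class == "transversion"
  at <- !is.na(catalog$pair_class) & catalog$pair_class == "AT"
  gc <- !is.na(catalog$pair_class) & catalog$pair_class == "GC"

  placement <- rep(NA_character_, nrow(catalog))
  if (any(is_ts)) {
    placement[is_ts] <- classify_transition_placement(
      catalog[is_ts, , drop = FALSE], genome)
  }

  gene_counts <- data.frame(
    gene_id = g$gene_id,
    cds_length = g$cds_length,
    orientation = ori$orientation[match(g$gene_id, ori$gene_id)],
    replichore = ori$replichore[match(g$gene_id, ori$gene_id)],
    n_bps = cnt(is_bps),
    n_indel = cnt(!is_bps),
    n_ts_at = cnt(is_ts & at),
    n_ts_gc = cnt(is_ts & gc),
    n_tv_at = cnt(is_tv & at),
    n_tv_gc = cnt(is_tv & gc),
    n_a_lgst = cnt(!is.na(placement) & placement == "A_on_LGST"),
    n_a_ldst = cnt(!is.na(placement) & placement == "A_on_LDST"),
    n_c_lgst = cnt(!is.na(placement) & placement == "C_on_LGST"),
    n_c_ldst = cnt(!is.na(placement) & placement == "C_on_LDST"),
    stringsAsFactors = FALSE)

  list(gene_counts = gene_counts, assignments = assignments,
       n_intergenic = n_intergenic, n_multi = n_multi)
}

#' Promoter analysis window around a TSS
#'
#' The window runs from 60 bp (by default) upstream of the transcription
#' start site to the TSS itself, on the promoter's own strand; 61 positions
#' in total. On a circular genome the window wraps.
#'
#' @param tss_pos 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param genome A [genome_annotation()].
#' @param width Upstream extent in nt (default 60).
#' @return Integer vector of the 1-based positions in the window (5' to 3'
#'   on the promoter strand).
#' @export
promoter_window <- function(tss_pos, strand, genome, width = 60L) {
  L <- genome$length
  tss_pos <- as.integer(tss_pos)
  stopifnot(tss_pos >= 1L, tss_pos <= L)
  raw <- if (strand == "+") (tss_pos - width):tss_pos else
    (tss_pos + width):tss_pos
  as.integer(((raw - 1L) %% L) + 1L)
}

#' Count mutations in promoter windows
#'
#' @param catalog A `mutation_catalog`.
#' @param genome A [genome_annotation()] with promoters.
#' @param width Upstream window width in nt (default 60).
#' @return `data.frame`, one row per promoter: `n_bps`, `n_indel`,
#'   orientation, and window coordinates.
#' @export
assign_to_promoters <- function(catalog, genome, width = 60L) {
  p <- genome$promoters
  ori <- classify_promoter_orientation(genome)
  n_bps <- integer(nrow(p)); n_indel <- integer(nrow(p))
  if (nrow(p) > 0 && nrow(catalog) > 0) {
    bps_pos <- catalog$pos[catalog$kind == "BPS"]
    ind_pos <- catalog$pos[catalog$kind != "BPS"]
    for (i in seq_len(nrow(p))) {
      win <- promoter_window(p$tss_pos[i], p$strand[i], genome, width)
      n_bps[i] <- sum(bps_pos %in% win)
      n_indel[i] <- sum(ind_pos %in% win)
    }
  }
  data.frame(promoter_id = p$promoter_id, tss_pos = p$tss_pos,
             strand = p$strand,
             orientation = ori$orientation[match(p$promoter_id,
                                                 ori$promoter_id)],
             n_bps = n_bps, n_indel = n_indel, stringsAsFactors = FALSE)
}

#' Find maximal mononucleotide runs
#'
#' @param sequence Character string over A/C/G/T.
#' @param min_len Minimum run length to report (default 5).
#' @return `data.frame` of maximal runs: `run_id`, `start`, `end`, `base`,
#'   `pair_class`, `run_len`.
#' @export
find_runs <- function(sequence, min_len = 5L) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    base = r$values[keep],
                    pair_class = ifelse(r$values[keep] %in% c("A", "T"),
                                        "AT", "GC"),
                    run_len = r$lengths[keep], stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  out$run_id <- if (nrow(out)) sprintf("run%05d", seq_len(nrow(out))) else
    character(0)
  rownames(out) <- NULL
  out[, c("run_id", "start", "end", "base", "pair_class", "run_len")]
}

#' Census of nucleotides by mononucleotide-run length
#'
#' For every run length present in the sequence, the fraction of all
#' nucleotides lying in maximal runs of exactly that length. The
#' length-weighted fractions sum to 1.
#'
#' @param sequence Character string over A/C/G/T.
#' @return `data.frame` with `run_len`, `n_runs`, `n_nt`, `nt_fraction`.
#' @export
run_census <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  r <- rle(chars)
  tab <- table(r$lengths)
  run_len <- as.integer(names(tab))
  n_runs <- as.integer(tab)
  n_nt <- run_len * n_runs
  data.frame(run_len = run_len, n_runs = n_runs, n_nt = n_nt,
             nt_fraction = n_nt / length(chars))
}

#' Assign indels to mononucleotide runs
#'
#' A left-normalized indel is attributed to a run when its position lies
#' within the run or at the position immediately 5' of it, and every
#' inserted/deleted base equals the run base. Indels matching no run are
#' labeled non-run.
#'
#' @param catalog A `mutation_catalog` (only indel rows are used).
#' @param runs Output of [find_runs()].
#' @return list with `mapping` (`mutation_id`, `run_id` or `NA`) and
#'   `run_counts` (`run_id`, `n_indel`), plus `n_non_run`.
#' @export
assign_indels_to_runs <- function(catalog, runs) {
  ind <- catalog[catalog$kind != "BPS", , drop = FALSE]
  run_id <- rep(NA_character_, nrow(ind))
  if (nrow(ind) > 0 && nrow(runs) > 0) {
    for (i in seq_len(nrow(ind))) {
      allele <- if (ind$kind[i] == "insertion") ind$alt[i] else ind$ref[i]
      bases <- unique(strsplit(allele, "", fixed = TRUE)[[1]])
      if (length(bases) != 1L) next  # mixed-base indel never run-compatible
      hit <- which(runs$base == bases &
                     ind$pos[i] >= runs$start - 1L & ind$pos[i] <= runs$end)
      if (length(hit) > 0) run_id[i] <- runs$run_id[hit[1]]
    }
  }
  counts <- table(factor(run_id, levels = runs$run_id))
  list(mapping = data.frame(mutation_id = ind$mutation_id, run_id = run_id,
                            stringsAsFactors = FALSE),
       run_counts = data.frame(run_id = runs$run_id,
                               n_indel = as.integer(counts),
                               stringsAsFactors = FALSE),
       n_non_run = sum(is.na(run_id)))
}

#' Strand placement of transition mutations
#'
#' For an A·T transition the informative base is the A; for a G·C transition
#' it is the C. If the forward-strand reference base is the informative base
#' itself, that base sits on the forward strand, otherwise on the reverse
#' strand; its placement is the template role (LDST/LGST) of the strand it
#' sits on at that position. Transition rates differ between the two
#' placements, which is what makes this labeling informative about
#' replication-error asymmetry.
#'
#' @param catalog A `mutation_catalog` containing only transition rows (or a
#'   subset thereof).
#' @param genome A [genome_annotation()].
#' @return Character vector over `A_on_LGST`, `A_on_LDST`, `C_on_LGST`,
#'   `C_on_LDST`.
#' @export
classify_transition_placement <- function(catalog, genome) {
  if (nrow(catalog) == 0) return(character(0))
  if (any(is.na(catalog$change_class) |
          catalog$change_class != "transition")) {
    stop("placement is defined only for transitions")
  }
  carrier_base <- ifelse(catalog$pair_class == "AT", "A", "C")
  carrier_strand <- ifelse(catalog$ref == carrier_base, "+", "-")
  tmpl <- strand_template(catalog$pos, carrier_strand, genome)
  paste0(carrier_base, "_on_", tmpl)
}

#' Scan promoters for -10 element hits at mutated T positions
#'
#' For each A·T transition within `max_upstream` nt upstream of a TSS whose
#' promoter-sense base is a T, searches for a hexamer on the promoter sense
#' strand whose 3' base is the mutated T and whose 3' end lies
#' `offset_range[1]`..`offset_range[2]` nt upstream of the TSS, scoring the
#' hexamer against the TATAAT consensus. A hit requires at least
#' `min_match` of 6 consensus matches (3' T included by construction).
#'
#' @param catalog A `mutation_catalog`.
#' @param genome A [genome_annotation()] with promoters.
#' @param max_upstream Scan window upstream of the TSS (default 20 nt).
#' @param offset_range Allowed distances of the hexamer 3' end from the TSS
#'   (default 5:9, i.e. the canonical T at -7 plus slack).
#' @param min_match Minimum consensus matches out of 6 (default 4).
#' @return `data.frame` of hits: `promoter_id`, `mutation_id`, `distance`
#'   (nt upstream of the TSS, so 7 means "T at -7"), `hexamer`, `n_match`,
#'   `orientation` (CD/HO of the promoter).
#' @export
scan_minus10 <- function(catalog, genome, max_upstream = 20L,
                         offset_range = c(5L, 9L), min_match = 4L) {
  p <- genome$promoters
  ori <- classify_promoter_orientation(genome)
  consensus <- strsplit("TATAAT", "")[[1]]
  L <- genome$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  ts <- catalog[!is.na(catalog$change_class) &
                  catalog$change_class == "transition" &
                  catalog$pair_class == "AT", , drop = FALSE]
  if (nrow(ts) == 0 || nrow(p) == 0) {
    return(data.frame(promoter_id = character(), mutation_id = character(),
                      distance = integer(), hexamer = character(),
                      n_match = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  sense_base_at <- function(pos, strand) {
    b <- genome_base(genome, pos)
    if (strand == "+") b else unname(comp[b])
  }
  for (i in seq_len(nrow(p))) {
    tss <- p$tss_pos[i]; strand <- p$strand[i]
    dirn <- if (strand == "+") 1L else -1L
    # upstream distance d of each transition: tss - pos on "+", pos - tss on "-"
    d_all <- (if (strand == "+") tss - ts$pos else ts$pos - tss) %% L
    cand <- which(d_all >= 1L & d_all <= max_upstream)
    for (j in cand) {
      d <- d_all[j]
      if (sense_base_at(ts$pos[j], strand) != "T") next
      if (d < offset_range[1] || d > offset_range[2]) next
      # hexamer with 3' end at the mutated T, read on the sense strand
      hex_pos <- ((ts$pos[j] + dirn * -(5:0) * 1L - 1L) %% L) + 1L
      hex <- vapply(hex_pos, sense_base_at, "", strand = strand)
      n_match <- sum(hex == consensus)
      if (n_match >= min_match) {
        hits[[length(hits) + 1L]] <- data.frame(
          promoter_id = p$promoter_id[i], mutation_id = ts$mutation_id[j],
          distance = as.integer(d), hexamer = paste(hex, collapse = ""),
          n_match = n_match,
          orientation = ori$orientation[match(p$promoter_id[i],
                                              ori$promoter_id)],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(promoter_id = character(), mutation_id = character(),
                      distance = integer(), hexamer = character(),
                      n_match = integer(), orientation = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Write mononucleotide runs as BED (0-based half-open)
#'
#' @param runs Output of [find_runs()].
#' @param genome A [genome_annotation()] (names the chromosome).
#' @param path Output BED path.
#' @export
write_runs_bed <- function(runs, genome, path) {
  bed <- data.frame(chrom = genome$genome_id, start = runs$start - 1L,
                    end = runs$end, name = runs$run_id,
                    score = runs$run_len, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
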