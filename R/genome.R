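#' Construct a circular genome annotation
#'
#' Bundles a circular bacterial genome sequence with its replication origin
#' and terminus and its gene and promoter annotation. All downstream
#' orientation calls (replichore, codirectional/head-on, leading/lagging
#' strand template) are derived from this object.
#'
#' Coordinates are 1-based inclusive on the forward strand (GFF3 convention).
#' When `terminus_pos` is not supplied it defaults to the position halfway
#' around the circle from the origin, `((origin_pos - 1 + floor(L/2)) %% L) + 1`,
#' which mirrors the standard practice of dividing the replichores at the
#' point opposite the origin, close to the terC terminus region.
#'
#' @param sequence Single character string over A/C/G/T (forward strand), or a
#'   `Biostrings::DNAStringSet` of length 1.
#' @param genes `data.frame` with columns `gene_id`, `start`, `end`, `strand`
#'   ("+" or "-"); optional columns `name`, `wraps_origin` (logical),
#'   `categories` (semicolon-joined tags), `tpm_lag`, `tpm_log`, `tpm_stat`.
#' @param promoters Optional `data.frame` with columns `promoter_id`,
#'   `tss_pos`, `strand`, and optionally `gene_id`.
#' @param origin_pos 1-based position of the replication origin.
#' @param terminus_pos 1-based position of the replication terminus, or `NULL`
#'   for the halfway default.
#' @param genome_id Identifier used in output files.
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id`, `length`, `origin_pos`, `terminus_pos`, `sequence`, `genes`
#'   (with derived `cds_length` and `midpoint` columns), `promoters`, and
#'   `is_circular = TRUE`.
#' @export
genome_annotation <- function(sequence, genes, promoters = NULL,
                              origin_pos = 1L, terminus_pos = NULL,
                              genome_id = "genome") {
  if (inherits(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    genome_id <- if (!is.null(names(sequence))) names(sequence)[1] else genome_id
    sequence <- as.character(sequence[[1]])
  }
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("genome sequence must be over {A,C,G,T}")
  }
  L <- nchar(sequence)
  origin_pos <- as.integer(origin_pos)
  if (is.null(terminus_pos)) {
    terminus_pos <- ((origin_pos - 1L + L %/% 2L) %% L) + 1L
  }
  terminus_pos <- as.integer(terminus_pos)
  if (origin_pos < 1L || origin_pos > L || terminus_pos < 1L || terminus_pos > L) {
    stop("origin/terminus positions must lie in [1, genome length]")
  }
  if (origin_pos == terminus_pos) stop("origin and terminus must differ")

  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "start", "end", "strand")
  if (nrow(genes) > 0 && !all(required %in% names(genes))) {
    stop("genes need columns: ", paste(required, collapse = ", "))
  }
  if (nrow(genes) == 0) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  nr <- nrow(genes)
  if (is.null(genes$name)) genes$name <- genes$gene_id
  if (is.null(genes$wraps_origin)) genes$wraps_origin <- rep(FALSE, nr)
  if (is.null(genes$categories)) genes$categories <- rep("", nr)
  for (col in c("tpm_lag", "tpm_log", "tpm_stat")) {
    if (is.null(genes[[col]])) genes[[col]] <- rep(NA_real_, nr)
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes) > 0) {
    if (any(genes$start < 1L | genes$start > L | genes$end < 1L | genes$end > L)) {
      stop("gene coordinates outside [1, genome length]")
    }
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
    # genes stated with start > end are treated as wrapping the circle
    genes$wraps_origin <- genes$wraps_origin | (genes$start > genes$end)
  }
  genes$cds_length <- ifelse(genes$wraps_origin,
                             L - genes$start + 1L + genes$end,
                             genes$end - genes$start + 1L)
  if (any(genes$cds_length <= 0L)) stop("zero or negative CDS length")
  genes$midpoint <- circular_midpoint(genes$start, genes$cds_length, L)

  if (is.null(promoters)) {
    promoters <- data.frame(promoter_id = character(), tss_pos = integer(),
                            strand = character(), gene_id = character(),
                            stringsAsFactors = FALSE)
  } else {
    promoters <- as.data.frame(promoters, stringsAsFactors = FALSE)
    stopifnot(all(c("promoter_id", "tss_pos", "strand") %in% names(promoters)))
    if (is.null(promoters$gene_id)) promoters$gene_id <- NA_character_
    promoters$tss_pos <- as.integer(promoters$tss_pos)
    if (nrow(promoters) > 0 &&
        any(promoters$tss_pos < 1L | promoters$tss_pos > L)) {
      stop("promoter TSS outside [1, genome length]")
    }
  }

  structure(list(genome_id = genome_id, length = L,
                 origin_pos = origin_pos, terminus_pos = terminus_pos,
                 sequence = sequence, genes = genes, promoters = promoters,
                 is_circular = TRUE),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("Circular genome annotation:", x$genome_id, "\n")
  cat(sprintf("  length %d bp; origin %d; terminus %d\n",
              x$length, x$origin_pos, x$terminus_pos))
  cat(sprintf("  %d genes, %d promoters\n", nrow(x$genes), nrow(x$promoters)))
  invisible(x)
}

# circular midpoint of an interval given its start and length (1-based)
circular_midpoint <- function(start, len, L) {
  if (length(start) == 0) return(integer())
  as.integer(((start - 1L + (len - 1L) %/% 2L) %% L) + 1L)
}

#' Classify positions by replichore
#'
#' A position belongs to the right replichore if it lies on the arc traversed
#' from the origin in the direction of increasing coordinates (wrapping at the
#' genome length) up to, but not including, the terminus; otherwise it belongs
#' to the left replichore. The origin itself is "right" and the terminus
#' "left".
#'
#' @param pos Vector of 1-based positions.
#' @param genome A [genome_annotation()].
#' @return Character vector, `"right"` or `"left"`.
#' @export
classify_replichore <- function(pos, genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  pos <- as.integer(pos)
  L <- genome$length
  if (any(pos < 1L | pos > L)) stop("position out of range [1, ", L, "]")
  off <- (pos - genome$origin_pos) %% L
  off_ter <- (genome$terminus_pos - genome$origin_pos) %% L
  ifelse(off < off_ter, "right", "left")
}

#' Leading/lagging strand template role of a strand at a position
#'
#' On the right replichore the fork travels in the direction of increasing
#' coordinates, so the reverse strand templates the leading strand (LDST) and
#' the forward strand templates the lagging strand (LGST); the assignment is
#' mirrored on the left replichore. This is the unique assignment under which
#' a codirectionally transcribed gene's template strand is the LDST and a
#' head-on gene's template strand is the LGST.
#'
#' @param pos Vector of 1-based positions.
#' @param strand `"+"`/`"-"` (recycled against `pos`).
#' @param genome A [genome_annotation()].
#' @return Character vector, `"LDST"` or `"LGST"`.
#' @export
strand_template <- function(pos, strand, genome) {
  repl <- classify_replichore(pos, genome)
  strand <- rep_len(as.character(strand), length(repl))
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ifelse((repl == "right") == (strand == "+"), "LGST", "LDST")
}

#' Classify genes as codirectional or head-on to replication
#'
#' A gene transcribed in the direction of fork travel is codirectional (CD);
#' one transcribed against it is head-on (HO). Concretely, forward-strand
#' genes on the right replichore and reverse-strand genes on the left
#' replichore are CD; the opposite combinations are HO. The replichore of a
#' gene is decided by its circular CDS midpoint, so boundary-spanning genes
#' get a deterministic, order-independent call. The transcribed (template)
#' strand of a CD gene is the leading-strand template (LDST); of an HO gene,
#' the lagging-strand template (LGST).
#'
#' @param genome A [genome_annotation()].
#' @return `data.frame` with one row per gene: `gene_id`, `replichore`,
#'   `orientation` ("CD"/"HO"), `transcribed_strand_template` ("LDST"/"LGST").
#' @export
classify_orientation <- function(genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  g <- genome$genes
  if (nrow(g) == 0) {
    return(data.frame(gene_id = character(), replichore = character(),
                      orientation = character(),
                      transcribed_strand_template = character(),
                      stringsAsFactors = FALSE))
  }
  repl <- classify_replichore(g$midpoint, genome)
  cd <- (g$strand == "+") == (repl == "right")
  data.frame(gene_id = g$gene_id,
             replichore = repl,
             orientation = ifelse(cd, "CD", "HO"),
             transcribed_strand_template = ifelse(cd, "LDST", "LGST"),
             stringsAsFactors = FALSE)
}

#' Count codirectional and head-on genes
#'
#' @param genome A [genome_annotation()].
#' @return Named integer vector with elements `n_CD` and `n_HO`.
#' @export
partition_counts <- function(genome) {
  ori <- classify_orientation(genome)
  c(n_CD = sum(ori$orientation == "CD"),
    n_HO = sum(ori$orientation == "HO"))
}

#' Orientation of a promoter relative to replication
#'
#' Same geometric rule as for genes, applied at the TSS position.
#'
#' @param genome A [genome_annotation()].
#' @return `data.frame` with `promoter_id`, `replichore`, `orientation`.
#' @export
classify_promoter_orientation <- function(genome) {
  p <- genome$promoters
  if (nrow(p) == 0) {
    return(data.frame(promoter_id = character(), replichore = character(),
                      orientation = character(), stringsAsFactors = FALSE))
  }
  repl <- classify_replichore(p$tss_pos, genome)
  cd <- (p$strand == "+") == (repl == "right")
  data.frame(promoter_id = p$promoter_id, replichore = repl,
             orientation = ifelse(cd, "CD", "HO"), stringsAsFactors = FALSE)
}

#' Read a genome annotation from FASTA + GFF3 (+ optional gene metadata)
#'
#' The FASTA must contain a single record (the circular chromosome, forward
#' strand). Gene features are taken from GFF3 rows of type `gene` (or `CDS`
#' where no `gene` rows exist); promoters from rows of type `promoter` or
#' `TSS` (the TSS is the feature start for "+" and the feature end for "-").
#' `gene_meta` is a TSV sidecar with columns `gene_id`, `categories`
#' (semicolon-joined), `tpm_lag`, `tpm_log`, `tpm_stat`.
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to the GFF3 annotation.
#' @param gene_meta Optional path to the gene metadata TSV.
#' @param origin_pos,terminus_pos Replication origin/terminus (1-based);
#'   terminus defaults to halfway around the circle.
#' @return A [genome_annotation()].
#' @export
read_genome <- function(fasta, gff, gene_meta = NULL,
                        origin_pos = 1L, terminus_pos = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected a single FASTA record")
  feats <- as.data.frame(rtracklayer::import(gff))
  type <- as.character(feats$type)
  gene_rows <- feats[type == "gene", , drop = FALSE]
  if (nrow(gene_rows) == 0) gene_rows <- feats[type == "CDS", , drop = FALSE]
  ids <- if (!is.null(gene_rows$ID)) as.character(gene_rows$ID) else
    sprintf("gene%04d", seq_len(nrow(gene_rows)))
  L <- Biostrings::width(seqs)[1]
  gend <- gene_rows$end
  wraps <- gend > L
  gend[wraps] <- gend[wraps] - L
  genes <- data.frame(gene_id = ids,
                      name = if (!is.null(gene_rows$Name))
                        as.character(gene_rows$Name) else ids,
                      start = gene_rows$start, end = gend,
                      strand = as.character(gene_rows$strand),
                      wraps_origin = wraps,
                      stringsAsFactors = FALSE)
  prom_rows <- feats[type %in% c("promoter", "TSS"), , drop = FALSE]
  promoters <- NULL
  if (nrow(prom_rows) > 0) {
    pstrand <- as.character(prom_rows$strand)
    promoters <- data.frame(
      promoter_id = if (!is.null(prom_rows$ID)) as.character(prom_rows$ID) else
        sprintf("prom%04d", seq_len(nrow(prom_rows))),
      tss_pos = ifelse(pstrand == "+", prom_rows$start, prom_rows$end),
      strand = pstrand,
      gene_id = if (!is.null(prom_rows$Parent))
        vapply(prom_rows$Parent, function(x)
          if (length(x)) as.character(x)[1] else NA_character_, "") else
        NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!is.null(gene_meta)) {
    meta <- utils::read.delim(gene_meta, stringsAsFactors = FALSE)
    idx <- match(genes$gene_id, meta$gene_id)
    if (!is.null(meta$categories)) genes$categories <- meta$categories[idx]
    for (col in c("tpm_lag", "tpm_log", "tpm_stat")) {
      if (!is.null(meta[[col]])) genes[[col]] <- meta[[col]][idx]
    }
    genes$categories[is.na(genes$categories)] <- ""
  }
  genome_annotation(seqs, genes, promoters,
                    origin_pos = origin_pos, terminus_pos = terminus_pos,
                    genome_id = names(seqs)[1])
}

#' Write a genome annotation to FASTA + GFF3 + gene metadata TSV
#'
#' @param genome A [genome_annotation()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_genome <- function(genome, dir) {
  stopifnot(inherits(genome, "genome_annotation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  seq <- Biostrings::DNAStringSet(genome$sequence)
  names(seq) <- genome$genome_id
  Biostrings::writeXStringSet(seq, fa, width = 80L)

  g <- genome$genes
  p <- genome$promoters
  gff <- file.path(dir, "genes.gff3")
  # wrapped genes are exported with end = start + cds_length - 1 (> L);
  # read_genome folds ends beyond the genome length back onto the circle
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = g$start,
                              end = g$start + g$cds_length - 1L),
    strand = g$strand, type = "gene", ID = g$gene_id, Name = g$name)
  gr_prom <- if (nrow(p) > 0) GenomicRanges::GRanges(
    seqnames = genome$genome_id,
    ranges = IRanges::IRanges(start = p$tss_pos, end = p$tss_pos),
    strand = p$strand, type = "TSS", ID = p$promoter_id,
    Name = p$promoter_id) else NULL
  gr <- if (is.null(gr_prom)) gr_genes else c(gr_genes, gr_prom)
  rtracklayer::export(gr, gff, format = "gff3")

  meta <- file.path(dir, "gene_meta.tsv")
  utils::write.table(
    g[, c("gene_id", "categories", "tpm_lag", "tpm_log", "tpm_stat")],
    meta, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, gff = gff, gene_meta = meta))
}
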