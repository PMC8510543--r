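#' Classify a base-pair substitution
#'
#' Maps a (ref, alt) base pair to the mutated base-pair class (A·T or G·C,
#' by the reference base) and to transition versus transversion. A→G, T→C,
#' G→A, and C→T are transitions; the remaining eight ordered changes are
#' transversions, grouped into A·T and G·C transversions by pair class.
#'
#' @param ref,alt Vectors of single bases in A/C/G/T, `ref != alt`.
#' @return `data.frame` with columns `pair_class` ("AT"/"GC"),
#'   `change_class` ("transition"/"transversion"), and `canonical_label`
#'   (e.g. "AT_transition").
#' @export
classify_bps <- function(ref, alt) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("non-ACGT base in BPS classification")
  if (any(ref == alt)) stop("ref and alt must differ for a BPS")
  pair_class <- ifelse(ref %in% c("A", "T"), "AT", "GC")
  transition <- paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
  change_class <- ifelse(transition, "transition", "transversion")
  data.frame(pair_class = pair_class, change_class = change_class,
             canonical_label = paste(pair_class, change_class, sep = "_"),
             stringsAsFactors = FALSE)
}

# base at 1-based position(s) of the genome sequence
genome_base <- function(genome, pos) {
  substring(genome$sequence, pos, pos)
}

genome_substr <- function(genome, start, len) {
  substr(genome$sequence, start, start + len - 1L)
}

#' Left-normalize an indel against the genome
#'
#' Shifts an insertion or deletion to its leftmost equivalent position (the
#' VCF convention): while the base immediately 5' of the variant equals the
#' last base of the indel allele, the allele is rotated and the position
#' decremented. Within a homopolymer run this places the indel at the run
#' start, making run assignment deterministic.
#'
#' @param pos 1-based position of the first affected base (deletion) or of
#'   the base before which the insertion occurs (insertion).
#' @param allele The inserted or deleted bases (1-4 nt).
#' @param genome A [genome_annotation()].
#' @return list(pos = shifted position, allele = rotated allele).
#' @export
left_normalize_indel <- function(pos, allele, genome) {
  pos <- as.integer(pos)
  allele <- toupper(as.character(allele))
  len <- nchar(allele)
  while (pos > 1L && genome_base(genome, pos - 1L) == substr(allele, len, len)) {
    allele <- paste0(genome_base(genome, pos - 1L), substr(allele, 1L, len - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

#' Build and validate a mutation catalog
#'
#' Validates one-row-per-mutation records against the genome sequence,
#' classifies base-pair substitutions, left-normalizes indels, drops indels
#' longer than 4 bp (reported via the `n_rejected` attribute), and orders
#' rows by (pos, line_id). Insertions have an empty `ref`, deletions an
#' empty `alt`; either may be written `""` or `"-"` on input.
#'
#' @param x `data.frame` with columns `experiment_id`, `line_id`, `pos`,
#'   `ref`, `alt`; an optional `mutation_id` column is preserved.
#' @param genome A [genome_annotation()].
#' @return A `mutation_catalog`: a `data.frame` with columns `mutation_id`,
#'   `experiment_id`, `line_id`, `pos`, `kind` (BPS/insertion/deletion),
#'   `ref`, `alt`, `indel_len`, `pair_class`, `change_class`. Attribute
#'   `n_rejected` counts indels > 4 bp that were excluded.
#' @export
mutation_catalog <- function(x, genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("experiment_id", "line_id", "pos", "ref", "alt")
  if (!all(need %in% names(x))) {
    stop("mutation table needs columns: ", paste(need, collapse = ", "))
  }
  x$pos <- as.integer(x$pos)
  x$ref <- toupper(ifelse(is.na(x$ref) | x$ref == "-", "", x$ref))
  x$alt <- toupper(ifelse(is.na(x$alt) | x$alt == "-", "", x$alt))
  if (any(x$pos < 1L | x$pos > genome$length)) {
    stop("mutation position outside [1, genome length]")
  }
  kind <- ifelse(x$ref == "", "insertion",
          ifelse(x$alt == "", "deletion", "BPS"))
  indel_len <- ifelse(kind == "insertion", nchar(x$alt),
               ifelse(kind == "deletion", nchar(x$ref), 0L))

  too_long <- indel_len > 4L
  n_rejected <- sum(too_long)
  if (n_rejected > 0) {
    message(n_rejected, " indel(s) > 4 bp excluded from the catalog")
    x <- x[!too_long, , drop = FALSE]
    kind <- kind[!too_long]; indel_len <- indel_len[!too_long]
  }

  is_bps <- kind == "BPS"
  if (any(is_bps)) {
    bad <- is_bps & (nchar(x$ref) != 1L | nchar(x$alt) != 1L)
    if (any(bad)) {
      stop("multi-base substitution not supported at row(s) ",
           paste(which(bad), collapse = ", "))
    }
    obs <- genome_base(genome, x$pos[is_bps])
    mism <- obs != x$ref[is_bps]
    if (any(mism)) {
      stop("ref base does not match genome at row(s) ",
           paste(which(is_bps)[mism], collapse = ", "))
    }
    if (any(x$ref[is_bps] == x$alt[is_bps])) stop("BPS with ref == alt")
  }
  is_del <- kind == "deletion"
  if (any(is_del)) {
    obs <- mapply(function(p, l) genome_substr(genome, p, l),
                  x$pos[is_del], indel_len[is_del])
    mism <- obs != x$ref[is_del]
    if (any(mism)) {
      stop("deleted bases do not match genome at row(s) ",
           paste(which(is_del)[mism], collapse = ", "))
    }
  }

  # left-normalize indels
  is_indel <- kind != "BPS"
  if (any(is_indel)) {
    for (i in which(is_indel)) {
      allele <- if (kind[i] == "insertion") x$alt[i] else x$ref[i]
      nn <- left_normalize_indel(x$pos[i], allele, genome)
      x$pos[i] <- nn$pos
      if (kind[i] == "insertion") x$alt[i] <- nn$allele else x$ref[i] <- nn$allele
    }
  }

  cls <- data.frame(pair_class = NA_character_, change_class = NA_character_,
                    stringsAsFactors = FALSE)[rep(1L, nrow(x)), , drop = FALSE]
  if (any(is_bps)) {
    cls[is_bps, ] <- classify_bps(x$ref[is_bps], x$alt[is_bps])[
      , c("pair_class", "change_class")]
  }

  out <- data.frame(
    mutation_id = if (!is.null(x$mutation_id)) as.character(x$mutation_id) else
      sprintf("mut%06d", seq_len(nrow(x))),
    experiment_id = as.character(x$experiment_id),
    line_id = as.character(x$line_id),
    pos = x$pos, kind = kind, ref = x$ref, alt = x$alt,
    indel_len = as.integer(indel_len),
    pair_class = cls$pair_class, change_class = cls$change_class,
    stringsAsFactors = FALSE)
  out <- out[order(out$pos, out$line_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("mutation_catalog", "data.frame")
  out
}

#' Read a mutation catalog TSV
#'
#' @param path TSV with header columns `experiment_id`, `line_id`, `pos`,
#'   `ref`, `alt` (and optionally `mutation_id`).
#' @param genome A [genome_annotation()] to validate against.
#' @return A validated `mutation_catalog` (see [mutation_catalog()]).
#' @export
read_catalog <- function(path, genome) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  mutation_catalog(x, genome)
}

#' Write a mutation catalog TSV
#'
#' Writes the normalized catalog columns; reading the file back through
#' [read_catalog()] and writing again is byte-identical.
#'
#' @param catalog A `mutation_catalog`.
#' @param path Output TSV path.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("mutation_id", "experiment_id", "line_id", "pos", "ref", "alt")
  utils::write.table(as.data.frame(catalog)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a mutation catalog as minimal VCF 4.2
#'
#' Indels are anchored on the preceding reference base, as VCF requires.
#'
#' @param catalog A `mutation_catalog`.
#' @param genome The [genome_annotation()] the catalog was validated against.
#' @param path Output VCF path.
#' @export
export_vcf <- function(catalog, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genome$genome_id,
                       genome$length),
               paste0("##INFO=<ID=LINE,Number=1,Type=String,",
                      "Description=\"MA line\">"),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(catalog))) {
    p <- catalog$pos[i]
    if (catalog$kind[i] == "BPS") {
      ref <- catalog$ref[i]; alt <- catalog$alt[i]; vp <- p
    } else {
      vp <- max(1L, p - 1L)
      anchor <- genome_base(genome, vp)
      if (catalog$kind[i] == "insertion") {
        ref <- anchor; alt <- paste0(anchor, catalog$alt[i])
      } else {
        ref <- paste0(anchor, catalog$ref[i]); alt <- anchor
      }
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tLINE=%s",
                       genome$genome_id, vp, catalog$mutation_id[i],
                       ref, alt, catalog$line_id[i]), con)
  }
  invisible(path)
}

#' Read experiment metadata (per-line generation counts)
#'
#' @param path TSV with columns `experiment_id`, `line_id`, `generations`,
#'   and optionally `genotype_tags` (semicolon-joined).
#' @return `data.frame` of experiment metadata.
#' @export
read_experiments <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("experiment_id", "line_id", "generations") %in% names(m)))
  if (is.null(m$genotype_tags)) m$genotype_tags <- ""
  m$generations <- as.numeric(m$generations)
  m
}

#' Total generational exposure of a set of MA lines
#'
#' The sum of per-line generation counts; the denominator of all
#' per-generation mutation rates.
#'
#' @param meta `data.frame` with a `generations` column (one row per line).
#' @return Total generations (numeric scalar).
#' @export
total_exposure <- function(meta) {
  if (NROW(meta) == 0) stop("no experiment metadata supplied")
  g <- meta$generations
  if (any(!is.finite(g)) || any(g <= 0)) stop("generations must be positive")
  sum(g)
}
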