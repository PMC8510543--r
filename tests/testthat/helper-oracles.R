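# Independent brute-force oracles used across the tests. These deliberately
# re-derive results with naive algorithms rather than calling package code.

# replichore by literal walk: step +1 (wrapping) from the origin; positions
# visited before reaching the terminus are "right"
walk_replichore <- function(pos, origin, terminus, L) {
  cur <- origin
  while (cur != terminus) {
    if (cur == pos) return("right")
    cur <- (cur %% L) + 1L
  }
  "left"
}

# quadratic run census: for every position, walk left and right to find the
# maximal run containing it, then tabulate nucleotides per run length
brute_census <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  len_at <- integer(n)
  for (i in seq_len(n)) {
    l <- i
    while (l > 1 && ch[l - 1] == ch[i]) l <- l - 1
    r <- i
    while (r < n && ch[r + 1] == ch[i]) r <- r + 1
    len_at[i] <- r - l + 1L
  }
  tab <- table(len_at)
  data.frame(run_len = as.integer(names(tab)),
             n_nt = as.integer(tab),
             nt_fraction = as.integer(tab) / n)
}

# deterministic toy genome: fixed 120 bp sequence, origin 1, terminus 61
toy_genome <- function(genes = NULL, promoters = NULL) {
  set.seed(424242)
  s <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
             collapse = "")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = c("gR+", "gR-", "gL+", "gL-"),
                        start = c(10, 30, 70, 90),
                        end = c(20, 40, 80, 100),
                        strand = c("+", "-", "+", "-"),
                        stringsAsFactors = FALSE)
  }
  genome_annotation(s, genes, promoters, origin_pos = 1L,
                    terminus_pos = 61L, genome_id = "toy")
}

# genome with a fully specified sequence (for placement truth tables etc.)
literal_genome <- function(sequence, origin_pos = 1L, terminus_pos = NULL,
                           genes = NULL, promoters = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        stringsAsFactors = FALSE)
  }
  genome_annotation(sequence, genes, promoters, origin_pos = origin_pos,
                    terminus_pos = terminus_pos, genome_id = "literal")
}
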