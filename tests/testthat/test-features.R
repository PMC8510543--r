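test_that("find_runs reports maximal runs only", {
  runs <- find_runs("AAAAAGTTTTT", min_len = 5)
  expect_equal(runs$start, c(1L, 7L))
  expect_equal(runs$end, c(5L, 11L))
  expect_equal(runs$base, c("A", "T"))
  expect_equal(runs$pair_class, c("AT", "AT"))
  expect_equal(nrow(find_runs("ACGTACGT", min_len = 5)), 0)
})

test_that("run census matches a quadratic brute-force scan and sums to one", {
  census <- run_census("ACGTACGT")
  expect_equal(census$run_len, 1L)
  expect_equal(census$nt_fraction, 1)
  set.seed(11)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  census <- run_census(s)
  oracle <- brute_census(s)
  expect_equal(census$run_len, oracle$run_len)
  expect_equal(census$nt_fraction, oracle$nt_fraction)
  expect_equal(sum(census$nt_fraction), 1)
  expect_equal(sum(census$run_len * census$n_runs), 10000)
})

test_that("promoter windows span TSS-60..TSS on the promoter strand, with wrap", {
  empty <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), strand = character())
  g <- genome_annotation(strrep("A", 2000), empty)
  fwd <- promoter_window(1000, "+", g)
  expect_equal(length(fwd), 61)
  expect_equal(range(fwd), c(940, 1000))
  rev <- promoter_window(1000, "-", g)
  expect_equal(range(rev), c(1000, 1060))
  g100 <- genome_annotation(strrep("A", 100), empty)
  wrap <- promoter_window(30, "+", g100)
  expect_equal(length(wrap), 61)
  # circular oracle: walking back 60 steps from 30 passes through 70..100
  expect_setequal(wrap, c(70:100, 1:30))
})

test_that("CDS assignment conserves counts and handles overlaps and intergenic hits", {
  genes <- data.frame(gene_id = c("a", "b"), start = c(10, 25),
                      end = c(30, 45), strand = c("+", "+"))
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  g <- genome_annotation(s, genes, origin_pos = 1, terminus_pos = 51)
  base_at <- function(p) substr(s, p, p)
  alt_for <- function(b) c(A = "G", C = "T", G = "A", T = "C")[[b]]
  mk <- function(p) data.frame(experiment_id = "e", line_id = "l", pos = p,
                               ref = base_at(p), alt = alt_for(base_at(p)))
  cat <- mutation_catalog(rbind(mk(15), mk(28), mk(60)), g)
  res <- assign_to_cds(cat, g)
  expect_equal(res$gene_counts$n_bps, c(2L, 1L))  # pos 28 hits both genes
  expect_equal(res$n_multi, 1L)
  expect_equal(res$n_intergenic, 1L)
  # conservation: unique + multi + intergenic = catalog size
  hits_per_mut <- table(factor(res$assignments$mutation_id,
                               levels = cat$mutation_id))
  expect_equal(sum(hits_per_mut == 1) + sum(hits_per_mut > 1) +
                 res$n_intergenic, nrow(cat))
})

test_that("indel-to-run assignment equals an exhaustive compatibility check", {
  #         1.......9012345....902123456
  s <- paste0("GCTGCTGC", "AAAAAA", "GTCGT", "CCCCC", "ATGCATGC",
              "TTTTTTT", "GCGATGCA")
  g <- literal_genome(s)
  runs <- find_runs(s, min_len = 5)
  expect_equal(nrow(runs), 3)
  set.seed(21)
  pool <- data.frame(pos = sample(seq_len(nchar(s) - 1), 20, replace = TRUE),
                     base = sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                     ins = sample(c(TRUE, FALSE), 20, replace = TRUE))
  rows <- lapply(seq_len(20), function(i) {
    p <- pool$pos[i]; b <- pool$base[i]
    if (pool$ins[i]) {
      data.frame(experiment_id = "e", line_id = "l", pos = p, ref = "",
                 alt = b)
    } else {
      data.frame(experiment_id = "e", line_id = "l", pos = p,
                 ref = substr(s, p, p), alt = "")
    }
  })
  cat <- mutation_catalog(do.call(rbind, rows), g)
  res <- assign_indels_to_runs(cat, runs)
  ind <- as.data.frame(cat)[cat$kind != "BPS", ]
  # oracle: try every run, demand base identity and position in
  # [start-1, end] after normalization
  oracle <- vapply(seq_len(nrow(ind)), function(i) {
    allele <- if (ind$kind[i] == "insertion") ind$alt[i] else ind$ref[i]
    hit <- NA_character_
    for (r in seq_len(nrow(runs))) {
      if (allele == runs$base[r] && ind$pos[i] >= runs$start[r] - 1 &&
          ind$pos[i] <= runs$end[r]) { hit <- runs$run_id[r]; break }
    }
    hit
  }, "")
  expect_equal(res$mapping$run_id, oracle)
  expect_equal(sum(res$run_counts$n_indel) + res$n_non_run, nrow(ind))
  # targeted cases: matching insertion at run start is assigned,
  # mismatched base adjacent to a run is not
  plusA <- mutation_catalog(data.frame(experiment_id = "e", line_id = "l",
                                       pos = 9, ref = "", alt = "A"), g)
  expect_false(is.na(assign_indels_to_runs(plusA, runs)$mapping$run_id))
  plusG <- mutation_catalog(data.frame(experiment_id = "e", line_id = "l",
                                       pos = 15, ref = "", alt = "G"), g)
  expect_true(is.na(assign_indels_to_runs(plusG, runs)$mapping$run_id))
})

test_that("transition placement equals the exhaustive replichore x strand x base table", {
  # genome of length 100, origin 1, terminus 51: right = 1..50, left = 51..100
  # place known bases at right/left positions and enumerate all 8 cases
  ch <- rep("G", 100)
  ch[c(10, 60)] <- "A"; ch[c(11, 61)] <- "T"
  ch[c(12, 62)] <- "C"; ch[c(13, 63)] <- "G"
  g <- literal_genome(paste(ch, collapse = ""), origin_pos = 1,
                      terminus_pos = 51)
  mk <- function(p, ref, alt) mutation_catalog(
    data.frame(experiment_id = "e", line_id = "l", pos = p, ref = ref,
               alt = alt), g)
  # right replichore: forward strand is the LGST
  expect_equal(classify_transition_placement(mk(10, "A", "G"), g), "A_on_LGST")
  expect_equal(classify_transition_placement(mk(11, "T", "C"), g), "A_on_LDST")
  expect_equal(classify_transition_placement(mk(12, "C", "T"), g), "C_on_LGST")
  expect_equal(classify_transition_placement(mk(13, "G", "A"), g), "C_on_LDST")
  # left replichore: roles mirror
  expect_equal(classify_transition_placement(mk(60, "A", "G"), g), "A_on_LDST")
  expect_equal(classify_transition_placement(mk(61, "T", "C"), g), "A_on_LGST")
  expect_equal(classify_transition_placement(mk(62, "C", "T"), g), "C_on_LDST")
  expect_equal(classify_transition_placement(mk(63, "G", "A"), g), "C_on_LGST")
  # transversions are rejected
  expect_error(classify_transition_placement(mk(10, "A", "C"), g),
               "transitions")
})

test_that("placement classes partition the transitions", {
  cfg <- sim_config("strand_bias", seed = 31, genome_length = 20000L,
                    n_genes = 15L, n_lines = 10L,
                    generations_per_line = 1000,
                    mu_ts_AT = 2e-6, mu_ts_GC = 1e-6)
  ds <- simulate_dataset(cfg)
  ts <- ds$catalog[!is.na(ds$catalog$change_class) &
                     ds$catalog$change_class == "transition", ]
  pl <- classify_transition_placement(ts, ds$genome)
  expect_equal(sum(pl %in% c("A_on_LGST", "A_on_LDST")),
               sum(ts$pair_class == "AT"))
  expect_equal(sum(pl %in% c("C_on_LGST", "C_on_LDST")),
               sum(ts$pair_class == "GC"))
})

test_that("reverse-complementing the genome leaves pair-class and placement counts invariant", {
  cfg <- sim_config("strand_bias", seed = 41, genome_length = 10000L,
                    n_genes = 8L, n_lines = 5L, generations_per_line = 1000,
                    mu_ts_AT = 2e-6, mu_ts_GC = 1e-6)
  ds <- simulate_dataset(cfg)
  g <- ds$genome; L <- g$length
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(g$sequence, "")[[1]]]), collapse = "")
  grc <- literal_genome(rc, origin_pos = L - g$origin_pos + 1L,
                        terminus_pos = L - g$terminus_pos + 1L)
  ts <- as.data.frame(ds$catalog)[ds$catalog$change_class %in% "transition", ]
  ts2 <- data.frame(experiment_id = ts$experiment_id, line_id = ts$line_id,
                    pos = L - ts$pos + 1L,
                    ref = unname(comp[ts$ref]), alt = unname(comp[ts$alt]))
  cat2 <- mutation_catalog(ts2, grc)
  expect_equal(table(cat2$pair_class), table(ts$pair_class))
  p1 <- table(classify_transition_placement(
    mutation_catalog(ts, g), g))
  p2 <- table(classify_transition_placement(cat2, grc))
  expect_equal(as.vector(p2[names(p1)]), as.vector(p1))
})

test_that("the -10 element scan finds a TATAAT hit at T-7 and ignores far or non-T sites", {
  # build: TSS at 100 on "+"; hexamer TATAAT occupying 88..93 means its 3'
  # T is at distance 7 from the TSS (position 93)
  ch <- rep("G", 200)
  ch[88:93] <- c("T", "A", "T", "A", "A", "T")
  ch[70] <- "T"  # a far-upstream T (distance 30)
  g <- literal_genome(paste(ch, collapse = ""),
                      promoters = data.frame(promoter_id = "p1",
                                             tss_pos = 100, strand = "+",
                                             gene_id = NA))
  mk <- function(p, ref, alt) mutation_catalog(
    data.frame(experiment_id = "e", line_id = "l", pos = p, ref = ref,
               alt = alt), g)
  hit <- scan_minus10(mk(93, "T", "C"), g)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 7L)
  expect_equal(hit$hexamer, "TATAAT")
  expect_equal(hit$n_match, 6L)
  # outside the 20-nt scan window: no hit
  expect_equal(nrow(scan_minus10(mk(70, "T", "C"), g)), 0)
  # a G.C transition is never a T-7 candidate
  expect_equal(nrow(scan_minus10(mk(95, "G", "A"), g)), 0)
})
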