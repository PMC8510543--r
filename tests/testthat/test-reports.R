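test_that("highly expressed selection applies the mean + 1 SD log10(TPM) rule", {
  genes <- data.frame(gene_id = letters[1:5],
                      tpm_lag = c(10, 10, 10, 10, 10000),
                      tpm_log = c(10, 10, 10, 10, 11),
                      tpm_stat = c(0, 10, 10, 10, 11))
  # hand computation, lag phase: log10 = (1,1,1,1,4); mean = 1.6, sd ~ 1.342;
  # cutoff = 2.942 -> only gene e qualifies; other phases select nobody
  sub <- select_highly_expressed(genes)
  m <- mean(c(1, 1, 1, 1, 4)); s <- sd(c(1, 1, 1, 1, 4))
  expect_equal(sub$thresholds$cutoff[1], m + s)
  expect_equal(sub$gene_ids, "e")
  # a gene with zero TPM in all phases can never be selected
  genes2 <- rbind(genes, data.frame(gene_id = "z", tpm_lag = 0, tpm_log = 0,
                                    tpm_stat = 0))
  expect_false("z" %in% select_highly_expressed(genes2)$gene_ids)
  # the all-phases subset is contained in the any-phase subset
  set.seed(18)
  big <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    tpm_lag = 10^rnorm(200, 1, 0.5),
                    tpm_log = 10^rnorm(200, 1, 0.5),
                    tpm_stat = 10^rnorm(200, 1, 0.5))
  any_ids <- select_highly_expressed(big)$gene_ids
  all_ids <- select_highly_expressed(big, "all_phases")$gene_ids
  expect_true(all(all_ids %in% any_ids))
  expect_error(select_highly_expressed(transform(big, tpm_lag = 0,
                                                 tpm_log = 0, tpm_stat = 0)),
               "all-zero")
})

test_that("comparison rows do exact bookkeeping and reproduce the essential-gene worked example", {
  # 252 CD genes carrying 15 indels, 106 HO genes carrying 16
  freq <- data.frame(
    gene_id = sprintf("g%03d", 1:358),
    orientation = rep(c("CD", "HO"), c(252, 106)),
    indel_per_cds = c(rep(c(1, 0), c(15, 237)), rep(c(1, 0), c(16, 90))))
  tab <- comparison_table(freq, metrics = c(indel_per_cds = "Indels/CDS"))
  expect_equal(round(tab$mean_cd, 2), 0.06)
  expect_equal(round(tab$mean_ho, 2), 0.15)
  expect_equal(round(tab$delta_ho), 154)
  # mean x n recovers the integer counts exactly
  expect_equal(tab$mean_cd * tab$n_cd, 15)
  expect_equal(tab$mean_ho * tab$n_ho, 16)
  expect_equal(tab$mean_all * tab$n_all, 31)

  # identical CD and HO vectors: no excess, p = 1
  freq2 <- data.frame(gene_id = sprintf("h%02d", 1:20),
                      orientation = rep(c("CD", "HO"), each = 10),
                      indel_per_cds = rep(c(0, 1, 2, 3, 4), 4))
  tab2 <- comparison_table(freq2, metrics = c(indel_per_cds = "Indels/CDS"))
  expect_equal(tab2$delta_ho, 0)
  expect_equal(tab2$p_t, 1)

  # an empty orientation class yields a flagged row, not an error
  freq3 <- freq2[freq2$orientation == "CD", ]
  tab3 <- comparison_table(freq3, metrics = c(indel_per_cds = "Indels/CDS"))
  expect_equal(tab3$flag, "empty_class")
  expect_true(is.na(tab3$p_t))
})

test_that("one BH pass spans all tables of a run; a single comparison is unchanged", {
  t1 <- data.frame(p_t = c(0.01, 0.04), p_t_adj = NA_real_,
                   p_mw = c(0.02, NA), p_mw_adj = NA_real_)
  t2 <- data.frame(p_pearson = 0.03, p_pearson_adj = NA_real_)
  out <- adjust_report(list(a = t1, b = t2))
  expect_equal(attr(out, "family_size"), 4)
  fam <- c(0.01, 0.04, 0.02, 0.03)
  adj <- p.adjust(fam, "BH")
  expect_equal(out$a$p_t_adj, adj[1:2])
  expect_equal(out$a$p_mw_adj, c(adj[3], NA))
  expect_equal(out$b$p_pearson_adj, adj[4])

  single <- adjust_report(list(a = data.frame(p_t = 0.2, p_t_adj = NA_real_)))
  expect_equal(single$a$p_t_adj, 0.2)
})

test_that("correlation tables find built-in length proportionality and flag constants", {
  set.seed(19)
  n <- 400
  len <- pmax(100, round(rnorm(n, 900, 300)))
  freq <- data.frame(gene_id = sprintf("g%04d", 1:n),
                     orientation = sample(c("CD", "HO"), n, TRUE),
                     cds_length = len,
                     tpm_lag = 10^rnorm(n, 1, 0.5),
                     bps_per_cds = rpois(n, len * 6e-3),
                     indel_per_cds = rpois(n, 0.3))
  tab <- correlation_table(freq, "cds_length")
  row <- tab[tab$group == "All" & tab$metric_col == "bps_per_cds", ]
  expect_gt(row$rho_pearson, 0.5)
  expect_lt(row$p_pearson, 1e-6)
  # counts independent of expression: correlation near zero
  tab2 <- correlation_table(freq, "tpm_lag")
  row2 <- tab2[tab2$group == "All" & tab2$metric_col == "bps_per_cds", ]
  expect_lt(abs(row2$rho_pearson), 0.15)
  # constant predictor is flagged undefined
  freq$cds_length <- 500
  tab3 <- correlation_table(freq, "cds_length")
  expect_true(all(tab3$flag == "degenerate"))
  expect_true(all(is.na(tab3$rho_pearson)))
})

test_that("tRNA decomposition: homogeneous hotspot homologues, ratio bookkeeping, empty safety", {
  freq <- data.frame(
    gene_id = c("leuP", "leuQ", "leuV", "leuT", sprintf("t%02d", 1:10)),
    orientation = c("HO", "HO", "HO", "CD", rep(c("CD", "HO"), 5)),
    cds_length = 120,
    n_bps = 0L,
    n_indel = c(23L, 29L, 25L, 23L, rep(0L, 10)))
  sub <- structure(list(name = "tRNA", gene_ids = freq$gene_id),
                   class = "gene_subset")
  dec <- trna_decomposition(freq, sub,
                            hotspot_ids = c("leuP", "leuQ", "leuV", "leuT"))
  expect_equal(dec$total_indels, 100L)
  expect_equal(dec$hotspot_indels, 100L)
  expect_gt(dec$chisq_homogeneity$p, 0.05)
  # naive CD/HO means: HO genes (3 x ~25.7 + 5 zeros), CD (23 + 5 zeros)
  expect_equal(dec$ho_cd_ratio, mean(c(23, 29, 25, rep(0, 5))) /
                 mean(c(23, rep(0, 5))))
  empty <- trna_decomposition(freq[0, ], sub, character())
  expect_equal(empty$total_indels, 0L)
})

test_that("placement summary agrees with orientation-level relabeling on a toy catalog", {
  # all mutations inside genes whose template placement mapping is known:
  # for a transition inside a CDS, orientation CD <=> informative base
  # placements distribute by strand geometry; here we check the genome-wide
  # ratio machinery on a catalog with a constructed 2:1 placement split
  ch <- rep(c("A", "G"), 50)   # alternating A/G, L = 100
  g <- literal_genome(paste(ch, collapse = ""), origin_pos = 1,
                      terminus_pos = 51)
  # A at odd positions; right replichore (1..50): A on forward = LGST
  # left (51..100): A on forward = LDST
  pos_lgst <- seq(1, 49, 2)
  pos_ldst <- seq(51, 99, 2)
  mk_rows <- function(pos) data.frame(experiment_id = "e", line_id = "l",
                                      pos = pos, ref = "A", alt = "G")
  cat <- mutation_catalog(rbind(mk_rows(rep(pos_lgst, 2)),  # 50 events
                                mk_rows(pos_ldst[1:25])),   # 25 events
                          g)
  meta <- data.frame(experiment_id = "e", line_id = "l", generations = 1000)
  ps <- placement_summary(cat, g, meta)
  at <- ps$placement[ps$placement$pair_class == "AT", ]
  expect_equal(at$n_lgst, 50L)
  expect_equal(at$n_ldst, 25L)
  # equal targets on both templates here, so the rate ratio is 2
  expect_equal(at$nt_lgst, at$nt_ldst)
  expect_equal(at$ratio, 2)
  expect_true(at$ratio_ci_low < 2 && 2 < at$ratio_ci_high)
  expect_equal(sum(ps$placement_counts), nrow(cat))
})

test_that("the full report runs end to end and writes its files", {
  cfg <- sim_config("strand_bias", seed = 23, genome_length = 30000L,
                    n_genes = 25L, n_lines = 20L,
                    generations_per_line = 1000,
                    mu_ts_AT = 4e-7, mu_ts_GC = 2e-7, mu_tv = 4e-8)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  rep <- run_report(ds$genome, ds$catalog, ds$meta, out_dir = dir)
  expect_s3_class(rep, "ori_report")
  expect_true(all(file.exists(file.path(dir, c(
    "comparison_cd_ho.tsv", "correlations.tsv", "gene_counts.tsv",
    "promoter_counts.tsv", "rates.tsv", "placement.tsv", "run_census.tsv",
    "runs.bed", "manifest.json")))))
  expect_equal(sum(rep$partition), nrow(ds$genome$genes))
  # every mean x n in the comparison table is an integer count
  per_cds <- rep$comparison[rep$comparison$metric_col %in%
                              c("bps_per_cds", "indel_per_cds") &
                              rep$comparison$subset_name == "all_genes", ]
  expect_equal(per_cds$mean_all * per_cds$n_all,
               round(per_cds$mean_all * per_cds$n_all))
  # determinism: the same inputs give byte-identical tables
  dir2 <- withr::local_tempdir()
  run_report(ds$genome, ds$catalog, ds$meta, out_dir = dir2)
  expect_identical(readLines(file.path(dir, "comparison_cd_ho.tsv")),
                   readLines(file.path(dir2, "comparison_cd_ho.tsv")))
})
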