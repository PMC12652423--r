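# helper: minimal stats table for rule tests
stats_row <- function(chrom = "chr1", pos = 100, effect = "stop_gained",
                      gene_id = "gX", depth_mt = 20, depth_wt = 20,
                      idx_mt = 1, idx_wt = 1 / 3) {
  data.frame(chrom = chrom, pos = pos, ref = "C", alt = "T",
             effect = effect, gene_id = gene_id,
             depth_mt = depth_mt, depth_wt = depth_wt,
             snp_index_mt = idx_mt, snp_index_wt = idx_wt,
             d_value = idx_mt - idx_wt, stringsAsFactors = FALSE)
}

test_that("SNP index is the mutant-read fraction", {
  expect_equal(snp_index(12, 0), 1)
  expect_equal(snp_index(10, 20), 1 / 3)   # theoretical WT value at a causal locus
  expect_equal(snp_index(0, 7), 0)
  expect_error(snp_index(0, 0), "zero depth")
})

test_that("D-value is the index difference and stays in [-1, 1]", {
  expect_equal(d_value(1.0, 1 / 3), 2 / 3)
  expect_equal(d_value(0.95, 0.50), 0.45)
  x <- runif(50)
  expect_equal(d_value(x, x), rep(0, 50))
  set.seed(2)
  a <- runif(100); b <- runif(100)
  expect_true(all(abs(d_value(a, b)) <= 1))
})

test_that("linked-SNP selection uses strict depth and D comparisons", {
  s <- rbind(stats_row(pos = 1, depth_mt = 11, depth_wt = 11,
                       idx_mt = 0.85, idx_wt = 0.44),   # D = 0.41 -> linked
             stats_row(pos = 2, depth_mt = 10, depth_wt = 30,
                       idx_mt = 1, idx_wt = 0.1),       # depth 10 not > 10
             stats_row(pos = 3, depth_mt = 30, depth_wt = 30,
                       idx_mt = 0.7, idx_wt = 0.3))     # D = 0.4 not > 0.4
  out <- call_linked_snps(s)
  expect_equal(out$pos, 1)
})

test_that("linked subset matches brute-force re-evaluation on random stats", {
  set.seed(13)
  rec <- random_records(50, effects = TRUE)
  s <- linkage_stats(filter_high_confidence(rec,
         config = filter_config(min_coverage = 1, require_both_pools = FALSE))$records)
  cfg <- linkage_config(d_threshold = 0.1)
  out <- call_linked_snps(s, cfg)
  brute <- s[sapply(seq_len(nrow(s)), function(i)
    s$depth_mt[i] > cfg$min_linked_depth & s$depth_wt[i] > cfg$min_linked_depth &
    s$d_value[i] > cfg$d_threshold), ]
  expect_equal(out, brute)
})

test_that("chromosome localization reports single, multiple or none", {
  one <- rbind(stats_row(chrom = "chr5", pos = 1),
               stats_row(chrom = "chr5", pos = 2),
               stats_row(chrom = "chr5", pos = 3))
  cc <- localize_chromosome(one)
  expect_equal(cc$status, "single")
  expect_equal(cc$called_chromosomes, "chr5")
  expect_equal(unname(cc$counts), 3L)

  two <- rbind(stats_row(chrom = "chr2", pos = 1),
               stats_row(chrom = "chr6", pos = 2))
  cc2 <- localize_chromosome(two)
  expect_equal(cc2$status, "multiple")
  expect_setequal(cc2$called_chromosomes, c("chr2", "chr6"))

  cc3 <- localize_chromosome(one[0, ])
  expect_equal(cc3$status, "none")
  expect_length(cc3$called_chromosomes, 0L)
})

test_that("candidate rule needs high MT index, high D and a large effect", {
  pass <- stats_row(idx_mt = 0.95, idx_wt = 0.35)           # D = 0.6
  expect_equal(call_candidate_genes(pass)$gene_id, "gX")
  syn <- stats_row(idx_mt = 0.95, idx_wt = 0.35, effect = "synonymous_variant")
  expect_equal(nrow(call_candidate_genes(syn)), 0L)
  low_idx <- stats_row(idx_mt = 0.9, idx_wt = 0.2)          # 0.9 not > 0.9
  expect_equal(nrow(call_candidate_genes(low_idx)), 0L)
  no_gene <- stats_row(gene_id = NA)
  out <- call_candidate_genes(no_gene)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_no_gene"), 1L)
  # splice_region_variant counts once added to the large-effect set
  spl <- stats_row(effect = "splice_region_variant")
  expect_equal(nrow(call_candidate_genes(spl)), 0L)
  cfg <- linkage_config(large_effects = c("stop_gained", "missense_variant",
                                          "splice_region_variant"))
  expect_equal(call_candidate_genes(spl, cfg)$gene_id, "gX")
})

test_that("candidate calling equals brute-force rule evaluation on a 50-site fixture", {
  set.seed(29)
  rec <- random_records(50, effects = TRUE)
  s <- linkage_stats(filter_high_confidence(rec,
         config = filter_config(min_coverage = 1, require_both_pools = FALSE))$records)
  for (chroms in list(NULL, "chr1", c("chr1", "chr2"))) {
    got <- sort(unique(call_candidate_genes(s, linkage_config(d_threshold = 0.05),
                                            chromosomes = chroms)$gene_id))
    expect_equal(got, brute_candidate_genes(s, linkage_config(d_threshold = 0.05),
                                            chromosomes = chroms))
  }
})

test_that("threshold sweep reports the FPR definition and is monotone", {
  # one mutant with 2 candidate genes at t = 0.2 but only 1 at t = 0.4
  m1 <- rbind(stats_row(gene_id = "gA", idx_mt = 1, idx_wt = 1 / 3),   # D = 0.667
              stats_row(chrom = "chr2", gene_id = "gB", idx_mt = 0.95,
                        idx_wt = 0.65))                                # D = 0.3
  sw <- sweep_thresholds(list(m1 = m1), thresholds = c(0.2, 0.4))
  expect_equal(sw$n_candidate_genes, c(2L, 1L))
  expect_equal(sw$false_positive_rate, c(1, 0))

  # synthetic 10-mutant cohort: counts non-increasing across the grid
  set.seed(31)
  cohort <- generate_cohort(synth_config(n_lines = 10, seed = 31))
  stats_list <- lapply(cohort$lines, function(l) {
    rec <- attach_effects(l$records, l$effects)
    rec <- assign_genes(rec, cohort$sketch$genes)
    linkage_stats(filter_high_confidence(rec)$records)
  })
  sw2 <- sweep_thresholds(stats_list, thresholds = seq(0.1, 0.9, by = 0.1))
  expect_true(all(diff(sw2$n_candidate_genes) <= 0))
  expect_true(all(sw2$false_positive_rate >= 0 & sw2$false_positive_rate <= 1))
  # FPR is exactly (#mutants with > 1 candidate gene) / #mutants
  cfg <- linkage_config(d_threshold = 0.1)
  genes_per_line <- vapply(stats_list, function(st) {
    cc <- localize_chromosome(call_linked_snps(st, cfg))
    if (cc$status == "none") return(0L)
    length(unique(call_candidate_genes(st, cfg,
                                       chromosomes = cc$called_chromosomes)$gene_id))
  }, integer(1))
  expect_equal(sw2$false_positive_rate[1], mean(genes_per_line > 1))
})

test_that("a singleton sweep grid equals a direct candidate-calling run", {
  set.seed(37)
  cohort <- generate_cohort(synth_config(n_lines = 3, seed = 37))
  stats_list <- lapply(cohort$lines, function(l) {
    rec <- attach_effects(l$records, l$effects)
    rec <- assign_genes(rec, cohort$sketch$genes)
    linkage_stats(filter_high_confidence(rec)$records)
  })
  sw <- sweep_thresholds(stats_list, thresholds = 0.4)
  direct <- vapply(stats_list, function(st) {
    cc <- localize_chromosome(call_linked_snps(st))
    if (cc$status == "none") return(0L)
    length(unique(call_candidate_genes(st,
                                       chromosomes = cc$called_chromosomes)$gene_id))
  }, integer(1))
  expect_equal(sw$n_candidate_genes, sum(direct))
  expect_equal(sw$n_mutants_with_candidates, sum(direct >= 1))
  expect_equal(sw$false_positive_rate, mean(direct > 1))
})

test_that("removing one linked site leaves the others' calls unchanged", {
  set.seed(41)
  rec <- random_records(40, effects = TRUE)
  s <- linkage_stats(filter_high_confidence(rec,
         config = filter_config(min_coverage = 1, require_both_pools = FALSE))$records)
  cfg <- linkage_config(d_threshold = 0.05)
  full <- call_linked_snps(s, cfg)
  if (nrow(full) > 1) {
    drop1 <- call_linked_snps(s[-which(s$pos == full$pos[1] &
                                       s$chrom == full$chrom[1]), ], cfg)
    expect_equal(drop1, full[-1, ], ignore_attr = TRUE)
  } else succeed("fewer than two linked sites in fixture")
})
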