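test_that("joint VCF lines map directly onto records", {
  p <- write_fixture_vcf(vcf_line("chr1", 100, "C", "T", "0,12", "8,4"))
  rec <- read_pool_vcf(p, "MT", "WT")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$chrom, "chr1")
  expect_equal(rec$pos, 100L)
  expect_equal(rec$ref, "C")
  expect_equal(rec$alt, "T")
  expect_equal(c(rec$mt_ref, rec$mt_alt, rec$wt_ref, rec$wt_alt),
               c(0L, 12L, 8L, 4L))
})

test_that("indel lines are skipped and counted", {
  p <- write_fixture_vcf(c(
    vcf_line("chr1", 100, "C", "T", "0,12", "8,4"),
    vcf_line("chr1", 200, "A", "AT", "5,3", "6,1")))
  rec <- read_pool_vcf(p, "MT", "WT")
  expect_equal(nrow(rec), 1L)
  expect_equal(unname(attr(rec, "io_counts")["indel_skipped"]), 1L)
})

test_that("multiallelic lines split per ALT and conserve alt depth", {
  p <- write_fixture_vcf(c(
    vcf_line("chr1", 100, "C", "T", "0,12", "8,4"),
    vcf_line("chr1", 200, "G", "A", "3,9", "7,2"),
    vcf_line("chr2", 50, "T", "C", "1,14", "9,3"),
    vcf_line("chr2", 90, "G", "A,C", "5,3,2", "6,1,4")))
  rec <- read_pool_vcf(p, "MT", "WT")
  expect_equal(nrow(rec), 5L)   # 3 biallelic + 2 from the multiallelic line
  multi <- rec[rec$pos == 90, ]
  expect_equal(sort(multi$alt), c("A", "C"))
  expect_equal(sum(multi$mt_alt), 3L + 2L)   # split conserves total ALT depth
  expect_equal(sum(multi$wt_alt), 1L + 4L)
  expect_equal(unique(multi$mt_ref), 5L)
})

test_that("missing sample is fatal and names the available samples", {
  p <- write_fixture_vcf(vcf_line("chr1", 100, "C", "T", "0,12", "8,4"))
  expect_error(read_pool_vcf(p, "MT", "nope"), "MT.*WT")
})

test_that("separately-called pools merge on site with zero fill", {
  mt <- write_fixture_vcf(c(vcf_line("chr1", 100, "C", "T", "0,12"),
                            vcf_line("chr1", 300, "G", "A", "4,6")),
                          samples = "MT")
  wt <- write_fixture_vcf(c(vcf_line("chr1", 100, "C", "T", "8,4"),
                            vcf_line("chr1", 500, "C", "T", "9,2")),
                          samples = "WT")
  rec <- read_pool_vcf_pair(mt, wt)
  expect_equal(nrow(rec), 3L)
  at300 <- rec[rec$pos == 300, ]
  expect_equal(c(at300$wt_ref, at300$wt_alt), c(0L, 0L))
  at100 <- rec[rec$pos == 100, ]
  expect_equal(c(at100$mt_alt, at100$wt_alt), c(12L, 4L))
})

test_that("effect severity collapses multi-effect annotations", {
  rec <- snp_records("chr2", 50, "C", "T", 5, 5, 5, 5)
  ann <- data.frame(chrom = "chr2", pos = c(50, 50),
                    alt = "T",
                    effect = c("missense_variant", "upstream_gene_variant"),
                    gene_id = "gX")
  out <- attach_effects(rec, ann)
  expect_equal(out$effect, "missense_variant")
  expect_equal(out$gene_id, "gX")
})

test_that("unannotated records keep effect absent; unknown labels map to other", {
  rec <- snp_records(c("chr1", "chr1"), c(10, 20), "C", "T", 5, 5, 5, 5)
  ann <- data.frame(chrom = "chr1", pos = 10, alt = "T",
                    effect = "weird_novel_label", gene_id = NA)
  out <- attach_effects(rec, ann)
  expect_equal(out$effect, c("other", NA_character_))
  expect_equal(attr(out, "n_unmatched_ann"), 0L)
})

test_that("effect classes survive a per-class fixture round trip", {
  classes <- c("stop_gained", "splice_region_variant", "missense_variant",
               "synonymous_variant")
  n_per <- 4L
  pos <- seq_len(n_per * length(classes)) * 10L
  rec <- snp_records("chr1", pos, "C", "T", 5, 5, 5, 5)
  ann <- data.frame(chrom = "chr1", pos = pos, alt = "T",
                    effect = rep(classes, each = n_per), gene_id = NA)
  out <- attach_effects(rec, ann)
  expect_equal(as.vector(table(out$effect)[classes]),
               rep(n_per, length(classes)))
})

test_that("ANN-annotated VCF supplies effects and gene ids", {
  body <- paste("chr1", 100, ".", "C", "T", "50", "PASS",
                "ANN=T|missense_variant|MODERATE|gX|gene001|transcript|t1,T|upstream_gene_variant|MODIFIER|gY|gene002|transcript|t2",
                "GT:AD", "0/1:0,12", "0/1:8,4", sep = "\t")
  p <- write_fixture_vcf(body)
  rec <- read_pool_vcf(p, "MT", "WT")
  out <- attach_effects(rec, p)
  expect_equal(out$effect, "missense_variant")
  expect_equal(out$gene_id, "gene001")
})

test_that("gene assignment is interval-inclusive and matches the brute-force scan", {
  genes <- data.frame(gene_id = c("gA", "gB", "gBov"),
                      chrom = c("chr1", "chr1", "chr1"),
                      start = c(100L, 500L, 550L), end = c(200L, 600L, 650L),
                      strand = "+")
  rec <- snp_records("chr1", c(150L, 100L, 200L, 99L, 575L, 1000L),
                     "C", "T", 5, 5, 5, 5)
  out <- assign_genes(rec, genes)
  expect_equal(out$gene_id,
               c("gA", "gA", "gA", NA, "gB;gBov", NA))

  rec2 <- random_records(200, seed = 11)
  genes2 <- data.frame(gene_id = sprintf("g%03d", 1:30),
                       chrom = paste0("chr", rep(1:3, each = 10)),
                       start = rep(seq(1000, 91000, by = 10000), 3),
                       end = rep(seq(1000, 91000, by = 10000), 3) + 4000L,
                       strand = "+")
  out2 <- assign_genes(rec2, genes2)
  expect_equal(out2$gene_id, brute_assign_genes(rec2, genes2))
})

test_that("GFF3 gene models round-trip through rtracklayer", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(10L, 400L), end = c(300L, 900L),
                      strand = c("+", "-"))
  p <- tempfile(fileext = ".gff3")
  write_gff3(genes, p)
  back <- read_gff_genes(p)
  expect_equal(back[, c("gene_id", "chrom", "start", "end", "strand")], genes)
})

test_that("result writing converts to BED half-open coordinates and round-trips", {
  stats <- linkage_stats(snp_records("chr1", 100, "C", "T", 0, 20, 10, 10))
  cands <- cbind(gene_id = "gX", stats)
  dir <- tempfile()
  write_results(dir, stats, cands, summary = list(n = 1))
  bed <- read.delim(file.path(dir, "linked.bed"), header = FALSE)
  expect_equal(c(bed$V2, bed$V3), c(99L, 100L))     # pos 100 -> [99, 100)
  back <- read.delim(file.path(dir, "candidates.tsv"))
  expect_equal(back$pos, cands$pos)
  expect_equal(back$d_value, cands$d_value)
  expect_equal(back$gene_id, cands$gene_id)

  # empty candidate set: header-only TSV, still succeeds
  dir2 <- tempfile()
  write_results(dir2, stats[0, ], cands[0, ], summary = list())
  lines <- readLines(file.path(dir2, "candidates.tsv"))
  expect_length(lines, 1L)
})
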