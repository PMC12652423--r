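# Fixture builders and brute-force oracles shared across the suite.
# Everything is generated in code at test time; no binary fixtures.

# Write a small VCF from a body of pre-formatted data lines.
write_fixture_vcf <- function(body, samples = c("MT", "WT"),
                              path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, ...) {
  ads <- list(...)
  paste(c(chrom, pos, ".", ref, alt, "50", "PASS", ".", "GT:AD",
          vapply(ads, function(ad) paste0("0/1:", ad), character(1))),
        collapse = "\t")
}

# Random record table used by oracle comparisons.
random_records <- function(n, n_chrom = 3, max_pos = 100000, seed = NULL,
                           effects = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  subs <- list(c("C", "T"), c("G", "A"), c("A", "G"), c("T", "C"),
               c("C", "G"), c("A", "T"))
  pick <- sample(length(subs), n, replace = TRUE)
  ref <- vapply(subs[pick], `[`, character(1), 1)
  alt <- vapply(subs[pick], `[`, character(1), 2)
  rec <- snp_records(
    chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    pos = sample.int(max_pos, n, replace = TRUE),
    ref = ref, alt = alt,
    mt_ref = rpois(n, 10), mt_alt = rpois(n, 10),
    wt_ref = rpois(n, 10), wt_alt = rpois(n, 10))
  if (effects) {
    rec$effect <- sample(effect_vocabulary(), n, replace = TRUE)
    rec$gene_id <- sprintf("g%02d", sample.int(20, n, replace = TRUE))
  }
  rec
}

# O(n * m) interval scan: the independent oracle for assign_genes().
brute_assign_genes <- function(records, genes) {
  vapply(seq_len(nrow(records)), function(i) {
    hit <- genes$gene_id[genes$chrom == records$chrom[i] &
                         genes$start <= records$pos[i] &
                         genes$end >= records$pos[i]]
    if (length(hit) == 0) NA_character_ else paste(hit, collapse = ";")
  }, character(1))
}

# Rule-by-rule re-check of the three high-confidence filters.
brute_filter <- function(records, cohort, line_id, config = filter_config()) {
  keys <- site_key(records)
  keep <- logical(nrow(records))
  first_fail <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    dm <- records$mt_ref[i] + records$mt_alt[i]
    dw <- records$wt_ref[i] + records$wt_alt[i]
    if (dm < config$min_coverage || dw < config$min_coverage) {
      first_fail[i] <- "coverage"
    } else if (config$require_both_pools &&
               (records$mt_alt[i] < 1 || records$wt_alt[i] < 1)) {
      first_fail[i] <- "both_pools"
    } else if (!is.null(cohort)) {
      frac <- mean(vapply(cohort, function(s) keys[i] %in% s, logical(1)))
      if (frac > config$max_line_fraction) first_fail[i] <- "shared"
      else keep[i] <- TRUE
    } else keep[i] <- TRUE
  }
  list(keep = keep, first_fail = first_fail)
}

# Direct evaluation of the three candidate criteria (strict comparisons).
brute_candidate_genes <- function(stats, config = linkage_config(),
                                  chromosomes = NULL) {
  genes <- character(0)
  for (i in seq_len(nrow(stats))) {
    if (!is.null(chromosomes) && !stats$chrom[i] %in% chromosomes) next
    if (is.na(stats$gene_id[i]) || is.na(stats$effect[i])) next
    if (stats$snp_index_mt[i] > config$mt_index_min &&
        stats$d_value[i] > config$d_threshold &&
        stats$effect[i] %in% config$large_effects)
      genes <- c(genes, strsplit(stats$gene_id[i], ";")[[1]])
  }
  sort(unique(genes))
}

# Run filter -> stats -> localize -> candidates on one synthetic experiment.
run_pipeline <- function(exp, sketch, cohort = NULL, line_id = NULL,
                         filter = filter_config(), linkage = linkage_config()) {
  rec <- attach_effects(exp$records, exp$effects)
  rec <- assign_genes(rec, sketch$genes)
  ebsr_map(rec, cohort = cohort, line_id = line_id,
           filter = filter, linkage = linkage, line = line_id)
}
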