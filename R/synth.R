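# Synthetic bulked-segregant RNA-seq experiments. Each simulated mutant
# line carries one planted causal SNP (homozygous in the mutant bulk; the
# wild-type sibling bulk segregates 2:1 het:hom), a background of unlinked
# EMS mutations (expected allele frequency 0.5 at heterozygous-parent sites
# in both bulks, 1.0 at homozygous ones), optional sites shared across
# lines (to exercise the cross-line blacklist), and spurious low-coverage
# calls with a non-canonical substitution spectrum (to exercise the
# coverage filter and the spectrum diagnostic). Read counts are drawn
# Binomial(Poisson(depth) , true frequency); no read-level simulation.

#' Configuration of the synthetic-experiment generator
#'
#' Defaults emulate the study conditions of a maize EMS M3 bulk experiment:
#' 20 lines, 30-80 SNPs per line, Poisson(30) depth, pools of 20 kernels,
#' 73.33% exonic sites with an effect mix of 30.56% synonymous, 63.63%
#' missense, 3.66% stop-gained and 1.89% splice-region (renormalised to
#' sum to one), and a fully canonical C->T / G->A spectrum for true EMS
#' sites.
#'
#' @param n_lines Number of mutant lines in the cohort (default 20).
#' @param snps_per_line Integer range (length 2) of sites per line; each
#'   line draws uniformly from it (default 30-80).
#' @param causal_effect Effect label planted at the causal site.
#' @param depth_lambda Mean Poisson per-pool read depth (default 30).
#' @param pool_size Individuals per bulk (default 20).
#' @param het_fraction_wt Heterozygote fraction among wild-type siblings at
#'   the causal locus (default 2/3).
#' @param background_het_fraction Fraction of background EMS sites that are
#'   heterozygous (frequency 0.5) rather than homozygous (frequency 1) in
#'   the parent; default 2/3.
#' @param canonical_fraction_true Fraction of true EMS sites with a
#'   canonical C->T / G->A substitution (default 1).
#' @param false_snp_rate Fraction of a line's sites that are spurious
#'   low-coverage calls, forced below the default coverage filter with a
#'   non-canonical spectrum (default 0.25).
#' @param exon_fraction Probability a non-causal site falls inside a gene
#'   (default 0.7333).
#' @param effect_mix Named proportions of effect labels for exonic
#'   non-causal sites; renormalised to sum to 1.
#' @param shared_site_rate Fraction of cohort lines carrying each shared
#'   site (default 0.25, above the 10 percent blacklist so shared sites are
#'   filtered out).
#' @param n_shared_sites Number of distinct shared sites in the cohort
#'   (default 3).
#' @param n_chromosomes,genes_per_chromosome,gene_length,intergenic_gap
#'   Genome-sketch parameters: genes of fixed length tile each chromosome
#'   separated by fixed intergenic gaps.
#' @param seed Optional integer seed for [generate_cohort()].
#' @return A list with class `ebsr_synth_config`.
#' @export
synth_config <- function(n_lines = 20L, snps_per_line = c(30L, 80L),
                         causal_effect = "stop_gained",
                         depth_lambda = 30, pool_size = 20L,
                         het_fraction_wt = 2 / 3,
                         background_het_fraction = 2 / 3,
                         canonical_fraction_true = 1.0,
                         false_snp_rate = 0.25,
                         exon_fraction = 0.7333,
                         effect_mix = c(synonymous_variant = 0.3056,
                                        missense_variant = 0.6363,
                                        stop_gained = 0.0366,
                                        splice_region_variant = 0.0189),
                         shared_site_rate = 0.25, n_shared_sites = 3L,
                         n_chromosomes = 10L, genes_per_chromosome = 40L,
                         gene_length = 3000L, intergenic_gap = 2000L,
                         seed = NULL) {
  stopifnot(n_lines >= 1, length(snps_per_line) == 2,
            snps_per_line[1] <= snps_per_line[2],
            causal_effect %in% effect_vocabulary(),
            depth_lambda > 0, pool_size >= 1,
            het_fraction_wt >= 0, het_fraction_wt <= 1,
            background_het_fraction >= 0, background_het_fraction <= 1,
            canonical_fraction_true >= 0, canonical_fraction_true <= 1,
            false_snp_rate >= 0, false_snp_rate < 1,
            exon_fraction >= 0, exon_fraction <= 1,
            all(effect_mix >= 0), sum(effect_mix) > 0,
            all(names(effect_mix) %in% effect_vocabulary()),
            shared_site_rate >= 0, shared_site_rate <= 1,
            n_shared_sites >= 0, n_chromosomes >= 1,
            genes_per_chromosome >= 1, gene_length >= 1, intergenic_gap >= 1)
  effect_mix <- effect_mix / sum(effect_mix)
  structure(list(n_lines = as.integer(n_lines),
                 snps_per_line = as.integer(snps_per_line),
                 causal_effect = causal_effect,
                 depth_lambda = depth_lambda,
                 pool_size = as.integer(pool_size),
                 het_fraction_wt = het_fraction_wt,
                 background_het_fraction = background_het_fraction,
                 canonical_fraction_true = canonical_fraction_true,
                 false_snp_rate = false_snp_rate,
                 exon_fraction = exon_fraction,
                 effect_mix = effect_mix,
                 shared_site_rate = shared_site_rate,
                 n_shared_sites = as.integer(n_shared_sites),
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 gene_length = as.integer(gene_length),
                 intergenic_gap = as.integer(intergenic_gap),
                 seed = seed),
            class = "ebsr_synth_config")
}

#' Generate the genome sketch
#'
#' Deterministic gene models: on each chromosome, `genes_per_chromosome`
#' genes of `gene_length` bp tile the sequence separated by
#' `intergenic_gap` bp, so genes never overlap and intergenic space exists
#' for non-genic sites.
#'
#' @param config A [synth_config()].
#' @return List with `genes` (data.frame as from [read_gff_genes()]) and
#'   `chrom_sizes` (named integer vector).
#' @export
generate_genome_sketch <- function(config = synth_config()) {
  per <- config$genes_per_chromosome
  len <- config$gene_length
  gap <- config$intergenic_gap
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    j <- seq_len(per)
    start <- (j - 1L) * (len + gap) + gap + 1L
    data.frame(gene_id = sprintf("gene_%s_%03d", chroms[ci], j),
               chrom = chroms[ci], start = start, end = start + len - 1L,
               strand = rep_len(c("+", "-"), per),
               stringsAsFactors = FALSE)
  }))
  sizes <- setNames(rep.int(per * (len + gap) + gap, length(chroms)), chroms)
  list(genes = genes, chrom_sizes = sizes)
}

# sample a substitution pair; canonical = EMS C->T / G->A
.sample_bases <- function(n, canonical) {
  bases <- c("A", "C", "G", "T")
  ref <- character(n); alt <- character(n)
  can <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(1, 1))
  for (i in seq_len(n)) {
    if (canonical[i]) {
      if (can[i]) { ref[i] <- "C"; alt[i] <- "T" } else { ref[i] <- "G"; alt[i] <- "A" }
    } else {
      repeat {
        r <- sample(bases, 1); a <- sample(setdiff(bases, r), 1)
        if (!is_canonical_ems(r, a)) { ref[i] <- r; alt[i] <- a; break }
      }
    }
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# positions: exonic sites land inside a random gene, intergenic ones in the
# gap immediately upstream of a random gene; returns chrom/pos/gene_id (NA
# outside genes)
.sample_positions <- function(n, exonic, sketch, gap) {
  genes <- sketch$genes
  out <- data.frame(chrom = character(n), pos = integer(n),
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- genes[sample.int(nrow(genes), 1), ]
    out$chrom[i] <- g$chrom
    if (exonic[i]) {
      out$pos[i] <- sample(g$start:g$end, 1)
      out$gene_id[i] <- g$gene_id
    } else {
      out$pos[i] <- sample((g$start - gap):(g$start - 1L), 1)
    }
  }
  out
}

.noncoding_effects <- c(upstream_gene_variant = 0.3,
                        downstream_gene_variant = 0.3,
                        intergenic_region = 0.4)

# draw per-pool read counts at a site with true alt frequencies
.draw_counts <- function(freq_mt, freq_wt, depth_lambda) {
  draw1 <- function(freq) {
    d <- rpois(1, depth_lambda)
    while (d == 0L) d <- rpois(1, depth_lambda)
    a <- rbinom(1, d, freq)
    c(ref = d - a, alt = a)
  }
  c(mt = draw1(freq_mt), wt = draw1(freq_wt))
}

#' Generate one synthetic mutant-line experiment
#'
#' Plants exactly one causal site inside a gene (mutant-pool frequency 1;
#' wild-type-pool frequency from a binomial draw of carriers), unlinked
#' heterozygous and homozygous background EMS sites, any shared sites
#' assigned to this line, and spurious non-canonical calls whose per-pool
#' depth is forced below 5.
#'
#' @param config A [synth_config()].
#' @param sketch A [generate_genome_sketch()] result.
#' @param line_id Line identifier.
#' @param shared_sites Optional data.frame of cohort-shared sites (columns
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `effect`) to include in this
#'   line.
#' @return List with `records` (a `snp_records` table, unannotated),
#'   `effects` (effect table for [attach_effects()]), `truth` (per-site
#'   data.frame with `category` in causal/background_het/background_hom/
#'   shared/false_lowcov and true pool frequencies) and `causal` (list with
#'   the planted site key and gene).
#' @export
generate_experiment <- function(config, sketch, line_id = "line01",
                                shared_sites = NULL) {
  stopifnot(inherits(config, "ebsr_synth_config"))
  genes <- sketch$genes
  n_total <- sample(config$snps_per_line[1]:config$snps_per_line[2], 1)
  n_shared <- if (is.null(shared_sites)) 0L else nrow(shared_sites)
  n_false <- round(config$false_snp_rate * n_total)
  n_bg <- max(0L, n_total - 1L - n_shared - n_false)

  # --- causal site -----------------------------------------------------
  g <- genes[sample.int(nrow(genes), 1), ]
  causal_bases <- .sample_bases(1, canonical = TRUE)
  causal <- data.frame(chrom = g$chrom, pos = sample(g$start:g$end, 1),
                       ref = causal_bases$ref, alt = causal_bases$alt,
                       gene_id = g$gene_id, effect = config$causal_effect,
                       category = "causal", stringsAsFactors = FALSE)
  k <- rbinom(1, config$pool_size, config$het_fraction_wt)
  causal$freq_mt <- 1
  causal$freq_wt <- k / (2 * config$pool_size)

  # --- background EMS sites -------------------------------------------
  make_sites <- function(n, category, canonical_p, freq_mt, freq_wt) {
    if (n == 0L) return(NULL)
    exonic <- runif(n) < config$exon_fraction
    posn <- .sample_positions(n, exonic, sketch, config$intergenic_gap)
    bases <- .sample_bases(n, canonical = runif(n) < canonical_p)
    effect <- character(n)
    effect[exonic] <- sample(names(config$effect_mix), sum(exonic),
                             replace = TRUE, prob = config$effect_mix)
    effect[!exonic] <- sample(names(.noncoding_effects), sum(!exonic),
                              replace = TRUE, prob = .noncoding_effects)
    data.frame(chrom = posn$chrom, pos = posn$pos,
               ref = bases$ref, alt = bases$alt, gene_id = posn$gene_id,
               effect = effect, category = category,
               freq_mt = freq_mt, freq_wt = freq_wt,
               stringsAsFactors = FALSE)
  }
  n_het <- rbinom(1, n_bg, config$background_het_fraction)
  sites <- rbind(
    causal,
    make_sites(n_het, "background_het", config$canonical_fraction_true, 0.5, 0.5),
    make_sites(n_bg - n_het, "background_hom", config$canonical_fraction_true, 1, 1),
    make_sites(n_false, "false_lowcov", 0, 0.5, 0.5)
  )
  if (n_shared > 0L) {
    sh <- shared_sites[, c("chrom", "pos", "ref", "alt", "gene_id", "effect")]
    sh$category <- "shared"
    sh$freq_mt <- 0.5
    sh$freq_wt <- 0.5
    sites <- rbind(sites, sh)
  }
  sites <- sites[!duplicated(paste(sites$chrom, sites$pos)), , drop = FALSE]
  rownames(sites) <- NULL

  # --- read counts -----------------------------------------------------
  n <- nrow(sites)
  cnt <- matrix(0L, n, 4, dimnames = list(NULL, c("mt_ref", "mt_alt",
                                                  "wt_ref", "wt_alt")))
  for (i in seq_len(n)) {
    if (sites$category[i] == "false_lowcov") {
      dm <- sample(1:4, 1); dw <- sample(1:4, 1)   # forced below coverage 5
      am <- rbinom(1, dm, sites$freq_mt[i])
      aw <- rbinom(1, dw, sites$freq_wt[i])
      cnt[i, ] <- c(dm - am, am, dw - aw, aw)
    } else {
      cnt[i, ] <- .draw_counts(sites$freq_mt[i], sites$freq_wt[i],
                               config$depth_lambda)
    }
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  cnt <- cnt[ord, , drop = FALSE]

  records <- snp_records(sites$chrom, sites$pos, sites$ref, sites$alt,
                         cnt[, "mt_ref"], cnt[, "mt_alt"],
                         cnt[, "wt_ref"], cnt[, "wt_alt"])
  truth <- cbind(line_id = line_id, sites,
                 as.data.frame(cnt), stringsAsFactors = FALSE)
  truth$key <- site_key(truth)
  list(records = records,
       effects = sites[, c("chrom", "pos", "alt", "effect", "gene_id")],
       truth = truth,
       causal = list(key = site_key(causal), gene_id = causal$gene_id,
                     wt_carriers = k))
}

#' Generate a synthetic cohort
#'
#' Generates `n_lines` experiments sharing one genome sketch and one pool of
#' shared sites. With `dir` set, writes per-line mutant/wild-type VCFs and
#' effect tables, the GFF3 gene models, a cohort manifest TSV
#' (`line_id vcf_mt vcf_wt effects`) and a truth table TSV; the same seed
#' regenerates byte-identical files.
#'
#' @param config A [synth_config()]; its `seed` drives all randomness.
#' @param dir Optional output directory.
#' @return List with `config`, `sketch`, `lines` (per-line
#'   [generate_experiment()] results), `truth` (row-bound truth table),
#'   `manifest` (data.frame; with file paths when `dir` is set) and `dir`.
#' @export
generate_cohort <- function(config = synth_config(), dir = NULL) {
  stopifnot(inherits(config, "ebsr_synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sketch <- generate_genome_sketch(config)

  # cohort-shared sites: heterozygous background sites recurring in a fixed
  # fraction of lines
  shared <- NULL
  assign_lines <- list()
  if (config$n_shared_sites > 0L && config$shared_site_rate > 0) {
    exonic <- runif(config$n_shared_sites) < config$exon_fraction
    posn <- .sample_positions(config$n_shared_sites, exonic, sketch,
                              config$intergenic_gap)
    bases <- .sample_bases(config$n_shared_sites, rep(TRUE, config$n_shared_sites))
    effect <- ifelse(exonic,
                     sample(names(config$effect_mix), config$n_shared_sites,
                            replace = TRUE, prob = config$effect_mix),
                     sample(names(.noncoding_effects), config$n_shared_sites,
                            replace = TRUE, prob = .noncoding_effects))
    shared <- data.frame(chrom = posn$chrom, pos = posn$pos, ref = bases$ref,
                         alt = bases$alt, gene_id = posn$gene_id,
                         effect = effect, stringsAsFactors = FALSE)
    n_carry <- max(1L, round(config$shared_site_rate * config$n_lines))
    assign_lines <- lapply(seq_len(config$n_shared_sites),
                           function(i) sample.int(config$n_lines, n_carry))
  }

  line_ids <- sprintf("line%02d", seq_len(config$n_lines))
  lines <- vector("list", config$n_lines)
  names(lines) <- line_ids
  for (li in seq_len(config$n_lines)) {
    carry <- if (length(assign_lines))
      vapply(assign_lines, function(s) li %in% s, logical(1)) else logical(0)
    sh <- if (any(carry)) shared[carry, , drop = FALSE] else NULL
    lines[[li]] <- generate_experiment(config, sketch, line_ids[li], sh)
  }
  truth <- do.call(rbind, lapply(lines, `[[`, "truth"))
  rownames(truth) <- NULL

  manifest <- data.frame(line_id = line_ids,
                         vcf_mt = NA_character_, vcf_wt = NA_character_,
                         effects = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(sketch$genes, file.path(dir, "genes.gff3"))
    for (li in seq_len(config$n_lines)) {
      id <- line_ids[li]
      mt <- file.path(dir, paste0(id, "_mt.vcf"))
      wt <- file.path(dir, paste0(id, "_wt.vcf"))
      eff <- file.path(dir, paste0(id, "_effects.tsv"))
      write_pool_vcf(lines[[li]]$records, mt, pool = "mt",
                     sample_name = paste0(id, "_MT"),
                     chrom_sizes = sketch$chrom_sizes)
      write_pool_vcf(lines[[li]]$records, wt, pool = "wt",
                     sample_name = paste0(id, "_WT"),
                     chrom_sizes = sketch$chrom_sizes)
      write.table(lines[[li]]$effects, eff, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest$vcf_mt[li] <- mt
      manifest$vcf_wt[li] <- wt
      manifest$effects[li] <- eff
    }
    # manifest stores paths relative to its own directory (portable and
    # byte-stable across regenerations)
    rel <- manifest
    for (col in c("vcf_mt", "vcf_wt", "effects"))
      rel[[col]] <- basename(rel[[col]])
    write.table(rel, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(config = config, sketch = sketch, lines = lines, truth = truth,
       manifest = manifest, dir = dir)
}

#' Write one pool of a record table as a single-sample VCF
#'
#' Emits every site with a GT:AD genotype column for the requested pool.
#'
#' @param records A `snp_records` table.
#' @param path Output path.
#' @param pool `"mt"` or `"wt"`.
#' @param sample_name Sample column name.
#' @param chrom_sizes Optional named vector for `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_pool_vcf <- function(records, path, pool = c("mt", "wt"),
                           sample_name = toupper(pool),
                           chrom_sizes = NULL) {
  pool <- match.arg(pool)
  refn <- records[[paste0(pool, "_ref")]]
  altn <- records[[paste0(pool, "_alt")]]
  gt <- ifelse(altn == 0L, "0/0", ifelse(refn == 0L, "1/1", "0/1"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ebsrmap-synth",
    if (!is.null(chrom_sizes))
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
              as.integer(chrom_sizes)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t%s:%d,%d",
                  records$chrom, records$pos, records$ref, records$alt,
                  gt, refn, altn)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tebsrmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}
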