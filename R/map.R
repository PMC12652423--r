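# The end-to-end mapping pipeline for one mutant line:
# read -> annotate -> filter -> linkage stats -> chromosome call ->
# candidate genes, returned as one classed object.

#' Map a mutant line from pooled variant calls
#'
#' Runs the full bulked-segregant mapping pipeline for one EMS mutant line.
#' Inputs are either one jointly-called two-sample VCF (`mt_vcf` plus
#' `mt_sample`/`wt_sample`) or two separately-called single-sample VCFs
#' (`mt_vcf` and `wt_vcf`). Stages: high-confidence filtering (per-pool
#' coverage, detection in both pools, cross-line blacklist), SNP-index and
#' D-value computation, linked-SNP selection, chromosome localization, and
#' candidate-gene calling restricted to the called chromosomes (or
#' genome-wide with `genome_wide = TRUE`).
#'
#' @param mt_vcf Path to the mutant-pool VCF (or the joint VCF); may also be
#'   a ready-made `snp_records` table, in which case VCF reading is skipped.
#' @param wt_vcf Path to the wild-type-pool VCF, for separately-called
#'   pools; `NULL` when `mt_vcf` is a joint VCF or a record table.
#' @param gff Gene models: a GFF3 path or a data.frame as from
#'   [read_gff_genes()]; optional but required for candidate genes.
#' @param ann Effect annotations: ANN-annotated VCF path, effect-table TSV
#'   path or data.frame (see [attach_effects()]); optional.
#' @param mt_sample,wt_sample Sample names inside a joint VCF.
#' @param cohort,line_id Cross-line blacklist inputs (see
#'   [filter_high_confidence()]).
#' @param filter A [filter_config()].
#' @param linkage A [linkage_config()].
#' @param genome_wide Call candidates on all chromosomes instead of only
#'   the localized ones.
#' @param line Label for this mutant line in outputs.
#' @return An object of class `ebsrmap` with components `records`
#'   (filtered), `stats`, `linked`, `chrom_call`, `candidates`,
#'   `candidate_genes`, `counts`, and the configurations used.
#' @export
ebsr_map <- function(mt_vcf, wt_vcf = NULL, gff = NULL, ann = NULL,
                     mt_sample = NULL, wt_sample = NULL,
                     cohort = NULL, line_id = NULL,
                     filter = filter_config(), linkage = linkage_config(),
                     genome_wide = FALSE, line = line_id) {
  # --- ingest ----------------------------------------------------------
  if (inherits(mt_vcf, "snp_records") || is.data.frame(mt_vcf)) {
    records <- .as_snp_records(mt_vcf)
  } else if (!is.null(wt_vcf)) {
    records <- read_pool_vcf_pair(mt_vcf, wt_vcf, mt_sample, wt_sample)
  } else {
    if (is.null(mt_sample) || is.null(wt_sample))
      stop("joint VCF input needs mt_sample and wt_sample")
    records <- read_pool_vcf(mt_vcf, mt_sample, wt_sample)
  }
  io_counts <- attr(records, "io_counts")
  if (!is.null(ann)) records <- attach_effects(records, ann)
  if (!is.null(gff)) {
    genes <- if (is.character(gff)) read_gff_genes(gff) else gff
    records <- assign_genes(records, genes)
  }

  # --- filter ----------------------------------------------------------
  filt <- filter_high_confidence(records, cohort = cohort, line_id = line_id,
                                 config = filter)

  # --- linkage ---------------------------------------------------------
  stats <- linkage_stats(filt$records)
  linked <- call_linked_snps(stats, linkage)
  chrom_call <- localize_chromosome(linked)
  chroms <- if (genome_wide || chrom_call$status == "none") NULL
            else chrom_call$called_chromosomes
  candidates <- if (genome_wide)
    call_candidate_genes(stats, linkage)
  else if (chrom_call$status == "none")
    call_candidate_genes(stats[0, , drop = FALSE], linkage)
  else call_candidate_genes(stats, linkage, chromosomes = chroms)

  structure(list(
    line = line %||% "mutant",
    records = filt$records,
    stats = stats,
    linked = linked,
    chrom_call = chrom_call,
    candidates = candidates,
    candidate_genes = unique(candidates$gene_id),
    counts = list(io = io_counts, n_raw = filt$n_input,
                  drops = filt$drops, n_filtered = nrow(filt$records),
                  n_linked = nrow(linked),
                  n_candidate_genes = length(unique(candidates$gene_id))),
    filter = filter, linkage = linkage, genome_wide = genome_wide
  ), class = "ebsrmap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ebsrmap <- function(x, ...) {
  cat("eBSR mapping of line", x$line, "\n")
  cat(sprintf("  sites: %d raw -> %d high-confidence (drops: coverage %d, both-pools %d, shared %d)\n",
              x$counts$n_raw, x$counts$n_filtered,
              x$counts$drops["coverage"], x$counts$drops["both_pools"],
              x$counts$drops["shared"]))
  cat(sprintf("  linked SNPs: %d; chromosome call: %s",
              x$counts$n_linked, x$chrom_call$status))
  if (x$chrom_call$status != "none")
    cat(" (", paste(x$chrom_call$called_chromosomes, collapse = ", "), ")",
        sep = "")
  cat("\n")
  if (length(x$candidate_genes))
    cat("  candidate gene(s):", paste(x$candidate_genes, collapse = ", "), "\n")
  else cat("  no candidate genes\n")
  invisible(x)
}

#' @export
summary.ebsrmap <- function(object, ...) {
  print(object)
  if (nrow(object$candidates)) {
    cat("\nSupporting sites:\n")
    print(object$candidates[, c("gene_id", "chrom", "pos", "ref", "alt",
                                "effect", "snp_index_mt", "snp_index_wt",
                                "d_value")], row.names = FALSE)
  }
  if (length(object$chrom_call$counts)) {
    cat("\nLinked SNPs per chromosome:\n")
    print(object$chrom_call$counts)
  }
  invisible(object)
}

#' Plot per-site D-values along the genome
#'
#' One panel per chromosome carrying data; linked SNPs are highlighted and
#' the D-value threshold drawn.
#'
#' @param x An `ebsrmap` object.
#' @param ... Passed to [plot()].
#' @export
plot.ebsrmap <- function(x, ...) {
  st <- x$stats
  if (nrow(st) == 0) {
    warning("no sites to plot")
    return(invisible(x))
  }
  chroms <- unique(st$chrom)
  old <- par(mfrow = c(min(length(chroms), 4), 1),
             mar = c(2.5, 4, 1.5, 1))
  on.exit(par(old))
  linked_key <- paste(x$linked$chrom, x$linked$pos)
  for (ch in chroms[seq_len(min(length(chroms), 4))]) {
    sub <- st[st$chrom == ch, ]
    is_linked <- paste(sub$chrom, sub$pos) %in% linked_key
    plot(sub$pos, sub$d_value, ylim = c(-1, 1), pch = 19,
         col = ifelse(is_linked, "red", "grey50"),
         xlab = "", ylab = "D-value", main = ch, ...)
    abline(h = x$linkage$d_threshold, lty = 2)
  }
  invisible(x)
}

#' Write an `ebsrmap` result to a run directory
#'
#' Convenience wrapper around [write_results()] assembling the run summary
#' from the object's stage counts and configuration.
#'
#' @param x An `ebsrmap` object.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_ebsrmap <- function(x, dir) {
  cands <- x$candidates
  if (nrow(cands)) cands <- cbind(line_id = x$line, cands)
  summary <- list(
    line = x$line,
    counts = x$counts,
    chromosome_call = list(status = x$chrom_call$status,
                           chromosomes = x$chrom_call$called_chromosomes,
                           linked_per_chrom = as.list(x$chrom_call$counts)),
    candidate_genes = x$candidate_genes,
    filter_config = unclass(x$filter),
    linkage_config = unclass(x$linkage),
    genome_wide = x$genome_wide
  )
  write_results(dir, x$linked, cands, summary)
}
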