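# SNP-index / D-value linkage statistics, chromosome localization, candidate
# gene calling and the D-value threshold sweep.

#' SNP index: fraction of reads carrying the mutant allele
#'
#' @param alt_count,ref_count Alternate/reference read counts (vectorised).
#' @return `alt_count / (alt_count + ref_count)`.
#' @export
snp_index <- function(alt_count, ref_count) {
  total <- alt_count + ref_count
  if (any(total <= 0))
    stop("SNP index undefined at zero depth; filter such sites first")
  alt_count / total
}

#' D-value: difference between the two pool SNP indices
#'
#' Large positive values indicate linkage to the causal locus: at a fully
#' linked site the mutant pool is fixed for the mutant allele (index 1)
#' while the wild-type sibling pool segregates at a lower frequency.
#'
#' @param index_mt,index_wt SNP indices of the mutant and wild-type pool,
#'   each in \[0, 1\].
#' @return `index_mt - index_wt`, in \[-1, 1\].
#' @export
d_value <- function(index_mt, index_wt) {
  stopifnot(all(index_mt >= 0 & index_mt <= 1),
            all(index_wt >= 0 & index_wt <= 1))
  index_mt - index_wt
}

#' Configuration of linkage and candidate calling
#'
#' All comparisons downstream are strict (`>`): a site is linked when both
#' pool depths exceed `min_linked_depth` and the D-value exceeds
#' `d_threshold`; a candidate site additionally needs a mutant-pool SNP
#' index above `mt_index_min` and a large-effect annotation.
#'
#' @param d_threshold Minimum D-value (exclusive), default 0.4 — the value
#'   at which the false-positive rate (lines with more than one candidate
#'   gene) vanishes and which the Monte Carlo calibration supports.
#' @param mt_index_min Minimum mutant-pool SNP index (exclusive), default
#'   0.9: a recessive causal allele is homozygous in the mutant bulk.
#' @param min_linked_depth Minimum per-pool depth (exclusive) for a site to
#'   count as linked, default 10.
#' @param large_effects Effect labels accepted as large-effect; default
#'   stop_gained and missense_variant. `splice_region_variant` can be added
#'   when splice disruption is a plausible mechanism.
#' @return A list with class `ebsr_linkage_config`.
#' @export
linkage_config <- function(d_threshold = 0.4, mt_index_min = 0.9,
                           min_linked_depth = 10L,
                           large_effects = c("stop_gained", "missense_variant")) {
  stopifnot(d_threshold > 0, d_threshold <= 1,
            mt_index_min > 0, mt_index_min <= 1,
            min_linked_depth >= 0,
            all(large_effects %in% effect_vocabulary()))
  structure(list(d_threshold = d_threshold, mt_index_min = mt_index_min,
                 min_linked_depth = as.integer(min_linked_depth),
                 large_effects = large_effects),
            class = "ebsr_linkage_config")
}

#' Per-site linkage statistics
#'
#' Computes pool depths, SNP indices and the D-value for every record.
#' Records must already have passed the coverage filter (zero-depth pools
#' are an error).
#'
#' @param records A filtered `snp_records` table.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `effect`,
#'   `gene_id`, `depth_mt`, `depth_wt`, `snp_index_mt`, `snp_index_wt`,
#'   `d_value`.
#' @export
linkage_stats <- function(records) {
  depth_mt <- records$mt_ref + records$mt_alt
  depth_wt <- records$wt_ref + records$wt_alt
  if (nrow(records) == 0) {
    idx_mt <- idx_wt <- numeric(0)
  } else {
    idx_mt <- snp_index(records$mt_alt, records$mt_ref)
    idx_wt <- snp_index(records$wt_alt, records$wt_ref)
  }
  data.frame(chrom = records$chrom, pos = records$pos,
             ref = records$ref, alt = records$alt,
             effect = records$effect, gene_id = records$gene_id,
             depth_mt = depth_mt, depth_wt = depth_wt,
             snp_index_mt = idx_mt, snp_index_wt = idx_wt,
             d_value = d_value(idx_mt, idx_wt),
             stringsAsFactors = FALSE)
}

#' Select linked SNPs
#'
#' A site is linked when its depth exceeds `min_linked_depth` in both pools
#' and its D-value exceeds `d_threshold`; all comparisons strict.
#'
#' @param stats A [linkage_stats()] table.
#' @param config A [linkage_config()].
#' @return The linked subset of `stats`.
#' @export
call_linked_snps <- function(stats, config = linkage_config()) {
  keep <- stats$depth_mt > config$min_linked_depth &
          stats$depth_wt > config$min_linked_depth &
          stats$d_value > config$d_threshold
  stats[keep, , drop = FALSE]
}

#' Localize the candidate chromosome
#'
#' Counts linked SNPs per chromosome. When they all fall on one chromosome
#' the call is unambiguous (`status = "single"`); linked SNPs on several
#' chromosomes yield `status = "multiple"` with every such chromosome
#' reported (no arbitrary winner on ties); no linked SNPs yield
#' `status = "none"`.
#'
#' @param linked Output of [call_linked_snps()].
#' @return List with `counts` (named, sorted decreasing),
#'   `called_chromosomes` and `status`.
#' @export
localize_chromosome <- function(linked) {
  if (nrow(linked) == 0)
    return(list(counts = integer(0), called_chromosomes = character(0),
                status = "none"))
  counts <- sort(table(linked$chrom), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts,
       called_chromosomes = names(counts),
       status = if (length(counts) == 1L) "single" else "multiple")
}

#' Call candidate genes
#'
#' A candidate site satisfies, strictly, (1) mutant-pool SNP index >
#' `mt_index_min`, (2) D-value > `d_threshold`, and (3) a large-effect
#' annotation. Candidate genes are the genes harbouring at least one such
#' site; sites without a gene assignment can never yield a candidate and
#' their count is recorded in attribute `"n_no_gene"`.
#'
#' @param stats A [linkage_stats()] table carrying `effect` and `gene_id`.
#' @param config A [linkage_config()].
#' @param chromosomes Optional chromosome restriction (normally the
#'   [localize_chromosome()] call); `NULL` for genome-wide calling.
#' @return data.frame with one row per supporting (gene, site) pair:
#'   `gene_id`, `chrom`, `pos`, `ref`, `alt`, `effect`, `snp_index_mt`,
#'   `snp_index_wt`, `d_value`, `depth_mt`, `depth_wt`.
#' @export
call_candidate_genes <- function(stats, config = linkage_config(),
                                 chromosomes = NULL) {
  if (!is.null(chromosomes))
    stats <- stats[stats$chrom %in% chromosomes, , drop = FALSE]
  pass <- stats$snp_index_mt > config$mt_index_min &
          stats$d_value > config$d_threshold &
          !is.na(stats$effect) & stats$effect %in% config$large_effects
  n_no_gene <- sum(pass & is.na(stats$gene_id))
  hits <- stats[pass & !is.na(stats$gene_id), , drop = FALSE]
  # a site inside overlapping genes supports each of them
  out <- if (nrow(hits) == 0) {
    hits$gene_id <- character(0)
    hits[, c("gene_id", setdiff(names(hits), "gene_id"))]
  } else {
    genes <- strsplit(hits$gene_id, ";", fixed = TRUE)
    idx <- rep(seq_len(nrow(hits)), lengths(genes))
    expanded <- hits[idx, , drop = FALSE]
    expanded$gene_id <- unlist(genes)
    rownames(expanded) <- NULL
    expanded[, c("gene_id", setdiff(names(expanded), "gene_id"))]
  }
  attr(out, "n_no_gene") <- n_no_gene
  out
}

#' Sweep the D-value threshold across a cohort
#'
#' Re-runs chromosome localization and candidate calling for every threshold
#' on every mutant line and reports, per threshold, the number of lines with
#' at least one candidate gene, the total number of candidate genes, and the
#' false-positive rate — the proportion of lines with more than one
#' candidate gene (every line carries a single recessive mutation, so more
#' than one candidate implies at least one false positive).
#'
#' @param stats_list Named list of per-line [linkage_stats()] tables.
#' @param thresholds Numeric vector of D-value thresholds.
#' @param config Base [linkage_config()]; its `d_threshold` is overridden by
#'   each grid value.
#' @param localize If `TRUE` (default) candidate calling is restricted to the
#'   chromosomes called at that threshold, mirroring the two-stage pipeline;
#'   `FALSE` calls genome-wide.
#' @return data.frame with columns `threshold`, `n_mutants_with_candidates`,
#'   `n_candidate_genes`, `false_positive_rate`.
#' @export
sweep_thresholds <- function(stats_list, thresholds = seq(0.1, 0.9, by = 0.1),
                             config = linkage_config(), localize = TRUE) {
  stopifnot(length(stats_list) >= 1)
  rows <- lapply(thresholds, function(t) {
    cfg <- config
    cfg$d_threshold <- t
    genes_per_line <- vapply(stats_list, function(st) {
      chroms <- NULL
      if (localize) {
        cc <- localize_chromosome(call_linked_snps(st, cfg))
        if (cc$status == "none") return(0L)
        chroms <- cc$called_chromosomes
      }
      length(unique(call_candidate_genes(st, cfg, chromosomes = chroms)$gene_id))
    }, integer(1))
    data.frame(threshold = t,
               n_mutants_with_candidates = sum(genes_per_line >= 1L),
               n_candidate_genes = sum(genes_per_line),
               false_positive_rate = mean(genes_per_line > 1L))
  })
  do.call(rbind, rows)
}
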