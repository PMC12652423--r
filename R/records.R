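# Internal data model: a table of biallelic SNP sites with per-pool allele
# depths. Coordinates are 1-based inclusive throughout (VCF/GFF3 convention);
# conversion to 0-based half-open happens only when writing BED.

#' Controlled vocabulary of variant effect labels
#'
#' Effect annotations attached to SNP records are mapped into this fixed
#' vocabulary; any label outside it becomes `"other"`. The first four entries
#' are ordered by decreasing severity, which is the order used to collapse
#' multi-effect annotations.
#'
#' @return Character vector of recognised effect labels.
#' @export
effect_vocabulary <- function() {
  c("stop_gained", "splice_region_variant", "missense_variant",
    "synonymous_variant", "intron_variant", "intergenic_region",
    "upstream_gene_variant", "downstream_gene_variant", "other")
}

# severity rank: smaller = more severe; everything past the first four ties
.effect_severity <- function(effect) {
  rank <- match(effect, effect_vocabulary())
  rank[is.na(rank)] <- length(effect_vocabulary())
  rank[rank > 4L] <- 5L
  rank
}

# Map arbitrary annotation strings (possibly "&"-joined SnpEff terms) into the
# vocabulary, keeping the most severe component.
normalize_effect <- function(x) {
  vocab <- effect_vocabulary()
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    parts <- strsplit(s, "&", fixed = TRUE)[[1]]
    parts[!parts %in% vocab] <- "other"
    parts[which.min(.effect_severity(parts))]
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a table of SNP records
#'
#' One row per biallelic SNP site, carrying read depths for the reference and
#' alternate allele in the mutant (MT) and wild-type (WT) pool. This is the
#' container every downstream stage (filtering, linkage statistics, candidate
#' calling) operates on.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Single-nucleotide reference and alternate alleles (A/C/G/T).
#' @param mt_ref,mt_alt Reference/alternate read counts in the mutant pool.
#' @param wt_ref,wt_alt Reference/alternate read counts in the wild-type pool.
#' @param effect Optional effect labels (see [effect_vocabulary()]); `NA` when
#'   unannotated.
#' @param gene_id Optional gene identifiers; sites inside several overlapping
#'   genes carry all ids joined with `";"`; `NA` outside any gene.
#' @return A `data.frame` with class `snp_records`.
#' @export
snp_records <- function(chrom, pos, ref, alt, mt_ref, mt_alt, wt_ref, wt_alt,
                        effect = NA_character_, gene_id = NA_character_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    mt_ref = as.integer(mt_ref), mt_alt = as.integer(mt_alt),
    wt_ref = as.integer(wt_ref), wt_alt = as.integer(wt_alt),
    effect = rep_len(as.character(effect), n),
    gene_id = rep_len(as.character(gene_id), n),
    stringsAsFactors = FALSE
  )
  validate_snp_records(df)
  class(df) <- c("snp_records", "data.frame")
  df
}

validate_snp_records <- function(df) {
  bases <- c("A", "C", "G", "T")
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  if (!all(df$ref %in% bases) || !all(df$alt %in% bases))
    stop("ref and alt must be single nucleotides in {A,C,G,T}")
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  counts <- as.matrix(df[, c("mt_ref", "mt_alt", "wt_ref", "wt_alt")])
  if (any(counts < 0L) || anyNA(counts)) stop("read counts must be >= 0")
  eff <- df$effect[!is.na(df$effect)]
  if (!all(eff %in% effect_vocabulary()))
    stop("effect labels must come from effect_vocabulary()")
  invisible(df)
}

#' Site keys for SNP records
#'
#' A site key identifies a variant as `"chrom:pos:alt"`; it is the join key
#' for effect annotations and for the cross-line presence filter.
#'
#' @param records A `snp_records` table (or any data.frame with `chrom`,
#'   `pos`, `alt` columns).
#' @return Character vector of keys.
#' @export
site_key <- function(records) {
  paste(records$chrom, records$pos, records$alt, sep = ":")
}

.as_snp_records <- function(df) {
  class(df) <- unique(c("snp_records", class(df)))
  df
}
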