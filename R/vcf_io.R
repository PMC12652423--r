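# VCF / GFF3 ingestion and result writing. Parsing is delegated to vcfR and
# rtracklayer; this file only maps their output onto the snp_records model.

# Parse one VCF into per-sample (ref, alt) depth columns for the requested
# samples. Multiallelic lines are split into one row per ALT allele; indel
# alleles and rows without usable depths are skipped and counted.
.parse_pool_vcf <- function(path, samples) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  avail <- colnames(v@gt)
  avail <- avail[avail != "FORMAT"]
  missing <- setdiff(samples, avail)
  if (length(missing) > 0)
    stop("sample(s) ", paste(missing, collapse = ", "),
         " not in VCF; available: ", paste(avail, collapse = ", "))

  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  counts <- c(lines = n, indel_skipped = 0L, depth_skipped = 0L,
              malformed_ad = 0L)
  empty <- function() {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE)
    for (s in samples) {
      out[[paste0(s, "_ref")]] <- integer()
      out[[paste0(s, "_alt")]] <- integer()
    }
    out
  }
  if (n == 0) {
    out <- empty()
    attr(out, "io_counts") <- counts
    return(out)
  }

  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"),
                 error = function(e) NULL)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (!(ref %in% bases)) {           # indel / MNP reference
      counts["indel_skipped"] <- counts["indel_skipped"] + 1L
      next
    }
    snp_alts_idx <- which(alts %in% bases & alts != ref)
    if (length(snp_alts_idx) == 0) {   # pure indel line
      counts["indel_skipped"] <- counts["indel_skipped"] + 1L
      next
    }
    # per-sample AD: "ref,alt1[,alt2...]"
    depths <- matrix(NA_integer_, nrow = length(samples),
                     ncol = length(alts) + 1L)
    ok <- TRUE
    for (j in seq_along(samples)) {
      adstr <- if (is.null(ad)) NA_character_ else ad[i, samples[j]]
      if (is.na(adstr) || !nzchar(adstr)) { ok <- FALSE; break }
      vals <- suppressWarnings(as.integer(strsplit(adstr, ",", fixed = TRUE)[[1]]))
      if (anyNA(vals) || length(vals) < length(alts) + 1L) {
        counts["malformed_ad"] <- counts["malformed_ad"] + 1L
        ok <- FALSE
        break
      }
      depths[j, seq_along(vals)] <- vals
    }
    if (!ok) {
      counts["depth_skipped"] <- counts["depth_skipped"] + 1L
      next
    }
    sub <- data.frame(chrom = unname(fix[i, "CHROM"]),
                      pos = as.integer(fix[i, "POS"]),
                      ref = unname(ref), alt = unname(alts[snp_alts_idx]),
                      row.names = NULL, stringsAsFactors = FALSE)
    for (j in seq_along(samples)) {
      sub[[paste0(samples[j], "_ref")]] <- depths[j, 1L]
      sub[[paste0(samples[j], "_alt")]] <- depths[j, 1L + snp_alts_idx]
    }
    rows[[i]] <- sub
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty()
  rownames(out) <- NULL
  attr(out, "io_counts") <- counts
  out
}

#' Read a two-sample pooled-variant VCF
#'
#' Reads a jointly-called VCF holding both the mutant pool and the wild-type
#' sibling pool, and returns one [snp_records] row per biallelic SNP allele.
#' Multiallelic lines are split per ALT allele; indel lines and lines without
#' a parseable AD (allele depth) field for either sample are skipped, with
#' skip counts recorded in the `"io_counts"` attribute.
#'
#' @param path Path to a VCF (v4.x) file with per-sample AD fields.
#' @param mt_sample,wt_sample Sample names of the mutant and wild-type pool.
#' @return A `snp_records` table with attribute `io_counts`.
#' @export
read_pool_vcf <- function(path, mt_sample, wt_sample) {
  raw <- .parse_pool_vcf(path, c(mt_sample, wt_sample))
  out <- snp_records(raw$chrom, raw$pos, raw$ref, raw$alt,
                     mt_ref = raw[[paste0(mt_sample, "_ref")]],
                     mt_alt = raw[[paste0(mt_sample, "_alt")]],
                     wt_ref = raw[[paste0(wt_sample, "_ref")]],
                     wt_alt = raw[[paste0(wt_sample, "_alt")]])
  attr(out, "io_counts") <- attr(raw, "io_counts")
  out
}

#' Read separately-called per-pool VCFs
#'
#' The two pools may be called separately, producing one single-sample VCF
#' each. Records are merged on (chrom, pos, ref, alt); a site absent from one
#' pool's VCF gets zero depths for that pool (such sites are later removed by
#' the coverage filter).
#'
#' @param mt_path,wt_path Paths to the mutant-pool and wild-type-pool VCFs.
#' @param mt_sample,wt_sample Optional sample names; default is the first
#'   sample in each file.
#' @return A `snp_records` table with attribute `io_counts` (summed over both
#'   files).
#' @export
read_pool_vcf_pair <- function(mt_path, wt_path,
                               mt_sample = NULL, wt_sample = NULL) {
  first_sample <- function(path) {
    v <- vcfR::read.vcfR(path, verbose = FALSE, nrows = 1)
    cols <- colnames(v@gt)
    cols[cols != "FORMAT"][1]
  }
  if (is.null(mt_sample)) mt_sample <- first_sample(mt_path)
  if (is.null(wt_sample)) wt_sample <- first_sample(wt_path)
  mt <- .parse_pool_vcf(mt_path, mt_sample)
  wt <- .parse_pool_vcf(wt_path, wt_sample)
  names(mt)[5:6] <- c("mt_ref", "mt_alt")
  names(wt)[5:6] <- c("wt_ref", "wt_alt")
  merged <- merge(mt, wt, by = c("chrom", "pos", "ref", "alt"), all = TRUE)
  for (col in c("mt_ref", "mt_alt", "wt_ref", "wt_alt"))
    merged[[col]][is.na(merged[[col]])] <- 0L
  merged <- merged[order(merged$chrom, merged$pos, merged$alt), ]
  out <- snp_records(merged$chrom, merged$pos, merged$ref, merged$alt,
                     merged$mt_ref, merged$mt_alt,
                     merged$wt_ref, merged$wt_alt)
  attr(out, "io_counts") <- attr(mt, "io_counts") + attr(wt, "io_counts")
  out
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene`-type features only and returns the 1-based inclusive
#' intervals used for variant-to-gene assignment.
#'
#' @param path Path to a GFF3 file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::import(path)
  g <- g[g$type == "gene"]
  id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

# Parse SnpEff ANN entries of one VCF into an effect table keyed by
# (chrom, pos, alt). ANN format: Allele|Annotation|Impact|Gene_Name|Gene_ID|...
.ann_vcf_effect_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ann <- vcfR::extract.info(v, element = "ANN")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    if (is.na(ann[i])) next
    for (entry in strsplit(ann[i], ",", fixed = TRUE)[[1]]) {
      f <- strsplit(entry, "|", fixed = TRUE)[[1]]
      if (length(f) < 2) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        alt = f[1], effect = f[2],
        gene_id = if (length(f) >= 5 && nzchar(f[5])) f[5] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(chrom = character(), pos = integer(), alt = character(),
                  effect = character(), gene_id = character())
}

#' Attach effect annotations to SNP records
#'
#' Annotations can come from a SnpEff-annotated VCF (ANN INFO field), from a
#' plain effect table (`chrom pos alt effect gene_id` TSV or data.frame), or
#' be absent. When a site carries several annotations, the most severe one is
#' kept, in the fixed order stop_gained > splice_region_variant >
#' missense_variant > synonymous_variant > everything else. Labels outside
#' [effect_vocabulary()] are mapped to `"other"`. Unmatched records keep
#' `effect = NA`; the number of annotations with no matching record is
#' recorded in attribute `"n_unmatched_ann"`.
#'
#' @param records A `snp_records` table.
#' @param ann_source Path to an ANN-annotated VCF, path to a TSV effect
#'   table, or a data.frame with columns `chrom`, `pos`, `alt`, `effect` and
#'   optionally `gene_id`.
#' @return `records` with `effect` (and `gene_id`, where provided) filled.
#' @export
attach_effects <- function(records, ann_source) {
  if (is.character(ann_source)) {
    if (!file.exists(ann_source)) stop("annotation source not found: ", ann_source)
    head1 <- readLines(ann_source, n = 1)
    tab <- if (grepl("^##fileformat=VCF", head1)) .ann_vcf_effect_table(ann_source)
           else read.delim(ann_source, stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(ann_source, stringsAsFactors = FALSE)
  }
  if (!all(c("chrom", "pos", "alt", "effect") %in% names(tab)))
    stop("effect table needs columns chrom, pos, alt, effect")
  if (is.null(tab$gene_id)) tab$gene_id <- NA_character_

  tab$effect <- normalize_effect(tab$effect)
  tab$key <- site_key(tab)
  # most severe annotation per site
  tab <- tab[order(.effect_severity(tab$effect)), ]
  tab <- tab[!duplicated(tab$key), ]

  idx <- match(site_key(records), tab$key)
  hit <- !is.na(idx)
  records$effect[hit] <- tab$effect[idx[hit]]
  fill_gene <- hit & !is.na(tab$gene_id[idx])
  records$gene_id[fill_gene] <- tab$gene_id[idx[fill_gene]]
  attr(records, "n_unmatched_ann") <- sum(!tab$key %in% site_key(records))
  records
}

#' Assign SNP records to gene models
#'
#' A record whose position falls inside a gene's 1-based inclusive
#' `[start, end]` interval gets that gene's id; a record inside several
#' overlapping genes gets all ids joined with `";"`; a record outside all
#' genes gets `NA`. Overlap is computed with `GenomicRanges::findOverlaps()`.
#'
#' @param records A `snp_records` table.
#' @param gene_models data.frame as returned by [read_gff_genes()].
#' @return `records` with `gene_id` filled.
#' @export
assign_genes <- function(records, gene_models) {
  if (nrow(records) == 0 || nrow(gene_models) == 0) return(records)
  sites <- GenomicRanges::GRanges(records$chrom,
                                  IRanges::IRanges(records$pos, records$pos))
  genes <- GenomicRanges::GRanges(gene_models$chrom,
                                  IRanges::IRanges(gene_models$start,
                                                   gene_models$end))
  ov <- GenomicRanges::findOverlaps(sites, genes)
  q <- S4Vectors::queryHits(ov)
  ids <- vapply(split(gene_models$gene_id[S4Vectors::subjectHits(ov)], q),
                paste, character(1), collapse = ";")
  records$gene_id <- NA_character_
  records$gene_id[as.integer(names(ids))] <- ids
  records
}

#' Write mapping results to disk
#'
#' Writes `candidates.tsv` (one row per supporting candidate site),
#' `linked.bed` (0-based half-open single-base intervals of linked SNPs,
#' with the site key as name and the D-value as score column) and
#' `summary.json` (run counts and configuration).
#'
#' @param dir Output directory (created if missing).
#' @param linked Linkage-statistics table of linked SNPs (may be empty).
#' @param candidates Candidate-site table (may be empty).
#' @param summary Named list serialised to `summary.json`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(dir, linked, candidates, summary = list()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) stop("cannot write to ", dir)
  tsv <- file.path(dir, "candidates.tsv")
  bed <- file.path(dir, "linked.bed")
  json <- file.path(dir, "summary.json")
  write.table(candidates, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_df <- data.frame(chrom = linked$chrom,
                       start = linked$pos - 1L,   # 0-based half-open
                       end = linked$pos,
                       name = site_key(linked),
                       score = round(linked$d_value, 4))
  write.table(bed_df, bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(candidates = tsv, linked = bed, summary = json))
}
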