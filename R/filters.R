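# High-confidence SNP filtering for EMS bulked-segregant experiments, plus
# the mutation-spectrum-vs-coverage diagnostic that motivates the coverage
# cutoff.

#' Configuration of the high-confidence SNP filters
#'
#' Three filters select high-confidence SNPs: (a) the site must be covered by
#' at least `min_coverage` reads in each pool, (b) the alternate allele must
#' be detected (>= 1 read) in both pools, and (c) sites present in more than
#' `max_line_fraction` of the mutant lines in the cohort are discarded as
#' shared background variants. Coverage is enforced per pool — an allele-
#' frequency estimate from fewer reads in either pool is not usable.
#'
#' @param min_coverage Minimum per-pool read depth (default 5).
#' @param max_line_fraction Maximum tolerated fraction of cohort lines
#'   carrying the site (default 0.10; the comparison is strict, so a site in
#'   exactly 10 percent of lines is kept).
#' @param require_both_pools Enforce filter (b)? Default `TRUE`.
#' @return A list with class `ebsr_filter_config`.
#' @export
filter_config <- function(min_coverage = 5L, max_line_fraction = 0.10,
                          require_both_pools = TRUE) {
  min_coverage <- as.integer(min_coverage)
  stopifnot(min_coverage >= 1L,
            max_line_fraction > 0, max_line_fraction <= 1,
            is.logical(require_both_pools))
  structure(list(min_coverage = min_coverage,
                 max_line_fraction = max_line_fraction,
                 require_both_pools = require_both_pools),
            class = "ebsr_filter_config")
}

#' Build the cross-line site cohort from a manifest
#'
#' Reads every line's raw (pre-filter) variant records and collects the site
#' keys seen in each line, in either pool. The result feeds the
#' shared-site filter (c) of [filter_high_confidence()].
#'
#' @param manifest data.frame (or TSV path) with columns `line_id`,
#'   `vcf_mt`, `vcf_wt`; relative file paths in a manifest read from disk
#'   are resolved against the manifest's directory.
#' @return Named list mapping `line_id` to a character vector of site keys.
#' @export
build_line_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(all(c("line_id", "vcf_mt", "vcf_wt") %in% names(manifest)))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_pool_vcf_pair(manifest$vcf_mt[i], manifest$vcf_wt[i])
    unique(site_key(rec))
  })
  names(out) <- manifest$line_id
  out
}

#' Read a cohort manifest TSV
#'
#' Columns `line_id`, `vcf_mt`, `vcf_wt` and optionally `effects`; relative
#' paths are resolved against the manifest's own directory, so a generated
#' cohort directory can be moved as a unit.
#'
#' @param path Manifest TSV path.
#' @return data.frame with absolute file paths.
#' @export
read_manifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  for (col in intersect(c("vcf_mt", "vcf_wt", "effects"), names(man))) {
    rel <- !grepl("^(/|[A-Za-z]:)", man[[col]])
    man[[col]][rel] <- file.path(base, man[[col]][rel])
  }
  man
}

#' Apply the high-confidence SNP filters
#'
#' Applies, in order, (a) per-pool coverage >= `min_coverage`, (b) alternate
#' allele detected in both pools, and (c) the cross-line blacklist: sites
#' whose key is present in more than `max_line_fraction` of cohort lines are
#' discarded. Drop counts attribute each removed record to the first filter
#' it fails, so drops + survivors always partition the input.
#'
#' Cohort presence is a property of the raw, pre-filter record sets (the
#' blacklist targets shared background variants, which is a detection
#' property, not a post-filter one); build the cohort with
#' [build_line_cohort()] on unfiltered records.
#'
#' @param records A `snp_records` table.
#' @param cohort Named list of per-line site-key vectors (or `NULL` to skip
#'   filter (c), e.g. for a single line without cohort context).
#' @param line_id Id of the line being filtered; must be a name of `cohort`
#'   when `cohort` is given.
#' @param config A [filter_config()].
#' @return List with elements `records` (survivors), `drops` (named counts
#'   for `coverage`, `both_pools`, `shared`) and `n_input`.
#' @export
filter_high_confidence <- function(records, cohort = NULL, line_id = NULL,
                                   config = filter_config()) {
  stopifnot(inherits(config, "ebsr_filter_config"))
  if (!is.null(cohort)) {
    if (length(cohort) == 0) stop("cohort is empty")
    if (!is.null(line_id) && !line_id %in% names(cohort))
      stop("line_id ", line_id, " not in cohort")
  }
  n <- nrow(records)
  pass_cov <- (records$mt_ref + records$mt_alt) >= config$min_coverage &
              (records$wt_ref + records$wt_alt) >= config$min_coverage
  pass_both <- if (config$require_both_pools)
    records$mt_alt >= 1L & records$wt_alt >= 1L else rep(TRUE, n)
  if (!is.null(cohort)) {
    keys <- site_key(records)
    n_lines <- length(cohort)
    if (n == 0) {
      pass_shared <- logical(0)
    } else {
      presence <- rowSums(vapply(cohort, function(s) keys %in% s, logical(n)))
      pass_shared <- presence / n_lines <= config$max_line_fraction
    }
  } else {
    pass_shared <- rep(TRUE, n)
  }
  drops <- c(coverage = sum(!pass_cov),
             both_pools = sum(pass_cov & !pass_both),
             shared = sum(pass_cov & pass_both & !pass_shared))
  keep <- pass_cov & pass_both & pass_shared
  list(records = records[keep, , drop = FALSE], drops = drops, n_input = n)
}

#' Is a substitution canonical for EMS mutagenesis?
#'
#' EMS alkylates guanine, producing almost exclusively C->T and G->A
#' transitions (reported on the reference strand, no complementing).
#'
#' @param ref_base,alt_base Reference and alternate bases (vectorised).
#' @return Logical vector: `TRUE` iff (ref, alt) is (C,T) or (G,A).
#' @export
is_canonical_ems <- function(ref_base, alt_base) {
  (ref_base == "C" & alt_base == "T") | (ref_base == "G" & alt_base == "A")
}

#' EMS-spectrum-versus-coverage diagnostic
#'
#' For each coverage cutoff `c`, restricts to records whose minimum per-pool
#' depth is at least `c` (cumulative semantics) and reports the fraction of
#' canonical EMS substitutions among them. On real EMS data this fraction
#' rises with the cutoff and plateaus once spurious low-coverage calls are
#' excluded — the behaviour that justifies the default coverage filter of 5.
#'
#' @param records A `snp_records` table.
#' @param cutoffs Strictly increasing integer coverage cutoffs.
#' @return data.frame with columns `cutoff`, `n_sites`,
#'   `canonical_fraction` (`NA` where no sites remain).
#' @export
ems_spectrum_curve <- function(records, cutoffs = 1:10) {
  cutoffs <- as.integer(cutoffs)
  if (is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing")
  min_depth <- pmin(records$mt_ref + records$mt_alt,
                    records$wt_ref + records$wt_alt)
  canonical <- is_canonical_ems(records$ref, records$alt)
  out <- lapply(cutoffs, function(cc) {
    sel <- min_depth >= cc
    data.frame(cutoff = cc, n_sites = sum(sel),
               canonical_fraction = if (any(sel)) mean(canonical[sel]) else NA_real_)
  })
  do.call(rbind, out)
}
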