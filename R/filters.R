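#' Somatic substitution post-processing filter
#'
#' A record passes when the normal-sample variant allele fraction is at most
#' `max_normal_vaf` (default 3%), the tumour VAF is at least
#' `min_tumor_vaf` (default 10%), and no germline SNP/indel lies within
#' `germline_window` bp (default 5). Records with zero depth in either
#' tissue fail with reason `no_coverage`. The filter is a pure function:
#' it never alters records, it only appends a verdict.
#'
#' @param catalog a mutation catalog
#' @param germline_sites tibble of known germline sites (`chrom`, `pos`)
#' @param max_normal_vaf,min_tumor_vaf,germline_window thresholds
#' @return the catalog with `pass` (logical) and `reason` columns appended;
#'   reason is one of `pass`, `no_coverage`, `normal_contamination`,
#'   `low_tumor_vaf`, `germline_proximity`
#' @export
somatic_snv_filter <- function(catalog, germline_sites = NULL,
                               max_normal_vaf = 0.03,
                               min_tumor_vaf = 0.10,
                               germline_window = 5L) {
  validate_mutations(catalog)
  n <- nrow(catalog)
  reason <- rep("pass", n)
  no_cov <- catalog$t_depth == 0 | catalog$n_depth == 0
  n_vaf <- ifelse(catalog$n_depth > 0, catalog$n_alt / catalog$n_depth, 0)
  t_vaf <- ifelse(catalog$t_depth > 0, catalog$t_alt / catalog$t_depth, 0)
  near_germ <- rep(FALSE, n)
  if (!is.null(germline_sites) && nrow(germline_sites) > 0) {
    rec_gr <- GRanges(catalog$chrom,
                      IRanges(catalog$pos - germline_window,
                              catalog$pos + germline_window))
    g_gr <- GRanges(germline_sites$chrom,
                    IRanges(germline_sites$pos, germline_sites$pos))
    near_germ <- countOverlaps(rec_gr, g_gr) > 0
  }
  reason[near_germ] <- "germline_proximity"
  reason[t_vaf < min_tumor_vaf] <- "low_tumor_vaf"
  reason[n_vaf > max_normal_vaf] <- "normal_contamination"
  reason[no_cov] <- "no_coverage"
  catalog$pass <- reason == "pass"
  catalog$reason <- reason
  catalog
}

#' Indel post-processing filter
#'
#' Requires a minimum depth of `min_depth` reads (default 15) in both
#' tumour and normal. Small indels (length change up to `small_max` bp,
#' default 10) additionally need at least `min_pindel` split-read supporting
#' reads (default 4) and at least `min_bwa` mapper-supporting reads
#' (default 1). Larger indels must lie outside repeat regions and be
#' supported at least once on each strand.
#'
#' @param catalog a mutation catalog of INS/DEL records
#' @param pindel_support,bwa_support per-record split-read and mapper
#'   support counts
#' @param strand_fwd,strand_rev per-record supporting reads by strand
#' @param in_repeat per-record logical: does the indel fall in a repeat
#' @param min_depth,small_max,min_pindel,min_bwa thresholds
#' @return the catalog with `pass` and `reason` columns appended
#' @export
indel_filter <- function(catalog, pindel_support, bwa_support,
                         strand_fwd, strand_rev, in_repeat,
                         min_depth = 15L, small_max = 10L,
                         min_pindel = 4L, min_bwa = 1L) {
  validate_mutations(catalog)
  if (any(catalog$class == "SNV")) {
    stop("indel_filter applies to INS/DEL records only")
  }
  n <- nrow(catalog)
  stopifnot(length(pindel_support) == n, length(bwa_support) == n,
            length(strand_fwd) == n, length(strand_rev) == n,
            length(in_repeat) == n)
  len <- abs(nchar(catalog$alt) - nchar(catalog$ref))
  small <- len <= small_max
  reason <- rep("pass", n)
  reason[small & (pindel_support < min_pindel | bwa_support < min_bwa)] <-
    "insufficient_support"
  reason[!small & (strand_fwd < 1 | strand_rev < 1)] <-
    "insufficient_support"
  reason[!small & in_repeat] <- "repeat_region"
  reason[catalog$t_depth < min_depth | catalog$n_depth < min_depth] <-
    "low_depth"
  catalog$pass <- reason == "pass"
  catalog$reason <- reason
  catalog
}

#' Non-synonymous to synonymous ratio of an annotated catalog
#'
#' The ratio of missense plus nonsense substitutions to synonymous
#' substitutions, reported to one decimal. Splice-site, UTR and indel
#' records do not enter either count. With the printed study counts
#' (168 missense, 16 nonsense, 79 synonymous) the ratio is 2.3.
#'
#' @param catalog an annotated mutation catalog (has a `consequence` column)
#' @return ratio rounded to one decimal, or `NA` with a warning when there
#'   are no synonymous mutations
#' @export
ns_s_ratio <- function(catalog) {
  if (!"consequence" %in% names(catalog)) {
    stop("catalog must be annotated (no consequence column)")
  }
  ns <- sum(catalog$consequence %in% c("missense", "nonsense"))
  s <- sum(catalog$consequence == "synonymous")
  if (s == 0) {
    warning("no synonymous mutations: NS:S ratio undefined")
    return(NA_real_)
  }
  round(ns / s, 1)
}
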