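#' Mutation catalog columns
#'
#' A mutation catalog is a tibble with one row per somatic call and columns
#' `sample_id`, `chrom`, `pos` (1-based), `ref`, `alt`, `class` (one of
#' `"SNV"`, `"INS"`, `"DEL"`), `t_depth`, `t_alt`, `n_depth`, `n_alt`, and
#' optionally `consequence` and `gene_id`.
#'
#' @name mutation_catalog
NULL

MUTATION_COLUMNS <- c(
  "sample_id", "chrom", "pos", "ref", "alt", "class",
  "t_depth", "t_alt", "n_depth", "n_alt"
)

VARIANT_CLASSES <- c("SNV", "INS", "DEL")

CONSEQUENCE_LEVELS <- c(
  "synonymous", "missense", "nonsense", "splice_site", "utr3", "utr5",
  "start_gained", "stop_lost", "intergenic", "frameshift", "inframe_indel"
)

#' Validate a mutation catalog
#'
#' Checks the catalog invariants: positive 1-based positions, single distinct
#' A/C/G/T alleles for SNVs, allele-length consistency for indels, and
#' alt counts bounded by depths in both tissues.
#'
#' @param catalog a data frame of mutation records
#' @return the catalog, invisibly, as a tibble
#' @export
validate_mutations <- function(catalog) {
  catalog <- as_tibble(catalog)
  missing <- setdiff(MUTATION_COLUMNS, names(catalog))
  if (length(missing) > 0) {
    stop("mutation catalog missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(catalog) == 0) {
    return(invisible(catalog))
  }
  if (any(catalog$pos < 1)) {
    stop("mutation positions must be 1-based (pos >= 1)")
  }
  if (!all(catalog$class %in% VARIANT_CLASSES)) {
    stop("variant class must be one of ", paste(VARIANT_CLASSES, collapse = "/"))
  }
  snv <- catalog$class == "SNV"
  if (any(snv)) {
    ok <- nchar(catalog$ref[snv]) == 1 & nchar(catalog$alt[snv]) == 1 &
      catalog$ref[snv] %in% DNA_BASES & catalog$alt[snv] %in% DNA_BASES &
      catalog$ref[snv] != catalog$alt[snv]
    if (!all(ok)) stop("SNV records must have single distinct A/C/G/T alleles")
  }
  ins <- catalog$class == "INS"
  if (any(ins) && !all(nchar(catalog$alt[ins]) > nchar(catalog$ref[ins]))) {
    stop("INS records must have alt longer than ref")
  }
  del <- catalog$class == "DEL"
  if (any(del) && !all(nchar(catalog$ref[del]) > nchar(catalog$alt[del]))) {
    stop("DEL records must have ref longer than alt")
  }
  if (any(catalog$t_alt > catalog$t_depth) || any(catalog$n_alt > catalog$n_depth)) {
    stop("alt count exceeds depth")
  }
  if (any(c(catalog$t_depth, catalog$t_alt, catalog$n_depth, catalog$n_alt) < 0)) {
    stop("depths and alt counts must be non-negative")
  }
  invisible(catalog)
}

#' Validate a copy-number segment table
#'
#' Segments are per-sample 1-based inclusive intervals with a non-negative
#' integer copy number (columns `sample_id`, `chrom`, `start`, `end`,
#' `copy_number`).
#'
#' @param segments a data frame of segments
#' @return the segments, invisibly, as a tibble
#' @export
validate_segments <- function(segments) {
  segments <- as_tibble(segments)
  need <- c("sample_id", "chrom", "start", "end", "copy_number")
  missing <- setdiff(need, names(segments))
  if (length(missing) > 0) {
    stop("segment table missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(segments) > 0) {
    if (any(segments$start > segments$end)) stop("segment start > end")
    if (any(segments$start < 1)) stop("segment coordinates are 1-based")
    if (any(segments$copy_number < 0)) stop("copy_number must be >= 0")
  }
  invisible(segments)
}

P53_LEVELS <- c("wt", "het", "hom")
MITF_LEVELS <- c("wt", "null", "vc7")
ONCOGENES <- c("BRAF", "NRAS")

#' Validate a sample sheet
#'
#' One row per fish/tumor with the engineered genotype: `sample_id`,
#' `oncogene` (`BRAF` or `NRAS`), `p53` (`wt`/`het`/`hom`), `mitf`
#' (`wt`/`null`/`vc7`), `mitf_rescue` (logical; MITF minigene rescue in a
#' mitf-null background), `extra_alleles` and `extra_transgenes`
#' (comma-separated, possibly empty), `age` (months, may be NA) and `ploidy`.
#'
#' @param sheet a data frame
#' @return the sheet, invisibly, as a tibble
#' @export
validate_sample_sheet <- function(sheet) {
  sheet <- as_tibble(sheet)
  need <- c(
    "sample_id", "oncogene", "p53", "mitf", "mitf_rescue",
    "extra_alleles", "extra_transgenes", "age", "ploidy"
  )
  missing <- setdiff(need, names(sheet))
  if (length(missing) > 0) {
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sample sheet")
  if (!all(sheet$oncogene %in% ONCOGENES)) {
    bad <- setdiff(unique(sheet$oncogene), ONCOGENES)
    stop("unknown oncogene token(s): ", paste(bad, collapse = ", "),
         " (each sample carries exactly one of BRAF/NRAS)")
  }
  if (!all(sheet$p53 %in% P53_LEVELS)) {
    stop("unknown p53 token(s): ",
         paste(setdiff(unique(sheet$p53), P53_LEVELS), collapse = ", "))
  }
  if (!all(sheet$mitf %in% MITF_LEVELS)) {
    stop("unknown mitf token(s): ",
         paste(setdiff(unique(sheet$mitf), MITF_LEVELS), collapse = ", "))
  }
  if (!is.logical(sheet$mitf_rescue)) stop("mitf_rescue must be logical")
  if (any(sheet$mitf_rescue & sheet$mitf != "null")) {
    stop("mitf_rescue implies a mitf-null background")
  }
  if (any(!is.na(sheet$ploidy) & sheet$ploidy <= 0)) stop("ploidy must be > 0")
  invisible(sheet)
}

#' Count engineered initiating drivers for each sample
#'
#' The driver-counting convention: one for the oncogenic transgene (BRAF or
#' NRAS), one if any mutant p53 allele is present (het and hom both count
#' once), one for a non-wild-type mitf background (null or the hypomorphic
#' vc7 allele), one for MITF minigene rescue, and one per additional germline
#' allele (e.g. ptena het, rps29 het). Co-expressed transcription-factor
#' transgenes (KROX20, FOXD3, OCT6, SETDB1, ...) are not counted: their
#' contribution to melanoma is unestablished. Under this convention the
#' BRAF;p53-/-;mitf-/- + MITF-rescue genotype counts four drivers.
#'
#' @param sheet a validated sample sheet (see [validate_sample_sheet()])
#' @return integer vector of driver counts, one per row
#' @export
count_drivers <- function(sheet) {
  sheet <- as_tibble(sheet)
  validate_sample_sheet(sheet)
  n_extra <- vapply(
    split_tokens(sheet$extra_alleles), length, integer(1)
  )
  as.integer(
    1L +
      (sheet$p53 %in% c("het", "hom")) +
      (sheet$mitf %in% c("null", "vc7")) +
      sheet$mitf_rescue +
      n_extra
  )
}

# split a comma-separated token column into a list of character vectors
split_tokens <- function(x) {
  x[is.na(x)] <- ""
  lapply(strsplit(x, ","), function(t) sort(t[nzchar(trimws(t))]))
}

#' Construct a toy gene-model set
#'
#' Gene models carry one transcript per gene: a `genes` table
#' (`gene_id`, `chrom`, `start`, `end`, `strand`), an `exons` table and a
#' `cds` table (both `gene_id`, `start`, `end`, 1-based inclusive). Exons
#' must be sorted, non-overlapping and contained in the gene span; CDS
#' intervals must lie within exons.
#'
#' @param genes,exons,cds data frames as described
#' @return an object of class `gene_models`
#' @export
gene_models <- function(genes, exons, cds) {
  genes <- as_tibble(genes)
  exons <- as_tibble(exons)
  cds <- as_tibble(cds)
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  for (gid in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == gid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", gid)
    }
    g <- genes[genes$gene_id == gid, ]
    if (nrow(g) != 1) stop("exon references unknown gene ", gid)
    if (min(ex$start) < g$start || max(ex$end) > g$end) {
      stop("exons outside gene span for ", gid)
    }
  }
  exons <- exons[order(exons$gene_id, exons$start), ]
  cds <- cds[order(cds$gene_id, cds$start), ]
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      nrow(x$exons), "exons,", nrow(x$cds), "CDS intervals\n")
  invisible(x)
}

genes_granges <- function(models) {
  GRanges(
    models$genes$chrom,
    IRanges(models$genes$start, models$genes$end),
    strand = models$genes$strand,
    gene_id = models$genes$gene_id
  )
}
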