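#' Read a mutation catalog
#'
#' Two dialects are supported. `tsv` is the package's tab-delimited catalog:
#' columns `sample_id`, `chrom`, `pos`, `ref`, `alt`, `class`, `t_depth`,
#' `t_alt`, `n_depth`, `n_alt` (optionally `consequence`, `gene_id`), with
#' `#` comment lines. `vcf` reads a VCF 4.2 file for one tumour/normal pair
#' with `NORMAL` and `TUMOR` genotype columns carrying an `AD` (ref,alt
#' allele depth) field; per-tissue depth is the sum of the AD entries.
#'
#' @param path file to read
#' @param format `"tsv"` or `"vcf"`
#' @param sample_id sample label for VCF input (defaults to the file stem)
#' @return a validated mutation catalog tibble
#' @export
read_mutations <- function(path, format = c("tsv", "vcf"),
                           sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    read_mutations_tsv(path)
  } else {
    read_mutations_vcf(path, sample_id = sample_id)
  }
}

read_mutations_tsv <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(body)
  if (length(idx) == 0) {
    return(validate_mutations(empty_catalog()))
  }
  nfields <- lengths(strsplit(lines[idx], "\t", fixed = TRUE))
  header_n <- nfields[1]
  bad <- which(nfields != header_n)
  if (length(bad) > 0) {
    stop("malformed mutation TSV at line ", idx[bad[1]],
         ": expected ", header_n, " fields, found ", nfields[bad[1]])
  }
  df <- read.delim(
    text = paste(lines[idx], collapse = "\n"),
    stringsAsFactors = FALSE, colClasses = "character"
  )
  for (col in c("pos", "t_depth", "t_alt", "n_depth", "n_alt")) {
    if (col %in% names(df)) {
      v <- suppressWarnings(as.integer(df[[col]]))
      if (anyNA(v) && !anyNA(df[[col]])) {
        stop("non-integer value in column ", col)
      }
      df[[col]] <- v
    }
  }
  if (any(df$pos == 0, na.rm = TRUE)) {
    stop("coordinate 0 found: mutation positions are 1-based")
  }
  out <- as_tibble(df)
  validate_mutations(out)
  out
}

empty_catalog <- function() {
  tibble(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), class = character(),
    t_depth = integer(), t_alt = integer(),
    n_depth = integer(), n_alt = integer()
  )
}

read_mutations_vcf <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(validate_mutations(empty_catalog()))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  cols <- colnames(ad)
  t_col <- grep("tumou?r", cols, ignore.case = TRUE, value = TRUE)
  n_col <- grep("normal", cols, ignore.case = TRUE, value = TRUE)
  if (length(t_col) != 1 || length(n_col) != 1) {
    stop("VCF must contain one TUMOR and one NORMAL genotype column")
  }
  parse_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  }
  t_ad <- parse_ad(ad[, t_col])
  n_ad <- parse_ad(ad[, n_col])
  ref <- fix$REF
  alt <- fix$ALT
  class <- ifelse(
    nchar(ref) == nchar(alt), "SNV",
    ifelse(nchar(alt) > nchar(ref), "INS", "DEL")
  )
  out <- tibble(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = ref,
    alt = alt,
    class = class,
    t_depth = as.integer(t_ad[, 1] + t_ad[, 2]),
    t_alt = as.integer(t_ad[, 2]),
    n_depth = as.integer(n_ad[, 1] + n_ad[, 2]),
    n_alt = as.integer(n_ad[, 2])
  )
  validate_mutations(out)
  out
}

#' Write a mutation catalog
#'
#' `tsv` writes the package catalog dialect (round-trips through
#' [read_mutations()]). `vcf` writes a minimal VCF 4.2 for a single
#' tumour/normal pair with `NORMAL`/`TUMOR` columns carrying `AD` and `DP`.
#'
#' @param catalog a mutation catalog
#' @param path output file
#' @param format `"tsv"` or `"vcf"`
#' @return `path`, invisibly
#' @export
write_mutations <- function(catalog, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  validate_mutations(catalog)
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# zebramel mutation catalog", con)
    keep <- intersect(
      c(MUTATION_COLUMNS, "consequence", "gene_id"), names(catalog)
    )
    write.table(catalog[, keep], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    if (length(unique(catalog$sample_id)) > 1) {
      stop("VCF output supports a single tumour/normal pair")
    }
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "NORMAL", "TUMOR", sep = "\t")
    )
    rec <- paste(
      catalog$chrom, catalog$pos, ".", catalog$ref, catalog$alt, ".", "PASS",
      ".", "AD:DP",
      paste0(catalog$n_depth - catalog$n_alt, ",", catalog$n_alt, ":",
             catalog$n_depth),
      paste0(catalog$t_depth - catalog$t_alt, ",", catalog$t_alt, ":",
             catalog$t_depth),
      sep = "\t"
    )
    writeLines(c(hdr, rec), path)
  }
  invisible(path)
}

#' Read / write SEG-like copy-number segment tables
#'
#' Tab-delimited with columns `sample_id`, `chrom`, `start`, `end`,
#' `copy_number` (1-based inclusive coordinates).
#'
#' @param path file path
#' @return a validated segment tibble
#' @export
read_segments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  out <- as_tibble(df)
  validate_segments(out)
  out
}

#' @rdname read_segments
#' @param segments a segment table
#' @export
write_segments <- function(segments, path) {
  validate_segments(segments)
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' Tab-delimited genotype sheet; see [validate_sample_sheet()] for columns.
#' Empty `extra_alleles`/`extra_transgenes` cells are read as `""`.
#'
#' @param path file path
#' @return a validated sample sheet tibble
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   na.strings = "NA")
  for (col in c("extra_alleles", "extra_transgenes")) {
    if (col %in% names(df)) {
      df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
    }
  }
  df$mitf_rescue <- as.logical(df$mitf_rescue)
  out <- as_tibble(df)
  validate_sample_sheet(out)
  out
}

#' @rdname read_sample_sheet
#' @param sheet a sample sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: set id, description, then member gene ids, tab-separated.
#' Sets must be non-empty.
#'
#' @param path file path
#' @return a tibble with columns `set_id`, `description` and a list-column
#'   `genes`
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("GMT line ", bad[1], " has no member genes (empty gene set)")
  }
  tibble(
    set_id = vapply(parts, `[`, character(1), 1),
    description = vapply(parts, `[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param sets a gene-set tibble as returned by [read_gmt()]
#' @export
write_gmt <- function(sets, path) {
  if (any(lengths(sets$genes) == 0)) stop("empty gene set")
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set_id[i], sets$description[i], sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write toy gene models as GFF3
#'
#' Gene models use `gene`, `exon` and `CDS` features with `ID=`/`Parent=`
#' attributes, one transcript per gene. Coordinates are 1-based inclusive.
#'
#' @param path file path
#' @return a [gene_models()] object
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- mcols(gr)
  type <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))
  is_gene <- type == "gene"
  genes <- tibble(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr)[is_gene])
  )
  sub_tbl <- function(what) {
    keep <- type == what
    tibble(
      gene_id = parent[keep],
      start = GenomicRanges::start(gr)[keep],
      end = GenomicRanges::end(gr)[keep]
    )
  }
  gene_models(genes, sub_tbl("exon"), sub_tbl("CDS"))
}

#' @rdname read_gene_models
#' @param models a `gene_models` object
#' @export
write_gene_models <- function(models, path) {
  g <- models$genes
  rows <- c(
    "##gff-version 3",
    sprintf("%s\tzebramel\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, g$start, g$end, g$strand, g$gene_id)
  )
  chrom_of <- setNames(g$chrom, g$gene_id)
  strand_of <- setNames(g$strand, g$gene_id)
  feat_rows <- function(tbl, what) {
    sprintf("%s\tzebramel\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
            chrom_of[tbl$gene_id], what, tbl$start, tbl$end,
            strand_of[tbl$gene_id],
            if (what == "CDS") "0" else ".", tbl$gene_id)
  }
  writeLines(c(rows, feat_rows(models$exons, "exon"),
               feat_rows(models$cds, "CDS")), path)
  invisible(path)
}
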