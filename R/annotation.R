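#' Annotate mutation consequences against toy gene models
#'
#' A minimal, strand-aware effect predictor over one-transcript gene models.
#' SNVs in coding sequence are classified by the standard genetic code as
#' synonymous, missense, nonsense or stop_lost; indels in coding sequence
#' are frameshift when the length change is not a multiple of three, else
#' inframe_indel. Intronic positions within 2 bp of an exon boundary are
#' splice_site (the canonical donor/acceptor window); deeper intronic
#' positions, like positions outside any gene, are reported intergenic.
#' Exonic non-coding positions are utr5/utr3 by their position relative to
#' the CDS on the coding strand, and a 5' UTR substitution that creates a
#' new ATG on the coding strand is start_gained.
#'
#' The reference allele of every record is checked against the genome; a
#' mismatch is a data-integrity error.
#'
#' @param catalog a mutation catalog
#' @param models a [gene_models()] object
#' @param genome named list/vector of chromosome strings (or DNAStringSet)
#' @return the catalog with `consequence` and `gene_id` columns appended
#' @export
annotate_consequence <- function(catalog, models, genome) {
  validate_mutations(catalog)
  genome <- as_genome_strings(genome)
  n <- nrow(catalog)
  consequence <- character(n)
  gene_id <- rep(NA_character_, n)
  if (n == 0) {
    catalog$consequence <- consequence
    catalog$gene_id <- gene_id
    return(catalog)
  }
  # reference integrity
  obs <- substring(
    unlist(genome[catalog$chrom], use.names = FALSE),
    catalog$pos, catalog$pos + nchar(catalog$ref) - 1L
  )
  bad <- which(obs != catalog$ref)
  if (length(bad) > 0) {
    stop("reference allele mismatch at ", catalog$chrom[bad[1]], ":",
         catalog$pos[bad[1]], " (genome ", obs[bad[1]], ", record ",
         catalog$ref[bad[1]], ")")
  }
  gene_gr <- genes_granges(models)
  rec_gr <- GRanges(catalog$chrom, IRanges(catalog$pos, catalog$pos))
  hits <- findOverlaps(rec_gr, gene_gr, select = "first")
  cds_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    h <- hits[i]
    if (is.na(h)) {
      consequence[i] <- "intergenic"
      next
    }
    gid <- models$genes$gene_id[h]
    gene_id[i] <- gid
    consequence[i] <- classify_site(
      catalog$pos[i], catalog$ref[i], catalog$alt[i], catalog$class[i],
      gid, models, genome, cds_cache
    )
  }
  catalog$consequence <- consequence
  catalog$gene_id <- gene_id
  catalog
}

classify_site <- function(pos, ref, alt, class, gid, models, genome,
                          cds_cache) {
  g <- models$genes[models$genes$gene_id == gid, ]
  ex <- models$exons[models$exons$gene_id == gid, ]
  cds <- models$cds[models$cds$gene_id == gid, ]
  in_exon <- any(pos >= ex$start & pos <= ex$end)
  if (!in_exon) {
    edge_dist <- min(abs(pos - ex$start), abs(pos - ex$end))
    # intronic: canonical +-2 splice window, else treated as non-coding
    return(if (edge_dist <= 2) "splice_site" else "intergenic")
  }
  in_cds <- nrow(cds) > 0 && any(pos >= cds$start & pos <= cds$end)
  if (!in_cds) {
    five_prime_left <- g$strand == "+"
    before_cds <- nrow(cds) > 0 && pos < min(cds$start)
    after_cds <- nrow(cds) > 0 && pos > max(cds$end)
    side <- if (before_cds) {
      if (five_prime_left) "utr5" else "utr3"
    } else if (after_cds) {
      if (five_prime_left) "utr3" else "utr5"
    } else {
      "intergenic"  # no CDS annotated
    }
    if (side == "utr5" && class == "SNV" &&
        creates_start(pos, alt, g, genome)) {
      return("start_gained")
    }
    return(side)
  }
  if (class != "SNV") {
    shift <- abs(nchar(alt) - nchar(ref))
    return(if (shift %% 3 != 0) "frameshift" else "inframe_indel")
  }
  key <- gid
  if (!exists(key, envir = cds_cache)) {
    assign(key, gene_cds_seq(genome, models, gid), envir = cds_cache)
  }
  cds_seq <- get(key, envir = cds_cache)
  total <- nchar(cds_seq)
  widths <- cds$end - cds$start + 1L
  row <- which(pos >= cds$start & pos <= cds$end)[1]
  plus_coord <- sum(widths[seq_len(row - 1)]) + (pos - cds$start[row] + 1L)
  coding_coord <- if (g$strand == "+") plus_coord else total - plus_coord + 1L
  alt_coding <- if (g$strand == "+") alt else unname(COMPLEMENT[alt])
  codon_i <- ceiling(coding_coord / 3)
  pos_in_codon <- coding_coord - (codon_i - 1L) * 3L
  codon <- substr(cds_seq, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  codon_alt <- codon
  substr(codon_alt, pos_in_codon, pos_in_codon) <- alt_coding
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_alt == "*" && aa_ref != "*") return("nonsense")
  if (aa_ref == aa_alt) "synonymous" else "missense"
}

# does substituting `alt` at `pos` create a new ATG on the coding strand?
creates_start <- function(pos, alt, g, genome) {
  chrom_seq <- genome[[g$chrom]]
  win_start <- max(1L, pos - 2L)
  win_end <- min(nchar(chrom_seq), pos + 2L)
  before <- substr(chrom_seq, win_start, win_end)
  after <- before
  substr(after, pos - win_start + 1L, pos - win_start + 1L) <- alt
  if (g$strand == "-") {
    before <- revcomp_chr(before)
    after <- revcomp_chr(after)
  }
  has_atg <- function(s) {
    any(vapply(seq_len(max(0, nchar(s) - 2)), function(i) {
      substr(s, i, i + 2) == "ATG"
    }, logical(1)))
  }
  has_atg(after) && !has_atg(before)
}
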