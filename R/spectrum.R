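#' Pyrimidine-folded substitution class of SNV records
#'
#' Substitutions with a purine reference are folded onto the complementary
#' pyrimidine class (G>A is counted as C>T), giving the conventional six
#' classes C>A, C>G, C>T, T>A, T>C, T>G.
#'
#' @param ref,alt single-base character vectors
#' @return character vector of classes
#' @export
fold_substitution <- function(ref, alt) {
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, unname(COMPLEMENT[ref]), ref)
  a <- ifelse(purine, unname(COMPLEMENT[alt]), alt)
  paste0(r, ">", a)
}

#' Mutation spectrum with transcriptional strand attribution
#'
#' Counts SNVs in the six pyrimidine-folded classes. When a site lies in an
#' annotated gene, the mutation is attributed to the transcribed or
#' untranscribed strand by comparing the strand carrying the reference
#' pyrimidine with the gene's coding strand: a pyrimidine on the coding
#' strand is an untranscribed-strand mutation, a pyrimidine on the template
#' strand a transcribed-strand one. Intergenic sites are `unassigned` and
#' excluded from strand-bias testing. Non-SNV records are ignored (their
#' count is reported in the result).
#'
#' @param catalog a mutation catalog
#' @param models optional [gene_models()] for strand attribution
#' @return a `spectrum_profile` list: `counts` (class x strand matrix),
#'   `class_counts`, `fractions` (NULL for an empty catalog), `n_snv`,
#'   `n_ignored`
#' @export
mutation_spectrum <- function(catalog, models = NULL) {
  snv <- catalog[catalog$class == "SNV", ]
  n_ignored <- nrow(catalog) - nrow(snv)
  strands <- c("transcribed", "untranscribed", "unassigned")
  counts <- matrix(0L, nrow = 6, ncol = 3,
                   dimnames = list(SPECTRUM_CLASSES, strands))
  if (nrow(snv) > 0) {
    cls <- fold_substitution(snv$ref, snv$alt)
    strand <- rep("unassigned", nrow(snv))
    if (!is.null(models)) {
      gene_gr <- genes_granges(models)
      hit <- findOverlaps(
        GRanges(snv$chrom, IRanges(snv$pos, snv$pos)), gene_gr,
        select = "first"
      )
      in_gene <- !is.na(hit)
      gene_strand <- as.character(GenomicRanges::strand(gene_gr))[hit]
      # strand carrying the reference pyrimidine: + when ref is C/T
      pyr_plus <- snv$ref %in% c("C", "T")
      pyr_strand <- ifelse(pyr_plus, "+", "-")
      strand[in_gene] <- ifelse(
        pyr_strand[in_gene] == gene_strand[in_gene],
        "untranscribed", "transcribed"
      )
    }
    tab <- table(factor(cls, levels = SPECTRUM_CLASSES),
                 factor(strand, levels = strands))
    counts <- counts + unclass(tab)
  }
  class_counts <- rowSums(counts)
  fractions <- if (sum(class_counts) > 0) {
    class_counts / sum(class_counts)
  } else NULL
  structure(list(counts = counts, class_counts = class_counts,
                 fractions = fractions, n_snv = nrow(snv),
                 n_ignored = n_ignored),
            class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat("mutation spectrum over", x$n_snv, "SNVs",
      if (x$n_ignored > 0) paste0("(", x$n_ignored, " non-SNV ignored)"),
      "\n")
  if (!is.null(x$fractions)) print(round(x$fractions, 3))
  invisible(x)
}

#' Exact binomial test of transcriptional strand bias per class
#'
#' For each substitution class, tests the transcribed-strand count against
#' an even split of the strand-assigned total (exact two-sided binomial,
#' p0 = 0.5). Classes with no strand-assigned mutations get `NA`.
#'
#' @param profile a [mutation_spectrum()] result
#' @return tibble with class, transcribed/untranscribed counts and p-value
#' @export
strand_bias_test <- function(profile) {
  tr <- profile$counts[, "transcribed"]
  ut <- profile$counts[, "untranscribed"]
  p <- vapply(seq_along(tr), function(i) {
    tot <- tr[i] + ut[i]
    if (tot == 0) return(NA_real_)
    binom.test(tr[i], tot, p = 0.5)$p.value
  }, numeric(1))
  tibble(class = SPECTRUM_CLASSES, transcribed = as.integer(tr),
         untranscribed = as.integer(ut), p_value = p)
}

#' Fraction of SNVs whose reference base is C or G
#'
#' The metric behind the hypermutant archetype whose substitutions occur
#' exclusively at cytosine:guanine base pairs.
#'
#' @param catalog a mutation catalog
#' @return fraction in `[0, 1]`, or `NA` if the catalog has no SNVs
#' @export
cg_only_fraction <- function(catalog) {
  snv <- catalog[catalog$class == "SNV", ]
  if (nrow(snv) == 0) return(NA_real_)
  mean(snv$ref %in% c("C", "G"))
}

#' Detect kataegis-style mutation microclusters
#'
#' Within each sample and chromosome, mutations are split wherever the gap
#' to the previous mutation exceeds `max_gap`; maximal runs of at least
#' `min_size` mutations are reported as clusters with their span, majority
#' folded class and tumour-VAF spread (max minus min).
#'
#' @param catalog a mutation catalog
#' @param min_size minimum cluster size (default 5)
#' @param max_gap maximum intermutation distance within a cluster, bp
#'   (default 2000)
#' @return tibble of clusters (`sample_id`, `chrom`, `start`, `end`,
#'   `size`, `span`, `majority_class`, `vaf_spread`) sorted by size
#' @export
detect_clusters <- function(catalog, min_size = 5L, max_gap = 2000L) {
  validate_mutations(catalog)
  out <- list()
  for (sid in unique(catalog$sample_id)) {
    for (chrom in unique(catalog$chrom[catalog$sample_id == sid])) {
      m <- catalog[catalog$sample_id == sid & catalog$chrom == chrom, ]
      m <- m[order(m$pos), ]
      if (nrow(m) < min_size) next
      grp <- cumsum(c(0, diff(m$pos) > max_gap))
      for (g in unique(grp)) {
        mm <- m[grp == g, ]
        if (nrow(mm) < min_size) next
        cls <- fold_substitution(mm$ref[mm$class == "SNV"],
                                 mm$alt[mm$class == "SNV"])
        vaf <- mm$t_alt / mm$t_depth
        out[[length(out) + 1]] <- tibble(
          sample_id = sid, chrom = chrom,
          start = min(mm$pos), end = max(mm$pos),
          size = nrow(mm), span = max(mm$pos) - min(mm$pos),
          majority_class = names(sort(table(cls), decreasing = TRUE))[1],
          vaf_spread = max(vaf) - min(vaf)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  start = integer(), end = integer(), size = integer(),
                  span = integer(), majority_class = character(),
                  vaf_spread = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(-res$size), ]
}

#' Per-sample intermutation distances (rainfall table)
#'
#' Distances to the previous mutation within each sample and chromosome;
#' the first mutation on a chromosome has distance `NA`.
#'
#' @param catalog a mutation catalog
#' @return tibble `sample_id`, `chrom`, `pos`, `distance`, `class`
#' @export
intermutation_distances <- function(catalog) {
  validate_mutations(catalog)
  if (nrow(catalog) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), distance = integer(),
                  class = character()))
  }
  ord <- order(catalog$sample_id, catalog$chrom, catalog$pos)
  m <- catalog[ord, ]
  key <- paste(m$sample_id, m$chrom)
  dist <- c(NA_integer_, diff(m$pos))
  dist[c(TRUE, key[-1] != key[-length(key)])] <- NA_integer_
  cls <- ifelse(m$class == "SNV", fold_substitution(m$ref, m$alt), m$class)
  tibble(sample_id = m$sample_id, chrom = m$chrom, pos = m$pos,
         distance = dist, class = cls)
}
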