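MODALITIES <- c("substitutions", "indels", "amplifications",
                "homozygous_deletions")

#' Per-modality background mutation rate
#'
#' The probability that a given gene is mutated in a random sample of
#' modality group `i`, estimated from the per-sample event counts `m_k`:
#' `q = (1 / n) * sum_k [1 - (1 - 1/N)^m_k]`, with `N` the number of genes
#' in the genome.
#'
#' @param m per-sample event counts for the modality (length `n_i`)
#' @param N number of genes in the genome
#' @return `q` in `[0, 1]`
#' @export
modality_rate <- function(m, N) {
  stopifnot(length(m) >= 1, N >= 1, all(m >= 0))
  mean(1 - (1 - 1 / N)^m)
}

#' Combined per-gene significance across mutation modalities
#'
#' For one gene, each modality contributes the binomial upper tail
#' `P(X >= x | Binomial(n, q))` of observing at least the seen number of
#' mutated samples; the combined statistic is the product over modalities.
#' `x = 0` contributes a factor of 1.
#'
#' @param x named (or ordered) vector of mutated-sample counts per modality
#' @param n per-modality group sizes
#' @param q per-modality background rates (see [modality_rate()])
#' @return combined p in `(0, 1]`
#' @export
combined_gene_pvalue <- function(x, n, q) {
  stopifnot(length(x) == length(n), length(n) == length(q),
            all(q >= 0), all(q <= 1), all(x <= n))
  tails <- ifelse(
    x == 0, 1,
    pbinom(x - 1, n, q, lower.tail = FALSE)
  )
  prod(tails)
}

#' Gene significance table over the four mutation modalities
#'
#' Applies the combined binomial statistic to every gene: per modality the
#' background rate is estimated from per-sample event counts, and the
#' number of samples with the gene mutated is the observed hit count.
#'
#' @param hits named list of logical genes x samples matrices, one per
#'   modality (names from substitutions / indels / amplifications /
#'   homozygous_deletions); row names are gene ids
#' @param events named list of per-sample event-count vectors, aligned with
#'   the columns of the corresponding hit matrix
#' @param N number of genes in the genome (default: union of row names)
#' @return tibble: `gene_id`, per-modality tails, `p_combined`, sorted by
#'   increasing `p_combined`
#' @export
gene_significance <- function(hits, events, N = NULL) {
  stopifnot(length(hits) >= 1, identical(names(hits), names(events)))
  genes <- sort(unique(unlist(lapply(hits, rownames))))
  if (is.null(N)) N <- length(genes)
  q <- vapply(names(hits), function(mod) {
    modality_rate(events[[mod]], N)
  }, numeric(1))
  n <- vapply(hits, ncol, integer(1))
  tails <- vapply(names(hits), function(mod) {
    x <- rep(0L, length(genes))
    idx <- match(rownames(hits[[mod]]), genes)
    x[idx] <- as.integer(rowSums(hits[[mod]]))
    ifelse(x == 0, 1, pbinom(x - 1, n[[mod]], q[[mod]],
                             lower.tail = FALSE))
  }, numeric(length(genes)))
  if (length(genes) == 1) tails <- matrix(tails, nrow = 1)
  colnames(tails) <- paste0("p_", names(hits))
  out <- cbind(
    tibble(gene_id = genes),
    as_tibble(as.data.frame(tails)),
    tibble(p_combined = apply(tails, 1, prod))
  )
  out[order(out$p_combined, out$gene_id), ]
}

#' Select genes at the combined-significance cutoff
#'
#' Strict inequality: a gene enters the pathway analysis only when its
#' combined p-value is below `alpha`.
#'
#' @param significance a [gene_significance()] table
#' @param alpha cutoff (default 0.05)
#' @return character vector of gene ids
#' @export
select_significant_genes <- function(significance, alpha = 0.05) {
  significance$gene_id[significance$p_combined < alpha]
}

#' Threshold-swept gene-set enrichment
#'
#' For each minimum-mutation threshold `N` in `thresholds`, the frequently
#' mutated list is the selected genes carrying at least `N` mutations; each
#' gene set is tested for over-representation of that list within the
#' universe by a one-sided hypergeometric tail (binomial approximation
#' available behind `method`). Sets disjoint from the universe are skipped
#' with a warning.
#'
#' @param selected character vector of significant gene ids
#' @param mutation_counts named vector of total mutation counts per gene
#'   (events across modalities) used for the threshold sweep
#' @param gene_sets tibble from [read_gmt()]
#' @param universe character vector of all testable gene ids
#' @param thresholds integer thresholds to sweep (default 1:10)
#' @param method `"hypergeometric"` (default) or `"binomial"`
#' @return tibble: `set_id`, `threshold`, `n_selected`, `overlap`, `p`
#' @export
pathway_enrichment <- function(selected, mutation_counts, gene_sets,
                               universe, thresholds = 1:10,
                               method = c("hypergeometric", "binomial")) {
  method <- match.arg(method)
  if (!all(selected %in% universe)) {
    stop("selected genes must be contained in the universe")
  }
  rows <- list()
  for (i in seq_len(nrow(gene_sets))) {
    set_genes <- intersect(gene_sets$genes[[i]], universe)
    if (length(set_genes) == 0) {
      warning("gene set ", gene_sets$set_id[i],
              " is disjoint from the universe; skipped")
      next
    }
    for (thr in thresholds) {
      freq <- selected[
        !is.na(mutation_counts[selected]) &
          mutation_counts[selected] >= thr
      ]
      k <- length(freq)
      ov <- length(intersect(freq, set_genes))
      p <- if (method == "hypergeometric") {
        if (ov == 0) 1 else {
          phyper(ov - 1, length(set_genes),
                 length(universe) - length(set_genes), k,
                 lower.tail = FALSE)
        }
      } else {
        if (ov == 0) 1 else {
          pbinom(ov - 1, k, length(set_genes) / length(universe),
                 lower.tail = FALSE)
        }
      }
      rows[[length(rows) + 1]] <- tibble(
        set_id = gene_sets$set_id[i], threshold = thr,
        n_selected = k, overlap = ov, p = p
      )
    }
  }
  do.call(rbind, rows)
}
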