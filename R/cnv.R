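#' Ploidy-aware amplification / homozygous deletion calling
#'
#' A segment is an amplification when its copy number reaches 5 for samples
#' with ploidy below 2.7, or 8 for samples with ploidy 2.7 and above; a
#' homozygous deletion is copy number 0. Only segments shorter than
#' `max_segment` (default 10 Mb) are eligible; longer segments are assigned
#' call `none` and their count is reported in a message.
#'
#' @param segments a segment table
#' @param ploidies named numeric vector of per-sample ploidies (or a sample
#'   sheet with `sample_id` and `ploidy`)
#' @param max_segment maximum eligible segment length in bp
#' @return the segments with a `call` column
#'   (`amplification` / `homozygous_deletion` / `none`)
#' @export
call_cna <- function(segments, ploidies, max_segment = 1e7) {
  validate_segments(segments)
  if (is.data.frame(ploidies)) {
    ploidies <- setNames(ploidies$ploidy, ploidies$sample_id)
  }
  missing <- setdiff(unique(segments$sample_id), names(ploidies))
  if (length(missing) > 0) {
    stop("missing ploidy for sample(s): ", paste(missing, collapse = ", "))
  }
  pl <- unname(ploidies[segments$sample_id])
  if (anyNA(pl)) stop("NA ploidy")
  width <- segments$end - segments$start + 1
  eligible <- width < max_segment
  n_dropped <- sum(!eligible)
  if (n_dropped > 0) {
    message(n_dropped, " segment(s) at or above ", max_segment,
            " bp excluded from calling")
  }
  amp_threshold <- ifelse(pl < 2.7, 5L, 8L)
  call <- rep("none", nrow(segments))
  call[eligible & segments$copy_number >= amp_threshold] <- "amplification"
  call[eligible & segments$copy_number == 0] <- "homozygous_deletion"
  segments$call <- call
  segments
}

#' Per-gene recurrence of called copy-number events
#'
#' A gene is hit by a sample when at least one called segment of the given
#' modality overlaps the gene interval by at least 1 bp.
#'
#' @param calls output of [call_cna()]
#' @param models a [gene_models()] object
#' @param sample_ids optional full sample universe (so samples without any
#'   call appear as all-FALSE columns)
#' @return a `gene_hit_matrix` list with logical genes x samples matrices
#'   `amplification` and `homozygous_deletion`, and a `recurrence` tibble of
#'   per-gene counts sorted decreasingly
#' @export
recurrence_profile <- function(calls, models,
                               sample_ids = unique(calls$sample_id)) {
  genes <- models$genes
  gene_gr <- genes_granges(models)
  make_mat <- function(modality) {
    m <- matrix(FALSE, nrow = nrow(genes), ncol = length(sample_ids),
                dimnames = list(genes$gene_id, sample_ids))
    seg <- calls[calls$call == modality, ]
    if (nrow(seg) > 0) {
      seg_gr <- GRanges(seg$chrom, IRanges(seg$start, seg$end))
      ov <- findOverlaps(seg_gr, gene_gr)
      if (length(ov) > 0) {
        m[cbind(subjectHits(ov),
                match(seg$sample_id[queryHits(ov)], sample_ids))] <- TRUE
      }
    }
    m
  }
  amp <- make_mat("amplification")
  del <- make_mat("homozygous_deletion")
  rec <- tibble(
    gene_id = genes$gene_id,
    amplification = as.integer(rowSums(amp)),
    homozygous_deletion = as.integer(rowSums(del))
  )
  rec <- rec[order(-rec$amplification, -rec$homozygous_deletion,
                   rec$gene_id), ]
  structure(list(amplification = amp, homozygous_deletion = del,
                 recurrence = rec),
            class = "gene_hit_matrix")
}

# map target regions into a single concatenated coordinate space
concat_space <- function(target_regions) {
  tr <- target_regions[order(target_regions$chrom, target_regions$start), ]
  w <- tr$end - tr$start + 1
  offset <- cumsum(c(0, w[-length(w)]))
  list(regions = tr, offset = offset, total = sum(w))
}

# project genomic intervals onto the concatenated space (clipped to the
# target regions; an interval may map to several concatenated pieces)
to_concat <- function(chrom, start, end, space) {
  tr <- space$regions
  gr <- GRanges(chrom, IRanges(start, end))
  tr_gr <- GRanges(tr$chrom, IRanges(tr$start, tr$end))
  ov <- findOverlaps(gr, tr_gr)
  q <- queryHits(ov)
  s <- subjectHits(ov)
  cs <- pmax(start[q], tr$start[s]) - tr$start[s] + space$offset[s] + 1
  ce <- pmin(end[q], tr$end[s]) - tr$start[s] + space$offset[s] + 1
  list(index = q, start = cs, end = ce)
}

#' Length-preserving permutation test of copy-number recurrence
#'
#' Under the null, each sample's called segments keep their number and
#' lengths but are placed uniformly at random (contiguously) within the
#' concatenated target space; per-gene recurrence (samples hit) is
#' recomputed for each permutation. The empirical p-value uses the add-one
#' estimator `(b + 1) / (n_perm + 1)` where `b` counts permutations with
#' recurrence at least the observed, so p is never zero. Bonferroni
#' adjustment multiplies by the number of genes tested (default: genes
#' overlapping the target space), capped at 1.
#'
#' @param calls output of [call_cna()]; only segments called with
#'   `modality` are permuted
#' @param models a [gene_models()] object
#' @param target_regions tibble `chrom`, `start`, `end` of the
#'   randomisation space; default: the full chromosomes spanned by the gene
#'   models (taken from `chrom_lengths` when given, else the max gene end)
#' @param modality `"amplification"` (default) or `"homozygous_deletion"`
#' @param n_perm number of permutations
#' @param seed integer seed
#' @param n_tested Bonferroni multiplier (default: genes tested)
#' @param chrom_lengths optional named vector of chromosome lengths
#' @return a `permutation_result` tibble: `gene_id`, `observed`,
#'   `p_empirical`, `p_bonferroni`, with attributes `n_perm` and `seed`
#' @export
permutation_enrichment <- function(calls, models, target_regions = NULL,
                                   modality = "amplification",
                                   n_perm = 10000, seed = 1,
                                   n_tested = NULL,
                                   chrom_lengths = NULL) {
  seg <- calls[calls$call == modality, ]
  if (is.null(target_regions)) {
    chroms <- sort(unique(models$genes$chrom))
    len <- if (!is.null(chrom_lengths)) {
      unname(chrom_lengths[chroms])
    } else {
      vapply(chroms, function(ch) {
        max(models$genes$end[models$genes$chrom == ch])
      }, numeric(1))
    }
    target_regions <- tibble(chrom = chroms, start = 1L,
                             end = as.integer(len))
  }
  space <- concat_space(target_regions)
  seg_w <- seg$end - seg$start + 1
  if (nrow(seg) > 0 && max(seg_w) > space$total) {
    stop("segment longer than the randomisation space")
  }
  genes <- models$genes
  gmap <- to_concat(genes$chrom, genes$start, genes$end, space)
  gene_ir <- IRanges(gmap$start, gmap$end)
  gene_of_piece <- gmap$index
  tested <- sort(unique(gene_of_piece))
  if (is.null(n_tested)) n_tested <- length(tested)

  # observed recurrence in genomic coordinates
  obs <- rep(0L, nrow(genes))
  if (nrow(seg) > 0) {
    ov <- findOverlaps(GRanges(seg$chrom, IRanges(seg$start, seg$end)),
                       genes_granges(models))
    if (length(ov) > 0) {
      hit <- unique(cbind(subjectHits(ov), seg$sample_id[queryHits(ov)]))
      obs <- as.integer(table(factor(as.integer(hit[, 1]),
                                     levels = seq_len(nrow(genes)))))
    }
  }

  set.seed(seed)
  geq <- rep(0L, nrow(genes))
  if (nrow(seg) > 0) {
    sample_idx <- match(seg$sample_id, unique(seg$sample_id))
    for (b in seq_len(n_perm)) {
      u <- floor(runif(nrow(seg)) * (space$total - seg_w + 1)) + 1
      placed <- IRanges(u, u + seg_w - 1)
      ov <- findOverlaps(placed, gene_ir)
      cnt <- rep(0L, nrow(genes))
      if (length(ov) > 0) {
        pairs <- unique(
          gene_of_piece[subjectHits(ov)] * 100000L +
            sample_idx[queryHits(ov)]
        )
        g <- pairs %/% 100000L
        cnt <- as.integer(table(factor(g, levels = seq_len(nrow(genes)))))
      }
      geq <- geq + (cnt >= obs)
    }
  } else {
    geq <- rep(n_perm, nrow(genes))
  }
  p_emp <- (geq + 1) / (n_perm + 1)
  res <- tibble(
    gene_id = genes$gene_id,
    observed = obs,
    p_empirical = p_emp,
    p_bonferroni = pmin(1, p_emp * n_tested)
  )
  attr(res, "n_perm") <- n_perm
  attr(res, "seed") <- seed
  attr(res, "n_tested") <- n_tested
  res
}

#' Chi-square association between a subgroup and a per-sample hit
#'
#' Pearson chi-square (df = 1, no continuity correction by default) on the
#' 2x2 table of subgroup membership against event presence at sample level.
#'
#' @param hit logical vector: does each sample carry the event
#' @param subgroup logical vector: subgroup membership
#' @param correct apply the Yates continuity correction
#' @return list with `statistic`, `p_value`, `table`; degenerate margins
#'   (all samples hit, or none) give `p_value = NA` with a warning
#' @export
subgroup_association <- function(hit, subgroup, correct = FALSE) {
  stopifnot(length(hit) == length(subgroup))
  tab <- table(factor(subgroup, levels = c(TRUE, FALSE)),
               factor(hit, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin: association undefined")
    return(list(statistic = NA_real_, p_value = NA_real_, table = tab))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}
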