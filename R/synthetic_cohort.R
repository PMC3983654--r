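#' Configuration for the synthetic melanoma cohort
#'
#' Returns the default study configuration: a 53-sample cohort whose genotype
#' composition follows the engineered transgenic study design (one
#' BRAF-only fish, BRAF;p53 combinations, a mitf-vc7 subgroup of 8, a
#' 25-sample mitf-null + MITF-rescue subgroup, and 15 NRAS-driven fish), a
#' negative-binomial substitution-burden model with a negative driver
#' coefficient and positive age coefficient calibrated to a cohort median of
#' 4 coding substitutions, a C>T-dominated 6-class spectrum (C>T weight
#' 0.244), two special-sample archetypes (a 47-substitution C:G-exclusive
#' hypermutant and a two-cluster kataegis sample), a 175 kb recurrent
#' amplicon implanted in 10 samples of the MITF-rescue subgroup, an excess
#' of homozygous deletions in the vc7 subgroup, and 13 cohort-wide indels
#' flanked by tandem repeats.
#'
#' @param seed integer seed driving every random choice
#' @param n_chrom,chrom_length synthetic genome shape (desk scale)
#' @param genes_per_chrom regular genes laid out per chromosome
#' @param burden_model overrides for the burden model list
#' @param spectrum_mixture named 6-class probability vector (must sum to 1)
#' @param amplicon overrides for the amplicon list
#' @param indel_total total indels implanted across the cohort
#' @return a `cohort_config` list
#' @export
cohort_config <- function(seed = 1,
                          n_chrom = 21,
                          chrom_length = 1e6,
                          genes_per_chrom = 30,
                          burden_model = list(),
                          spectrum_mixture = NULL,
                          amplicon = list(),
                          indel_total = 13) {
  bm <- utils::modifyList(
    list(
      family = "negative-binomial",
      intercept = NULL,          # calibrated at generation time
      driver_coefficient = -0.25,
      age_coefficient = 0.035,   # per month
      dispersion = 1.5,          # NB size
      target_median = 4
    ),
    burden_model
  )
  stopifnot(bm$driver_coefficient < 0, bm$age_coefficient > 0)
  if (is.null(spectrum_mixture)) {
    spectrum_mixture <- c(
      "C>A" = 0.170, "C>G" = 0.110, "C>T" = 0.244,
      "T>A" = 0.130, "T>C" = 0.226, "T>G" = 0.120
    )
  }
  stopifnot(abs(sum(spectrum_mixture) - 1) < 1e-8,
            identical(names(spectrum_mixture), SPECTRUM_CLASSES))
  amp <- utils::modifyList(
    list(chrom = "chr3", start = NULL, width = 175000L,
         subgroup = "mitf_rescue", n_carriers = 10L, copy_number = 10L),
    amplicon
  )
  gt <- default_genotype_table()
  structure(list(
    n_samples = sum(gt$count),
    genotype_table = gt,
    burden_model = bm,
    spectrum_mixture = spectrum_mixture,
    special_samples = list(
      zd0038a = list(archetype = "zd0038a", sample_id = "ZD0038a_like",
                     n = 47L),
      zd8a = list(archetype = "zd8a", sample_id = "ZD8a_like",
                  clusters = list(list(size = 12L, span = 4500L),
                                  list(size = 5L, span = 5000L)),
                  background = 13L, vaf_tol = 0.05)
    ),
    amplicon = amp,
    deletion_excess_subgroup = "mitf_vc7",
    indel_total = as.integer(indel_total),
    genome = list(n_chrom = n_chrom, chrom_length = as.integer(chrom_length),
                  genes_per_chrom = genes_per_chrom),
    age_range = c(6, 18),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# genotype composition of the study set (counts sum to 53)
default_genotype_table <- function() {
  tibble(
    oncogene = c(rep("BRAF", 11), rep("NRAS", 4)),
    p53 = c("wt", "het", "het", "wt", "het", rep("hom", 6),
            "wt", "hom", "het", "het"),
    mitf = c("wt", "wt", "wt", "vc7", "vc7", rep("null", 6),
             rep("wt", 4)),
    mitf_rescue = c(rep(FALSE, 5), rep(TRUE, 6), rep(FALSE, 4)),
    extra_alleles = c("", "", "ptena_het", rep("", 11), "rps29_het"),
    extra_transgenes = c(rep("", 6), "FOXD3", "KROX20", "KROX20,FOXD3,OCT6",
                         "SETDB1", "EGFP", rep("", 4)),
    count = c(1L, 2L, 1L, 4L, 4L, 6L, 4L, 12L, 1L, 1L, 1L, 2L, 5L, 4L, 5L)
  )
}

#' Identify genotype subgroups used by the generator
#'
#' `mitf_rescue`: mitf-null fish with MITF minigene rescue (the amplicon
#' carrier pool). `mitf_vc7`: fish carrying the hypomorphic vc7 allele (the
#' homozygous-deletion-enriched subgroup).
#'
#' @param sheet a sample sheet
#' @param subgroup subgroup name
#' @return logical vector over rows of `sheet`
#' @export
subgroup_members <- function(sheet, subgroup = c("mitf_rescue", "mitf_vc7")) {
  subgroup <- match.arg(subgroup)
  switch(subgroup,
    mitf_rescue = sheet$mitf_rescue,
    mitf_vc7 = sheet$mitf == "vc7"
  )
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# replace stop codons (and force an ATG start) in an in-frame CDS string
sanitize_cds <- function(s) {
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  codons[1] <- "ATG"
  bad <- codons %in% STOP_CODONS
  if (any(bad)) {
    pool <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
    codons[bad] <- sample(pool, sum(bad), replace = TRUE)
  }
  paste(codons, collapse = "")
}

# extract the spliced CDS of one gene (coding-strand orientation)
gene_cds_seq <- function(genome, models, gid) {
  g <- models$genes[models$genes$gene_id == gid, ]
  cds <- models$cds[models$cds$gene_id == gid, ]
  parts <- substring(genome[[g$chrom]], cds$start, cds$end)
  s <- paste(parts, collapse = "")
  if (g$strand == "-") revcomp_chr(s) else s
}

# write a (sanitized) coding sequence back into the genome strings
patch_gene_cds <- function(genome, models, gid, cds_seq) {
  g <- models$genes[models$genes$gene_id == gid, ]
  cds <- models$cds[models$cds$gene_id == gid, ]
  if (g$strand == "-") cds_seq <- revcomp_chr(cds_seq)
  offset <- 0L
  chrom_seq <- genome[[g$chrom]]
  for (i in seq_len(nrow(cds))) {
    w <- cds$end[i] - cds$start[i] + 1L
    substr(chrom_seq, cds$start[i], cds$end[i]) <-
      substr(cds_seq, offset + 1L, offset + w)
    offset <- offset + w
  }
  genome[[g$chrom]] <- chrom_seq
  genome
}

# one toy gene: UTR5 + in-frame CDS exons + UTR3 laid left to right;
# for minus-strand genes the 5' side is at the high-coordinate end
make_gene <- function(gene_id, chrom, start, strand,
                      n_exons = NULL, cds_exon_len = NULL) {
  if (is.null(n_exons)) n_exons <- sample(2:4, 1)
  if (is.null(cds_exon_len)) {
    cds_exon_len <- 3L * sample(60:240, n_exons, replace = TRUE)
  }
  utr5 <- 60L
  utr3 <- 90L
  introns <- sample(100:700, n_exons - 1, replace = TRUE)
  exons <- vector("list", n_exons)
  cds <- vector("list", n_exons)
  cur <- start
  for (i in seq_len(n_exons)) {
    lead <- if (i == 1) utr5 else 0L
    tail_ <- if (i == n_exons) utr3 else 0L
    ex_start <- cur
    cds_start <- cur + lead
    cds_end <- cds_start + cds_exon_len[i] - 1L
    ex_end <- cds_end + tail_
    exons[[i]] <- c(ex_start, ex_end)
    cds[[i]] <- c(cds_start, cds_end)
    cur <- ex_end + if (i < n_exons) introns[i] else 0L
    cur <- cur + 1L
  }
  ex <- do.call(rbind, exons)
  cd <- do.call(rbind, cds)
  list(
    gene = tibble(gene_id = gene_id, chrom = chrom,
                  start = ex[1, 1], end = ex[n_exons, 2], strand = strand),
    exons = tibble(gene_id = gene_id, start = ex[, 1], end = ex[, 2]),
    cds = tibble(gene_id = gene_id, start = cd[, 1], end = cd[, 2])
  )
}

AMPLICON_GENES <- c("prkacaa_like", "samd1_like", "asf1ba_like",
                    "wu_fj41e11_like", "tecra_like")
AMPLICON_FLANK_GENES <- c("RNF222_like", "gcgr_like")

# lay out the synthetic genome's gene models; returns list(models, landmarks)
build_gene_layout <- function(config) {
  gs <- config$genome
  chroms <- paste0("chr", seq_len(gs$n_chrom))
  L <- gs$chrom_length
  amp <- config$amplicon
  amp_start <- amp$start %||% as.integer(L * 0.5)
  amp_end <- amp_start + amp$width - 1L
  if (amp_end > L) stop("amplicon does not fit on ", amp$chrom)

  genes <- list(); exons <- list(); cds <- list()
  add <- function(g) {
    genes[[length(genes) + 1]] <<- g$gene
    exons[[length(exons) + 1]] <<- g$exons
    cds[[length(cds) + 1]] <<- g$cds
  }

  # special landmark genes ------------------------------------------------
  # amplicon gene cluster on the chr3 analog, spaced through the 175 kb
  amp_pos <- as.integer(seq(amp_start + 2000, amp_end - 8000,
                            length.out = length(AMPLICON_GENES)))
  for (i in seq_along(AMPLICON_GENES)) {
    add(make_gene(AMPLICON_GENES[i], amp$chrom, amp_pos[i],
                  if (i %% 2 == 0) "-" else "+"))
  }
  add(make_gene(AMPLICON_FLANK_GENES[1], amp$chrom,
                as.integer(amp_start - 15000), "+"))
  add(make_gene(AMPLICON_FLANK_GENES[2], amp$chrom,
                as.integer(amp_end + 9000), "-"))

  # kataegis hosts: two adjacent compact hox-like genes (combined span
  # < 4.5 kb) and a longer second-cluster host, on the chr10 analog when it
  # exists (falling back to the last non-amplicon chromosome)
  kat_chrom <- if (gs$n_chrom >= 10) "chr10" else
    setdiff(rev(chroms), amp$chrom)[1]
  kat1 <- as.integer(L * 0.2)
  kat2 <- as.integer(L * 0.4)
  add(make_gene("hoxd9a_like", kat_chrom, kat1, "+",
                n_exons = 2, cds_exon_len = c(900L, 750L)))
  h1_end <- genes[[length(genes)]]$end
  add(make_gene("hoxd10a_like", kat_chrom, h1_end + 350L, "+",
                n_exons = 2, cds_exon_len = c(900L, 750L)))
  h2_end <- genes[[length(genes)]]$end
  add(make_gene("kataegis2_host", kat_chrom, kat2, "+",
                n_exons = 4, cds_exon_len = c(720L, 720L, 720L, 720L)))
  if (kat2 <= h2_end + 20000L) stop("chromosome too short for cluster hosts")

  reserved <- tibble(
    chrom = c(amp$chrom, kat_chrom, kat_chrom),
    start = c(amp_start - 40000L, kat1 - 20000L, kat2 - 20000L),
    end = c(amp_end + 40000L, h2_end + 20000L, kat2 + 40000L)
  )

  # regular genes, evenly spaced, skipping reserved windows ---------------
  for (chrom in chroms) {
    anchors <- as.integer(seq(20000, L - 20000,
                              length.out = gs$genes_per_chrom))
    k <- 0L
    for (a in anchors) {
      res <- reserved[reserved$chrom == chrom, ]
      if (nrow(res) > 0 &&
          any(a + 10000 >= res$start & a <= res$end)) next
      k <- k + 1L
      gid <- sprintf("g_%s_%02d", sub("chr", "", chrom), k)
      add(make_gene(gid, chrom, a, if (k %% 2 == 0) "-" else "+"))
    }
  }
  models <- gene_models(
    do.call(rbind, genes), do.call(rbind, exons), do.call(rbind, cds)
  )
  list(models = models,
       landmarks = list(amp_start = amp_start, amp_end = amp_end,
                        kat_chrom = kat_chrom))
}

# random genome strings + implanted tandem repeats + stop-free CDS
build_genome <- function(config, models) {
  gs <- config$genome
  chroms <- paste0("chr", seq_len(gs$n_chrom))
  genome <- setNames(vector("list", length(chroms)), chroms)
  repeats <- list()
  unit <- "AC"
  rep_len <- 24L
  gene_gr <- genes_granges(models)
  for (chrom in chroms) {
    genome[[chrom]] <- random_dna(gs$chrom_length)
    # three intergenic tandem-repeat loci per chromosome
    placed <- 0L
    guard <- 0L
    while (placed < 3L && guard < 200L) {
      guard <- guard + 1L
      p <- sample.int(gs$chrom_length - rep_len - 10L, 1)
      hit <- countOverlaps(
        GRanges(chrom, IRanges(p, p + rep_len + 5L)), gene_gr
      )
      if (hit > 0) next
      substr(genome[[chrom]], p, p + rep_len - 1L) <-
        strrep(unit, rep_len / nchar(unit))
      repeats[[length(repeats) + 1]] <-
        tibble(chrom = chrom, start = p, end = p + rep_len - 1L)
      placed <- placed + 1L
    }
  }
  for (gid in models$genes$gene_id) {
    genome <- patch_gene_cds(genome, models, gid,
                             sanitize_cds(gene_cds_seq(genome, models, gid)))
  }
  list(genome = genome, repeats = do.call(rbind, repeats))
}

# enumerate all CDS positions with their reference base
cds_position_pool <- function(genome, models) {
  out <- vector("list", 0)
  for (chrom in unique(models$genes$chrom)) {
    gids <- models$genes$gene_id[models$genes$chrom == chrom]
    cds <- models$cds[models$cds$gene_id %in% gids, ]
    if (nrow(cds) == 0) next
    pos <- unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE))
    pos <- sort(unique(pos))
    chars <- strsplit(genome[[chrom]], "")[[1]]
    out[[length(out) + 1]] <- tibble(
      chrom = chrom, pos = as.integer(pos), ref = chars[pos]
    )
  }
  do.call(rbind, out)
}

# alt base for a pyrimidine-class mutation at a site with reference `ref`
class_alt_base <- function(class, ref) {
  pyr_alt <- substr(class, 3, 3)
  ifelse(ref %in% c("C", "T"), pyr_alt, unname(COMPLEMENT[pyr_alt]))
}

# tumour/normal depths and counts for a batch of substitutions
draw_depths <- function(n, vaf = NULL) {
  t_depth <- rpois(n, 75) + 15L
  n_depth <- rpois(n, 75) + 15L
  if (is.null(vaf)) vaf <- runif(n, 0.25, 0.65)
  t_alt <- pmax(1L, rbinom(n, t_depth, vaf))
  tibble(t_depth = t_depth, t_alt = t_alt,
         n_depth = n_depth, n_alt = 0L)
}

#' Draw per-sample substitution burdens from the cohort burden model
#'
#' Counts follow a negative binomial with
#' `log(mu) = intercept + driver_coefficient * drivers +
#' age_coefficient * age`. Exposed separately so the direction of the
#' driver/age effects can be studied over many replicate cohorts.
#'
#' @param drivers integer vector of engineered driver counts
#' @param ages ages in months
#' @param model burden-model list (see [cohort_config()]); `intercept` must
#'   be set
#' @return integer vector of substitution counts
#' @export
draw_burden_counts <- function(drivers, ages, model) {
  stopifnot(!is.null(model$intercept))
  mu <- exp(model$intercept +
              model$driver_coefficient * drivers +
              model$age_coefficient * ages)
  rnbinom(length(drivers), mu = mu, size = model$dispersion)
}

# calibrate the burden intercept so the realized cohort median (including
# the fixed special-sample loads) hits the configured target
calibrate_burdens <- function(drivers, ages, special_n, model) {
  target <- model$target_median
  b0 <- log(target) -
    stats::median(model$driver_coefficient * drivers +
                    model$age_coefficient * ages)
  step <- 0.3
  for (iter in 1:80) {
    model$intercept <- b0
    n <- draw_burden_counts(drivers, ages, model)
    med <- stats::median(c(n, special_n))
    if (med == target) {
      return(list(counts = n, intercept = b0))
    }
    b0 <- b0 + step * sign(target - med)
    step <- step * 0.93
  }
  warning("burden calibration did not reach the target median exactly")
  list(counts = n, intercept = b0)
}

#' Generate mutation records for a special-sample archetype
#'
#' Two archetypes are supported. `zd0038a`: a hypermutant whose `n`
#' substitutions fall exclusively at C:G base pairs (reference base C or G),
#' dispersed across coding sequence. `zd8a`: a kataegis sample carrying the
#' configured mutation microclusters (default 12 substitutions within
#' 4,500 bp spanning the two adjacent hox-like genes, and 5 within 5 kb in a
#' second host gene) with tightly matched variant allele fractions and a
#' C>T majority, plus dispersed background substitutions on other
#' chromosomes.
#'
#' @param spec archetype spec list (see [cohort_config()]
#'   `$special_samples`); must name a supported archetype
#' @param genome named list of chromosome strings (or a bundle's `genome`)
#' @param models the cohort [gene_models()]
#' @param pool optional precomputed CDS position pool
#' @param spectrum_mixture 6-class probabilities for class assignment
#' @return a mutation catalog tibble for the one sample
#' @export
generate_special_sample <- function(spec, genome, models, pool = NULL,
                                    spectrum_mixture = NULL) {
  if (is.null(spec$archetype) ||
      !spec$archetype %in% c("zd0038a", "zd8a")) {
    stop("unsupported special-sample archetype")
  }
  if (is.null(pool)) pool <- cds_position_pool(genome, models)
  if (is.null(spectrum_mixture)) {
    spectrum_mixture <- cohort_config()$spectrum_mixture
  }
  if (spec$archetype == "zd0038a") {
    generate_zd0038a(spec, pool, spectrum_mixture)
  } else {
    generate_zd8a(spec, pool, models, spectrum_mixture)
  }
}

generate_zd0038a <- function(spec, pool, mixture) {
  n <- spec$n
  cg <- pool[pool$ref %in% c("C", "G"), ]
  if (nrow(cg) < n) stop("not enough C:G coding positions for archetype")
  take <- cg[sample.int(nrow(cg), n), ]
  c_classes <- SPECTRUM_CLASSES[1:3]
  w <- mixture[c_classes] / sum(mixture[c_classes])
  class <- sample(c_classes, n, replace = TRUE, prob = w)
  alt <- class_alt_base(class, take$ref)
  cbind(
    tibble(sample_id = spec$sample_id, chrom = take$chrom, pos = take$pos,
           ref = take$ref, alt = alt, class = "SNV"),
    draw_depths(n)
  )
}

# sample `size` positions from `sub` (sorted pool rows) so that the span is
# <= `span` and successive gaps <= `max_gap`, majority at C:G sites
sample_cluster_positions <- function(sub, size, span, max_gap = 2000L,
                                     n_ct = NULL) {
  if (size < 2) stop("cluster size must be at least 2")
  if (nrow(sub) < size) stop("span constraint infeasible for requested count")
  if (is.null(n_ct)) n_ct <- ceiling(size * 0.75)
  cg_idx <- which(sub$ref %in% c("C", "G"))
  if (length(cg_idx) < n_ct) stop("too few C:G sites in cluster window")
  for (try in 1:500) {
    i_cg <- sample(cg_idx, n_ct)
    rest <- sample(setdiff(seq_len(nrow(sub)), i_cg), size - n_ct)
    idx <- sort(c(i_cg, rest))
    p <- sub$pos[idx]
    if (max(p) - min(p) > span) next
    if (size > 1 && any(diff(p) > max_gap)) next
    return(list(rows = sub[idx, ], is_ct = idx %in% i_cg))
  }
  stop("span constraint infeasible for requested count")
}

generate_zd8a <- function(spec, pool, models, mixture) {
  sizes <- vapply(spec$clusters, function(cl) cl$size, integer(1))
  if (any(sizes < 2)) stop("cluster size must be at least 2")
  hosts <- list(c("hoxd9a_like", "hoxd10a_like"), "kataegis2_host")
  vaf_tol <- spec$vaf_tol %||% 0.05
  recs <- list()
  for (i in seq_along(spec$clusters)) {
    cl <- spec$clusters[[i]]
    host <- hosts[[min(i, length(hosts))]]
    cds <- models$cds[models$cds$gene_id %in% host, ]
    chrom <- models$genes$chrom[models$genes$gene_id == host[1]]
    win_pos <- unlist(mapply(seq.int, cds$start, cds$end, SIMPLIFY = FALSE))
    sub <- pool[pool$chrom == chrom & pool$pos %in% win_pos, ]
    sub <- sub[order(sub$pos), ]
    picked <- sample_cluster_positions(sub, cl$size, cl$span)
    class <- ifelse(picked$is_ct, "C>T",
                    sample(SPECTRUM_CLASSES, cl$size, replace = TRUE,
                           prob = mixture))
    # non-C>T classes must agree with the reference base's purine/pyrimidine
    ref <- picked$rows$ref
    fix <- !picked$is_ct
    class[fix] <- ifelse(ref[fix] %in% c("C", "G"),
                         sample(SPECTRUM_CLASSES[1:3], sum(fix), TRUE),
                         sample(SPECTRUM_CLASSES[4:6], sum(fix), TRUE))
    base_vaf <- 0.45
    vaf <- base_vaf + runif(cl$size, -0.8, 0.8) * vaf_tol
    depths <- draw_depths(cl$size)
    depths$t_alt <- pmax(1L, as.integer(round(depths$t_depth * vaf)))
    recs[[i]] <- cbind(
      tibble(sample_id = spec$sample_id, chrom = chrom,
             pos = picked$rows$pos, ref = ref,
             alt = class_alt_base(class, ref), class = "SNV"),
      depths
    )
  }
  # dispersed background away from the cluster chromosome
  bg_n <- spec$background
  kat_chrom <- recs[[1]]$chrom[1]
  bg_pool <- pool[pool$chrom != kat_chrom, ]
  take <- bg_pool[sample.int(nrow(bg_pool), bg_n), ]
  class <- sample(SPECTRUM_CLASSES, bg_n, replace = TRUE, prob = mixture)
  ok_c <- take$ref %in% c("C", "G")
  class[ok_c] <- ifelse(substr(class[ok_c], 1, 1) == "C", class[ok_c],
                        sample(SPECTRUM_CLASSES[1:3], sum(ok_c), TRUE))
  class[!ok_c] <- ifelse(substr(class[!ok_c], 1, 1) == "T", class[!ok_c],
                         sample(SPECTRUM_CLASSES[4:6], sum(!ok_c), TRUE))
  recs[[length(recs) + 1]] <- cbind(
    tibble(sample_id = spec$sample_id, chrom = take$chrom, pos = take$pos,
           ref = take$ref, alt = class_alt_base(class, take$ref),
           class = "SNV"),
    draw_depths(bg_n)
  )
  out <- do.call(rbind, recs)
  out[order(out$chrom, out$pos), ]
}

# background substitutions for one ordinary sample
generate_sample_substitutions <- function(sample_id, n, pool, mixture,
                                          exclude_chrom = character()) {
  if (n == 0) return(NULL)
  p <- pool[!pool$chrom %in% exclude_chrom, ]
  class <- sample(SPECTRUM_CLASSES, n, replace = TRUE, prob = mixture)
  is_c <- substr(class, 1, 1) == "C"
  idx_cg <- which(p$ref %in% c("C", "G"))
  idx_ta <- which(p$ref %in% c("T", "A"))
  rows <- integer(n)
  rows[is_c] <- sample(idx_cg, sum(is_c))
  rows[!is_c] <- sample(idx_ta, sum(!is_c))
  take <- p[rows, ]
  cbind(
    tibble(sample_id = sample_id, chrom = take$chrom, pos = take$pos,
           ref = take$ref, alt = class_alt_base(class, take$ref),
           class = "SNV"),
    draw_depths(n)
  )
}

# 13 short indels adjacent to implanted tandem repeats
generate_indels <- function(config, genome, repeats, sample_ids,
                            zd0038a_id) {
  total <- config$indel_total
  if (total == 0) return(NULL)
  lens <- c(rep(1L, min(8L, total)),
            rep(2:4, length.out = max(0L, total - 8L)))
  # four indels go to the hypermutant (highest-burden) sample
  owners <- c(rep(zd0038a_id, min(4L, total)),
              sample(setdiff(sample_ids, zd0038a_id),
                     max(0L, total - 4L), replace = TRUE))
  loci <- repeats[sample.int(nrow(repeats), total), ]
  recs <- vector("list", total)
  for (i in seq_len(total)) {
    chrom <- loci$chrom[i]
    pos <- loci$end[i] + 1L
    len <- lens[i]
    anchor <- substr(genome[[chrom]], pos, pos)
    if (i %% 2 == 0) {  # deletion
      ref <- substr(genome[[chrom]], pos, pos + len)
      rec <- tibble(sample_id = owners[i], chrom = chrom, pos = pos,
                    ref = ref, alt = anchor, class = "DEL")
    } else {            # insertion
      ins <- random_dna(len)
      rec <- tibble(sample_id = owners[i], chrom = chrom, pos = pos,
                    ref = anchor, alt = paste0(anchor, ins), class = "INS")
    }
    recs[[i]] <- cbind(rec, draw_depths(1, vaf = runif(1, 0.3, 0.6)))
  }
  do.call(rbind, recs)
}

# per-sample copy-number segments: implanted amplicon + background events
generate_segments <- function(config, sheet, landmarks) {
  amp <- config$amplicon
  L <- config$genome$chrom_length
  in_sub <- subgroup_members(sheet, amp$subgroup)
  if (sum(in_sub) < amp$n_carriers) {
    stop("amplicon carrier subgroup smaller than n_carriers")
  }
  carriers <- if (amp$n_carriers > 0) {
    sort(sample(sheet$sample_id[in_sub], amp$n_carriers))
  } else character(0)
  segs <- list()
  add_seg <- function(sid, chrom, start, end, cn) {
    segs[[length(segs) + 1]] <<- tibble(
      sample_id = sid, chrom = chrom, start = as.integer(start),
      end = as.integer(end), copy_number = as.integer(cn)
    )
  }
  for (sid in carriers) {
    add_seg(sid, amp$chrom, landmarks$amp_start, landmarks$amp_end,
            amp$copy_number)
  }
  chroms <- paste0("chr", seq_len(config$genome$n_chrom))
  bg_chroms <- setdiff(chroms, amp$chrom)
  del_sub <- subgroup_members(sheet, config$deletion_excess_subgroup)
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    # background amplifications (mixed copy numbers; some below threshold)
    for (k in seq_len(rpois(1, 2))) {
      w <- sample(c(20000:60000, 100000:300000), 1)
      chrom <- sample(bg_chroms, 1)
      s <- sample.int(L - w, 1)
      cn <- sample(c(3L, 4L, 5L, 6L, 9L), 1,
                   prob = c(0.25, 0.2, 0.2, 0.2, 0.15))
      add_seg(sid, chrom, s, s + w - 1L, cn)
    }
    # homozygous deletions, enriched in the configured subgroup; the
    # background rate puts ~30% of ordinary samples at >=1 deletion
    lambda <- if (del_sub[i]) 3 else 0.35
    for (k in seq_len(rpois(1, lambda))) {
      w <- sample(20000:150000, 1)
      chrom <- sample(bg_chroms, 1)
      s <- sample.int(L - w, 1)
      add_seg(sid, chrom, s, s + w - 1L, 0L)
    }
  }
  list(segments = do.call(rbind, segs), carriers = carriers)
}

# small KEGG-style gene-set collection over the synthetic gene universe
generate_gene_sets <- function(models) {
  ids <- models$genes$gene_id
  named <- list(
    pka_signaling = unique(c(AMPLICON_GENES, sample(ids, 12))),
    p53_signaling = sample(ids, 25),
    mapk_signaling = sample(ids, 35),
    melanogenesis = sample(ids, 20),
    apoptosis = sample(ids, 28),
    cell_cycle = sample(ids, 30),
    vegf_signaling = sample(ids, 18)
  )
  rand <- lapply(1:8, function(i) sample(ids, sample(10:40, 1)))
  names(rand) <- sprintf("pathway_%02d", seq_along(rand))
  all <- c(named, rand)
  tibble(
    set_id = names(all),
    description = paste("synthetic gene set:", names(all)),
    genes = unname(all)
  )
}

#' Generate the full synthetic study bundle
#'
#' Builds, from one seed, everything downstream analysis needs: a random
#' genome with stop-free coding sequence and tandem-repeat loci, toy gene
#' models (including the amplicon gene cluster on the chr3 analog and the
#' kataegis host genes), the genotype sample sheet with ages and ploidies,
#' a mutation catalog (burden-model substitutions, the two special-sample
#' archetypes, and repeat-flanked indels), per-sample copy-number segments
#' with the implanted recurrent amplicon, a gene-set collection, and a
#' truth manifest recording every implanted structure.
#'
#' @param config a [cohort_config()]
#' @return a `cohort_bundle` list with elements `genome` (named character
#'   vector of chromosome sequences), `gene_models`, `sample_sheet`,
#'   `mutations`, `segments`, `gene_sets`, `truth`, `config`
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  layout <- build_gene_layout(config)
  models <- layout$models
  gb <- build_genome(config, models)
  genome <- gb$genome
  pool <- cds_position_pool(genome, models)

  # sample sheet -----------------------------------------------------------
  gt <- config$genotype_table
  rows <- rep(seq_len(nrow(gt)), gt$count)
  sheet <- tibble(
    sample_id = sprintf("ZD%03da", seq_along(rows)),
    oncogene = gt$oncogene[rows],
    p53 = gt$p53[rows],
    mitf = gt$mitf[rows],
    mitf_rescue = gt$mitf_rescue[rows],
    extra_alleles = gt$extra_alleles[rows],
    extra_transgenes = gt$extra_transgenes[rows],
    age = round(runif(length(rows), config$age_range[1],
                      config$age_range[2]), 1),
    ploidy = round(ifelse(runif(length(rows)) < 0.65,
                          runif(length(rows), 1.9, 2.5),
                          runif(length(rows), 2.8, 3.6)), 2)
  )
  # archetype samples: the BRAF-only fish and one BRAF;p53-het fish
  sp <- config$special_samples
  id038 <- which(sheet$oncogene == "BRAF" & sheet$p53 == "wt" &
                   sheet$mitf == "wt")[1]
  id8 <- which(sheet$oncogene == "BRAF" & sheet$p53 == "het" &
                 sheet$mitf == "wt" & sheet$extra_alleles == "")[1]
  sheet$sample_id[id038] <- sp$zd0038a$sample_id
  sheet$sample_id[id8] <- sp$zd8a$sample_id
  validate_sample_sheet(sheet)
  drivers <- count_drivers(sheet)

  # burdens ----------------------------------------------------------------
  zd8a_total <- sum(vapply(sp$zd8a$clusters, `[[`, integer(1), "size")) +
    sp$zd8a$background
  ordinary <- setdiff(seq_len(nrow(sheet)), c(id038, id8))
  cal <- calibrate_burdens(drivers[ordinary], sheet$age[ordinary],
                           special_n = c(sp$zd0038a$n, zd8a_total),
                           model = config$burden_model)
  burdens <- integer(nrow(sheet))
  burdens[ordinary] <- cal$counts
  burdens[id038] <- sp$zd0038a$n
  burdens[id8] <- zd8a_total

  # mutations --------------------------------------------------------------
  mix <- config$spectrum_mixture
  recs <- list(
    generate_special_sample(sp$zd0038a, genome, models, pool, mix),
    generate_special_sample(sp$zd8a, genome, models, pool, mix)
  )
  for (i in ordinary) {
    recs[[length(recs) + 1]] <- generate_sample_substitutions(
      sheet$sample_id[i], burdens[i], pool, mix,
      exclude_chrom = layout$landmarks$kat_chrom
    )
  }
  indels <- generate_indels(config, genome, gb$repeats, sheet$sample_id,
                            sp$zd0038a$sample_id)
  mutations <- do.call(rbind, c(recs, list(indels)))
  mutations <- mutations[order(mutations$sample_id, mutations$chrom,
                               mutations$pos), ]
  validate_mutations(mutations)

  # copy number ------------------------------------------------------------
  seg <- generate_segments(config, sheet, layout$landmarks)

  truth <- list(
    seed = config$seed,
    burden = list(sample_id = sheet$sample_id, drivers = drivers,
                  age = sheet$age, substitutions = burdens,
                  intercept = cal$intercept),
    special_samples = list(
      zd0038a = list(sample_id = sp$zd0038a$sample_id, n = sp$zd0038a$n),
      zd8a = list(
        sample_id = sp$zd8a$sample_id,
        clusters = lapply(sp$zd8a$clusters, function(cl) cl),
        cluster_positions = {
          m <- mutations[mutations$sample_id == sp$zd8a$sample_id &
                           mutations$chrom == layout$landmarks$kat_chrom &
                           mutations$class == "SNV", ]
          list(chrom = layout$landmarks$kat_chrom, pos = m$pos)
        },
        background = sp$zd8a$background
      )
    ),
    amplicon = list(chrom = config$amplicon$chrom,
                    start = layout$landmarks$amp_start,
                    end = layout$landmarks$amp_end,
                    copy_number = config$amplicon$copy_number,
                    carriers = seg$carriers,
                    genes = AMPLICON_GENES),
    indels = if (is.null(indels)) NULL else
      indels[, c("sample_id", "chrom", "pos", "ref", "alt", "class")],
    repeats = gb$repeats
  )

  structure(list(
    genome = genome,
    gene_models = models,
    sample_sheet = sheet,
    mutations = as_tibble(mutations),
    segments = as_tibble(seg$segments),
    gene_sets = generate_gene_sets(models),
    truth = truth,
    config = config
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$sample_sheet), "samples,",
      nrow(x$mutations), "mutations,", nrow(x$segments), "segments,",
      nrow(x$gene_models$genes), "genes\n")
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `sample_sheet.tsv`, `mutations.tsv`,
#' `segments.tsv`, `gene_sets.gmt` and `truth_manifest.json` under `dir`.
#'
#' @param bundle a `cohort_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(DNAStringSet(unlist(bundle$genome)),
                  file.path(dir, "genome.fa"))
  write_gene_models(bundle$gene_models, file.path(dir, "genes.gff3"))
  write_sample_sheet(bundle$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  write_mutations(bundle$mutations, file.path(dir, "mutations.tsv"))
  write_segments(bundle$segments, file.path(dir, "segments.tsv"))
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_json(bundle$truth, file.path(dir, "truth_manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
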