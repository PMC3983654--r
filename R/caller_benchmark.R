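#' Simulate a germline-bearing normal genome and a matched tumour
#'
#' Germline SNPs are placed by binomial sampling at the configured density
#' (expected count = density x genome length); the tumour then receives
#' `n_somatic` additional substitutions at positions disjoint from the
#' germline set, so the tumour sequence differs from the normal at exactly
#' the somatic positions.
#'
#' @param reference a named `DNAStringSet`, named character vector of
#'   chromosome sequences, or FASTA path
#' @param snp_density germline SNPs per base (the study grid is
#'   0, 0.001, 0.01, 0.1, 0.5)
#' @param n_somatic number of somatic substitutions (default 2000)
#' @param seed integer seed
#' @return a `genome_pair` list: `normal`, `tumor` (named character
#'   vectors), `germline_truth` and `somatic_truth` tibbles
#'   (`chrom`, `pos`, `ref`, `alt`), `snp_density`, `n_somatic`
#' @export
simulate_genome_pair <- function(reference, snp_density, n_somatic = 2000,
                                 seed = 1) {
  ref <- as_genome_strings(reference)
  stopifnot(snp_density >= 0, snp_density <= 1)
  set.seed(seed)
  total_len <- sum(nchar(ref))
  if (n_somatic > total_len) stop("n_somatic exceeds available positions")
  normal <- ref
  germ <- list()
  taken <- lapply(ref, function(s) logical(nchar(s)))
  for (chrom in names(ref)) {
    L <- nchar(ref[[chrom]])
    n_g <- rbinom(1, L, snp_density)
    if (n_g == 0) next
    pos <- sort(sample.int(L, n_g))
    taken[[chrom]][pos] <- TRUE
    chars <- strsplit(ref[[chrom]], "")[[1]]
    old <- chars[pos]
    new <- mutate_bases(old)
    chars[pos] <- new
    normal[[chrom]] <- paste(chars, collapse = "")
    germ[[chrom]] <- tibble(chrom = chrom, pos = pos, ref = old, alt = new)
  }
  germline <- if (length(germ)) do.call(rbind, germ) else
    tibble(chrom = character(), pos = integer(),
           ref = character(), alt = character())

  # somatic positions: uniform over the genome, avoiding germline sites
  lens <- nchar(ref)
  free_per_chrom <- lens - vapply(taken, sum, numeric(1))
  if (n_somatic > sum(free_per_chrom)) {
    stop("n_somatic exceeds available positions")
  }
  chrom_draw <- sample(names(ref), n_somatic, replace = TRUE,
                       prob = free_per_chrom)
  tumor <- normal
  som <- list()
  for (chrom in names(ref)) {
    n_s <- sum(chrom_draw == chrom)
    if (n_s == 0) next
    free <- which(!taken[[chrom]])
    pos <- sort(sample(free, n_s))
    chars <- strsplit(normal[[chrom]], "")[[1]]
    old <- chars[pos]
    new <- mutate_bases(old)
    chars[pos] <- new
    tumor[[chrom]] <- paste(chars, collapse = "")
    som[[chrom]] <- tibble(chrom = chrom, pos = pos, ref = old, alt = new)
  }
  somatic <- if (length(som)) do.call(rbind, som) else
    tibble(chrom = character(), pos = integer(),
           ref = character(), alt = character())
  structure(list(
    reference = ref, normal = normal, tumor = tumor,
    germline_truth = germline, somatic_truth = somatic,
    snp_density = snp_density, n_somatic = as.integer(n_somatic)
  ), class = "genome_pair")
}

as_genome_strings <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- readDNAStringSet(x)
  }
  if (inherits(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("reference sequences must be named")
  }
  as.list(x)
}

mutate_bases <- function(old) {
  vapply(old, function(b) sample(setdiff(DNA_BASES, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Mixing design for contamination benchmarking
#'
#' @param total_reads total reads in the mixed tumour file
#' @param tumor_fraction tumour content in `[0, 1]` (the study grid is
#'   0.30, 0.60, 1.00)
#' @param read_length read length in bp (75 in the study design)
#' @param paired emit read pairs
#' @param fragment_length outer distance between paired-read starts
#' @return a `mix_spec` list; the sequencing error and indel rates are
#'   structurally zero in this harness
#' @export
mix_spec <- function(total_reads, tumor_fraction, read_length = 75L,
                     paired = TRUE, fragment_length = 300L) {
  stopifnot(tumor_fraction >= 0, tumor_fraction <= 1, total_reads >= 0)
  list(total_reads = as.integer(total_reads),
       tumor_fraction = tumor_fraction,
       read_length = as.integer(read_length),
       paired = paired,
       fragment_length = as.integer(fragment_length),
       error_rate = 0, indel_rate = 0)
}

#' Simulate error-free reads with origin coordinates in the read names
#'
#' Reads are represented as an origin table (one row per read):
#' `qname`, `chrom`, `start`, `end`, `hap` (source haplotype label),
#' `mate`. Because the error rate is zero, a read's bases are exactly the
#' source haplotype substring, so sequences are materialised lazily with
#' [read_sequences()] / [write_fastq()].
#'
#' @param sequences named list/vector of haplotype chromosome strings
#' @param n_reads number of reads to emit (pairs count as two)
#' @param spec a [mix_spec()]
#' @param hap haplotype label recorded in each read
#' @param seed integer seed
#' @return a read-origin tibble
#' @export
simulate_reads <- function(sequences, n_reads, spec, hap = "hap", seed = 1) {
  sequences <- as_genome_strings(sequences)
  set.seed(seed)
  rl <- spec$read_length
  lens <- vapply(sequences, nchar, numeric(1))
  span <- if (spec$paired) spec$fragment_length else rl
  if (any(lens < span)) stop("sequence shorter than the simulated fragment")
  n_frag <- if (spec$paired) ceiling(n_reads / 2) else n_reads
  chrom <- sample(names(sequences), n_frag, replace = TRUE,
                  prob = lens - span + 1)
  start <- floor(runif(n_frag) * (lens[chrom] - span + 1)) + 1L
  first <- tibble(
    qname = sprintf("%s:%s:%d:1", hap, chrom, start),
    chrom = chrom, start = as.integer(start),
    end = as.integer(start + rl - 1L), hap = hap, mate = 1L
  )
  if (!spec$paired) {
    return(first[seq_len(n_reads), ])
  }
  m2_start <- as.integer(start + spec$fragment_length - rl)
  second <- tibble(
    qname = sprintf("%s:%s:%d:2", hap, chrom, start),
    chrom = chrom, start = m2_start,
    end = as.integer(m2_start + rl - 1L), hap = hap, mate = 2L
  )
  # keep fragments in their (random) draw order with mates adjacent, so a
  # head() subset is itself a uniform read sample
  reads <- rbind(first, second)[order(rep(seq_len(n_frag), 2)), ]
  reads[seq_len(min(n_reads, nrow(reads))), ]
}

#' Materialise read sequences from their origins
#'
#' @param reads a read-origin tibble
#' @param haplotypes named list of haplotype genomes (each a named list of
#'   chromosome strings), keyed by the `hap` labels used in `reads`
#' @return character vector of read sequences (mate 2 reverse-complemented)
#' @export
read_sequences <- function(reads, haplotypes) {
  out <- character(nrow(reads))
  for (h in unique(reads$hap)) {
    genome <- as_genome_strings(haplotypes[[h]])
    sel <- which(reads$hap == h)
    for (chrom in unique(reads$chrom[sel])) {
      i <- sel[reads$chrom[sel] == chrom]
      out[i] <- substring(genome[[chrom]], reads$start[i], reads$end[i])
    }
  }
  rev2 <- reads$mate == 2L
  if (any(rev2)) {
    out[rev2] <- as.character(
      reverseComplement(DNAStringSet(out[rev2]))
    )
  }
  out
}

#' @rdname read_sequences
#' @param path output FASTQ path (plain text)
#' @export
write_fastq <- function(reads, haplotypes, path) {
  seqs <- read_sequences(reads, haplotypes)
  dna <- DNAStringSet(seqs)
  names(dna) <- reads$qname
  writeXStringSet(dna, path, format = "fastq")
  invisible(path)
}

#' Mix tumour and normal reads to a target tumour fraction
#'
#' The mixed set contains `round(total * (1 - f))` normal-origin and
#' `round(total * f)` tumour-origin reads, deterministically shuffled.
#'
#' @param normal_reads,tumor_reads read-origin tibbles
#' @param spec a [mix_spec()]
#' @param seed shuffle seed
#' @return a read-origin tibble of `spec$total_reads` rows
#' @export
mix_contamination <- function(normal_reads, tumor_reads, spec, seed = 1) {
  n_norm <- round(spec$total_reads * (1 - spec$tumor_fraction))
  n_tum <- spec$total_reads - n_norm
  if (nrow(normal_reads) < n_norm || nrow(tumor_reads) < n_tum) {
    stop("insufficient reads to mix: need ", n_norm, " normal and ",
         n_tum, " tumour reads")
  }
  mixed <- rbind(head(normal_reads, n_norm), head(tumor_reads, n_tum))
  set.seed(seed)
  mixed[sample.int(nrow(mixed)), ]
}

#' Simulate the paired tumour/normal read sets for one genome pair
#'
#' Somatic variants are carried heterozygously: tumour reads are drawn in
#' equal proportion from the normal haplotype and the somatic-bearing tumour
#' haplotype. Normal reads are drawn from the normal haplotype only.
#'
#' @param pair a [simulate_genome_pair()] result
#' @param spec a [mix_spec()]; `total_reads` is used for both files
#' @param seed integer seed
#' @return list of read-origin tibbles `normal_reads`, `tumor_reads`, plus
#'   `haplotypes` for sequence materialisation
#' @export
simulate_tumor_normal_reads <- function(pair, spec, seed = 1) {
  n <- spec$total_reads
  normal_reads <- simulate_reads(pair$normal, n, spec, hap = "NORM",
                                 seed = seed)
  half <- ceiling(n / 2)
  tum_norm <- simulate_reads(pair$normal, half, spec, hap = "NORM",
                             seed = seed + 1L)
  tum_tum <- simulate_reads(pair$tumor, n - half, spec, hap = "TUM",
                            seed = seed + 2L)
  tumor_reads <- rbind(tum_norm, tum_tum)
  set.seed(seed + 3L)
  tumor_reads <- tumor_reads[sample.int(nrow(tumor_reads)), ]
  list(normal_reads = normal_reads, tumor_reads = tumor_reads,
       haplotypes = list(NORM = pair$normal, TUM = pair$tumor))
}

# per-haplotype variant sites relative to the reference
hap_variant_sites <- function(pair) {
  g <- pair$germline_truth
  s <- pair$somatic_truth
  list(
    NORM = g,
    TUM = rbind(g, s)
  )
}

# depth and alt counts at candidate sites from origin-encoded reads.
# Error-free reads match their haplotype exactly, so a read supports the
# alternate allele at a site iff its haplotype carries that variant and the
# read covers the site; this is an exact pileup.
pileup_at_sites <- function(reads, sites, hap_variants) {
  if (nrow(sites) == 0) {
    return(cbind(sites, tibble(depth = integer(), alt = integer())))
  }
  key <- function(chrom, pos) paste(chrom, pos)
  site_gr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  read_gr <- GRanges(reads$chrom, IRanges(reads$start, reads$end))
  depth <- countOverlaps(site_gr, read_gr)
  alt <- integer(nrow(sites))
  for (h in unique(reads$hap)) {
    hv <- hap_variants[[h]]
    if (is.null(hv) || nrow(hv) == 0) next
    carries <- key(sites$chrom, sites$pos) %in% key(hv$chrom, hv$pos)
    if (!any(carries)) next
    sel <- reads$hap == h
    alt[carries] <- alt[carries] + countOverlaps(
      site_gr[carries],
      GRanges(reads$chrom[sel], IRanges(reads$start[sel], reads$end[sel]))
    )
  }
  cbind(as_tibble(sites), tibble(depth = depth, alt = alt))
}

#' Naive somatic caller over origin-encoded pileups
#'
#' Calls a site somatic when tumour alternate-allele support reaches
#' `min_alt_reads` and the normal-sample variant allele fraction is at most
#' `max_normal_vaf`. Candidate sites are all sites at which any covering
#' read carries a non-reference base (with a zero error rate this is the
#' complete candidate set).
#'
#' @param tumor_reads,normal_reads read-origin tibbles
#' @param pair the [simulate_genome_pair()] the reads were drawn from
#'   (provides the per-haplotype variant lists that define the pileup)
#' @param min_alt_reads minimum tumour alt reads (default 3)
#' @param max_normal_vaf maximum normal VAF (default 0.05)
#' @return tibble of calls (`chrom`, `pos`, tumour/normal depth and alt)
#' @export
naive_somatic_caller <- function(tumor_reads, normal_reads, pair,
                                 min_alt_reads = 3, max_normal_vaf = 0.05) {
  hv <- hap_variant_sites(pair)
  sites <- unique(rbind(hv$NORM, hv$TUM))
  if (nrow(sites) == 0 || nrow(tumor_reads) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  t_depth = integer(), t_alt = integer(),
                  n_depth = integer(), n_alt = integer()))
  }
  tum <- pileup_at_sites(tumor_reads, sites[, c("chrom", "pos")], hv)
  nor <- pileup_at_sites(normal_reads, sites[, c("chrom", "pos")], hv)
  n_vaf <- ifelse(nor$depth > 0, nor$alt / nor$depth, 0)
  keep <- tum$alt >= min_alt_reads & n_vaf <= max_normal_vaf
  tibble(
    chrom = tum$chrom[keep], pos = tum$pos[keep],
    t_depth = tum$depth[keep], t_alt = tum$alt[keep],
    n_depth = nor$depth[keep], n_alt = nor$alt[keep]
  )
}

#' Score a somatic call set against truth
#'
#' Exact set arithmetic on (chrom, pos) keys. Sensitivity is
#' `TP / (TP + FN)`; precision is `TP / (TP + FP)`; either is `NA` (with a
#' warning) when its denominator is zero.
#'
#' @param calls tibble with `chrom`, `pos`
#' @param truth tibble with `chrom`, `pos` (the somatic truth set)
#' @return a `call_score` list: `tp`, `fp`, `fn`, `sensitivity`, `precision`
#' @export
score_calls <- function(calls, truth) {
  ck <- paste(calls$chrom, calls$pos)
  tk <- paste(truth$chrom, truth$pos)
  tp <- sum(ck %in% tk)
  fp <- length(ck) - tp
  fn <- length(tk) - tp
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("sensitivity undefined: empty truth set"); NA_real_
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("precision undefined: no calls made"); NA_real_
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity = sens, precision = prec),
            class = "call_score")
}

#' Run the density-by-contamination benchmark grid
#'
#' For each germline SNP density and tumour fraction, simulates a genome
#' pair, error-free paired reads at the target mean coverage, a contaminated
#' tumour read set, runs the naive caller, and scores it against the somatic
#' truth.
#'
#' @param reference reference genome (see [simulate_genome_pair()])
#' @param densities germline SNP densities to sweep
#' @param fractions tumour fractions to sweep
#' @param target_depth mean per-base coverage of each read file
#' @param n_somatic somatic substitutions per pair
#' @param min_alt_reads,max_normal_vaf caller thresholds
#' @param seed integer seed
#' @return tibble with one row per grid cell (density, fraction, tp/fp/fn,
#'   sensitivity, precision)
#' @export
run_benchmark_grid <- function(reference,
                               densities = c(0, 0.001, 0.01, 0.1, 0.5),
                               fractions = c(0.3, 0.6, 1.0),
                               target_depth = 80,
                               n_somatic = 2000,
                               min_alt_reads = 3,
                               max_normal_vaf = 0.05,
                               seed = 1) {
  ref <- as_genome_strings(reference)
  genome_len <- sum(nchar(ref))
  rows <- list()
  for (d in densities) {
    pair <- simulate_genome_pair(ref, d, n_somatic = n_somatic,
                                 seed = seed + round(1000 * d))
    for (f in fractions) {
      n_reads <- ceiling(target_depth * genome_len / 75)
      spec <- mix_spec(total_reads = n_reads, tumor_fraction = f)
      rs <- simulate_tumor_normal_reads(pair, spec, seed = seed)
      mixed <- mix_contamination(rs$normal_reads, rs$tumor_reads, spec,
                                 seed = seed)
      calls <- naive_somatic_caller(mixed, rs$normal_reads, pair,
                                    min_alt_reads = min_alt_reads,
                                    max_normal_vaf = max_normal_vaf)
      sc <- score_calls(calls, pair$somatic_truth)
      rows[[length(rows) + 1]] <- tibble(
        snp_density = d, tumor_fraction = f,
        tp = sc$tp, fp = sc$fp, fn = sc$fn,
        sensitivity = sc$sensitivity, precision = sc$precision
      )
    }
  }
  do.call(rbind, rows)
}
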