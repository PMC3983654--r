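# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# the full default cohort (53 samples, 21 x 1 Mb genome); cached because
# several files exercise it
default_bundle <- function() {
  if (is.null(.fixture_env$default)) {
    .fixture_env$default <- generate_cohort(cohort_config(seed = 1))
  }
  .fixture_env$default
}

# a scaled-down cohort (same 53 samples, smaller genome) for cheap tests
small_bundle <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(small_config())
  }
  .fixture_env$small
}

small_config <- function(seed = 42) {
  cohort_config(seed = seed, n_chrom = 6, chrom_length = 3e5,
                genes_per_chrom = 12, amplicon = list(width = 50000L))
}

# a hand-built single-gene genome for annotation oracles.
# chrT (length 400):
#   gene tp1 (+): exon1 [101,158] (utr5 101-110, CDS 111-158),
#   intron [159,219], exon2 [220,321] (CDS 220-279, utr3 280-321)
# CDS(108 bp) starts ATG TGG CCA ... (known codons for the oracles)
tiny_annotation_fixture <- function() {
  set.seed(7)
  chrom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  cds_seq <- paste0(
    "ATG", "TGG", "CCA",
    paste(rep("GGA", 33), collapse = "")
  )  # 108 bp, no stop codons
  substr(chrom, 111, 158) <- substr(cds_seq, 1, 48)
  substr(chrom, 220, 279) <- substr(cds_seq, 49, 108)
  # 5' UTR without an ATG; position 106 C>T creates one (CACGC -> CATGC)
  substr(chrom, 101, 110) <- "CCCCACGCCC"
  genome <- list(chrT = chrom)
  models <- gene_models(
    genes = tibble::tibble(gene_id = "tp1", chrom = "chrT",
                           start = 101L, end = 321L, strand = "+"),
    exons = tibble::tibble(gene_id = "tp1",
                           start = c(101L, 220L), end = c(158L, 321L)),
    cds = tibble::tibble(gene_id = "tp1",
                         start = c(111L, 220L), end = c(158L, 279L))
  )
  list(genome = genome, models = models, cds_seq = cds_seq)
}

# one mutation-catalog row with sane depths
rec <- function(sample_id = "s1", chrom = "chrT", pos, ref, alt,
                class = "SNV", t_depth = 60L, t_alt = 20L,
                n_depth = 50L, n_alt = 0L) {
  tibble::tibble(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, class = class,
                 t_depth = as.integer(t_depth), t_alt = as.integer(t_alt),
                 n_depth = as.integer(n_depth), n_alt = as.integer(n_alt))
}

# a single valid sample-sheet row to perturb in genotype tests
default_genotype_sheet_row <- function() {
  tibble::tibble(
    sample_id = "s1", oncogene = "BRAF", p53 = "wt", mitf = "wt",
    mitf_rescue = FALSE, extra_alleles = "", extra_transgenes = "",
    age = 10, ploidy = 2.1
  )
}

# stop-free random in-frame CDS of the given length
random_cds <- function(len, seed = 1) {
  stopifnot(len %% 3 == 0)
  set.seed(seed)
  codons <- setdiff(names(Biostrings::GENETIC_CODE),
                    c("TAA", "TAG", "TGA"))
  paste(sample(codons, len / 3, replace = TRUE), collapse = "")
}
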