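test_that("coding consequences follow the genetic code, strand-aware", {
  fx <- tiny_annotation_fixture()
  # codon 2 is TGG at 114-116; G>A at its middle gives TAG (stop)
  nonsense <- annotate_consequence(rec(pos = 115, ref = "G", alt = "A"),
                                   fx$models, fx$genome)
  expect_equal(nonsense$consequence, "nonsense")
  expect_equal(nonsense$gene_id, "tp1")
  # codon 3 is CCA at 117-119; A>G gives CCG (both Pro)
  syn <- annotate_consequence(rec(pos = 119, ref = "A", alt = "G"),
                              fx$models, fx$genome)
  expect_equal(syn$consequence, "synonymous")
  # GGA -> GAA (Gly -> Glu) is missense
  mis <- annotate_consequence(rec(pos = 121, ref = "G", alt = "A"),
                              fx$models, fx$genome)
  expect_equal(mis$consequence, "missense")
  # a 1 bp CDS deletion shifts the frame; a 3 bp one does not
  del_ref <- substr(fx$genome$chrT, 120, 121)
  fs <- annotate_consequence(
    rec(pos = 120, ref = del_ref, alt = substr(del_ref, 1, 1),
        class = "DEL"),
    fx$models, fx$genome
  )
  expect_equal(fs$consequence, "frameshift")
  del3_ref <- substr(fx$genome$chrT, 120, 123)
  inframe <- annotate_consequence(
    rec(pos = 120, ref = del3_ref, alt = substr(del3_ref, 1, 1),
        class = "DEL"),
    fx$models, fx$genome
  )
  expect_equal(inframe$consequence, "inframe_indel")
})

test_that("splice, UTR, start-gain and intergenic classes are positional", {
  fx <- tiny_annotation_fixture()
  at <- function(pos, alt = "A") {
    ref <- substr(fx$genome$chrT, pos, pos)
    if (ref == alt) alt <- "G"
    annotate_consequence(rec(pos = pos, ref = ref, alt = alt),
                         fx$models, fx$genome)$consequence
  }
  expect_equal(at(159), "splice_site")  # intron base 1
  expect_equal(at(160), "splice_site")  # intron base 2
  expect_equal(at(165), "intergenic")   # deep intron: non-coding
  expect_equal(at(219), "splice_site")  # acceptor side
  expect_equal(at(103), "utr5")
  expect_equal(at(300), "utr3")
  expect_equal(at(50), "intergenic")
  # 5' UTR C>T at 106 creates CATGC -> a new ATG on the coding strand
  sg <- annotate_consequence(rec(pos = 106, ref = "C", alt = "T"),
                             fx$models, fx$genome)
  expect_equal(sg$consequence, "start_gained")
})

test_that("annotation is invariant under reverse-complementing the locus", {
  fx <- tiny_annotation_fixture()
  L <- nchar(fx$genome$chrT)
  flip <- function(p) L - p + 1L
  rc_genome <- list(chrT = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$genome$chrT)
  )))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_models <- gene_models(
    genes = tibble::tibble(gene_id = "tp1", chrom = "chrT",
                           start = flip(321L), end = flip(101L),
                           strand = "-"),
    exons = tibble::tibble(gene_id = "tp1",
                           start = flip(c(158L, 321L)),
                           end = flip(c(101L, 220L))),
    cds = tibble::tibble(gene_id = "tp1",
                         start = flip(c(158L, 279L)),
                         end = flip(c(111L, 220L)))
  )
  cases <- list(c(115, "G", "A"), c(119, "A", "G"), c(121, "G", "A"),
                c(159, "N", "A"), c(103, "N", "A"))
  for (cs in cases) {
    pos <- as.integer(cs[1])
    ref <- substr(fx$genome$chrT, pos, pos)
    alt <- if (cs[3] != ref) cs[3] else "C"
    fwd <- annotate_consequence(rec(pos = pos, ref = ref, alt = alt),
                                fx$models, fx$genome)$consequence
    rev <- annotate_consequence(
      rec(pos = flip(pos), ref = unname(comp[ref]), alt = unname(comp[alt])),
      rc_models, rc_genome
    )$consequence
    expect_equal(rev, fwd, info = paste("pos", pos))
  }
})

test_that("a reference mismatch is a data-integrity error", {
  fx <- tiny_annotation_fixture()
  pos <- 115L
  genome_base <- substr(fx$genome$chrT, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), genome_base)[1]
  other <- setdiff(c("A", "C", "G", "T"), c(genome_base, wrong))[1]
  expect_error(
    annotate_consequence(rec(pos = pos, ref = wrong, alt = other),
                         fx$models, fx$genome),
    "mismatch"
  )
})

test_that("somatic SNV filter applies the VAF and germline-proximity rules", {
  base <- rbind(
    rec(pos = 100, ref = "C", alt = "T", t_depth = 60L, t_alt = 20L,
        n_depth = 50L, n_alt = 0L),                 # clean pass
    rec(pos = 200, ref = "C", alt = "T", t_depth = 60L, t_alt = 20L,
        n_depth = 50L, n_alt = 5L),                 # normal VAF 0.10
    rec(pos = 300, ref = "C", alt = "T", t_depth = 60L, t_alt = 3L,
        n_depth = 50L, n_alt = 0L),                 # tumour VAF 0.05
    rec(pos = 400, ref = "C", alt = "T", t_depth = 60L, t_alt = 20L,
        n_depth = 50L, n_alt = 0L),                 # germline 3 bp away
    rec(pos = 500, ref = "C", alt = "T", t_depth = 0L, t_alt = 0L,
        n_depth = 50L, n_alt = 0L)                  # no tumour coverage
  )
  germ <- tibble::tibble(chrom = "chrT", pos = 403L)
  out <- somatic_snv_filter(base, germ)
  expect_equal(out$reason, c("pass", "normal_contamination",
                             "low_tumor_vaf", "germline_proximity",
                             "no_coverage"))
  expect_equal(out$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # boundary cases: normal VAF exactly 3% passes; tumour VAF exactly 10%
  edge <- rbind(
    rec(pos = 10, ref = "C", alt = "T", t_depth = 100L, t_alt = 10L,
        n_depth = 100L, n_alt = 3L),
    rec(pos = 20, ref = "C", alt = "T", t_depth = 100L, t_alt = 9L,
        n_depth = 100L, n_alt = 0L)
  )
  oe <- somatic_snv_filter(edge)
  expect_equal(oe$pass, c(TRUE, FALSE))
  # the filter never alters the record fields
  expect_equal(out[, names(base)], base)
  # pure function: same verdicts on a second call
  expect_identical(somatic_snv_filter(base, germ), out)
})

test_that("indel filter enforces depth, support and repeat rules", {
  ind <- rbind(
    rec(pos = 10, ref = "CAT", alt = "C", class = "DEL",
        t_depth = 20L, n_depth = 12L),      # normal depth 12 < 15
    rec(pos = 20, ref = "CAT", alt = "C", class = "DEL",
        t_depth = 20L, n_depth = 20L),      # small, well supported
    rec(pos = 30, ref = paste(rep("A", 26), collapse = ""), alt = "A",
        class = "DEL", t_depth = 30L, n_depth = 30L),  # 25 bp in repeat
    rec(pos = 40, ref = "C", alt = "CAT", class = "INS",
        t_depth = 30L, n_depth = 30L)       # small, weak pindel support
  )
  out <- indel_filter(
    ind,
    pindel_support = c(5L, 4L, 6L, 3L),
    bwa_support = c(2L, 1L, 2L, 2L),
    strand_fwd = c(2L, 2L, 3L, 1L),
    strand_rev = c(2L, 2L, 3L, 1L),
    in_repeat = c(FALSE, FALSE, TRUE, FALSE)
  )
  expect_equal(out$reason, c("low_depth", "pass", "repeat_region",
                             "insufficient_support"))
  expect_error(
    indel_filter(rec(pos = 1, ref = "C", alt = "T"), 1, 1, 1, 1, FALSE),
    "INS/DEL"
  )
})

test_that("NS:S ratio reproduces the printed 2.3 and guards degenerates", {
  printed <- tibble::tibble(
    consequence = rep(c("missense", "nonsense", "synonymous", "splice_site"),
                      c(168, 16, 79, 25))
  )
  expect_equal(ns_s_ratio(printed), 2.3)
  expect_equal(
    ns_s_ratio(tibble::tibble(consequence = rep(c("missense", "synonymous"),
                                                c(10, 10)))),
    1.0
  )
  expect_equal(
    ns_s_ratio(tibble::tibble(consequence = rep("synonymous", 5))),
    0.0
  )
  expect_warning(
    r <- ns_s_ratio(tibble::tibble(consequence = rep("missense", 5))),
    "undefined"
  )
  expect_true(is.na(r))
})
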