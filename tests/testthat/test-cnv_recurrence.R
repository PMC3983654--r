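seg_row <- function(sample_id, chrom, start, end, cn) {
  tibble::tibble(sample_id = sample_id, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 copy_number = as.integer(cn))
}

two_gene_models <- function() {
  gene_models(
    genes = tibble::tibble(gene_id = c("gA", "gB"), chrom = "c1",
                           start = c(1L, 51L), end = c(50L, 100L),
                           strand = "+"),
    exons = tibble::tibble(gene_id = c("gA", "gB"),
                           start = c(1L, 51L), end = c(50L, 100L)),
    cds = tibble::tibble(gene_id = character(), start = integer(),
                         end = integer())
  )
}

test_that("amplification calling is ploidy-gated and deletions are CN 0", {
  segs <- rbind(
    seg_row("s1", "chr1", 1, 50000, 6),      # ploidy 2.0 -> amplification
    seg_row("s2", "chr1", 1, 50000, 6),      # ploidy 3.0 -> none
    seg_row("s2", "chr2", 1, 50000, 8),      # ploidy 3.0 -> amplification
    seg_row("s1", "chr3", 1, 50000, 0),      # homozygous deletion
    seg_row("s1", "chr4", 1, 2e7, 20)        # 20 Mb: ineligible
  )
  pl <- c(s1 = 2.0, s2 = 3.0)
  expect_message(calls <- call_cna(segs, pl), "excluded")
  expect_equal(calls$call, c("amplification", "none", "amplification",
                             "homozygous_deletion", "none"))
  expect_error(call_cna(seg_row("sX", "chr1", 1, 10, 6), pl),
               "missing ploidy")
  # boundary: ploidy exactly 2.7 uses the >=8 threshold
  b <- call_cna(rbind(seg_row("s3", "chr1", 1, 10, 5),
                      seg_row("s3", "chr1", 20, 30, 8)),
                c(s3 = 2.7))
  expect_equal(b$call, c("none", "amplification"))
})

test_that("recurrence counts 1 bp overlaps per sample", {
  models <- two_gene_models()
  calls <- rbind(
    cbind(seg_row("s1", "c1", 45, 60, 9), call = "amplification"),
    cbind(seg_row("s2", "c1", 50, 50, 9), call = "amplification"),
    cbind(seg_row("s3", "c1", 90, 99, 0), call = "homozygous_deletion")
  )
  rp <- recurrence_profile(calls, models,
                           sample_ids = c("s1", "s2", "s3"))
  # the straddling segment hits both genes; the 1 bp one only gA
  expect_equal(rp$amplification["gA", ], c(s1 = TRUE, s2 = TRUE, s3 = FALSE))
  expect_equal(rp$amplification["gB", ], c(s1 = TRUE, s2 = FALSE, s3 = FALSE))
  expect_equal(rp$homozygous_deletion["gB", "s3"], TRUE)
  rec <- rp$recurrence
  expect_equal(rec$amplification[rec$gene_id == "gA"], 2L)
  none <- recurrence_profile(calls[0, ], models, sample_ids = "s1")
  expect_true(all(!none$amplification))
})

test_that("permutation p-values match exhaustive placement enumeration", {
  models <- two_gene_models()
  calls <- cbind(seg_row("s1", "c1", 1, 50, 9), call = "amplification")
  target <- tibble::tibble(chrom = "c1", start = 1L, end = 100L)

  # exhaustive oracle over all 51 placements of a 50-length segment
  hits_A <- 0; hits_B <- 0
  for (u in 1:51) {
    if (u <= 50) hits_A <- hits_A + 1          # overlaps [1,50]
    if (u + 49 >= 51) hits_B <- hits_B + 1     # overlaps [51,100]
  }
  exact_A <- hits_A / 51   # P(perm count >= observed 1)
  n_perm <- 10000
  res <- permutation_enrichment(calls, models, target_regions = target,
                                n_perm = n_perm, seed = 33)
  pA <- res$p_empirical[res$gene_id == "gA"]
  pB <- res$p_empirical[res$gene_id == "gB"]
  se <- sqrt(exact_A * (1 - exact_A) / n_perm)
  expect_lt(abs(pA - (n_perm * exact_A + 1) / (n_perm + 1)), 3 * se + 1e-6)
  # gene B observed 0: every permutation has >= 0, so p is exactly 1
  expect_equal(pB, 1)
  # determinism
  res2 <- permutation_enrichment(calls, models, target_regions = target,
                                 n_perm = 1000, seed = 33)
  res3 <- permutation_enrichment(calls, models, target_regions = target,
                                 n_perm = 1000, seed = 33)
  expect_equal(res2, res3)
  # a segment longer than the space is rejected
  expect_error(
    permutation_enrichment(
      cbind(seg_row("s1", "c1", 1, 200, 9), call = "amplification"),
      models, target_regions = target, n_perm = 10
    ),
    "longer than"
  )
})

test_that("the implanted amplicon is recovered as significant", {
  # the full-scale genome: on a toy genome, background segments are so
  # large relative to the randomisation space that tenfold recurrence is
  # unremarkable, which is itself correct permutation behaviour
  b <- default_bundle()
  calls <- suppressMessages(call_cna(b$segments, b$sample_sheet))
  chrom_lengths <- setNames(
    rep(b$config$genome$chrom_length, b$config$genome$n_chrom),
    paste0("chr", seq_len(b$config$genome$n_chrom))
  )
  res <- permutation_enrichment(calls, b$gene_models, n_perm = 20000,
                                seed = 17, chrom_lengths = chrom_lengths)
  amp <- res[res$gene_id == "prkacaa_like", ]
  expect_equal(amp$observed, 10L)
  expect_lte(amp$p_empirical, 1 / 20001 + 1e-9)
  expect_lte(amp$p_bonferroni, 0.05)
  # empirical p is monotone non-increasing in observed recurrence
  expect_true(all(res$p_empirical[res$observed >= 10] <=
                    min(res$p_empirical[res$observed == 0])))
})

test_that("subgroup association reproduces the hand-computed chi-square", {
  # 10 carriers all in a 25-sample subgroup, 43 non-carriers split 15/28
  hit <- rep(c(TRUE, FALSE, FALSE), c(10, 15, 28))
  sub <- rep(c(TRUE, TRUE, FALSE), c(10, 15, 28))
  out <- subgroup_association(hit, sub)
  # Pearson chi-square on [[10,0],[15,28]] = 53*(10*28)^2/(10*43*25*28)
  expect_equal(out$statistic, 53 * (10 * 28)^2 / (10 * 43 * 25 * 28),
               tolerance = 1e-10)
  expect_equal(out$p_value, 2.03e-4, tolerance = 5e-3)
  # proportional table: no association
  hit2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(5, 5, 10, 10))
  sub2 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(5, 5, 10, 10))
  out2 <- subgroup_association(hit2, sub2)
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$p_value, 1)
  # Yates correction shrinks the statistic
  outc <- subgroup_association(hit, sub, correct = TRUE)
  expect_lt(outc$statistic, out$statistic)
  expect_warning(out3 <- subgroup_association(rep(TRUE, 10),
                                              rep(c(TRUE, FALSE), 5)),
                 "degenerate")
  expect_true(is.na(out3$p_value))
})
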