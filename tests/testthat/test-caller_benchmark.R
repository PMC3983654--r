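ref_200k <- function(seed = 3) {
  set.seed(seed)
  list(
    chrA = paste(sample(c("A", "C", "G", "T"), 120000, replace = TRUE),
                 collapse = ""),
    chrB = paste(sample(c("A", "C", "G", "T"), 80000, replace = TRUE),
                 collapse = "")
  )
}

count_differences <- function(a, b) {
  # independent string-level oracle for tumour-normal differences
  sum(vapply(names(a), function(ch) {
    sum(strsplit(a[[ch]], "")[[1]] != strsplit(b[[ch]], "")[[1]])
  }, numeric(1)))
}

test_that("genome-pair simulation places the exact somatic count", {
  ref <- ref_200k()
  pair <- simulate_genome_pair(ref, snp_density = 0.001, n_somatic = 500,
                               seed = 2)
  expect_equal(nrow(pair$somatic_truth), 500)
  expect_equal(count_differences(pair$normal, pair$tumor), 500)
  # somatic and germline sets are disjoint
  expect_length(
    intersect(paste(pair$somatic_truth$chrom, pair$somatic_truth$pos),
              paste(pair$germline_truth$chrom, pair$germline_truth$pos)),
    0
  )
})

test_that("germline density behaves binomially", {
  ref <- ref_200k()
  pair0 <- simulate_genome_pair(ref, snp_density = 0, n_somatic = 10,
                                seed = 1)
  expect_equal(nrow(pair0$germline_truth), 0)
  expect_identical(pair0$normal, pair0$reference)

  set.seed(4)
  small <- list(c1 = paste(sample(c("A", "C", "G", "T"), 10000,
                                  replace = TRUE), collapse = ""))
  pair <- simulate_genome_pair(small, snp_density = 0.5, n_somatic = 10,
                               seed = 5)
  # binomial mean 5000, sd = sqrt(10000 * 0.25) = 50
  expect_lt(abs(nrow(pair$germline_truth) - 5000), 3 * 50)
  expect_error(
    simulate_genome_pair(small, snp_density = 0, n_somatic = 20000),
    "exceeds available"
  )
})

test_that("read simulation is error-free with exact counts and coverage", {
  ref <- ref_200k()
  spec <- mix_spec(total_reads = 200, tumor_fraction = 1)
  reads <- simulate_reads(ref, 200, spec, hap = "N", seed = 9)
  expect_equal(nrow(reads), 200)
  expect_true(all(reads$end - reads$start + 1 == 75))
  # realigning by encoded origins reconstructs source bases exactly
  seqs <- read_sequences(reads, list(N = ref))
  i1 <- which(reads$mate == 1)[1:20]
  expect_equal(
    seqs[i1],
    unname(substring(unlist(ref[reads$chrom[i1]]), reads$start[i1],
                     reads$end[i1]))
  )
  i2 <- which(reads$mate == 2)[1:5]
  expect_equal(
    seqs[i2],
    unname(as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(
        substring(unlist(ref[reads$chrom[i2]]), reads$start[i2],
                  reads$end[i2])
      )
    )))
  )
  # mean depth identity
  n <- 20000
  reads2 <- simulate_reads(ref, n, spec, hap = "N", seed = 10)
  cov <- sum(reads2$end - reads2$start + 1) / 200000
  expect_equal(cov, n * 75 / 200000, tolerance = 1e-6)
  expect_error(
    simulate_reads(list(x = "ACGT"), 10, spec),
    "shorter"
  )
})

test_that("contamination mixing hits the exact proportions", {
  ref <- ref_200k()
  spec <- mix_spec(total_reads = 1000, tumor_fraction = 0.3)
  norm <- simulate_reads(ref, 1200, spec, hap = "A", seed = 1)
  tum <- simulate_reads(ref, 1200, spec, hap = "B", seed = 2)
  mixed <- mix_contamination(norm, tum, spec, seed = 3)
  expect_equal(nrow(mixed), 1000)
  expect_equal(sum(mixed$hap == "A"), 700)
  expect_equal(sum(mixed$hap == "B"), 300)
  # the printed full-scale design: 8M reads at 60% is 3.2M + 4.8M
  spec60 <- mix_spec(total_reads = 8e6, tumor_fraction = 0.6)
  expect_equal(round(spec60$total_reads * (1 - spec60$tumor_fraction)),
               3.2e6)
  spec100 <- mix_spec(total_reads = 500, tumor_fraction = 1)
  mixed100 <- mix_contamination(norm, tum, spec100, seed = 3)
  expect_equal(sum(mixed100$hap == "A"), 0)
  expect_error(
    mix_contamination(norm[1:10, ], tum, spec, seed = 1),
    "insufficient"
  )
})

test_that("the naive caller is exact on noise-free pure tumour input", {
  ref <- ref_200k()
  pair <- simulate_genome_pair(ref, snp_density = 0.005, n_somatic = 100,
                               seed = 6)
  spec <- mix_spec(total_reads = ceiling(60 * 200000 / 75),
                   tumor_fraction = 1)
  rs <- simulate_tumor_normal_reads(pair, spec, seed = 7)
  mixed <- mix_contamination(rs$normal_reads, rs$tumor_reads, spec,
                             seed = 7)
  calls <- naive_somatic_caller(mixed, rs$normal_reads, pair)
  sc <- score_calls(calls, pair$somatic_truth)
  # conservation holds and no germline site leaks through
  expect_equal(sc$tp + sc$fn, nrow(pair$somatic_truth))
  expect_equal(sc$fp, 0)
  expect_equal(sc$precision, 1.0)
  expect_gte(sc$sensitivity, 0.99)
})

test_that("sensitivity under contamination matches the binomial-tail oracle", {
  ref <- ref_200k()
  pair <- simulate_genome_pair(ref, snp_density = 0.001, n_somatic = 200,
                               seed = 8)
  spec <- mix_spec(total_reads = ceiling(60 * 200000 / 75),
                   tumor_fraction = 0.3)
  rs <- simulate_tumor_normal_reads(pair, spec, seed = 9)
  mixed <- mix_contamination(rs$normal_reads, rs$tumor_reads, spec,
                             seed = 9)
  calls <- naive_somatic_caller(mixed, rs$normal_reads, pair,
                                min_alt_reads = 3)
  sc <- score_calls(calls, pair$somatic_truth)
  # per covered site, an alt read requires tumour origin (30%) AND the
  # somatic haplotype (het, 50%): p = 0.15 per covering read
  sites <- pair$somatic_truth
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  read_gr <- GenomicRanges::GRanges(
    mixed$chrom, IRanges::IRanges(mixed$start, mixed$end)
  )
  depth <- GenomicRanges::countOverlaps(site_gr, read_gr)
  p_call <- stats::pbinom(2, depth, 0.3 * 0.5, lower.tail = FALSE)
  expected_sens <- mean(p_call)
  sd_sens <- sqrt(sum(p_call * (1 - p_call))) / length(p_call)
  expect_lt(abs(sc$sensitivity - expected_sens), 3 * sd_sens + 0.02)
})

test_that("call scoring is exact set arithmetic with guarded degenerates", {
  truth <- tibble::tibble(chrom = "c", pos = 1:10)
  calls <- tibble::tibble(chrom = "c", pos = c(1:8, 101, 102))
  sc <- score_calls(calls, truth)
  expect_equal(c(sc$tp, sc$fp, sc$fn), c(8, 2, 2))
  expect_equal(sc$sensitivity, 0.8)
  expect_equal(sc$precision, 0.8)
  expect_warning(
    sc0 <- score_calls(tibble::tibble(chrom = character(), pos = integer()),
                       truth),
    "no calls"
  )
  expect_equal(sc0$sensitivity, 0)
  expect_true(is.na(sc0$precision))
  perfect <- score_calls(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
})

test_that("the benchmark grid runs with monotone sensitivity in tumour content", {
  set.seed(12)
  ref <- list(c1 = paste(sample(c("A", "C", "G", "T"), 60000,
                               replace = TRUE), collapse = ""))
  grid <- run_benchmark_grid(
    ref, densities = c(0, 0.01), fractions = c(0.3, 0.6, 1.0),
    target_depth = 40, n_somatic = 100, seed = 13
  )
  expect_equal(nrow(grid), 6)
  expect_true(all(grid$tp + grid$fn == 100))
  for (d in unique(grid$snp_density)) {
    s <- grid$sensitivity[grid$snp_density == d][
      order(grid$tumor_fraction[grid$snp_density == d])
    ]
    expect_true(all(diff(s) >= 0))
  }
})
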