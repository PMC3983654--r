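test_that("purine-reference mutations fold onto pyrimidine classes", {
  expect_equal(fold_substitution(c("C", "G"), c("T", "A")),
               c("C>T", "C>T"))
  expect_equal(fold_substitution("A", "C"), "T>G")
  cat2 <- rbind(rec(pos = 10, ref = "C", alt = "T"),
                rec(pos = 20, ref = "G", alt = "A"))
  prof <- mutation_spectrum(cat2)
  expect_equal(unname(prof$fractions["C>T"]), 1.0)
  empty <- mutation_spectrum(rec(pos = 1, ref = "C", alt = "T")[0, ])
  expect_null(empty$fractions)
})

test_that("spectrum is invariant under complementing every record", {
  set.seed(21)
  n <- 300
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1))
  cat1 <- rec(pos = seq_len(n) * 10, ref = ref, alt = alt)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cat2 <- cat1
  cat2$ref <- unname(comp[cat1$ref])
  cat2$alt <- unname(comp[cat1$alt])
  expect_equal(mutation_spectrum(cat1)$class_counts,
               mutation_spectrum(cat2)$class_counts)
})

test_that("generated catalogs hit the configured C>T weight", {
  b <- small_bundle()
  pool <- zebramel:::cds_position_pool(b$genome, b$gene_models)
  set.seed(31)
  big <- zebramel:::generate_sample_substitutions(
    "big", 6000, pool, b$config$spectrum_mixture
  )
  prof <- mutation_spectrum(big)
  expect_lt(abs(prof$fractions[["C>T"]] - 0.244), 0.02)
})

test_that("strand attribution and exact binomial bias test behave", {
  profile <- structure(list(counts = cbind(
    transcribed = c(10, 10, 0, 0, 0, 0),
    untranscribed = c(10, 0, 0, 0, 0, 0),
    unassigned = rep(0, 6)
  )), class = "spectrum_profile")
  rownames(profile$counts) <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- strand_bias_test(profile)
  expect_equal(out$p_value[1], 1.0)
  expect_equal(out$p_value[2], 2 * 0.5^10, tolerance = 1e-12)
  expect_true(is.na(out$p_value[3]))

  # type-I error of the exact test tracks its analytic rejection rate
  n_assigned <- 100
  crit <- vapply(0:n_assigned, function(k) {
    stats::binom.test(k, n_assigned, 0.5)$p.value <= 0.05
  }, logical(1))
  exact_rate <- sum(stats::dbinom(0:n_assigned, n_assigned, 0.5)[crit])
  set.seed(41)
  reps <- 1000
  rej <- replicate(reps, {
    k <- stats::rbinom(1, n_assigned, 0.5)
    stats::binom.test(k, n_assigned, 0.5)$p.value <= 0.05
  })
  se <- sqrt(exact_rate * (1 - exact_rate) / reps)
  expect_lt(abs(mean(rej) - exact_rate), 3 * se + 1e-9)
  expect_lt(exact_rate, 0.065)
})

test_that("strand assignment uses the gene model only", {
  fx <- tiny_annotation_fixture()
  pos <- 121L  # CDS of the + strand gene
  ref <- substr(fx$genome$chrT, pos, pos)  # G
  prof <- mutation_spectrum(rec(pos = pos, ref = "G", alt = "A"),
                            fx$models)
  # purine reference: the pyrimidine sits on the template strand of a +
  # strand gene, i.e. the transcribed strand
  expect_equal(prof$counts["C>T", "transcribed"], 1L)
  prof2 <- mutation_spectrum(rec(pos = 50, ref = "G", alt = "A"),
                             fx$models)
  expect_equal(prof2$counts["C>T", "unassigned"], 1L)
})

test_that("C:G-exclusivity fraction is exact", {
  expect_equal(cg_only_fraction(rec(pos = 1:2, ref = c("T", "T"),
                                    alt = c("C", "C"))), 0)
  half <- rbind(rec(pos = 1, ref = "C", alt = "T"),
                rec(pos = 2, ref = "T", alt = "C"))
  expect_equal(cg_only_fraction(half), 0.5)
  expect_true(is.na(cg_only_fraction(half[0, ])))
})

brute_force_clusters <- function(pos, min_size, max_gap) {
  # all maximal runs of successive gaps <= max_gap with length >= min_size
  pos <- sort(pos)
  out <- list()
  i <- 1
  while (i <= length(pos)) {
    j <- i
    while (j < length(pos) && pos[j + 1] - pos[j] <= max_gap) j <- j + 1
    if (j - i + 1 >= min_size) {
      out[[length(out) + 1]] <- c(start = pos[i], end = pos[j],
                                  size = j - i + 1)
    }
    i <- j + 1
  }
  out
}

test_that("cluster detection equals brute-force enumeration", {
  expect_equal(
    nrow(detect_clusters(rec(pos = (1:10) * 100000, ref = "C", alt = "T"))),
    0
  )
  set.seed(51)
  for (trial in 1:200) {
    n <- sample(1:12, 1)
    pos <- sort(sample.int(20000, n))
    min_size <- sample(2:5, 1)
    max_gap <- sample(c(100, 500, 2000), 1)
    cat1 <- rec(pos = pos, ref = "C", alt = "T")
    got <- detect_clusters(cat1, min_size = min_size, max_gap = max_gap)
    want <- brute_force_clusters(pos, min_size, max_gap)
    expect_equal(nrow(got), length(want), info = paste("trial", trial))
    if (length(want) > 0) {
      want_df <- as.data.frame(do.call(rbind, want))
      got <- got[order(got$start), ]
      want_df <- want_df[order(want_df$start), ]
      expect_equal(got$start, want_df$start)
      expect_equal(got$end, want_df$end)
      expect_equal(got$size, want_df$size)
    }
  }
})

test_that("cluster detection is monotone in the gap threshold and conserves counts", {
  set.seed(61)
  pos <- sort(sample.int(50000, 40))
  cat1 <- rec(pos = pos, ref = "C", alt = "T")
  for (gaps in list(c(200, 500), c(500, 2000), c(1000, 5000))) {
    small_g <- detect_clusters(cat1, min_size = 3, max_gap = gaps[1])
    big_g <- detect_clusters(cat1, min_size = 3, max_gap = gaps[2])
    # every cluster at the small gap lies inside one at the large gap,
    # which can only be at least as large
    if (nrow(small_g) > 0) {
      for (i in seq_len(nrow(small_g))) {
        container <- big_g[big_g$start <= small_g$start[i] &
                             big_g$end >= small_g$end[i], ]
        expect_equal(nrow(container), 1)
        expect_gte(container$size, small_g$size[i])
      }
    }
  }
  # clustered + unclustered = total
  cl <- detect_clusters(cat1, min_size = 3, max_gap = 1000)
  clustered <- sum(cl$size)
  in_cluster <- vapply(pos, function(p) {
    any(p >= cl$start & p <= cl$end)
  }, logical(1))
  expect_equal(clustered, sum(in_cluster))
  expect_equal(sum(in_cluster) + sum(!in_cluster), length(pos))
})

test_that("intermutation distances reset per chromosome", {
  cat1 <- rbind(
    rec(pos = c(100, 200, 500), ref = "C", alt = "T"),
    rec(chrom = "chr2", pos = 900, ref = "C", alt = "T")
  )
  d <- intermutation_distances(cat1)
  expect_equal(d$distance[d$chrom == "chrT"], c(NA, 100, 300))
  expect_equal(d$distance[d$chrom == "chr2"], NA_integer_)
  one <- intermutation_distances(rec(pos = 5, ref = "C", alt = "T"))
  expect_equal(one$distance, NA_integer_)
})
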