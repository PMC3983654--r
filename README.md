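# zebramel

Somatic mutation analysis of engineered zebrafish melanoma exomes.

## The problem

Melanomas driven by engineered *BRAF*^V600E^ or *NRAS*^Q61K^ transgenes in
zebrafish develop without UV exposure and carry remarkably few somatic
mutations — a median of about four coding substitutions per tumour. At that
burden, every analysis step that is routine in human cancer genomics
(somatic calling, spectrum analysis, driver-gene statistics, copy-number
recurrence) operates at the edge of its statistical power, and the analysis
has to be engineered around small counts. `zebramel` packages that whole
workflow for a 53-sample engineered-melanoma cohort design:

* **Synthetic cohort generator** — a seeded, fully parameterised stand-in
  for the study data: a desk-scale genome with toy gene models, a genotype
  sample sheet (BRAF/NRAS, p53, mitf, MITF-rescue, extra alleles), a
  negative-binomial burden model (burden falls with engineered driver
  count, rises with age, calibrated to a cohort median of 4), a
  C>T-dominated substitution spectrum (C>T weight 0.244), a 47-substitution
  hypermutant mutated exclusively at C:G pairs, a kataegis sample with two
  mutation microclusters (12 substitutions within 4,500 bp; 5 within 5 kb),
  a 175 kb amplicon implanted in 10 of the 25 MITF-rescue samples, 13
  repeat-flanked indels, and a truth manifest recording all of it.
* **Caller benchmarking harness** — simulated normal/tumour genome pairs
  over a germline SNP density grid (0–0.5 SNPs/base), 2,000 implanted
  somatic substitutions, error-free 75 bp paired reads, normal-contamination
  mixing (30/60/100% tumour content), a naive somatic caller as the system
  under test, and sensitivity/precision scoring.
* **Filtering & annotation** — the somatic SNV post-processing filter
  (normal VAF ≤ 3%, tumour VAF ≥ 10%, no germline variant within 5 bp),
  the indel filter (depth ≥ 15; small indels need ≥ 4 split-read plus ≥ 1
  mapper-supporting reads; large indels need non-repeat placement and
  both-strand support), and a minimal strand-aware consequence annotator.
* **Spectrum & kataegis** — 6-class pyrimidine-folded spectra with
  transcribed/untranscribed strand attribution, exact binomial strand-bias
  tests, the C:G-exclusivity metric, intermutation (rainfall) distances and
  a gap-based microcluster detector.
* **Selection (dN/dS)** — a mutation–selection model with 12 substitution
  rate parameters and two selection parameters,
  `mu[s,c] = r[s] * L[s,c] * omega[c]` under a Poisson likelihood, where
  `L` is the opportunity matrix counting coding sites per substitution type
  and consequence class; maximum-likelihood fitting with likelihood-ratio
  tests of neutrality (`omega = 1`, chi-squared, 1 df).
* **Copy-number recurrence** — ploidy-gated calling (amplification: CN ≥ 5
  at ploidy < 2.7, CN ≥ 8 at ploidy ≥ 2.7; homozygous deletion: CN = 0;
  segments < 10 Mb), per-gene recurrence, a length-preserving permutation
  test with add-one empirical p-values and Bonferroni adjustment, and
  subgroup chi-square association tests.
* **Gene significance & pathways** — a combined per-gene statistic
  multiplying binomial upper tails across four mutation modalities,
  `p_j = prod_i P(X >= x_ij | Binomial(n_i, q_i))` with background rates
  `q_i = (1/n_i) sum_k [1 - (1 - 1/N)^{m_k}]`, and threshold-swept
  hypergeometric gene-set enrichment.
* **Burden correlates** — Pearson correlations and Poisson/quasi-Poisson
  GLMs of burden against age and driver count.

## Worked example

```r
library(zebramel)

bundle <- generate_cohort(cohort_config(seed = 1))
bundle
#> synthetic cohort: 53 samples, 342 mutations, 150 segments, 628 genes

snv <- bundle$mutations[bundle$mutations$class == "SNV", ]
median(table(factor(snv$sample_id, levels = bundle$sample_sheet$sample_id)))
#> [1] 4        # cohort median coding substitution burden

z <- snv[snv$sample_id == "ZD0038a_like", ]
nrow(z); cg_only_fraction(z)
#> [1] 47      # the hypermutant archetype
#> [1] 1       # every substitution at a C:G pair

detect_clusters(bundle$mutations[bundle$mutations$sample_id == "ZD8a_like", ])
#> # A tibble: 2 x 8
#>   sample_id chrom  start    end  size  span majority_class vaf_spread
#> 1 ZD8a_like chr10 200248 203900    12  3652 C>T                0.0660
#> 2 ZD8a_like chr10 402830 404010     5  1180 C>T                0.0422

calls <- call_cna(bundle$segments, bundle$sample_sheet)
rp <- recurrence_profile(calls, bundle$gene_models,
                         sample_ids = bundle$sample_sheet$sample_id)
head(rp$recurrence, 3)
#>   gene_id      amplification homozygous_deletion
#> 1 asf1ba_like             10                   0
#> 2 prkacaa_like            10                   0
#> 3 samd1_like              10                   0
```

The two cluster sizes (12 within ≤ 4,500 bp, 5 within ≤ 5 kb), the
47-substitution C:G-only load, the burden median of 4 and the
10-of-53 amplicon recurrence are the cohort landmarks every downstream
module is tested against.

The `analysis/` directory holds numbered driver scripts that run the whole
workflow over the generated cohort and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R     # cohort bundle -> results/cohort/
Rscript analysis/02_caller_benchmark.R    # 5 x 3 benchmark grid
Rscript analysis/03_filter_annotate.R     # filters + consequence annotation
Rscript analysis/04_spectrum_clusters.R   # spectra, strand bias, kataegis
Rscript analysis/05_selection.R           # dN/dS selection model
Rscript analysis/06_cnv_recurrence.R      # CNA calls, permutation test
Rscript analysis/07_gene_significance_pathways.R
Rscript analysis/08_burden_correlates.R   # correlations and GLMs
```

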