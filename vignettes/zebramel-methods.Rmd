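---
title: "zebramel: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zebramel: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`zebramel` implements the complete computational analysis of a low-burden,
UV-independent melanoma exome study in transgenic zebrafish, driven by a
synthetic cohort generator so that every stage is testable without any
external data. This vignette explains the models, the tunable parameters,
the generator's calibration, and what passing tests do and do not
demonstrate about real data.

## The synthetic cohort and what it emulates

`generate_cohort(cohort_config(seed))` builds the entire study from one
seed. The generator's defaults are the study conditions, not free dials:

* **Genotypes.** 53 samples in fifteen genotype groups (one BRAF-only
  fish, BRAF;p53 combinations, an 8-sample mitf-vc7 subgroup, a 25-sample
  mitf-null + MITF-rescue subgroup, and 16 NRAS-driven fish per the study
  table). Driver counting assigns one event per engineered lesion —
  oncogene, any mutant p53 (het and hom both count once, which reproduces
  the published driver count of 4 for the rescue genotype and 2 for
  NRAS;p53^+/-^), non-wild-type mitf, MITF rescue, and each extra germline
  allele; co-expressed transcription-factor transgenes are not counted
  because their contribution to melanoma is unestablished.
* **Burden model.** Substitution counts are negative binomial with
  `log mu = b0 + b_d * drivers + b_a * age`, `b_d = -0.25` (inverse driver
  association), `b_a = 0.035` per month (positive age association),
  dispersion (NB size) 1.5. The counts family is a design choice — the
  study reports only correlations and a GLM — and the negative binomial is
  the standard overdispersed choice for mutation counts. The intercept is
  *calibrated* at generation time: it is iteratively adjusted until the
  realized cohort median (including the two fixed archetypes) equals the
  published median of 4 coding substitutions; ages are uniform on 6–18
  months. At a median burden of 4 the age effect is small relative to
  sampling noise, so any single 53-sample cohort may show a weak or even
  sign-flipped marginal age correlation; the driver effect is the dominant,
  reliably negative signal (tested over 200 replicate cohorts).
* **Spectrum.** Six pyrimidine-folded class weights with C>T at 0.244 (the
  published overall fraction) and the remainder spread over the other five
  classes in roughly the proportions seen in non-UV melanomas. Ordinary
  samples draw classes i.i.d. from this mixture; the archetypes override
  it, so the cohort-wide C>T fraction sits a few points above 0.244 —
  exactly as the real cohort's overall fraction includes its outlier
  samples.
* **Archetypes.** The BRAF-only fish becomes the hypermutant: 47
  substitutions, reference base C or G at every site (the C:G-exclusive
  signature). One BRAF;p53-het fish becomes the kataegis sample: a
  12-substitution cluster spanning ≤ 4,500 bp across two adjacent compact
  hox-like genes, a 5-substitution cluster within ≤ 5 kb in a second host
  gene, both with tightly matched VAFs (±0.05 around 0.45, matched by
  construction rather than binomially resampled, so the similar-VAF
  hallmark is exact) and a C>T majority, plus 13 dispersed background
  substitutions — 12/30 = 40% of the load in the main cluster.
* **Copy number.** A 175 kb amplicon (copy number 10, so it passes the
  amplification threshold at any ploidy) implanted in exactly 10 of the 25
  MITF-rescue samples on the chr3 analog, which carries the five analog
  genes of the amplified locus; background amplifications avoid the
  amplicon chromosome so the implanted recurrence is exact. Homozygous
  deletions arrive at a background rate putting ~30% of ordinary samples at
  ≥ 1 deletion (the published prevalence), with a threefold-enriched rate
  in the vc7 subgroup.
* **Indels.** 13 in total, all < 5 bp, 8 of them single-base, each placed
  immediately 3' of an implanted tandem repeat (the repeat-flanked pattern
  of replication-slippage indels); four belong to the hypermutant.
* **Genome scale.** 21 chromosomes × 1 Mb with ~30 genes each. This is a
  desk-scale stand-in: large enough that a 175 kb segment is a rare event
  against the randomisation space, small enough to regenerate in under a
  minute. Coding sequence is recoded stop-free and ATG-initiated so the
  annotator and the opportunity matrix are well defined.

**What the generator does not emulate:** subclonality and tumour purity in
the catalogs, sequencing error, mapping artefacts, fragile sites and other
non-uniform CNA background, realistic gene length/composition
distributions, and linkage between modalities. Passing tests on this cohort
demonstrate that the statistics recover implanted structure under their own
model assumptions — not that those assumptions hold in real tumours.

## Caller benchmarking

`simulate_genome_pair()` draws germline SNPs binomially at a configured
density (the study grid: 0, 0.001, 0.01, 0.1, 0.5 SNPs/base), then implants
exactly `n_somatic` (default 2,000) somatic substitutions disjoint from the
germline set. Reads are 75 bp error-free pairs whose names encode their
true origin; no aligner is run, because with a zero error rate alignment
adds no information at desk scale — this isolates the statistical detection
problem the benchmark is about. Somatic variants are carried
heterozygously: tumour reads are drawn half from the normal haplotype and
half from the somatic-bearing haplotype (the conservative caller test; the
design is silent on zygosity). Contamination mixing combines
`round(total*(1-f))` normal-origin and `round(total*f)` tumour-origin
reads. Reads are kept in random draw order so any prefix is a uniform
sample. The published 80× / 8M-read design is treated as a target coverage,
scaled to the simulated genome.

The naive caller computes an exact pileup at candidate sites — with zero
sequencing error, a read supports the alternate allele iff its source
haplotype carries the variant and the read covers the site, so interval
counting reproduces a full per-base pileup — and calls sites with tumour
alt support ≥ 3 (default) and normal VAF ≤ 0.05. The read-count
interpretation of the mixing table (reads vs pairs) is exposed through
`mix_spec(paired=)`.

## Filters and annotation

The substitution filter passes records with normal VAF ≤ 3% and tumour VAF
≥ 10% and no germline variant within 5 bp. The tumour-side clause is
implemented as a *minimum* tumour VAF: a maximum would discard exactly the
calls the filter exists to keep, so the stated "less than 10% of the
tumor" is read as a slip for "no less than"; the threshold is a parameter.
The indel filter needs depth ≥ 15 in both tissues; small indels (≤ 10 bp —
the small/large boundary is unstated upstream and all confirmed indels
were < 5 bp, so either regime covers them) need ≥ 4 split-read and ≥ 1
mapper-supporting reads, large ones non-repeat placement and both-strand
support.

The annotator is deliberately minimal: one transcript per gene, standard
genetic code, strand-aware codon extraction, splice sites as the canonical
±2 intronic window (unstated upstream; the canonical choice), 5'/3' UTR
assignment on the coding strand, and start-gain detection for 5' UTR
substitutions creating a new ATG. Deep-intronic positions are reported
`intergenic` (non-coding) rather than given their own class. The NS:S
ratio counts (missense + nonsense) / synonymous, which reproduces the
published 2.3 from the published counts ((168+16)/79); splice-site events
are excluded from both sides.

## Spectrum, strand bias and kataegis

Spectra use the 6-class pyrimidine-folded convention; the unfolded 12-type
representation is retained for the selection model, where strand matters.
Strand attribution compares the strand carrying the reference pyrimidine
with the gene's coding strand; intergenic sites are unassigned and excluded
from bias testing. The bias test is an exact two-sided binomial against an
even split — at the study's per-class counts an exact test is the only
defensible choice, and its discreteness makes it mildly conservative
(the type-I simulations compare against the analytic size, not nominal
alpha).

The cluster detector splits each sample-chromosome's sorted positions
wherever the intermutation gap exceeds `max_gap` (default 2,000 bp) and
reports maximal runs of ≥ `min_size` (default 5). The thresholds are
package choices, not published ones — the original clusters were found by
inspection — set so that both described microclusters are detected while a
median-burden sample cannot cluster by chance; both are parameters, and the
detector is validated against brute-force enumeration.

## The mutation–selection model

Counts of mutations by substitution type `s` (12 strand-specific types)
and consequence class `c` (synonymous/missense/nonsense) are modelled as
independent Poisson with mean `r_s * L[s,c] * omega_c`, `omega_syn = 1`.
`L` is the opportunity matrix: for every coding position and alternative
base, the consequence implied by the genetic code, so composition and
per-type rate differences cannot masquerade as selection. The Poisson
family is the package's construction (the upstream description names the
parameterisation but not the likelihood); it yields closed-form coordinate
updates — `r_s = sum_c n[s,c] / sum_c L[s,c] omega_c` and
`omega_c = sum_s n[s,c] / sum_s r_s L[s,c]` — iterated to a log-likelihood
tolerance of 1e-10 (so point estimates are reproducible to ~1e-5, the
resolution the tests assert). Neutrality is tested by likelihood ratio
against `omega_mis = 1` and `omega_non = 1` separately, chi-squared with
1 df. Types with zero opportunity are excluded with a warning. A CpG
context extension is deliberately out of scope: the cohort's spectra are
modelled without context dependence, and the printed per-sample p-values
depend on an unpublished mutation list, so they are not reproduction
targets. Splice and UTR mutations never enter the fit (CDS-only model).

## Copy-number recurrence

Amplification calling is ploidy-gated (CN ≥ 5 below ploidy 2.7, CN ≥ 8 at
or above; homozygous deletion is CN = 0; segments ≥ 10 Mb are ineligible).
The permutation test preserves each sample's segment count and lengths and
places each segment uniformly in a single concatenated target space —
placement is not restricted to the source chromosome, matching a
randomisation "across the target regions"; the genes are projected into
the same space, so per-gene recurrence under the null is recomputed by pure
interval arithmetic. The empirical p uses the add-one estimator
`(b+1)/(n_perm+1)`, never zero, so a reported "p = 0" becomes
`p <= 1/(n_perm+1)`. Bonferroni multiplies by the number of genes tested in
the run (the published n = 6,677 is dataset-specific). Desk runs use
10,000–20,000 permutations rather than the published 10^6; the add-one
floor times the Bonferroni multiplier then bounds the smallest attainable
adjusted p, which is why the driver scripts use 20,000 for the 628-gene
synthetic genome. Subgroup association is a Pearson chi-square on the
sample-level 2×2 table without continuity correction (a Yates flag is
provided); the published table cannot be reconstructed from printed counts,
so the printed subgroup p-value is a structural, not numerical, target.

## Combined gene significance and pathways

Each modality contributes a binomial upper tail for the number of samples
carrying the gene, with a background rate `q_i` estimated from per-sample
event counts `m_k` as `q_i = (1/n_i) sum_k [1-(1-1/N)^{m_k}]` — the chance
that a sample with `m_k` uniformly thrown events hits a given one of `N`
genes. `m_k` counts *events* (not mutated genes); the alternative reading
is configurable. `N` defaults to the number of genes in the supplied
models. The combined statistic is the product of the four tails; genes with
`p < 0.05` (strict) enter the pathway analysis. Enrichment per gene set and
per minimum-mutation threshold (1–10) is a one-sided hypergeometric tail —
the enrichment test is unnamed upstream; hypergeometric is the standard
choice, with a binomial mode behind a flag.

## Burden correlates

Pearson correlations with two-sided t-tests; count GLMs are Poisson with
log link, with an automatic quasi-Poisson refit when the Pearson dispersion
exceeds 2 (same point estimates, honest standard errors under
overdispersion). Driver count enters numerically. Samples without age are
excluded listwise.

## Numerical and scale choices

Coordinates are 1-based inclusive everywhere, matching the native
convention of the R/Bioconductor interval stack and the file formats
(VCF/GFF3/SEG); no internal 0-based layer exists to get out of sync.
Problem sizes are chosen for a single CPU: the default cohort genome is
21 Mb; benchmark unit tests run on 60–200 kb genomes at 40–60× with the
full 1 Mb / 80× grid in `analysis/02_caller_benchmark.R`; permutation runs
use 10^4–2×10^4 permutations; LRT and strand-bias calibrations use 1,000–
2,000 replicates. Test fixtures at toy scale exposed a real property worth
knowing: when background segments are large relative to the genome,
recurrence statistics are legitimately uninformative, so the
recurrence-oriented tests run at the full default scale.

## Known limitations

* The generator emulates marginal structure (burden, spectrum, recurrence),
  not joint structure; modality correlations within samples are whatever
  the independent components induce.
* The consequence annotator handles one transcript per gene and no
  multi-exon edge cases beyond the splice window; it is a toy stand-in for
  a full effect predictor.
* The naive caller is a harness component, not a competitive caller; its
  purpose is to make the benchmark's sensitivity/precision machinery
  testable end to end.
* The selection model's archetype catalog is generated without selection,
  so fitting it tests machinery, not inference power; power is demonstrated
  on counts simulated under strong selection.
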