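#!/usr/bin/env Rscript
# Generate the default synthetic 53-sample melanoma cohort and write the
# full bundle (genome, gene models, sample sheet, catalogs, segments, gene
# sets, truth manifest) under results/cohort/.
#
# Finding to expect: 53 samples in the configured genotype composition, a
# cohort median of 4 coding substitutions, one 47-substitution C:G-only
# hypermutant, one two-cluster kataegis sample, 13 indels, and a 175 kb
# amplicon implanted in 10 of the 25 MITF-rescue samples.

suppressPackageStartupMessages(library(zebramel))

bundle <- generate_cohort(cohort_config(seed = 1))
write_cohort(bundle, "results/cohort")

snv <- bundle$mutations[bundle$mutations$class == "SNV", ]
burden <- table(factor(snv$sample_id, levels = bundle$sample_sheet$sample_id))
cat("samples:", nrow(bundle$sample_sheet), "\n")
cat("substitutions:", nrow(snv), " indels:",
    sum(bundle$mutations$class != "SNV"), "\n")
cat("median coding substitution burden:", median(as.integer(burden)), "\n")
cat("amplicon carriers:",
    length(bundle$truth$amplicon$carriers), "of",
    sum(bundle$sample_sheet$mitf_rescue), "MITF-rescue samples\n")
cat("bundle written to results/cohort/\n")
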