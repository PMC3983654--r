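#!/usr/bin/env Rscript
# Annotate the cohort catalog against the toy gene models, apply the
# somatic SNV filter, and summarise the confirmed catalog (consequence
# composition and NS:S ratio).
#
# Run 01_simulate_cohort.R first (reads results/cohort/).

suppressPackageStartupMessages(library(zebramel))

models <- read_gene_models("results/cohort/genes.gff3")
genome <- Biostrings::readDNAStringSet("results/cohort/genome.fa")
catalog <- read_mutations("results/cohort/mutations.tsv")

ann <- annotate_consequence(catalog, models, genome)
flt <- somatic_snv_filter(ann[ann$class == "SNV", ])
cat("filter pass rate:", round(mean(flt$pass), 3), "\n")
print(table(flt$reason))

confirmed <- rbind(flt[flt$pass, names(ann)], ann[ann$class != "SNV", ])
write_mutations(confirmed, "results/confirmed_catalog.tsv")
cat("\nconsequences of confirmed substitutions:\n")
print(table(confirmed$consequence[confirmed$class == "SNV"]))
cat("NS:S ratio:", ns_s_ratio(confirmed[confirmed$class == "SNV", ]), "\n")
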