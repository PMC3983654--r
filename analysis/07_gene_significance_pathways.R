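#!/usr/bin/env Rscript
# Combined per-gene significance across the four mutation modalities
# (substitutions, indels, amplifications, homozygous deletions) and the
# threshold-swept gene-set enrichment over the cohort's gene sets.
#
# Run 01_simulate_cohort.R and 03_filter_annotate.R first.

suppressPackageStartupMessages(library(zebramel))

models <- read_gene_models("results/cohort/genes.gff3")
sheet <- read_sample_sheet("results/cohort/sample_sheet.tsv")
segments <- read_segments("results/cohort/segments.tsv")
catalog <- read_mutations("results/confirmed_catalog.tsv")
sets <- read_gmt("results/cohort/gene_sets.gmt")

calls <- call_cna(segments, sheet)
rp <- recurrence_profile(calls, models, sample_ids = sheet$sample_id)
genes <- models$genes$gene_id

hit_matrix <- function(m) {
  h <- matrix(FALSE, length(genes), nrow(sheet),
              dimnames = list(genes, sheet$sample_id))
  ok <- !is.na(m$gene_id)
  h[cbind(m$gene_id[ok], m$sample_id[ok])] <- TRUE
  h
}
snv <- catalog[catalog$class == "SNV", ]
ind <- catalog[catalog$class != "SNV", ]
hits <- list(
  substitutions = hit_matrix(snv),
  indels = hit_matrix(ind),
  amplifications = rp$amplification,
  homozygous_deletions = rp$homozygous_deletion
)
events <- list(
  substitutions = as.integer(table(factor(snv$sample_id, sheet$sample_id))),
  indels = as.integer(table(factor(ind$sample_id, sheet$sample_id))),
  amplifications = as.integer(table(factor(
    calls$sample_id[calls$call == "amplification"], sheet$sample_id))),
  homozygous_deletions = as.integer(table(factor(
    calls$sample_id[calls$call == "homozygous_deletion"], sheet$sample_id)))
)
sig <- gene_significance(hits, events)
cat("most significant genes (combined across modalities):\n")
print(head(as.data.frame(sig[, c("gene_id", "p_combined")]), 8))

selected <- select_significant_genes(sig)
cat("\nselected genes (combined p < 0.05):", length(selected), "\n")

mutation_counts <- setNames(
  rowSums(hits$substitutions) + rowSums(hits$indels) +
    rowSums(hits$amplifications) + rowSums(hits$homozygous_deletions),
  genes
)
enr <- pathway_enrichment(selected, mutation_counts, sets, genes,
                          thresholds = 1:10)
cat("\nenrichment at threshold 1 (top sets):\n")
at1 <- enr[enr$threshold == 1, ]
print(head(as.data.frame(at1[order(at1$p), ]), 6))

dir.create("results", showWarnings = FALSE)
write.table(sig, "results/gene_significance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enr, "results/pathway_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
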