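#!/usr/bin/env Rscript
# Step 5 -- analyses over the published result tables.
#
# The two printed DMR tables (21 preterm-associated regions, 67
# gestational-age-associated regions) ship with the package and are
# treated as inputs: width-convention checks, methylation-direction
# percentages, the cross-model overlap, unique nearest genes, and a
# gene-set overlap analysis of the two models' gene lists. When TSV
# exports of the nominal (p < 0.01) supplementary tables are present
# under inst/extdata they are checked against their printed totals too.

suppressMessages(library(medipdmr))
dir.create("results", showWarnings = FALSE)

ptb <- published_dmr_table("ptb")
ga <- published_dmr_table("ga")

cat(sprintf("preterm model: %d FDR DMRs; gestational age: %d\n",
            nrow(ptb), nrow(ga)))
stopifnot(all(ptb$width == interval_width(ptb)),
          all(ga$width == interval_width(ga)))
cat("printed widths reproduced as end - start for all",
    nrow(ptb) + nrow(ga), "locations\n")

cat(sprintf("hypo-methylated in preterm: %d/%d = %.0f%%\n",
            sum(ptb$log2FoldChange > 0), nrow(ptb),
            100 * mean(ptb$log2FoldChange > 0)))

shared <- table_intersection(ptb, ga)
cat(sprintf("regions in both models: %d (PTB-only: %d)\n",
            nrow(shared), nrow(ptb) - nrow(shared)))
write_results_table(shared, "results/shared_dmrs.tsv")

cat("annotation category percentages (preterm table):\n")
print(round(category_percentages(ptb), 1))

genes_ptb <- unique_nearest_genes(ptb)
genes_ga <- unique_nearest_genes(ga)
cat(sprintf("unique nearest genes: %d (ptb), %d (ga)\n",
            length(genes_ptb), length(genes_ga)))

# overlap of the two models' gene lists against their joint universe
ov <- overlap_stats(genes_ptb, genes_ga, union(genes_ptb, genes_ga))
cat(sprintf("gene-list overlap: %d observed vs %.1f expected (p = %.3g)\n",
            ov$observed, ov$expected, ov$pvalue))

# optional: supplementary nominal tables, if the user has exported them
p2 <- system.file("extdata", "ptb_nominal_table.tsv", package = "medipdmr")
p4 <- system.file("extdata", "ga_nominal_table.tsv", package = "medipdmr")
if (nzchar(p2) && nzchar(p4)) {
  a <- read_results_table(p2)
  b <- read_results_table(p4)
  cat(sprintf("nominal tables: %d and %d records, %d shared, %d/%d unique genes\n",
              nrow(a), nrow(b), nrow(table_intersection(a, b)),
              length(unique_nearest_genes(a)),
              length(unique_nearest_genes(table_intersection(a, b)))))
} else {
  cat("nominal supplementary tables not present; skipping their checks\n")
}
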