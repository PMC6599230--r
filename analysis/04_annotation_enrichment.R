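#!/usr/bin/env Rscript
# Step 4 -- window grid, feature flags and directional enrichment.
#
# The genome is tiled into 500-bp windows; each window is flagged for
# CpG islands, shores (0-2 kb) and shelves (2-4 kb), exons, introns and
# the promoter/enhancer chromatin states. Enrichment of each feature
# among the nominally significant (p < 0.01) preterm DMRs is the ratio
# of the DMR overlap fraction to the genome-wide flagged fraction,
# stratified by methylation direction.

suppressMessages(library(medipdmr))

chrom_lengths <- with(read_bed("results/sim/chromatin_states.bed"),
                      tapply(end, chrom, max))
islands <- read_bed("results/sim/cpg_islands.bed")
states <- read_bed("results/sim/chromatin_states.bed")
genes <- read_bed12("results/sim/genes.bed12")

ctx <- cpg_flanks(islands, chrom_lengths)
parts <- gene_parts(genes)
st <- state_features(states)
grid <- flag_windows(make_windows(chrom_lengths, 500),
                     list(islands = ctx$islands, shores = ctx$shores,
                          shelves = ctx$shelves, exons = parts$exons,
                          introns = parts$introns,
                          promoters = st$promoters,
                          enhancers = st$enhancers))
write.table(grid, "results/window_flags.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

res <- read_results_table("results/dmr_ptb.tsv")
nominal <- res[!is.na(res$pvalue) & res$pvalue < 0.01, ]
nominal$direction <- ifelse(nominal$log2FoldChange > 0, "hypo", "hyper")
cat(sprintf("nominal (p < 0.01) preterm DMRs: %d\n", nrow(nominal)))
cat(sprintf("annotation categories:\n"))
print(round(category_percentages(nominal), 1))

enr <- directional_enrichment(nominal, grid)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\ndirectional enrichment scores:\n")
print(enr[c("feature", "direction", "score", "n_dmrs_overlapping",
            "n_dmrs")], digits = 3)
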