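#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic study bundle.
#
# Emulates the deposited peak-count-matrix structure: 9 placental
# samples (6 preterm, gestational age 25-34 wk; 3 term, 37-41 wk), 3
# technical replicates each, NB-distributed counts over 2000 shared
# peak regions on a 20-Mb toy genome, with group effects (|log2FC| 1.5)
# planted in 5% of peaks, per-week GA slopes (|log2FC/wk| 0.08) in
# another 5%, and both in 2%. Everything downstream reads these files.

suppressMessages(library(medipdmr))

out <- "results/sim"
cfg <- sim_config(seed = 20260101)
bundle <- simulate_bundle(cfg, dir = out)

cat(sprintf("wrote synthetic bundle to %s\n", out))
cat(sprintf("  %d true peaks on %d chromosomes\n",
            nrow(bundle$peaks), length(cfg$chrom_lengths)))
cat(sprintf("  cohort: %d preterm / %d term, %d replicates each\n",
            sum(bundle$samples$group == "preterm"),
            sum(bundle$samples$group == "term"), cfg$n_replicates))
print(table(planted_effect = bundle$truth$class))
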