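#!/usr/bin/env Rscript
# Step 2 -- consensus peaks and the replicate-summed count matrix.
#
# Per individual, a peak survives only if present in all 3 technical
# replicate call sets; individual consensus sets are then merged into a
# cohort master set (support >= 2 individuals) and replicate counts are
# summed per individual over each master peak.

suppressMessages(library(medipdmr))

sim <- "results/sim"
samples <- read.csv(file.path(sim, "samples.csv"))
counts <- read.delim(file.path(sim, "replicate_counts.tsv"),
                     check.names = FALSE)
rep_files <- list.files(sim, pattern = "^peaks_.*\\.bed$",
                        full.names = TRUE)
rep_peaks <- lapply(rep_files, read_bed)
names(rep_peaks) <- sub("^peaks_(.*)\\.bed$", "\\1", basename(rep_files))

cons <- build_count_matrix(rep_peaks, counts, samples, min_overlap = 2)

write_bed(cons$master, "results/master_peaks.bed")
write.table(data.frame(cons$cm$peaks, cons$cm$counts,
                       check.names = FALSE),
            "results/count_matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n_ind <- vapply(cons$individual, nrow, integer(1))
cat(sprintf("individual consensus sizes: %d-%d peaks (of %d called)\n",
            min(n_ind), max(n_ind), nrow(counts)))
cat(sprintf("cohort master set: %d peaks\n", nrow(cons$master)))
cat(sprintf("count matrix: %d x %d, total reads %.0f\n",
            nrow(cons$cm$counts), ncol(cons$cm$counts),
            sum(cons$cm$counts)))
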