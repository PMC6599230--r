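# Independent brute-force oracles used across the suite. These are kept
# deliberately literal (loops, per-base labels, enumeration) so they share
# no code with the package implementations they check.

# literal Benjamini-Hochberg step-up: sort, adj(k) = min_{j>=k} n*p(j)/j
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (k in seq_len(n)) {
    m <- Inf
    for (j in k:n) m <- min(m, n * ps[j] / j)
    adj[k] <- min(1, m)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# quadratic interval overlap (half-open, same chrom)
oracle_overlap <- function(a_chrom, a_start, a_end, b_chrom, b_start, b_end) {
  a_chrom == b_chrom && a_start < b_end && b_start < a_end
}

# replicate consensus by definition: merged union intervals kept iff they
# overlap >= 1 interval from every replicate
oracle_replicate_consensus <- function(replicates) {
  merged <- merge_intervals(do.call(rbind, replicates))
  keep <- logical(nrow(merged))
  for (i in seq_len(nrow(merged))) {
    keep[i] <- all(vapply(replicates, function(r) {
      any(vapply(seq_len(nrow(r)), function(j)
        oracle_overlap(merged$chrom[i], merged$start[i], merged$end[i],
                       r$chrom[j], r$start[j], r$end[j]), logical(1)))
    }, logical(1)))
  }
  merged[keep, , drop = FALSE]
}

# enrichment score by double loop over DMRs and flagged windows
oracle_enrichment <- function(dmrs, grid, feature) {
  flagged <- grid[grid[[feature]], , drop = FALSE]
  n_over <- 0
  for (i in seq_len(nrow(dmrs))) {
    hit <- FALSE
    for (j in seq_len(nrow(flagged)))
      if (oracle_overlap(dmrs$chrom[i], dmrs$start[i], dmrs$end[i],
                         flagged$chrom[j], flagged$start[j],
                         flagged$end[j])) hit <- TRUE
    n_over <- n_over + hit
  }
  (n_over / nrow(dmrs)) / (nrow(flagged) / nrow(grid))
}

# upper-tail hypergeometric by exhaustive enumeration of all query draws
oracle_hyper_tail <- function(n_universe, target_idx, n_query, observed) {
  draws <- utils::combn(n_universe, n_query)
  hits <- colSums(matrix(draws %in% target_idx, nrow = n_query))
  mean(hits >= observed)
}

# per-base CpG-context labels with island > shore > shelf precedence
oracle_base_labels <- function(islands, chrom_len, shore_bp = 2000,
                               shelf_bp = 4000) {
  lab <- rep("none", chrom_len)
  near <- function(bp) {
    hit <- rep(FALSE, chrom_len)
    for (i in seq_len(nrow(islands))) {
      lo <- max(islands$start[i] - bp, 0)
      hi <- min(islands$end[i] + bp, chrom_len)
      if (hi > lo) hit[(lo + 1):hi] <- TRUE
    }
    hit
  }
  lab[near(shelf_bp)] <- "shelf"
  lab[near(shore_bp)] <- "shore"
  for (i in seq_len(nrow(islands)))
    lab[(islands$start[i] + 1):islands$end[i]] <- "island"
  lab
}

# coverage vector of an interval set on one chromosome
coverage_vector <- function(df, chrom_len) {
  v <- rep(FALSE, chrom_len)
  for (i in seq_len(nrow(df)))
    if (df$end[i] > df$start[i])
      v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

random_intervals <- function(n, chrom = "c1", max_pos = 1000,
                             max_width = 50) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = chrom, start = start,
             end = start + sample.int(max_width, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# match result rows back to true peak rows by exact coordinates
peak_key <- function(df) paste(df$chrom, df$start, df$end)
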