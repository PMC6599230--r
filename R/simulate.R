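#' Simulation configuration
#'
#' Parameters of the synthetic MeDIP-seq bundle. Defaults emulate the
#' study cohort (6 preterm individuals with gestational age 25-34 weeks,
#' 3 term with 37-41 weeks, 3 technical replicates each) and a
#' peak-count matrix of negative-binomial counts over shared peak
#' regions with planted group effects and per-week gestational-age
#' slopes.
#'
#' @param seed RNG seed; every draw in the generator flows through it.
#' @param n_preterm,n_term,n_replicates cohort shape.
#' @param n_peaks number of true peak regions.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param frac_ptb_effect,frac_ga_effect,frac_both fractions of peaks
#'   carrying a preterm-birth effect only, a gestational-age effect only,
#'   or both (must sum to at most 1).
#' @param lfc_ptb planted |log2 fold change| of the preterm effect
#'   (sign drawn per peak, so both hyper- and hypo-methylation occur).
#' @param slope_ga planted |per-week log2 slope| of the GA effect.
#' @param dispersion negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param base_mean_range range of expected baseline counts.
#' @param replicate_dropout probability that a true peak is missing from
#'   one replicate's peak call set.
#' @param window_bp,shore_bp,shelf_bp annotation geometry defaults
#'   (500-bp windows; CpG shores 2 kb and shelves 4 kb from islands).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_preterm = 6L, n_term = 3L, n_replicates = 3L,
                       n_peaks = 2000L,
                       chrom_lengths = c(chrS1 = 12e6, chrS2 = 8e6),
                       frac_ptb_effect = 0.05, frac_ga_effect = 0.05,
                       frac_both = 0.02,
                       lfc_ptb = 1.5, slope_ga = 0.08,
                       dispersion = 0.1,
                       base_mean_range = c(100, 2000),
                       replicate_dropout = 0.05,
                       window_bp = 500L, shore_bp = 2000L,
                       shelf_bp = 4000L) {
  chrom_lengths <- unlist(chrom_lengths)   # tolerate YAML-style lists
  base_mean_range <- unlist(base_mean_range)
  cfg <- list(seed = as.integer(seed), n_preterm = as.integer(n_preterm),
              n_term = as.integer(n_term),
              n_replicates = as.integer(n_replicates),
              n_peaks = as.integer(n_peaks),
              chrom_lengths = chrom_lengths,
              frac_ptb_effect = frac_ptb_effect,
              frac_ga_effect = frac_ga_effect, frac_both = frac_both,
              lfc_ptb = lfc_ptb, slope_ga = slope_ga,
              dispersion = dispersion,
              base_mean_range = base_mean_range,
              replicate_dropout = replicate_dropout,
              window_bp = as.integer(window_bp),
              shore_bp = as.integer(shore_bp),
              shelf_bp = as.integer(shelf_bp))
  with(cfg, {
    stopifnot(n_preterm >= 0, n_term >= 0, n_replicates >= 1, n_peaks >= 1,
              length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
              all(chrom_lengths > 0),
              frac_ptb_effect >= 0, frac_ga_effect >= 0, frac_both >= 0,
              frac_ptb_effect + frac_ga_effect + frac_both <= 1,
              dispersion > 0, length(base_mean_range) == 2,
              base_mean_range[1] > 0, diff(base_mean_range) >= 0,
              replicate_dropout >= 0, replicate_dropout <= 1,
              window_bp > 0, shore_bp > 0, shelf_bp > shore_bp)
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a toy genome annotation bundle
#'
#' Generates, deterministically for a given seed, the annotation tracks
#' the real pipeline downloads for hg19: a BED12-style gene model with
#' strand, coding span and exon blocks; disjoint CpG islands; and a
#' chromatin-state segmentation whose labels include promoter ("Tss")
#' and enhancer ("Enh") states.
#'
#' @param cfg a [sim_config()].
#' @return List with data frames `genes` (see [read_bed12()] for the
#'   shape), `islands` and `states` (intervals with a `name` state label).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$chrom_lengths < 60000))
    stop("chromosome too short to place any gene (need >= 60 kb)")
  withr::with_seed(cfg$seed, {
    genes <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
      L <- cfg$chrom_lengths[[ch]]
      n <- max(1L, floor(L / 1e5))
      slot <- L / n
      tx_len <- pmin(round(stats::runif(n, 5e3, 0.6 * slot)), slot - 4e3)
      start <- round((seq_len(n) - 1) * slot + stats::runif(n, 1e3, 2e3))
      data.frame(chrom = ch, start = start, end = start + tx_len,
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    genes$symbol <- sprintf("GENE%04d", seq_len(nrow(genes)))
    # exon blocks: first/last exons at the transcript ends
    n_ex <- sample(2:8, nrow(genes), replace = TRUE)
    blocks <- lapply(seq_len(nrow(genes)), function(i) {
      k <- n_ex[i]
      len <- genes$end[i] - genes$start[i]
      inner <- sort(sample(seq(50, len - 50), 2 * (k - 1)))
      bounds <- c(0, inner, len)
      es <- genes$start[i] + bounds[seq(1, 2 * k, by = 2)]
      ee <- genes$start[i] + bounds[seq(2, 2 * k, by = 2)]
      list(starts = es, ends = ee)
    })
    genes$exon_starts <- lapply(blocks, `[[`, "starts")
    genes$exon_ends <- lapply(blocks, `[[`, "ends")
    # coding span strictly inside the outer exons leaves 5'/3' UTRs
    genes$thick_start <- genes$start +
      round(0.5 * (vapply(blocks, function(b) b$ends[1], 0) - genes$start))
    genes$thick_end <- genes$end -
      round(0.5 * (genes$end - vapply(blocks, function(b)
        b$starts[length(b$starts)], 0)))
    islands <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
      L <- cfg$chrom_lengths[[ch]]
      n <- max(1L, floor(L / 5e4))
      slot <- L / n
      w <- round(stats::runif(n, 300, min(2000, slot / 4)))
      start <- round((seq_len(n) - 1) * slot +
                       stats::runif(n, 0, slot - w - 1))
      data.frame(chrom = ch, start = start, end = start + w,
                 stringsAsFactors = FALSE)
    }))
    states <- do.call(rbind, lapply(names(cfg$chrom_lengths), function(ch) {
      L <- cfg$chrom_lengths[[ch]]
      cuts <- unique(sort(c(0, round(stats::runif(floor(L / 2e4),
                                                  0, L)), L)))
      data.frame(chrom = ch, start = cuts[-length(cuts)], end = cuts[-1],
                 name = sample(c("TssA", "Enh", "Quies", "Tx"),
                               length(cuts) - 1, replace = TRUE,
                               prob = c(0.15, 0.2, 0.45, 0.2)),
                 stringsAsFactors = FALSE)
    }))
    list(genes = genes, islands = validate_intervals(islands),
         states = validate_intervals(states))
  })
}

#' Simulate the study cohort
#'
#' Draws sample metadata matching the cohort structure: preterm
#' gestational ages uniform in 25-34 weeks, term in 37-41 weeks; birth
#' weight grows with gestational age around the reported group means
#' (about 1540 g at 30 weeks, 3030 g at 39 weeks).
#'
#' @param cfg a [sim_config()].
#' @return Data frame with `sample_id`, `group` ("preterm"/"term"),
#'   `gestational_age` (weeks) and `birth_weight` (g).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_preterm + cfg$n_term
    group <- rep(c("preterm", "term"), c(cfg$n_preterm, cfg$n_term))
    ga <- ifelse(group == "preterm",
                 stats::runif(n, 25, 34), stats::runif(n, 37, 41))
    bw <- round(1540 + (ga - 30) * 165 + stats::rnorm(n, 0, 150))
    data.frame(sample_id = sprintf("S%d", seq_len(n)), group = group,
               gestational_age = round(ga, 1), birth_weight = bw,
               stringsAsFactors = FALSE)
  })
}

#' Simulate replicate peak calls and the peak-count matrix
#'
#' True peak regions are placed disjointly across the genome. For peak i
#' and individual j the summed count over replicates is drawn once from
#' a negative binomial with mean
#' `sf_j * 2^(b0_i + lfc_i * I[preterm_j] + slope_i * (GA_j - 33))`
#' and dispersion `alpha`, then split multinomially into the technical
#' replicates, so the replicate-summed matrix is exactly NB-distributed
#' (the model the differential test assumes). Each replicate's peak call
#' set omits each true peak independently with probability
#' `replicate_dropout`. Size factors `sf_j` are drawn log-uniform in
#' [0.5, 2] to exercise normalization.
#'
#' @param cfg a [sim_config()].
#' @param genome bundle from [simulate_genome()] (used for chromosome
#'   bounds).
#' @param samples cohort data frame from [simulate_cohort()] (or any
#'   frame with `sample_id`, `group`, `gestational_age`).
#' @return List: `peaks` (true peak intervals with `peak_id`),
#'   `rep_peaks` (named list of per-replicate peak data frames,
#'   `"<sample>_rep<k>"`), `counts` (data frame: peak coordinates plus
#'   one integer column per sample/replicate), `totals` (matrix of the
#'   drawn per-sample totals), `truth` (per-peak truth table),
#'   `size_factors`, and `samples`.
#' @export
simulate_counts <- function(cfg, genome, samples) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot(all(c("sample_id", "group", "gestational_age") %in%
                  names(samples)))
  withr::with_seed(cfg$seed + 2L, {
    # disjoint placement: one peak per equal-width slot
    tot <- sum(cfg$chrom_lengths)
    n_per <- pmax(1L, round(cfg$n_peaks * cfg$chrom_lengths / tot))
    # adjust rounding so the total is exact
    n_per[1] <- n_per[1] + cfg$n_peaks - sum(n_per)
    peaks <- do.call(rbind, Map(function(ch, L, n) {
      slot <- L / n
      w <- round(stats::runif(n, 800, pmin(3000, slot - 2)))
      start <- round((seq_len(n) - 1) * slot +
                       stats::runif(n, 0, slot - w - 1))
      data.frame(chrom = ch, start = start, end = start + w,
                 stringsAsFactors = FALSE)
    }, names(cfg$chrom_lengths), cfg$chrom_lengths, n_per))
    peaks <- sort_intervals(validate_intervals(peaks))
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))

    n <- nrow(peaks)
    cls <- rep("null", n)
    n_ptb <- round(cfg$frac_ptb_effect * n)
    n_ga <- round(cfg$frac_ga_effect * n)
    n_both <- round(cfg$frac_both * n)
    idx <- sample.int(n, n_ptb + n_ga + n_both)
    cls[idx[seq_len(n_ptb)]] <- "ptb"
    cls[idx[n_ptb + seq_len(n_ga)]] <- "ga"
    if (n_both) cls[idx[n_ptb + n_ga + seq_len(n_both)]] <- "both"

    b0 <- stats::runif(n, log2(cfg$base_mean_range[1]),
                       log2(cfg$base_mean_range[2]))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    lfc <- ifelse(cls %in% c("ptb", "both"), sgn * cfg$lfc_ptb, 0)
    sgn2 <- sample(c(-1, 1), n, replace = TRUE)
    slope <- ifelse(cls %in% c("ga", "both"), sgn2 * cfg$slope_ga, 0)
    truth <- data.frame(peak_id = peaks$peak_id, class = cls,
                        base_log2_mean = b0, lfc_ptb = lfc,
                        slope_ga = slope, stringsAsFactors = FALSE)

    m <- nrow(samples)
    sf <- 2^stats::runif(m, log2(0.5), log2(2))
    names(sf) <- samples$sample_id
    is_pre <- as.numeric(samples$group == "preterm")
    # GA effect centered at 33 wk so b0 stays the baseline scale
    log2mu <- outer(b0, rep(1, m)) + outer(lfc, is_pre) +
      outer(slope, samples$gestational_age - 33)
    mu <- sweep(2^log2mu, 2, sf, `*`)
    totals <- matrix(stats::rnbinom(n * m, mu = mu,
                                    size = 1 / cfg$dispersion),
                     nrow = n, dimnames = list(peaks$peak_id,
                                               samples$sample_id))

    reps <- seq_len(cfg$n_replicates)
    counts <- peaks
    for (j in seq_len(m)) {
      split <- vapply(totals[, j], function(tt)
        as.integer(stats::rmultinom(1, tt, rep(1, cfg$n_replicates))),
        integer(cfg$n_replicates))
      for (r in reps)
        counts[[sprintf("%s_rep%d", samples$sample_id[j], r)]] <- split[r, ]
    }

    rep_peaks <- list()
    for (j in seq_len(m)) for (r in reps) {
      keep <- stats::runif(n) >= cfg$replicate_dropout
      rep_peaks[[sprintf("%s_rep%d", samples$sample_id[j], r)]] <-
        peaks[keep, c("chrom", "start", "end", "peak_id")]
    }

    list(peaks = peaks, rep_peaks = rep_peaks, counts = counts,
         totals = totals, truth = truth, size_factors = sf,
         samples = samples)
  })
}

#' Generate and optionally write a complete synthetic bundle
#'
#' Convenience wrapper running [simulate_genome()], [simulate_cohort()]
#' and [simulate_counts()]; when `dir` is given, all tracks are written
#' as plain-text files (BED12 genes, BED islands/states/peaks, counts
#' TSV, sample CSV, truth TSV) together with a manifest listing every
#' output and the seed.
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory.
#' @return The bundle list (invisibly when writing): `genome`, `samples`
#'   and the [simulate_counts()] components.
#' @export
simulate_bundle <- function(cfg, dir = NULL) {
  genome <- simulate_genome(cfg)
  samples <- simulate_cohort(cfg)
  sim <- simulate_counts(cfg, genome, samples)
  bundle <- c(list(genome = genome), sim)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(genes = "genes.bed12", islands = "cpg_islands.bed",
               states = "chromatin_states.bed", peaks = "true_peaks.bed",
               counts = "replicate_counts.tsv", samples = "samples.csv",
               truth = "truth.tsv")
    write_bed12(genome$genes, file.path(dir, paths["genes"]))
    write_bed(genome$islands, file.path(dir, paths["islands"]))
    write_bed(genome$states, file.path(dir, paths["states"]))
    write_bed(sim$peaks, file.path(dir, paths["peaks"]))
    utils::write.table(sim$counts, file.path(dir, paths["counts"]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(sim$samples, file.path(dir, paths["samples"]),
                     row.names = FALSE)
    utils::write.table(sim$truth, file.path(dir, paths["truth"]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(sim$rep_peaks))
      write_bed(sim$rep_peaks[[nm]],
                file.path(dir, sprintf("peaks_%s.bed", nm)))
    manifest <- c(sprintf("seed\t%d", cfg$seed),
                  sprintf("%s\t%s", names(paths), paths),
                  sprintf("rep_peaks_%s\tpeaks_%s.bed",
                          names(sim$rep_peaks), names(sim$rep_peaks)))
    writeLines(manifest, file.path(dir, "MANIFEST.tsv"))
    return(invisible(bundle))
  }
  bundle
}
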