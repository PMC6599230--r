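#' CpG island shores and shelves
#'
#' Shores are the 2 kb flanks on each side of each island and shelves
#' the next 2 kb (2-4 kb from the island edge), with island > shore >
#' shelf precedence where flanks of neighbouring islands meet, clipped
#' at chromosome bounds. The three sets are pairwise disjoint.
#'
#' @param islands disjoint island interval data frame.
#' @param chrom_lengths named chromosome-length vector covering every
#'   island chromosome.
#' @param shore_bp,shelf_bp flank extents (defaults 2 kb / 4 kb).
#' @return List of interval data frames: `islands` (merged), `shores`,
#'   `shelves`.
#' @export
cpg_flanks <- function(islands, chrom_lengths, shore_bp = 2000L,
                       shelf_bp = 4000L) {
  islands <- merge_intervals(islands)
  if (!all(islands$chrom %in% names(chrom_lengths)))
    stop("island on chromosome without a length")
  if (any(islands$end > chrom_lengths[islands$chrom]))
    stop("island outside chromosome bounds")
  expand <- function(df, by) {
    out <- df
    out$start <- pmax(df$start - by, 0)
    out$end <- pmin(df$end + by, chrom_lengths[df$chrom])
    merge_intervals(out)
  }
  gr_set <- function(a, b) {   # a \ b in 0-based half-open space
    d <- GenomicRanges::setdiff(as_granges(a), as_granges(b))
    sort_intervals(from_granges(d))
  }
  shore_zone <- expand(islands, shore_bp)
  shelf_zone <- expand(islands, shelf_bp)
  shores <- gr_set(shore_zone, islands)
  shelves <- gr_set(gr_set(shelf_zone, shore_zone), islands)
  list(islands = islands, shores = shores, shelves = shelves)
}

#' Tile chromosomes into fixed-width windows
#'
#' Consecutive half-open tiles `[0,size)`, `[size,2*size)`, ...; the
#' final partial tile is kept.
#'
#' @param chrom_lengths named chromosome-length vector.
#' @param size window width in bp (default 500).
#' @return Interval data frame of windows in chromosome order.
#' @export
make_windows <- function(chrom_lengths, size = 500L) {
  stopifnot(size > 0, length(chrom_lengths) >= 1)
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + size, L),
               stringsAsFactors = FALSE)
  }))
}

#' Flag windows by genomic-feature overlap
#'
#' A window is flagged for a feature iff it overlaps at least one of the
#' feature's intervals by >= 1 bp.
#'
#' @param windows window data frame from [make_windows()].
#' @param features named list of interval data frames.
#' @return `windows` with one logical column per feature.
#' @export
flag_windows <- function(windows, features) {
  stopifnot(length(names(features)) == length(features))
  for (nm in names(features))
    windows[[nm]] <- overlaps_any(windows, features[[nm]])
  windows
}

#' Map chromatin-state labels to promoter/enhancer features
#'
#' States whose label matches `promoter_pattern` (default: "Tss" or
#' "promoter") become the `promoters` feature; matches of
#' `enhancer_pattern` ("Enh"/"enhancer") become `enhancers`.
#'
#' @param states interval data frame with a `name` state-label column.
#' @param promoter_pattern,enhancer_pattern case-insensitive regexes.
#' @return List of two interval data frames: `promoters`, `enhancers`.
#' @export
state_features <- function(states,
                           promoter_pattern = "Tss|promoter",
                           enhancer_pattern = "Enh|enhancer") {
  list(promoters = states[grepl(promoter_pattern, states$name,
                                ignore.case = TRUE), , drop = FALSE],
       enhancers = states[grepl(enhancer_pattern, states$name,
                                ignore.case = TRUE), , drop = FALSE])
}

# strand-aware TSS position (0-based coordinate of the first
# transcribed base)
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

# strand-aware upstream distance from the TSS to a point (positive
# when the point lies upstream of the gene)
upstream_dist <- function(point, tss, strand) {
  ifelse(strand == "+", tss - point, point - tss)
}

#' Genic sub-intervals of a BED12 gene model
#'
#' Derives exon, intron (with strand-aware rank) and 5'/3' UTR interval
#' sets from a gene model; UTRs are the exonic sequence outside the
#' coding (thick) span.
#'
#' @param genes gene model data frame from [read_bed12()].
#' @return List of interval data frames: `exons`, `introns` (with a
#'   `rank` column, 1 = nearest the TSS), `utr5`, `utr3`.
#' @export
gene_parts <- function(genes) {
  rows <- function(build) {
    out <- do.call(rbind, lapply(seq_len(nrow(genes)), build))
    if (is.null(out))
      out <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE)
    out[out$start < out$end, , drop = FALSE]
  }
  exons <- rows(function(i)
    data.frame(chrom = genes$chrom[i], start = genes$exon_starts[[i]],
               end = genes$exon_ends[[i]], stringsAsFactors = FALSE))
  introns_all <- lapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) < 2) return(NULL)
    st <- ee[-length(ee)]; en <- es[-1]
    rank <- if (genes$strand[i] == "+") seq_along(st) else rev(seq_along(st))
    data.frame(chrom = genes$chrom[i], start = st, end = en, rank = rank,
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, introns_all)
  if (is.null(introns))
    introns <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), rank = integer())
  # UTRs: exonic sequence outside the coding (thick) span
  utr5 <- rows(function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (genes$strand[i] == "+") {
      data.frame(chrom = genes$chrom[i], start = es,
                 end = pmin(ee, genes$thick_start[i]))
    } else {
      data.frame(chrom = genes$chrom[i],
                 start = pmax(es, genes$thick_end[i]), end = ee)
    }
  })
  utr3 <- rows(function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (genes$strand[i] == "+") {
      data.frame(chrom = genes$chrom[i],
                 start = pmax(es, genes$thick_end[i]), end = ee)
    } else {
      data.frame(chrom = genes$chrom[i], start = es,
                 end = pmin(ee, genes$thick_start[i]))
    }
  })
  list(exons = exons, introns = introns, utr5 = utr5, utr3 = utr3)
}

point_in <- function(chrom, pos, df) {
  if (nrow(df) == 0) return(rep(FALSE, length(pos)))
  pts <- data.frame(chrom = chrom, start = pos, end = pos + 1)
  overlaps_any(pts, df)
}

#' Classify DMRs into genomic categories
#'
#' Classification is by the DMR midpoint with fixed precedence:
#' `Promoter (<=1 kb)` > `Promoter (1-2 kb)` > `Promoter (2-3 kb)` >
#' `5' UTR` > `3' UTR` > `Exon` > `1st Intron` > `Intron` >
#' `Downstream (<=3 kb)` > `Distal Intergenic`. Promoter bins measure
#' the distance upstream of the strand-aware TSS; downstream is within
#' 3 kb past the strand-aware transcript end.
#'
#' @param dmrs interval data frame.
#' @param genes gene model from [read_bed12()] (or
#'   `simulate_genome()$genes`).
#' @return Character vector of category strings.
#' @export
classify_dmr <- function(dmrs, genes) {
  if (nrow(dmrs) == 0) return(character(0))
  parts <- gene_parts(genes)
  tss <- gene_tss(genes)
  # 0-based position of the last transcribed base
  tes <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  pts <- data.frame(chrom = dmrs$chrom, start = mid, end = mid + 1)

  # minimum strand-aware upstream (promoter) and downstream distance to
  # any same-chromosome gene, per midpoint
  min_up <- rep(Inf, nrow(dmrs))
  min_down <- rep(Inf, nrow(dmrs))
  for (ch in unique(dmrs$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(dmrs$chrom == ch)
    if (!length(gi) || !length(pi)) next
    sgn <- ifelse(genes$strand[gi] == "+", 1, -1)
    # rows = midpoints, cols = genes: tss_g - m, sign-flipped on minus
    delta <- outer(mid[pi], tss[gi], function(m, t) t - m)
    up <- sweep(delta, 2, sgn, `*`)
    up[up < 0] <- Inf
    min_up[pi] <- apply(up, 1, min)
    down <- sweep(outer(mid[pi], tes[gi], function(m, t) t - m),
                  2, -sgn, `*`)
    down[down < 1] <- Inf
    min_down[pi] <- apply(down, 1, min)
  }

  intr <- parts$introns
  in_intron1 <- overlaps_any(pts, intr[intr$rank == 1, , drop = FALSE])
  in_intronO <- overlaps_any(pts, intr[intr$rank != 1, , drop = FALSE])
  in_utr5 <- overlaps_any(pts, parts$utr5)
  in_utr3 <- overlaps_any(pts, parts$utr3)
  in_exon <- overlaps_any(pts, parts$exons)

  out <- rep("Distal Intergenic", nrow(dmrs))
  out[min_down <= 3000] <- "Downstream (<=3 kb)"
  out[in_intronO] <- "Intron"
  out[in_intron1] <- "1st Intron"
  out[in_exon] <- "Exon"
  out[in_utr3] <- "3' UTR"
  out[in_utr5] <- "5' UTR"
  out[min_up <= 3000] <- "Promoter (2-3 kb)"
  out[min_up <= 2000] <- "Promoter (1-2 kb)"
  out[min_up <= 1000] <- "Promoter (<=1 kb)"
  out
}

#' Nearest gene by TSS distance
#'
#' For each DMR midpoint, the same-chromosome gene with the closest TSS;
#' the distance is 0 when the midpoint falls inside the transcript.
#' Ties go to the lexicographically smaller symbol; chromosomes without
#' genes yield `NA`.
#'
#' @param dmrs interval data frame.
#' @param genes gene model data frame.
#' @return Data frame with `symbol` and `distance` (signed; positive
#'   downstream of the TSS in the gene's orientation).
#' @export
nearest_gene <- function(dmrs, genes) {
  if (nrow(genes) == 0) stop("empty gene model")
  tss <- gene_tss(genes)
  mid <- floor((dmrs$start + dmrs$end) / 2)
  out <- data.frame(symbol = rep(NA_character_, nrow(dmrs)),
                    distance = rep(NA_real_, nrow(dmrs)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dmrs))) {
    on_ch <- which(genes$chrom == dmrs$chrom[i])
    if (!length(on_ch)) next
    m <- mid[i]
    inside <- m >= genes$start[on_ch] & m < genes$end[on_ch]
    d <- ifelse(inside, 0, abs(tss[on_ch] - m))
    best <- on_ch[order(d, genes$symbol[on_ch])][1]
    out$symbol[i] <- genes$symbol[best]
    out$distance[i] <- ifelse(genes$strand[best] == "+",
                              m - tss[best], tss[best] - m)
  }
  out
}

#' Annotate a results table
#'
#' Adds the genomic category ([classify_dmr()]) and nearest gene
#' ([nearest_gene()]) columns to a differential-methylation results
#' frame.
#'
#' @param results results data frame (from [run_model()]).
#' @param genes gene model data frame.
#' @return `results` with `annotation` and `nearest_gene` columns.
#' @export
annotate_results <- function(results, genes) {
  results$annotation <- classify_dmr(results, genes)
  results$nearest_gene <- nearest_gene(results, genes)$symbol
  results
}

#' Category percentages of an annotated table
#'
#' @param results annotated results data frame.
#' @return Named numeric vector of percentages (sums to 100 up to
#'   rounding), sorted decreasing.
#' @export
category_percentages <- function(results) {
  stopifnot(nrow(results) > 0, !is.null(results$annotation))
  tab <- table(results$annotation)
  sort(stats::setNames(100 * as.numeric(tab) / nrow(results),
                       names(tab)), decreasing = TRUE)
}
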