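#' Per-individual consensus peaks across technical replicates
#'
#' Merges the union of all replicate peak calls and keeps a merged
#' interval only if it overlaps at least one peak from *every*
#' replicate, i.e. the individual's consensus set contains only peaks
#' present in all technical replicates. Retained intervals are the
#' merged union spans, so downstream counts capture the full enriched
#' region.
#'
#' @param replicates list (length >= 2) of interval data frames, one per
#'   technical replicate.
#' @return Sorted disjoint interval data frame.
#' @export
replicate_consensus <- function(replicates) {
  if (length(replicates) < 2)
    stop("need at least 2 replicate peak sets")
  merged <- merge_intervals(do.call(rbind, lapply(replicates, function(r)
    r[, c("chrom", "start", "end")])))
  if (nrow(merged) == 0) return(merged)
  keep <- Reduce(`&`, lapply(replicates, function(r)
    overlaps_any(merged, r)))
  sort_intervals(merged[keep, , drop = FALSE])
}

#' Cohort-level consensus peaks
#'
#' Merges the union of the per-individual consensus sets and keeps
#' intervals supported by peaks from at least `min_overlap` distinct
#' individuals (>= 1 bp overlap). `min_overlap = 2`, the common default
#' of consensus peak-set tools, is the package default.
#'
#' @param individual_sets list of per-individual interval data frames.
#' @param min_overlap minimum number of supporting individuals.
#' @return Sorted disjoint interval data frame.
#' @export
cohort_consensus <- function(individual_sets, min_overlap = 2L) {
  n <- length(individual_sets)
  if (n < 1) stop("need at least 1 individual peak set")
  if (min_overlap < 1 || min_overlap > n)
    stop(sprintf("min_overlap must be in [1, %d]", n))
  merged <- merge_intervals(do.call(rbind, lapply(individual_sets,
    function(r) r[, c("chrom", "start", "end")])))
  if (nrow(merged) == 0) return(merged)
  support <- Reduce(`+`, lapply(individual_sets, function(r)
    as.integer(overlaps_any(merged, r))))
  sort_intervals(merged[support >= min_overlap, , drop = FALSE])
}

#' Replicate-summed count matrix over a master peak set
#'
#' For each master peak and individual, sums the counts of all
#' per-replicate count rows whose region overlaps the master peak,
#' over all technical replicates (columns named `"<sample>_rep<k>"`).
#' Regions absent from the replicate table contribute 0.
#'
#' @param master master peak interval data frame.
#' @param replicate_counts data frame with `chrom`, `start`, `end` and
#'   one integer count column per sample/replicate.
#' @param sample_ids character vector of individual sample ids.
#' @return A `count_matrix`: list with `peaks` (the master set, with a
#'   `location` column) and `counts` (peaks x samples integer matrix).
#' @export
summed_counts <- function(master, replicate_counts, sample_ids) {
  master <- sort_intervals(validate_intervals(
    master[, c("chrom", "start", "end")]))
  cnt_cols <- setdiff(names(replicate_counts),
                      c("chrom", "start", "end", "peak_id", "name",
                        "score", "strand"))
  rep_of <- sub("_rep[0-9]+$", "", cnt_cols)
  unknown <- setdiff(rep_of, sample_ids)
  if (length(unknown))
    stop(sprintf("count column(s) for unknown sample: %s",
                 paste(unique(unknown), collapse = ", ")))
  vals <- as.matrix(replicate_counts[, cnt_cols, drop = FALSE])
  bad <- which(is.na(vals) | vals < 0 | vals != floor(vals),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-integer count at %s:%d-%d (%s)",
                 replicate_counts$chrom[bad[1, 1]],
                 replicate_counts$start[bad[1, 1]],
                 replicate_counts$end[bad[1, 1]], cnt_cols[bad[1, 2]]))
  counts <- matrix(0L, nrow(master), length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  if (nrow(replicate_counts)) {
    hits <- GenomicRanges::findOverlaps(as_granges(replicate_counts),
                                        as_granges(master))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    per_sample <- matrix(vapply(sample_ids, function(s)
      rowSums(vals[, rep_of == s, drop = FALSE]),
      numeric(nrow(replicate_counts))),
      nrow = nrow(replicate_counts),
      dimnames = list(NULL, sample_ids))
    for (k in seq_along(qi))
      counts[si[k], ] <- counts[si[k], ] + per_sample[qi[k], ]
  }
  storage.mode(counts) <- "integer"
  master$location <- format_location(master)
  structure(list(peaks = master, counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d peaks x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
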