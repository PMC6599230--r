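#' Genomic intervals
#'
#' Intervals throughout the package are plain data frames with columns
#' `chrom` (character), `start` and `end` (integer-valued), using 0-based
#' half-open coordinates: a base at position p is covered by an interval
#' with `start <= p < end`, and the width of an interval is `end - start`.
#' This convention reproduces every printed DMR width in the published
#' result tables as `end - start` on the printed coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors of 0-based half-open coordinates.
#' @param ... further columns carried along as opaque payload.
#' @return A validated interval data frame.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(df)
  if (anyNA(df$chrom) || any(!nzchar(df$chrom)))
    stop("intervals on unnamed chromosome")
  if (anyNA(df$start) || anyNA(df$end))
    stop("interval coordinates must not be NA")
  if (any(df$start != floor(df$start)) || any(df$end != floor(df$end)))
    stop("interval coordinates must be integers")
  if (any(df$start < 0))
    stop("interval start must be >= 0")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("interval start >= end at row %d (%s:%s-%s)",
                 bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  df
}

#' @rdname genomic_intervals
#' @param df an interval data frame.
#' @export
interval_width <- function(df) {
  as.integer(df$end - df$start)
}

# 0-based half-open data frame <-> 1-based closed GRanges
as_granges <- function(df) {
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(start = df$start + 1,
                                                   end = df$end))
}

from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Parse printed DMR location strings
#'
#' Accepts the format used in the published tables, `"chrN:start-end"`,
#' tolerating en-dash or hyphen separators and comma digit grouping
#' (e.g. `"chr10:1281019–1,282,852"`). Printed coordinates are taken
#' verbatim as 0-based half-open, the convention under which every printed
#' width equals `end - start`.
#'
#' @param text character vector of location strings.
#' @return Interval data frame with one row per input string.
#' @export
parse_location <- function(text) {
  text <- trimws(text)
  # en-dash (U+2013) or hyphen between coordinates; commas allowed in digits
  pat <- "^(\\w+):([0-9,]+)[–-]([0-9,]+)$"
  ok <- grepl(pat, text)
  if (any(!ok))
    stop(sprintf("malformed location string: '%s'", text[which(!ok)[1]]))
  chrom <- sub(pat, "\\1", text)
  start <- as.numeric(gsub(",", "", sub(pat, "\\2", text)))
  end <- as.numeric(gsub(",", "", sub(pat, "\\3", text)))
  genomic_intervals(chrom, start, end)
}

#' @rdname parse_location
#' @param df interval data frame.
#' @return `format_location` returns the canonical `"chrN:start-end"`
#'   string (plain hyphen, no digit grouping).
#' @export
format_location <- function(df) {
  sprintf("%s:%d-%d", df$chrom, as.integer(df$start), as.integer(df$end))
}

#' Merge intervals into a minimal disjoint set
#'
#' Computes the union of the input intervals as a sorted set of disjoint
#' intervals. Book-ended intervals (one ending where the next starts) are
#' merged, so consensus regions do not fragment at abutting peaks.
#'
#' @param df interval data frame (any order, duplicates allowed).
#' @return Sorted disjoint interval data frame.
#' @export
merge_intervals <- function(df) {
  df <- validate_intervals(df[, c("chrom", "start", "end")])
  if (nrow(df) == 0) return(df)
  sort_intervals(from_granges(GenomicRanges::reduce(as_granges(df))))
}

sort_intervals <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pairwise interval overlap
#'
#' Half-open overlap test: intervals overlap iff they are on the same
#' chromosome and `a.start < b.end` and `b.start < a.end`. Intervals that
#' merely touch (one's end equals the other's start) do not overlap.
#'
#' @param a,b interval data frames, recycled to a common length.
#' @return Logical vector.
#' @export
intervals_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n)
  ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] &
    a$start[ia] < b$end[ib] &
    b$start[ib] < a$end[ia]
}

# indices of rows of `query` overlapping >= 1 row of `subject`
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  # disjoint chromosome sets are a legitimate no-overlap case
  suppressWarnings(
    GenomicRanges::countOverlaps(as_granges(query),
                                 as_granges(subject)) > 0)
}
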