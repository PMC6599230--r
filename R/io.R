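#' Read and write BED interval files
#'
#' BED3+ reader: tab-separated, 0-based half-open coordinates, at least
#' three columns. Columns beyond the third are preserved as an opaque
#' payload (named per the BED standard up to column 6, then `V7`, ...),
#' so `write_bed(read_bed(f))` round-trips canonical files.
#'
#' @param path file path.
#' @return Interval data frame (sorted order is *not* imposed; the file
#'   order is kept).
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("%s: fewer than 3 fields at line %d", path, which(nf < 3)[1]))
  nf0 <- min(nf)
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("%s: non-integer coordinates at line %d", path, bad[1]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s: start >= end at line %d", path, bad[1]))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  std <- c("name", "score", "strand")
  for (k in seq_len(nf0 - 3)) {
    nm <- if (k <= 3) std[k] else paste0("V", k + 3)
    df[[nm]] <- vapply(fields, `[[`, "", k + 3)
  }
  validate_intervals(df)
}

#' @rdname read_bed
#' @param df interval data frame (extra columns written after the first 3).
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  out <- df
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Published results-table schema (column order is fixed)
results_schema <- c("DMR Location", "DMR Width", "baseMean",
                    "log2 FoldChange", "padj", "Annotation", "Nearest Gene")

#' Read and write DMR results tables
#'
#' Tab-separated tables in the published schema: `DMR Location`,
#' `DMR Width`, `baseMean`, `log2 FoldChange`, `padj`, `Annotation`,
#' `Nearest Gene` (an optional `pvalue` column is carried through when
#' present). Locations are parsed with [parse_location()] and the printed
#' width column is validated against `end - start`; a mismatch raises an
#' integrity warning.
#'
#' @param path file path.
#' @return Data frame with columns `location` (canonical string), `chrom`,
#'   `start`, `end`, `width`, `baseMean`, `log2FoldChange`, `padj`,
#'   `annotation`, `nearest_gene` and optionally `pvalue`.
#' @export
read_results_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(results_schema, names(df))
  if (length(missing))
    stop(sprintf("results table %s: missing column(s) %s", path,
                 paste(sQuote(missing), collapse = ", ")))
  iv <- if (nrow(df)) parse_location(df[["DMR Location"]]) else
    genomic_intervals(character(), numeric(), numeric())
  out <- data.frame(location = if (nrow(df)) format_location(iv) else character(),
                    chrom = iv$chrom, start = iv$start, end = iv$end,
                    width = as.integer(df[["DMR Width"]]),
                    baseMean = as.numeric(df[["baseMean"]]),
                    log2FoldChange = as.numeric(df[["log2 FoldChange"]]),
                    padj = as.numeric(df[["padj"]]),
                    annotation = as.character(df[["Annotation"]]),
                    nearest_gene = as.character(df[["Nearest Gene"]]),
                    stringsAsFactors = FALSE)
  if ("pvalue" %in% names(df)) out$pvalue <- as.numeric(df[["pvalue"]])
  if (nrow(out) && any(out$width != interval_width(out)))
    warning(sprintf("results table %s: printed width disagrees with coordinates at row %d",
                    path, which(out$width != interval_width(out))[1]))
  if (anyDuplicated(out$location))
    stop(sprintf("results table %s: duplicate location %s", path,
                 out$location[anyDuplicated(out$location)]))
  out
}

#' @rdname read_results_table
#' @param df results data frame as returned by [read_results_table()] or
#'   [run_model()].
#' @export
write_results_table <- function(df, path) {
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    `DMR Location` = df$location,
                    `DMR Width` = interval_width(df),
                    baseMean = df$baseMean,
                    `log2 FoldChange` = df$log2FoldChange,
                    padj = df$padj,
                    Annotation = if (is.null(df$annotation)) NA else df$annotation,
                    `Nearest Gene` = if (is.null(df$nearest_gene)) NA else df$nearest_gene)
  if (!is.null(df$pvalue)) out$pvalue <- df$pvalue
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Published DMR tables
#'
#' Fixture copies of the two published differential-methylation result
#' tables ship with the package: 21 regions associated with preterm birth
#' (dichotomous model) and 67 regions associated with gestational age
#' (continuous model).
#'
#' @param which `"ptb"` (preterm-birth model) or `"ga"` (gestational age).
#' @return Results data frame (see [read_results_table()]).
#' @export
published_dmr_table <- function(which = c("ptb", "ga")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   sprintf("%s_dmr_table.tsv", which),
                   package = "medipdmr", mustWork = TRUE)
  read_results_table(f)
}

#' Read a BED12 gene-model file
#'
#' Parses transcript intervals, strand, thick (coding) span and exon
#' blocks; block structure is validated (blocks within the transcript,
#' sizes/starts lists consistent with blockCount).
#'
#' @param path BED12 file path.
#' @return Data frame, one row per gene: `chrom`, `start`, `end`,
#'   `symbol`, `strand`, `thick_start`, `thick_end`, plus list columns
#'   `exon_starts`/`exon_ends` of absolute 0-based half-open exon spans.
#' @export
read_bed12 <- function(path) {
  df <- read_bed(path)
  need <- c("name", "score", "strand", "V7", "V8", "V9", "V10", "V11", "V12")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: not a BED12 file (12 columns required)", path))
  n_blocks <- as.integer(df$V10)
  sizes <- lapply(strsplit(df$V11, ",", fixed = TRUE), as.numeric)
  offs <- lapply(strsplit(df$V12, ",", fixed = TRUE), as.numeric)
  if (any(lengths(sizes) != n_blocks) || any(lengths(offs) != n_blocks))
    stop(sprintf("%s: block list length disagrees with blockCount", path))
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    symbol = df$name, strand = df$strand,
                    thick_start = as.numeric(df$V7),
                    thick_end = as.numeric(df$V8),
                    stringsAsFactors = FALSE)
  out$exon_starts <- Map(function(s, o) s + o, df$start, offs)
  out$exon_ends <- Map(`+`, out$exon_starts, sizes)
  bad <- which(vapply(seq_len(nrow(out)), function(i) {
    es <- out$exon_starts[[i]]; ee <- out$exon_ends[[i]]
    any(es < out$start[i]) || any(ee > out$end[i]) || any(es >= ee) ||
      is.unsorted(es)
  }, logical(1)))
  if (length(bad))
    stop(sprintf("%s: invalid exon block structure at line %d", path, bad[1]))
  if (!all(out$strand %in% c("+", "-")))
    stop(sprintf("%s: strand must be + or -", path))
  out
}

write_bed12 <- function(genes, path) {
  df <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                   name = genes$symbol, score = 0, strand = genes$strand,
                   thickStart = genes$thick_start, thickEnd = genes$thick_end,
                   itemRgb = "0,0,0",
                   blockCount = lengths(genes$exon_starts),
                   blockSizes = vapply(seq_len(nrow(genes)), function(i)
                     paste(genes$exon_ends[[i]] - genes$exon_starts[[i]],
                           collapse = ","), ""),
                   blockStarts = vapply(seq_len(nrow(genes)), function(i)
                     paste(genes$exon_starts[[i]] - genes$start[i],
                           collapse = ","), ""),
                   stringsAsFactors = FALSE)
  write_bed(df, path)
}
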