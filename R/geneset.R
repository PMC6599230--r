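#' Read gene sets from a two-column TSV
#'
#' Format: `set_name<TAB>symbol`, one symbol per line, no header
#' required (a header line reading `set` / `symbol` is tolerated).
#' Symbols are upper-cased and deduplicated within each set.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("set", "symbol"))
  if (nrow(df) && tolower(df$set[1]) == "set") df <- df[-1, , drop = FALSE]
  lapply(split(toupper(df$symbol), df$set), function(s) sort(unique(s)))
}

#' Gene-set overlap against a universe
#'
#' Observed overlap between a query gene list and a target set, the
#' count expected by chance (`|query| * |target| / |universe|`), and the
#' upper-tail hypergeometric p-value `P(X >= observed)` for drawing
#' `|query|` genes from the universe. Query or target genes outside the
#' universe are dropped with a warning.
#'
#' @param query,target,universe character vectors of gene symbols
#'   (case-insensitive; matching is exact after upper-casing).
#' @return List: `observed`, `expected`, `pvalue`, `n_query`,
#'   `n_target`, `n_universe`, `genes` (the overlapping symbols).
#' @export
overlap_stats <- function(query, target, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop("empty gene universe")
  query <- unique(toupper(query))
  target <- unique(toupper(target))
  drop_q <- setdiff(query, universe)
  drop_t <- setdiff(target, universe)
  if (length(drop_q) || length(drop_t))
    warning(sprintf("dropped %d query / %d target gene(s) outside the universe",
                    length(drop_q), length(drop_t)))
  query <- intersect(query, universe)
  target <- intersect(target, universe)
  hit <- intersect(query, target)
  obs <- length(hit)
  p <- stats::phyper(obs - 1, length(target),
                     length(universe) - length(target), length(query),
                     lower.tail = FALSE)
  list(observed = obs,
       expected = length(query) * length(target) / length(universe),
       pvalue = p, n_query = length(query), n_target = length(target),
       n_universe = length(universe), genes = sort(hit))
}

#' Shared records between two results tables
#'
#' Records of `a` whose canonical location (`chrN:start-end`) appears in
#' `b`, in the order of `a`. Intersection counts are symmetric.
#'
#' @param a,b results data frames with a `location` column (e.g. from
#'   [read_results_table()] or [run_model()]).
#' @return Subset of `a`.
#' @export
table_intersection <- function(a, b) {
  canon <- function(x) format_location(parse_location(x$location))
  a[canon(a) %in% canon(b), , drop = FALSE]
}

#' Unique nearest genes of a results table
#'
#' @param results annotated results data frame with `nearest_gene`.
#' @return Sorted vector of unique symbols (NA dropped).
#' @export
unique_nearest_genes <- function(results) {
  sort(unique(results$nearest_gene[!is.na(results$nearest_gene)]))
}
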