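#' Window-based genomic-feature enrichment score
#'
#' The enrichment of a feature among a DMR set is the ratio between the
#' fraction of DMRs overlapping windows flagged for the feature and the
#' fraction of all genome windows flagged for the feature:
#' `(n_dmrs_overlapping / n_dmrs) / (n_windows_flagged / n_windows)`.
#' A DMR "overlaps" the feature iff it overlaps at least one flagged
#' window — overlap is mediated through the window grid, not by direct
#' DMR/feature intersection.
#'
#' @param dmrs DMR interval data frame.
#' @param grid flagged window data frame from [flag_windows()].
#' @param feature name of a logical flag column of `grid`.
#' @return One-row data frame: `feature`, `score`,
#'   `n_dmrs_overlapping`, `n_dmrs`, `n_windows_flagged`, `n_windows`.
#' @export
enrichment_score <- function(dmrs, grid, feature) {
  stopifnot(nrow(dmrs) > 0, nrow(grid) > 0,
            feature %in% names(grid), is.logical(grid[[feature]]))
  flagged <- grid[grid[[feature]], c("chrom", "start", "end"),
                  drop = FALSE]
  if (nrow(flagged) == 0)
    stop(sprintf("undefined enrichment (zero background) for feature '%s'",
                 feature))
  n_over <- sum(overlaps_any(dmrs, flagged))
  data.frame(feature = feature,
             score = (n_over / nrow(dmrs)) /
               (nrow(flagged) / nrow(grid)),
             n_dmrs_overlapping = n_over, n_dmrs = nrow(dmrs),
             n_windows_flagged = nrow(flagged), n_windows = nrow(grid),
             stringsAsFactors = FALSE)
}

#' Direction-stratified feature enrichment
#'
#' Computes [enrichment_score()] for every feature separately within the
#' hyper- and hypo-methylated DMR strata (per the `direction` column of
#' the results frame). A stratum with zero DMRs is omitted with a
#' warning. Output is ordered feature-major and is directly usable as
#' two-panel bar-plot data.
#'
#' @param results results data frame with `chrom`/`start`/`end` and
#'   `direction` columns.
#' @param grid flagged window data frame.
#' @param features character vector of flag column names (defaults to
#'   every logical column of `grid`).
#' @return Data frame of per-feature, per-direction enrichment rows.
#' @export
directional_enrichment <- function(results, grid, features = NULL) {
  if (is.null(features))
    features <- names(grid)[vapply(grid, is.logical, logical(1))]
  out <- list()
  for (feat in features) {
    for (dir in c("hyper", "hypo")) {
      sub <- results[!is.na(results$direction) &
                       results$direction == dir, , drop = FALSE]
      if (nrow(sub) == 0) {
        warning(sprintf("no %s-methylated DMRs; stratum omitted", dir))
        next
      }
      row <- enrichment_score(sub, grid, feat)
      row$direction <- dir
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}
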