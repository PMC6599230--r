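#' Build per-individual consensus sets and the cohort count matrix
#'
#' Convenience step chaining [replicate_consensus()] per individual,
#' [cohort_consensus()] across individuals, and [summed_counts()].
#'
#' @param rep_peaks named list of replicate peak data frames
#'   (`"<sample>_rep<k>"`).
#' @param replicate_counts per-replicate count data frame (see
#'   [summed_counts()]).
#' @param samples cohort data frame.
#' @param min_overlap cohort-level support threshold.
#' @return List: `individual` (named list of consensus sets), `master`
#'   (cohort peak set), `cm` (`count_matrix`).
#' @export
build_count_matrix <- function(rep_peaks, replicate_counts, samples,
                               min_overlap = 2L) {
  ids <- samples$sample_id
  individual <- lapply(ids, function(s) {
    reps <- rep_peaks[grep(sprintf("^%s_rep", s), names(rep_peaks))]
    replicate_consensus(unname(reps))
  })
  names(individual) <- ids
  master <- cohort_consensus(individual, min_overlap = min_overlap)
  cm <- summed_counts(master, replicate_counts, ids)
  list(individual = individual, master = master, cm = cm)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration on a synthetic bundle: simulate -> consensus
#' -> differential testing (both the dichotomous preterm model and the
#' continuous gestational-age model) -> annotation -> window-based
#' feature enrichment -> cross-model comparison. All outputs are written
#' under `out_dir` as tab-separated text plus a run manifest recording
#' the seed and every parameter; reruns with the same config are
#' byte-identical.
#'
#' @param config a list (or path to a YAML file) with optional blocks
#'   `simulate` (arguments of [sim_config()]), `analysis` (`alpha_fdr`,
#'   `alpha_nominal`, `min_overlap`) and `out_dir`.
#' @return Invisible list of the main in-memory objects (`bundle`,
#'   `cm`, `results` per model, `enrichment`, `comparison`, `paths`).
#' @export
run_all <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- do.call(sim_config, config$simulate %||% list())
  an <- config$analysis %||% list()
  alpha_fdr <- an$alpha_fdr %||% 0.05
  alpha_nominal <- an$alpha_nominal %||% 0.01
  min_overlap <- an$min_overlap %||% 2L
  out_dir <- config$out_dir %||% "medipdmr_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  bundle <- simulate_bundle(cfg, dir = file.path(out_dir, "sim"))
  cons <- build_count_matrix(bundle$rep_peaks, bundle$counts,
                             bundle$samples, min_overlap = min_overlap)
  write_bed(cons$master, file.path(out_dir, "master_peaks.bed"))
  cm_out <- data.frame(cons$cm$peaks, cons$cm$counts,
                       check.names = FALSE)
  utils::write.table(cm_out, file.path(out_dir, "count_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  results <- list()
  for (model in c("ptb", "ga")) {
    res <- run_model(cons$cm, bundle$samples, model = model,
                     alpha_fdr = alpha_fdr)
    res <- annotate_results(res, bundle$genome$genes)
    write_results_table(res,
                        file.path(out_dir, sprintf("dmr_%s.tsv", model)))
    results[[model]] <- res
  }

  ctx <- cpg_flanks(bundle$genome$islands, cfg$chrom_lengths,
                    shore_bp = cfg$shore_bp, shelf_bp = cfg$shelf_bp)
  parts <- gene_parts(bundle$genome$genes)
  st <- state_features(bundle$genome$states)
  grid <- flag_windows(make_windows(cfg$chrom_lengths, cfg$window_bp),
                       list(islands = ctx$islands, shores = ctx$shores,
                            shelves = ctx$shelves, exons = parts$exons,
                            introns = parts$introns,
                            promoters = st$promoters,
                            enhancers = st$enhancers))
  utils::write.table(grid, file.path(out_dir, "window_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nominal <- results$ptb[!is.na(results$ptb$pvalue) &
                           results$ptb$pvalue < alpha_nominal, ]
  enr <- if (nrow(nominal)) directional_enrichment(nominal, grid)
         else NULL
  if (!is.null(enr))
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  sig <- function(r) r[!is.na(r$padj) & r$padj < alpha_fdr, ]
  shared <- table_intersection(sig(results$ptb), sig(results$ga))
  comparison <- list(
    n_ptb_sig = nrow(sig(results$ptb)),
    n_ga_sig = nrow(sig(results$ga)),
    n_shared = nrow(shared),
    n_hypo_ptb = sum(sig(results$ptb)$direction == "hypo"),
    genes_ptb = unique_nearest_genes(sig(results$ptb)),
    genes_ga = unique_nearest_genes(sig(results$ga)))
  writeLines(c(sprintf("n_ptb_sig\t%d", comparison$n_ptb_sig),
               sprintf("n_ga_sig\t%d", comparison$n_ga_sig),
               sprintf("n_shared\t%d", comparison$n_shared),
               sprintf("n_hypo_ptb\t%d", comparison$n_hypo_ptb)),
             file.path(out_dir, "comparison.tsv"))

  # data layer of the read-count heat map: normalized counts of the
  # FDR-significant regions
  sf <- attr(results$ptb, "size_factors")
  sig_loc <- sig(results$ptb)$location
  if (length(sig_loc)) {
    norm <- sweep(cons$cm$counts, 2, sf, `/`)
    hm <- data.frame(location = cons$cm$peaks$location,
                     round(norm, 2), check.names = FALSE)
    utils::write.table(hm[hm$location %in% sig_loc, ],
                       file.path(out_dir, "heatmap_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(sprintf("seed\t%d", cfg$seed),
                sprintf("alpha_fdr\t%g", alpha_fdr),
                sprintf("alpha_nominal\t%g", alpha_nominal),
                sprintf("min_overlap\t%d", min_overlap),
                sprintf("n_peaks\t%d", cfg$n_peaks),
                sprintf("dispersion\t%g", cfg$dispersion),
                sprintf("package_version\t%s",
                        as.character(utils::packageVersion("medipdmr"))))
  writeLines(manifest, file.path(out_dir, "run_manifest.tsv"))

  invisible(list(bundle = bundle, cm = cons$cm, results = results,
                 enrichment = enr, comparison = comparison,
                 out_dir = out_dir))
}
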