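#' Pipeline configuration
#'
#' Bundles the data and parameters for a full phase-analysis run. Each
#' structure entry is a list with elements `counts` (gene_id + sample
#' columns) and `metadata` (see [validate_metadata()]); `limb` may be
#' omitted for a jaw-only run (the comparison stage is then skipped).
#'
#' @param jaw,limb Lists with `counts` and `metadata` tibbles (or `NULL`).
#' @param filter A [filter_config()].
#' @param k `"auto"` for gap-statistic selection, or a fixed integer.
#' @param k_range Candidate k for the gap statistic (default `1:10`).
#' @param B Reference sets for the gap statistic (default 50).
#' @param n_init k-means restarts for the final clustering (default 25).
#' @param gap_n_init k-means restarts inside the gap computation (default 5).
#' @param theta_r Cluster-score threshold for genes of interest (default 0.75).
#' @param phase Named list of [phase_config()]s per structure; defaults used
#'   when omitted.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(jaw = NULL, limb = NULL,
                            filter = filter_config(),
                            k = "auto", k_range = 1:10, B = 50,
                            n_init = 25, gap_n_init = 5,
                            theta_r = 0.75,
                            phase = NULL, seed = 1L) {
  if (is.null(jaw) && is.null(limb)) stop("at least one structure is required")
  for (s in c("jaw", "limb")) {
    dat <- get(s)
    if (!is.null(dat) && !all(c("counts", "metadata") %in% names(dat))) {
      stop("'", s, "' must be a list with elements counts and metadata")
    }
  }
  if (is.null(phase)) phase <- list()
  base::structure(
    list(jaw = jaw, limb = limb, filter = filter, k = k, k_range = k_range,
         B = B, n_init = n_init, gap_n_init = gap_n_init, theta_r = theta_r,
         phase = phase, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# one structure through normalise -> filter -> z -> (gap) -> k-means ->
# score -> phase
run_structure <- function(dat, structure, cfg, seed) {
  metadata <- validate_metadata(dat$metadata)
  counts <- validate_counts(dat$counts, metadata)
  cpm <- compute_cpm(counts)
  tp <- average_replicates(cpm, metadata, structure)
  report <- apply_filters(cpm, tp, cfg$filter)
  if (length(report$kept_gene_ids) < 2) {
    stop("stage 'filter' (", structure, "): fewer than 2 genes survive")
  }
  zp <- zscore_profiles(subset_profile(tp, report$kept_gene_ids))
  if (identical(cfg$k, "auto")) {
    gap <- select_k_gap(zp, k_range = cfg$k_range, B = cfg$B,
                        seed = seed, n_init = cfg$gap_n_init)
    k <- gap$k_star
  } else {
    gap <- NULL
    k <- as.integer(cfg$k)
  }
  cr <- cluster_kmeans(zp, k, seed = seed + 100L, n_init = cfg$n_init)
  goi <- select_genes_of_interest(cr, cfg$theta_r)
  pcfg <- cfg$phase[[structure]]
  if (is.null(pcfg)) pcfg <- phase_config(structure)
  pa <- assign_gene_phases(cr, goi, pcfg)
  list(structure = structure, cpm = cpm, profile = tp, report = report,
       zp = zp, gap = gap, k = k, clusters = cr, goi = goi, phases = pa,
       seed = seed)
}

write_structure_outputs <- function(res, out_dir) {
  pre <- file.path(out_dir, res$structure)
  write_filter_report(res$report, paste0(pre, "_filter_report.tsv"))
  if (!is.null(res$gap)) {
    readr::write_tsv(tidy(res$gap), paste0(pre, "_gap.tsv"), progress = FALSE)
  }
  readr::write_tsv(tidy(res$clusters), paste0(pre, "_clusters.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$phases$cluster_phase, paste0(pre, "_phases.tsv"),
                   progress = FALSE)
  readr::write_tsv(res$phases$gene_phase, paste0(pre, "_gene_phases.tsv"),
                   progress = FALSE)
}

phase_counts_list <- function(pa) {
  labs <- c(pa$labels, "unassigned")
  as.list(setNames(
    vapply(labs, function(l) length(phase_genes(pa, l)), 0L), labs
  ))
}

#' Run the full phase-analysis pipeline
#'
#' Executes, per structure: CPM normalisation, replicate averaging, the
#' four-stage expression filter, z-scoring, gap-statistic k selection (or a
#' fixed k), k-means clustering, cluster-score gene selection and phase
#' assignment; then, when both structures are present, the cross-structure
#' shared-gene and overlap statistics and the early-transient fraction.
#' All seeds and thresholds used are recorded in the summary, and every
#' summary number is recomputable from the stage outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, per-stage TSVs and a
#'   machine-readable `summary.json` are written there.
#' @return A `pipeline_result` list with per-structure results
#'   (`$jaw`, `$limb`), the comparison (`$comparison`) and the summary
#'   (`$summary`), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  results <- list()
  offsets <- c(jaw = 1L, limb = 2L)
  for (s in c("jaw", "limb")) {
    if (is.null(config[[s]])) next
    results[[s]] <- run_structure(config[[s]], s, config, config$seed + offsets[[s]])
  }

  comparison <- NULL
  if (!is.null(results$jaw) && !is.null(results$limb)) {
    shared <- intersect_goi(results$jaw$goi, results$limb$goi)
    overlap <- overlap_percentages(results$jaw$phases, results$limb$phases,
                                   shared$shared)
    jaw_first <- results$jaw$phases$labels[1]
    limb_first <- results$limb$phases$labels[1]
    transient_genes <- Reduce(intersect, list(
      shared$shared,
      phase_genes(results$jaw$phases, jaw_first),
      phase_genes(results$limb$phases, limb_first)
    ))
    limb_t <- profile_times(results$limb$zp)
    transient_pct <- if (all(c(0, 3, 24) %in% limb_t)) {
      early_transient_fraction(transient_genes, results$limb$zp)
    } else {
      NA_real_
    }
    comparison <- list(shared = shared, overlap = overlap,
                       transient_genes = transient_genes,
                       transient_pct = transient_pct)
  }

  summary <- list(
    seed = config$seed,
    parameters = list(
      theta_mean = config$filter$theta_mean,
      theta_var = config$filter$theta_var,
      theta_max = config$filter$theta_max,
      theta_r = config$theta_r,
      k_mode = if (identical(config$k, "auto")) "auto" else "fixed",
      B = config$B, n_init = config$n_init
    )
  )
  for (s in names(results)) {
    r <- results[[s]]
    summary[[s]] <- list(
      seed = r$seed,
      n_input = r$report$n_input,
      n_after_stage = as.list(setNames(r$report$stages$n_kept,
                                       r$report$stages$stage)),
      k = r$k,
      n_genes_of_interest = length(r$goi),
      phase_group_sizes = phase_counts_list(r$phases)
    )
  }
  if (!is.null(comparison)) {
    summary$comparison <- list(
      n_shared = comparison$shared$n_shared,
      shared_pct_of_jaw = comparison$shared$pct_of_jaw,
      early_transient_pct = comparison$transient_pct,
      overlap = lapply(seq_len(nrow(comparison$overlap)), function(i) {
        as.list(comparison$overlap[i, c("jaw_group", "limb_group",
                                        "count", "pct")])
      })
    )
  }

  out <- base::structure(
    list(jaw = results$jaw, limb = results$limb,
         comparison = comparison, summary = summary),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in names(results)) write_structure_outputs(results[[s]], out_dir)
    if (!is.null(comparison)) {
      readr::write_tsv(tibble::as_tibble(comparison$overlap),
                       file.path(out_dir, "overlap.tsv"), progress = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
    return(invisible(out))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("regenphase pipeline result\n")
  for (s in c("jaw", "limb")) {
    if (is.null(x[[s]])) next
    cat(sprintf("  %s: %d genes in, %d genes of interest, k = %d\n",
                s, x[[s]]$report$n_input, length(x[[s]]$goi), x[[s]]$k))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  shared genes: %d (%.2f%% of jaw)\n",
                x$comparison$shared$n_shared, x$comparison$shared$pct_of_jaw))
  }
  invisible(x)
}
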