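#' Phase-group configuration
#'
#' Defines the named temporal phase groups for a structure as ordered,
#' non-overlapping time bins, plus the monotone-rise rule. Defaults mirror
#' the regeneration stages of each structure:
#'
#' * jaw: `'5 dpi peak'` (120 h), `'14 dpi peak'` (336 h),
#'   `'35 dpi peak'` (840 h) - point bins on the sampled grid;
#' * limb: `'early peak'` (0, 72] h, `'mid peak'` (72, 336] h,
#'   `'late rise'` (336, 672] h - half-open intervals.
#'
#' A centroid whose peak sits at the final time point and that rises
#' monotonically within tolerance `monotone_tolerance` (no step down larger
#' than tau z-units) is labelled `'general rise'` instead of a peak bin.
#'
#' @param structure `"jaw"` or `"limb"`.
#' @param bins Optional tibble with columns `label`, `lo`, `hi` (hours);
#'   a point bin has `lo == hi`.
#' @param rise_label Label for steadily rising centroids.
#' @param monotone_tolerance Largest tolerated downward step (z-units) for
#'   the rise rule. Default 0.25.
#' @return A `phase_config` list.
#' @export
phase_config <- function(structure = c("jaw", "limb"), bins = NULL,
                         rise_label = "general rise",
                         monotone_tolerance = 0.25) {
  structure <- match.arg(structure)
  if (is.null(bins)) {
    bins <- if (structure == "jaw") {
      tibble::tibble(label = c("5 dpi peak", "14 dpi peak", "35 dpi peak"),
                     lo = c(120, 336, 840), hi = c(120, 336, 840))
    } else {
      tibble::tibble(label = c("early peak", "mid peak", "late rise"),
                     lo = c(0, 72, 336), hi = c(72, 336, 672))
    }
  }
  bins <- tibble::as_tibble(bins)
  stopifnot(all(c("label", "lo", "hi") %in% names(bins)),
            all(bins$hi >= bins$lo),
            monotone_tolerance >= 0)
  if (nrow(bins) > 1 && any(bins$lo[-1] < bins$hi[-nrow(bins)])) {
    stop("phase bins must be ordered and non-overlapping")
  }
  base::structure(
    list(structure = structure, bins = bins, rise_label = rise_label,
         monotone_tolerance = monotone_tolerance,
         labels = c(bins$label, rise_label)),
    class = "phase_config"
  )
}

# membership of a peak time in a bin row: point bins are closed, interval
# bins half-open (lo, hi]
bin_label_for <- function(t, bins) {
  for (i in seq_len(nrow(bins))) {
    inside <- if (bins$lo[i] == bins$hi[i]) t == bins$lo[i]
              else t > bins$lo[i] & t <= bins$hi[i]
    if (inside) return(bins$label[i])
  }
  "unassigned"
}

#' Classify a cluster centroid into a temporal phase group
#'
#' Rule, in order of precedence:
#' 1. peak (argmax) at the intact time point (0 h) - `'unassigned'`
#'    (down-regulated pattern);
#' 2. peak at the final time point and non-decreasing within tolerance -
#'    the rise label;
#' 3. otherwise, the bin containing the peak time (a non-monotone profile
#'    peaking at the final time falls into the last bin); a peak in no bin
#'    is `'unassigned'`.
#'
#' The rule depends only on the ordering and differences of the centroid,
#' so it is invariant to adding a constant and to positive rescaling.
#'
#' @param centroid Numeric z-score vector over `times`.
#' @param times Strictly increasing time points (hours), same length.
#' @param cfg A [phase_config()].
#' @return A single phase label.
#' @export
classify_centroid <- function(centroid, times, cfg) {
  if (length(centroid) != length(times)) {
    stop("centroid and times lengths differ")
  }
  if (length(centroid) < 3) stop("need at least 3 time points")
  peak <- which.max(centroid)
  if (times[peak] == 0) return("unassigned")
  if (peak == length(centroid)) {
    if (all(diff(centroid) >= -cfg$monotone_tolerance)) return(cfg$rise_label)
    lbl <- bin_label_for(times[peak], cfg$bins)
    if (lbl == "unassigned") lbl <- cfg$bins$label[nrow(cfg$bins)]
    return(lbl)
  }
  bin_label_for(times[peak], cfg$bins)
}

#' Assign clusters and their genes of interest to phase groups
#'
#' Every cluster is labelled by [classify_centroid()]; each gene of
#' interest inherits its cluster's label. Genes in `'unassigned'` clusters
#' remain in the genes-of-interest universe but are excluded from
#' phase-restricted statistics.
#'
#' @param cr A `cluster_result` (see [cluster_kmeans()]).
#' @param goi Character vector of genes of interest (subset of clustered
#'   genes, see [select_genes_of_interest()]).
#' @param cfg A [phase_config()].
#' @return A `phase_assignment`: list with `cluster_phase` (tibble
#'   `cluster`, `label`, `peak_time_hours`, `n_genes` of interest) and
#'   `gene_phase` (tibble `gene_id`, `label`).
#' @export
assign_gene_phases <- function(cr, goi, cfg) {
  stopifnot(all(goi %in% cr$assignment$gene_id))
  labels <- vapply(seq_len(cr$k), function(c) {
    classify_centroid(cr$centroids[c, ], cr$times, cfg)
  }, "")
  peak_times <- cr$times[apply(cr$centroids, 1, which.max)]
  gene_phase <- cr$assignment |>
    dplyr::filter(.data$gene_id %in% goi) |>
    dplyr::mutate(label = labels[.data$cluster]) |>
    dplyr::select("gene_id", "cluster", "label")
  cluster_phase <- tibble::tibble(
    cluster = seq_len(cr$k),
    label = labels,
    peak_time_hours = peak_times,
    n_genes = vapply(seq_len(cr$k),
                     function(c) sum(gene_phase$cluster == c), 0L)
  )
  base::structure(
    list(cluster_phase = cluster_phase,
         gene_phase = gene_phase[, c("gene_id", "label")],
         labels = cfg$labels,
         structure = cfg$structure),
    class = "phase_assignment"
  )
}

#' @rdname assign_gene_phases
#' @param x A `phase_assignment`.
#' @param ... Unused.
#' @export
tidy.phase_assignment <- function(x, ...) x$gene_phase

#' @rdname assign_gene_phases
#' @export
glance.phase_assignment <- function(x, ...) {
  counts <- table(factor(x$gene_phase$label, levels = c(x$labels, "unassigned")))
  dplyr::bind_cols(tibble::tibble(structure = x$structure,
                                  n_genes = nrow(x$gene_phase)),
                   tibble::as_tibble(t(as.matrix(counts))))
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("Phase assignment (", x$structure, "): ",
      nrow(x$gene_phase), " genes of interest\n", sep = "")
  print(x$cluster_phase)
  invisible(x)
}

#' Genes of interest carrying a given phase label
#'
#' @param pa A `phase_assignment`.
#' @param label Phase label.
#' @return Character vector of gene ids.
#' @export
phase_genes <- function(pa, label) {
  pa$gene_phase$gene_id[pa$gene_phase$label == label]
}
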