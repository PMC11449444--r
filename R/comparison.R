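#' Shared genes between two genes-of-interest sets
#'
#' Exact intersection by gene identifier (both structures are assumed to be
#' quantified against the same genome annotation), together with the share
#' of the first set that is common.
#'
#' @param jaw_goi Character vector of jaw genes of interest.
#' @param limb_goi Character vector of limb genes of interest.
#' @return A list: `shared` (sorted character vector), `n_shared`,
#'   `pct_of_jaw` (100 * n_shared / length of jaw set).
#' @export
intersect_goi <- function(jaw_goi, limb_goi) {
  jaw_goi <- unique(jaw_goi)
  limb_goi <- unique(limb_goi)
  if (length(jaw_goi) == 0) {
    stop("jaw gene set is empty; shared percentage undefined")
  }
  shared <- sort(intersect(jaw_goi, limb_goi))
  list(shared = shared,
       n_shared = length(shared),
       pct_of_jaw = 100 * length(shared) / length(jaw_goi))
}

#' Cross-structure phase overlap percentages
#'
#' For each jaw phase group g and limb phase group h, counts the shared
#' genes lying in both and expresses the count as a percentage of the
#' shared genes in g. Shared genes of g sitting in `'unassigned'` limb
#' clusters make the per-group percentages sum to less than 100.
#'
#' @param jaw_pa Jaw `phase_assignment`.
#' @param limb_pa Limb `phase_assignment`.
#' @param shared Character vector of shared genes (see [intersect_goi()]).
#' @return An `overlap_table`: tibble `jaw_group`, `limb_group`, `count`,
#'   `pct` (NA when the jaw group holds no shared genes), with the
#'   per-jaw-group shared counts in attribute `n_shared_in_jaw_group`.
#' @export
overlap_percentages <- function(jaw_pa, limb_pa, shared) {
  stopifnot(inherits(jaw_pa, "phase_assignment"),
            inherits(limb_pa, "phase_assignment"))
  jaw_groups <- jaw_pa$labels
  limb_groups <- limb_pa$labels
  denom <- vapply(jaw_groups, function(g) {
    length(intersect(shared, phase_genes(jaw_pa, g)))
  }, 0L)
  cells <- tidyr::expand_grid(jaw_group = jaw_groups, limb_group = limb_groups)
  cells$count <- purrr::map2_int(cells$jaw_group, cells$limb_group, function(g, h) {
    length(Reduce(intersect,
                  list(shared, phase_genes(jaw_pa, g), phase_genes(limb_pa, h))))
  })
  cells$pct <- unname(ifelse(denom[cells$jaw_group] == 0, NA_real_,
                             100 * cells$count / denom[cells$jaw_group]))
  attr(cells, "n_shared_in_jaw_group") <-
    tibble::tibble(jaw_group = jaw_groups, n_shared = unname(denom))
  class(cells) <- c("overlap_table", class(cells))
  cells
}

#' Heatmap of phase overlap percentages
#'
#' @param object An `overlap_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_table <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  tb$jaw_group <- factor(tb$jaw_group, levels = rev(unique(tb$jaw_group)))
  tb$limb_group <- factor(tb$limb_group, levels = unique(tb$limb_group))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$limb_group, y = .data$jaw_group,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$pct), "", sprintf("%.1f", .data$pct)))) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 100)) +
    ggplot2::labs(x = "limb group", y = "jaw group",
                  fill = "% of shared\ngenes in group") +
    ggplot2::theme_minimal()
}

#' Fraction of genes with an early transient limb response
#'
#' Among a gene set, the percentage whose limb z-profile peaks at
#' `peak_time_hours` (default 3 h post amputation) and has returned to the
#' intact level or lower by `return_time_hours` (default 24 h, i.e. 1 day):
#' `z(return) <= z(0) + tolerance`.
#'
#' @param genes Character vector of gene ids (subset of the profile genes).
#' @param limb_zp Limb `z_profile`.
#' @param peak_time_hours Required peak time (default 3).
#' @param return_time_hours Time by which expression must be back to basal
#'   (default 24).
#' @param tolerance Allowed excess over the intact z value (default 0).
#' @return Percentage (0-100), or `NA` for an empty gene set.
#' @export
early_transient_fraction <- function(genes, limb_zp, peak_time_hours = 3,
                                     return_time_hours = 24, tolerance = 0) {
  times <- profile_times(limb_zp)
  if (!all(c(0, peak_time_hours, return_time_hours) %in% times)) {
    stop("limb profile must include times 0, ", peak_time_hours, " and ",
         return_time_hours, " hours")
  }
  if (length(genes) == 0) return(NA_real_)
  Z <- z_matrix(limb_zp)
  missing <- setdiff(genes, rownames(Z))
  if (length(missing) > 0) {
    stop("gene(s) absent from limb profile: ",
         paste(head(missing, 10), collapse = ", "))
  }
  Z <- Z[genes, , drop = FALSE]
  tcols <- as.numeric(colnames(Z))
  peak_at <- tcols[apply(Z, 1, which.max)] == peak_time_hours
  back <- Z[, which(tcols == return_time_hours)] <=
    Z[, which(tcols == 0)] + tolerance
  100 * mean(peak_at & back)
}
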