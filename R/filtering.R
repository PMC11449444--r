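#' Expression-filter configuration
#'
#' Thresholds for the four-stage candidate-gene filter applied before
#' clustering a low-replicate time course:
#' mean CPM, sample variance, maximum CPM, and a minimum-dependent
#' max/min fold-change requirement.
#'
#' The fold-change stage uses a non-increasing step function of a gene's
#' minimum CPM: genes of low abundance must show a larger fold change to be
#' retained (default multiplier 5 below 1 CPM, 3 from 1 to 5 CPM, 2 at or
#' above 5 CPM). `ratio_floor_epsilon` floors the denominator so genes that
#' drop to zero do not divide by zero.
#'
#' @param theta_mean Minimum mean CPM across all samples (genes with mean
#'   below this are removed). Default 0.8.
#' @param theta_var Minimum sample variance (denominator n-1) across all
#'   samples. Default 0.4.
#' @param theta_max Maximum CPM over time must strictly exceed this. Default 20.
#' @param ratio_breaks Increasing breakpoints of the multiplier step function
#'   on the minimum CPM scale. Default `c(1, 5)`.
#' @param ratio_multipliers Multiplier per interval, length
#'   `length(ratio_breaks) + 1`, non-increasing. Default `c(5, 3, 2)`.
#' @param ratio_floor_epsilon Floor for the ratio denominator. Default 0.1.
#' @return A `filter_config` list.
#' @export
filter_config <- function(theta_mean = 0.8, theta_var = 0.4, theta_max = 20,
                          ratio_breaks = c(1, 5),
                          ratio_multipliers = c(5, 3, 2),
                          ratio_floor_epsilon = 0.1) {
  stopifnot(theta_mean > 0, theta_var > 0, theta_max > 0,
            ratio_floor_epsilon > 0,
            length(ratio_multipliers) == length(ratio_breaks) + 1,
            all(ratio_multipliers >= 1),
            all(diff(ratio_breaks) > 0),
            all(diff(ratio_multipliers) <= 0))
  structure(
    list(theta_mean = theta_mean, theta_var = theta_var, theta_max = theta_max,
         ratio_breaks = ratio_breaks, ratio_multipliers = ratio_multipliers,
         ratio_floor_epsilon = ratio_floor_epsilon),
    class = "filter_config"
  )
}

# row-wise statistics that stay numeric(0) on empty matrices
row_stat <- function(m, f) vapply(seq_len(nrow(m)), function(i) f(m[i, ]), 0)

#' Fold-change multiplier for a gene's minimum expression
#'
#' @param min_cpm Numeric vector of per-gene minimum CPM over time.
#' @param cfg A [filter_config()].
#' @return Numeric vector of required max/min multipliers.
#' @export
ratio_multiplier <- function(min_cpm, cfg = filter_config()) {
  cfg$ratio_multipliers[findInterval(min_cpm, cfg$ratio_breaks) + 1]
}

#' Pre-filter genes of very low mean expression or variation
#'
#' Keeps a gene iff its mean CPM over all samples is at least `theta_mean`
#' and its sample variance (denominator n-1, over all samples) is at least
#' `theta_var`. Genes below either threshold carry too little information to
#' cluster.
#'
#' @param cpm CPM tibble (`gene_id` plus sample columns).
#' @param cfg A [filter_config()].
#' @return Character vector of kept gene ids.
#' @export
prefilter_low_info <- function(cpm, cfg = filter_config()) {
  m <- expr_matrix(cpm)
  if (ncol(m) < 2) stop("at least 2 samples required (variance undefined)")
  keep <- rowMeans(m) >= cfg$theta_mean & row_stat(m, var) >= cfg$theta_var
  rownames(m)[keep]
}

#' Strict filter on replicate-averaged time profiles
#'
#' Keeps a gene iff its maximum mean CPM over time strictly exceeds
#' `theta_max` and its max/min ratio (denominator floored at
#' `ratio_floor_epsilon`) strictly exceeds the minimum-dependent multiplier.
#'
#' @param tp A `time_profile` tibble (see [average_replicates()]).
#' @param cfg A [filter_config()].
#' @return Character vector of kept gene ids.
#' @export
strict_filter <- function(tp, cfg = filter_config()) {
  m <- profile_matrix(tp)
  if (nrow(m) == 0) return(character(0))
  mx <- row_stat(m, max)
  mn <- row_stat(m, min)
  ratio <- mx / pmax(mn, cfg$ratio_floor_epsilon)
  keep <- mx > cfg$theta_max & ratio > ratio_multiplier(mn, cfg)
  rownames(m)[keep]
}

#' Apply all four expression filters in order
#'
#' Stage order: mean, variance (per-sample CPM), maximum, max/min ratio
#' (replicate-averaged profile). The report records the survivor count after
#' each stage.
#'
#' @param cpm CPM tibble over all samples of one structure.
#' @param tp Matching replicate-averaged `time_profile`.
#' @param cfg A [filter_config()].
#' @return A `filter_report`: list with `n_input`, a `stages` tibble
#'   (`stage`, `n_kept`) and `kept_gene_ids`.
#' @export
apply_filters <- function(cpm, tp, cfg = filter_config()) {
  genes_cpm <- cpm$gene_id
  genes_tp <- unique(tp$gene_id)
  if (!setequal(genes_cpm, genes_tp)) {
    stop("cpm and time profile gene ids disagree")
  }
  m <- expr_matrix(cpm)
  n_input <- nrow(m)
  if (n_input > 0 && ncol(m) < 2) {
    stop("at least 2 samples required (variance undefined)")
  }

  keep_mean <- rownames(m)[rowMeans(m) >= cfg$theta_mean]
  keep_var <- keep_mean[row_stat(m[keep_mean, , drop = FALSE], var) >= cfg$theta_var]

  pm <- profile_matrix(tp)[keep_var, , drop = FALSE]
  mx <- row_stat(pm, max)
  mn <- row_stat(pm, min)
  pass_max <- mx > cfg$theta_max
  keep_max <- rownames(pm)[pass_max]
  mn <- mn[pass_max]
  mx <- mx[pass_max]
  ratio <- mx / pmax(mn, cfg$ratio_floor_epsilon)
  keep_ratio <- keep_max[ratio > ratio_multiplier(mn, cfg)]

  if (n_input == 0) {
    keep_mean <- keep_var <- keep_max <- keep_ratio <- character(0)
  }
  structure(
    list(
      n_input = n_input,
      stages = tibble::tibble(
        stage = c("mean", "variance", "max", "ratio"),
        n_kept = c(length(keep_mean), length(keep_var),
                   length(keep_max), length(keep_ratio))
      ),
      kept_gene_ids = keep_ratio,
      config = cfg
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Expression filter report\n")
  cat("  input genes:", x$n_input, "\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  after %-8s %d\n", x$stages$stage[i], x$stages$n_kept[i]))
  }
  invisible(x)
}

#' @rdname apply_filters
#' @param x A `filter_report`.
#' @param ... Unused.
#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(stage = "input", n_kept = x$n_input),
    x$stages
  )
}

#' Write a filter report to TSV
#'
#' Writes per-stage survivor counts followed by the kept gene ids.
#'
#' @param report A `filter_report`.
#' @param path Output path.
#' @return The report, invisibly.
#' @export
write_filter_report <- function(report, path) {
  readr::write_tsv(tidy(report), path, progress = FALSE)
  readr::write_lines(c("# kept_gene_ids", report$kept_gene_ids), path, append = TRUE)
  invisible(report)
}
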