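#' Read a sample metadata table
#'
#' The metadata TSV must contain the columns `sample_id`, `structure`
#' (`"jaw"` or `"limb"`), `time_label` (e.g. `"5dpi"`, `"3hpa"`),
#' `time_hours` (hours since injury, intact = 0) and `replicate`.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A tibble with one row per sample, validated.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(md)
}

#' Validate a sample metadata tibble
#'
#' @param metadata A data frame of per-sample metadata.
#' @return The metadata as a tibble, invisibly checked.
#' @export
validate_metadata <- function(metadata) {
  md <- tibble::as_tibble(metadata)
  required <- c("sample_id", "structure", "time_label", "time_hours", "replicate")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  if (!all(md$structure %in% c("jaw", "limb"))) {
    stop("structure must be 'jaw' or 'limb'")
  }
  if (any(md$time_hours < 0)) stop("time_hours must be non-negative")
  if (any(md$replicate < 1 | md$replicate != round(md$replicate))) {
    stop("replicate must be a positive integer")
  }
  for (s in unique(md$structure)) {
    if (!any(md$time_hours[md$structure == s] == 0)) {
      stop("structure '", s, "' has no intact (time_hours = 0) samples")
    }
  }
  md
}

#' Read a gene-level count matrix
#'
#' Reads a TSV whose first column holds gene identifiers and whose remaining
#' columns are integer counts named by `sample_id`. Columns are reordered to
#' match the metadata row order.
#'
#' @param path Path to the counts TSV.
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @return A tibble: `gene_id` plus one integer column per sample.
#' @export
read_counts <- function(path, metadata) {
  metadata <- validate_metadata(metadata)
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(counts)[1] <- "gene_id"
  validate_counts(counts, metadata)
}

#' Validate a counts tibble against sample metadata
#'
#' @param counts Tibble with `gene_id` plus one column per sample.
#' @param metadata Sample metadata tibble.
#' @return The counts tibble with sample columns in metadata order.
#' @export
validate_counts <- function(counts, metadata) {
  counts <- tibble::as_tibble(counts)
  if (names(counts)[1] != "gene_id") names(counts)[1] <- "gene_id"
  if (anyDuplicated(counts$gene_id)) {
    stop("duplicate gene id(s): ",
         paste(unique(counts$gene_id[duplicated(counts$gene_id)]), collapse = ", "))
  }
  sample_cols <- setdiff(names(counts), "gene_id")
  extra <- setdiff(sample_cols, metadata$sample_id)
  absent <- setdiff(metadata$sample_id, sample_cols)
  if (length(extra) > 0) {
    stop("sample(s) in counts absent from metadata: ", paste(extra, collapse = ", "))
  }
  if (length(absent) > 0) {
    stop("sample(s) in metadata absent from counts: ", paste(absent, collapse = ", "))
  }
  m <- as.matrix(counts[metadata$sample_id])
  if (!is.numeric(m)) stop("counts must be numeric")
  if (any(is.na(m))) stop("counts contain missing values")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(m != round(m))) stop("counts must be integral")
  out <- counts[metadata$sample_id]
  out[] <- lapply(out, as.integer)
  dplyr::bind_cols(counts["gene_id"], tibble::as_tibble(out))
}

#' Write a counts or expression table to TSV
#'
#' @param x Tibble with `gene_id` first.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

# gene_id-first tibble -> numeric matrix with gene rownames
expr_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  rownames(m) <- x$gene_id
  m
}

#' Counts-per-million normalisation
#'
#' Scales each sample's counts by its library size (total counts) times 1e6.
#' No between-sample scaling factors are applied: CPM here is plain
#' library-size scaling, so every column of the result sums to one million.
#'
#' @param counts Tibble with `gene_id` plus integer sample columns.
#' @return A tibble of the same shape holding CPM values.
#' @export
compute_cpm <- function(counts) {
  m <- expr_matrix(counts)
  libs <- colSums(m)
  zero <- names(libs)[libs == 0]
  if (length(zero) > 0) {
    stop("zero library size for sample(s): ", paste(zero, collapse = ", "))
  }
  cpm <- sweep(m, 2, libs, "/") * 1e6
  dplyr::bind_cols(counts["gene_id"], tibble::as_tibble(cpm))
}

#' Collapse replicates into a per-time expression profile
#'
#' Averages CPM values over replicates at each time point for one structure,
#' returning a long tibble ordered by ascending time.
#'
#' @param cpm CPM tibble (see [compute_cpm()]).
#' @param metadata Sample metadata tibble.
#' @param structure `"jaw"` or `"limb"`.
#' @return A `time_profile`: tibble with columns `gene_id`, `time_hours`,
#'   `value` (mean CPM over replicates), carrying the structure as an
#'   attribute.
#' @export
average_replicates <- function(cpm, metadata, structure) {
  metadata <- validate_metadata(metadata)
  md <- dplyr::filter(metadata, .data$structure == !!structure)
  if (nrow(md) == 0) {
    stop("no samples for structure '", structure, "'")
  }
  m <- expr_matrix(cpm)[, md$sample_id, drop = FALSE]
  times <- sort(unique(md$time_hours))
  means <- vapply(times, function(t) {
    rowMeans(m[, md$sample_id[md$time_hours == t], drop = FALSE])
  }, numeric(nrow(m)))
  tp <- tibble::tibble(
    gene_id = rep(rownames(m), times = length(times)),
    time_hours = rep(times, each = nrow(m)),
    value = as.vector(means)
  )
  new_time_profile(tp, structure)
}

#' Construct a time-profile tibble
#'
#' @param x Tibble with columns `gene_id`, `time_hours`, `value`.
#' @param structure `"jaw"` or `"limb"`.
#' @return The validated `time_profile` tibble.
#' @export
new_time_profile <- function(x, structure) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("gene_id", "time_hours", "value") %in% names(x)))
  times <- sort(unique(x$time_hours))
  if (any(diff(times) <= 0)) stop("time points must be strictly increasing")
  if (any(x$value < 0)) stop("profile values must be non-negative")
  x <- dplyr::arrange(x, .data$time_hours, .data$gene_id)
  attr(x, "structure") <- structure
  class(x) <- c("time_profile", class(x))
  x
}

# long profile tibble -> genes x times matrix (value_col in z or value space)
profile_matrix <- function(tp, value_col = "value") {
  times <- sort(unique(tp$time_hours))
  wide <- tidyr::pivot_wider(
    tp[, c("gene_id", "time_hours", value_col)],
    names_from = "time_hours", values_from = dplyr::all_of(value_col)
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

profile_times <- function(tp) sort(unique(tp$time_hours))

profile_structure <- function(tp) attr(tp, "structure")

#' Restrict a time profile to a gene set
#'
#' @param tp A `time_profile` (or `z_profile`) tibble.
#' @param gene_ids Character vector of genes to keep.
#' @return The subsetted profile with attributes preserved.
#' @export
subset_profile <- function(tp, gene_ids) {
  out <- tp[tp$gene_id %in% gene_ids, , drop = FALSE]
  attributes(out)$structure <- attr(tp, "structure")
  class(out) <- class(tp)
  out
}
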