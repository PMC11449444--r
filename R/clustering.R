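#' Standardize time profiles to per-gene z-scores
#'
#' Converts each gene's mean-CPM trajectory into z-scores over time
#' (mean 0, standard deviation 1 with denominator n-1), so that clustering
#' compares profile shapes rather than absolute expression levels.
#'
#' @param tp A `time_profile` tibble (see [average_replicates()]).
#' @return A `z_profile`: long tibble with columns `gene_id`, `time_hours`,
#'   `z`, carrying the structure attribute.
#' @export
zscore_profiles <- function(tp) {
  m <- profile_matrix(tp)
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  flat <- rownames(m)[s == 0]
  if (length(flat) > 0) {
    stop("zero-variance gene(s) cannot be standardized: ",
         paste(head(flat, 10), collapse = ", "),
         if (length(flat) > 10) " ..." else "")
  }
  z <- (m - mu) / s
  times <- as.numeric(colnames(z))
  out <- tibble::tibble(
    gene_id = rep(rownames(z), times = ncol(z)),
    time_hours = rep(times, each = nrow(z)),
    z = as.vector(z)
  )
  out <- dplyr::arrange(out, .data$time_hours, .data$gene_id)
  attr(out, "structure") <- attr(tp, "structure")
  class(out) <- c("z_profile", class(out))
  out
}

# z_profile -> genes x times matrix
z_matrix <- function(zp) profile_matrix(zp, value_col = "z")

# Total within-cluster sum of squared Euclidean distances for a matrix,
# clustered at k (k = 1 needs no clustering).
within_ss <- function(X, k, n_init, max_iter = 100L) {
  if (k == 1) {
    mu <- colMeans(X)
    return(sum(sweep(X, 2, mu)^2))
  }
  kmeans_lloyd_cpp(X, k, n_init, max_iter)$inertia
}

#' Select the number of clusters by the gap statistic
#'
#' For each candidate k, the log within-cluster dispersion of the data is
#' compared to its expectation under B reference data sets drawn uniformly
#' over the per-dimension range box of the observed profiles:
#' `Gap(k) = mean_b log(W*_kb) - log(W_k)`. The selected k is the smallest k
#' with `Gap(k) >= Gap(k+1) - s_{k+1}`, where
#' `s_k = sd_b(log W*_kb) * sqrt(1 + 1/B)`; if the rule never fires within
#' the candidate range, the k maximising the gap is returned.
#'
#' @param zp A `z_profile` (see [zscore_profiles()]).
#' @param k_range Integer vector of candidate k (default `1:10`).
#' @param B Number of uniform reference data sets (default 50, minimum 10).
#' @param seed Integer seed controlling reference draws and k-means restarts.
#' @param n_init k-means++ restarts per clustering (default 5; reference
#'   clusterings need only a good, not optimal, dispersion estimate).
#' @return A `gap_result` with the gap curve, `s_k`, and the selected
#'   `k_star`; see [tidy.gap_result()] and [glance.gap_result()].
#' @export
select_k_gap <- function(zp, k_range = 1:10, B = 50, seed = 1L, n_init = 5L) {
  X <- z_matrix(zp)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= nrow(X)) {
    stop("max(k_range) must be smaller than the number of genes")
  }
  if (B < 10) stop("B must be at least 10")
  set.seed(seed)

  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  refs <- lapply(seq_len(B), function(b) {
    R <- matrix(runif(length(X)), nrow(X), ncol(X))
    sweep(sweep(R, 2, hi - lo, "*"), 2, lo, "+")
  })

  log_w <- vapply(k_range, function(k) log(within_ss(X, k, n_init)), 0)
  log_w_ref <- vapply(k_range, function(k) {
    vapply(refs, function(R) log(within_ss(R, k, n_init)), 0)
  }, numeric(B))
  gap <- colMeans(log_w_ref) - log_w
  sd_ref <- sqrt(colMeans(sweep(log_w_ref, 2, colMeans(log_w_ref))^2))
  s_k <- sd_ref * sqrt(1 + 1 / B)

  k_star <- NA_integer_
  for (i in seq_along(k_range)[-length(k_range)]) {
    if (k_range[i + 1] == k_range[i] + 1 && gap[i] >= gap[i + 1] - s_k[i + 1]) {
      k_star <- k_range[i]
      break
    }
  }
  if (is.na(k_star)) k_star <- k_range[which.max(gap)]

  structure(
    list(table = tibble::tibble(k = k_range, log_w = log_w,
                                gap = gap, s_k = s_k),
         k_star = k_star, B = B, seed = seed, n_init = n_init),
    class = "gap_result"
  )
}

#' @rdname select_k_gap
#' @param x A `gap_result`.
#' @param ... Unused.
#' @export
tidy.gap_result <- function(x, ...) x$table

#' @rdname select_k_gap
#' @export
glance.gap_result <- function(x, ...) {
  tibble::tibble(k_star = x$k_star, B = x$B, seed = x$seed)
}

#' @rdname select_k_gap
#' @param object A `gap_result`.
#' @export
autoplot.gap_result <- function(object, ...) {
  tb <- object$table
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$k, y = .data$gap)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$gap - .data$s_k,
                                        ymax = .data$gap + .data$s_k),
                           width = 0.2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters k", y = "Gap(k)",
                  title = paste0("Gap statistic (k* = ", object$k_star, ")")) +
    ggplot2::theme_minimal()
}

#' @export
print.gap_result <- function(x, ...) {
  cat("Gap statistic over k =", paste(range(x$table$k), collapse = "-"),
      " (B =", x$B, ")\n  selected k* =", x$k_star, "\n")
  invisible(x)
}

#' k-means clustering of standardized time profiles
#'
#' Lloyd iterations from k-means++ starts, best of `n_init` restarts by
#' within-cluster sum of squares; deterministic given `seed`. A cluster that
#' empties during iteration is re-seeded at the point farthest from its
#' centroid. Each gene receives a cluster score: the Pearson correlation of
#' its z-profile with its cluster centroid.
#'
#' @param zp A `z_profile`.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 25).
#' @return A `cluster_result` with fields `k`, `assignment` (tibble
#'   `gene_id`, `cluster`, `score`), `centroids` (k x times matrix in
#'   z-space), `times`, `inertia`, `seed`.
#' @export
cluster_kmeans <- function(zp, k, seed = 1L, n_init = 25L) {
  X <- z_matrix(zp)
  if (k < 1 || k > nrow(X)) stop("k must be between 1 and the number of genes")
  set.seed(seed)
  fit <- kmeans_lloyd_cpp(X, as.integer(k), as.integer(n_init), 100L)
  centroids <- fit$centers
  colnames(centroids) <- colnames(X)
  score <- vapply(seq_len(nrow(X)), function(i) {
    cen <- centroids[fit$cluster[i], ]
    if (sd(cen) == 0) return(0)
    cor(X[i, ], cen)
  }, 0)
  structure(
    list(k = as.integer(k),
         assignment = tibble::tibble(gene_id = rownames(X),
                                     cluster = fit$cluster,
                                     score = score),
         centroids = centroids,
         times = as.numeric(colnames(X)),
         inertia = fit$inertia,
         seed = seed, n_init = n_init,
         structure = attr(zp, "structure")),
    class = "cluster_result"
  )
}

#' @rdname cluster_kmeans
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) x$assignment

#' @rdname cluster_kmeans
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(k = x$k, n_genes = nrow(x$assignment),
                 inertia = x$inertia, seed = x$seed)
}

#' @rdname cluster_kmeans
#' @param object A `cluster_result`.
#' @export
autoplot.cluster_result <- function(object, ...) {
  cen <- tibble::as_tibble(object$centroids)
  cen$cluster <- seq_len(object$k)
  long <- tidyr::pivot_longer(cen, -"cluster",
                              names_to = "time_hours", values_to = "z")
  long$time_hours <- as.numeric(long$time_hours)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_hours, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "time (h)", y = "centroid z-score") +
    ggplot2::theme_minimal()
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("k-means clustering of", nrow(x$assignment), "genes into", x$k,
      "clusters\n  inertia:", format(x$inertia), " seed:", x$seed, "\n")
  invisible(x)
}

#' Select genes of interest by cluster score
#'
#' Keeps genes whose Pearson correlation with their cluster centroid
#' strictly exceeds `theta_r`; these are the genes whose temporal profile
#' the clustering represents well.
#'
#' @param cr A `cluster_result`.
#' @param theta_r Score threshold (default 0.75, strict inequality).
#' @return Character vector of gene ids.
#' @export
select_genes_of_interest <- function(cr, theta_r = 0.75) {
  a <- cr$assignment
  a$gene_id[!is.na(a$score) & a$score > theta_r]
}
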