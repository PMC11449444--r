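# Shared fixture builders. Everything is generated in code at test time.

std1 <- function(v) (v - mean(v)) / sd(v)

# jaw-like metadata: 2 replicates at each of 4 time points
tiny_metadata <- function(structure = "jaw", times = c(0, 120, 336, 840),
                          reps = 2) {
  grid <- expand.grid(replicate = seq_len(reps), time_hours = times)
  tibble::tibble(
    sample_id = sprintf("%s_t%g_r%d", structure, grid$time_hours, grid$replicate),
    structure = structure,
    time_label = ifelse(grid$time_hours == 0, "intact",
                        paste0(grid$time_hours / 24, "dpi")),
    time_hours = grid$time_hours,
    replicate = grid$replicate
  )
}

# counts tibble from a genes x samples matrix
counts_from_matrix <- function(m, metadata,
                               gene_ids = sprintf("g%03d", seq_len(nrow(m)))) {
  colnames(m) <- metadata$sample_id
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), tibble::as_tibble(m))
}

random_counts <- function(n_genes, metadata, seed = 1, lambda = 60) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * nrow(metadata), lambda), n_genes)
  counts_from_matrix(m, metadata)
}

# z-profile straight from a genes x times matrix (rows need not be
# re-standardised; clustering operates on whatever profile it is given)
zp_from_matrix <- function(Z, times, structure = "jaw",
                           gene_ids = sprintf("g%03d", seq_len(nrow(Z)))) {
  zp <- tibble::tibble(
    gene_id = rep(gene_ids, times = length(times)),
    time_hours = rep(times, each = nrow(Z)),
    z = as.vector(Z)
  )
  attr(zp, "structure") <- structure
  class(zp) <- c("z_profile", class(zp))
  zp
}

# direct long-table lookup of a profile value
profile_matrix_oracle <- function(tp, gene, time) {
  tp$value[tp$gene_id == gene & tp$time_hours == time]
}

# well-separated standardized archetype centers on the jaw grid
planted_centers <- function() {
  rbind(std1(c(0, 1, 0, 0)),     # peak at 120 h
        std1(c(0, 0, 1, 0)),     # peak at 336 h
        std1(c(0.1, 0.35, 0.65, 0.9)), # steady rise
        std1(c(1, 0, 0, 0)),     # peak at intact
        std1(c(1, 0.6, 0.3, 0))) # steady fall
}

# n genes drawn around the first k planted centers with isotropic noise,
# rows re-standardized so they are genuine z-profiles
planted_zp <- function(k, n, sigma, seed, times = c(0, 120, 336, 840)) {
  set.seed(seed)
  centers <- planted_centers()[seq_len(k), , drop = FALSE]
  idx <- rep_len(seq_len(k), n)
  Z <- centers[idx, , drop = FALSE] +
    matrix(rnorm(n * length(times), 0, sigma), n)
  Z <- t(apply(Z, 1, std1))
  zp <- zp_from_matrix(Z, times)
  attr(zp, "planted") <- idx
  zp
}
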