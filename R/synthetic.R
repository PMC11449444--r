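#' Standard sampling grids (hours since injury)
#'
#' The jaw grid covers intact, 5, 14 and 35 days post injury; the limb grid
#' covers intact, 3/6/12 hours and 1/3/7/14/21/28 days post amputation.
#'
#' @return Numeric vector of hours.
#' @export
jaw_times <- function() c(0, 120, 336, 840)

#' @rdname jaw_times
#' @export
limb_times <- function() c(0, 3, 6, 12, 24, 72, 168, 336, 504, 672)

# human-readable label for a time in hours
time_label_for <- function(hours, structure) {
  if (hours == 0) return("intact")
  if (structure == "jaw") return(paste0(hours / 24, "dpi"))
  if (hours < 24) paste0(hours, "hpa") else paste0(hours / 24, "dpa")
}

#' Default temporal archetypes for simulation
#'
#' Four planted expression archetypes per structure: an early peak
#' (gaussian bump at an early regeneration time), a steady `general rise`
#' (logistic), uninformative `flat` genes, and an `intact_peak` pattern that
#' is highest before injury (exercising the unassigned/down-regulated
#' rule). The limb default adds mid and late peaks so every limb phase bin
#' is populated.
#'
#' @param structure `"jaw"` or `"limb"`.
#' @return Tibble with columns `label`, `shape`, `peak_time`, `width`,
#'   `midpoint`, `slope`, `n_genes`, `baseline_cpm`, `amplitude_fold`.
#' @export
default_archetypes <- function(structure = c("jaw", "limb")) {
  structure <- match.arg(structure)
  if (structure == "jaw") {
    tibble::tribble(
      ~label,        ~shape,          ~peak_time, ~width, ~midpoint, ~slope, ~n_genes, ~baseline_cpm, ~amplitude_fold,
      "peak_5dpi",   "gaussian_peak", 120,        60,     NA,        NA,     100,      2,             25,
      "peak_14dpi",  "gaussian_peak", 336,        90,     NA,        NA,     100,      2,             25,
      "rise",        "logistic_rise", NA,         NA,     420,       120,    100,      2,             25,
      "flat",        "flat",          NA,         NA,     NA,        NA,     50,       50,            1,
      "intact_peak", "intact_peak",   NA,         40,     NA,        NA,     50,       2,             25
    )
  } else {
    tibble::tribble(
      ~label,        ~shape,          ~peak_time, ~width, ~midpoint, ~slope, ~n_genes, ~baseline_cpm, ~amplitude_fold,
      "peak_early",  "gaussian_peak", 3,          3,      NA,        NA,     100,      2,             25,
      "peak_mid",    "gaussian_peak", 168,        80,     NA,        NA,     100,      2,             25,
      "peak_late",   "gaussian_peak", 504,        90,     NA,        NA,     100,      2,             25,
      "rise",        "logistic_rise", NA,         NA,     360,       110,    100,      2,             25,
      "flat",        "flat",          NA,         NA,     NA,        NA,     50,       50,            1,
      "intact_peak", "intact_peak",   NA,         30,     NA,        NA,     50,       2,             25
    )
  }
}

# expected CPM trajectory of one archetype row over `times`
archetype_mean_cpm <- function(row, times) {
  A <- row$amplitude_fold
  b <- row$baseline_cpm
  shape <- switch(
    row$shape,
    gaussian_peak = 1 + (A - 1) * exp(-(times - row$peak_time)^2 / (2 * row$width^2)),
    logistic_rise = 1 + (A - 1) / (1 + exp(-(times - row$midpoint) / row$slope)),
    flat = rep(1, length(times)),
    intact_peak = 1 + (A - 1) * exp(-times^2 / (2 * row$width^2)),
    stop("unknown archetype shape: ", row$shape)
  )
  b * shape
}

#' Simulation configuration
#'
#' @param structure `"jaw"` or `"limb"`.
#' @param times Hours grid including 0; defaults to the structure's grid.
#' @param replicates_per_time Biological replicates per time point
#'   (default 2, matching a two-animal design with no pooling).
#' @param archetypes Archetype tibble (see [default_archetypes()]).
#' @param dispersion Negative-binomial dispersion phi (variance =
#'   m + phi m^2); 0 gives Poisson counts. Default 0.05.
#' @param library_size_range Range from which per-sample library sizes are
#'   drawn uniformly. Default 8-12 million.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(structure = c("jaw", "limb"), times = NULL,
                             replicates_per_time = 2,
                             archetypes = NULL,
                             dispersion = 0.05,
                             library_size_range = c(8e6, 12e6),
                             seed = 1L) {
  structure <- match.arg(structure)
  if (is.null(times)) {
    times <- if (structure == "jaw") jaw_times() else limb_times()
  }
  times <- sort(unique(times))
  if (!0 %in% times) stop("times must include 0 (the intact condition)")
  if (is.null(archetypes)) archetypes <- default_archetypes(structure)
  archetypes <- tibble::as_tibble(archetypes)
  stopifnot(all(archetypes$n_genes >= 1),
            all(archetypes$baseline_cpm > 0),
            all(archetypes$amplitude_fold >= 1),
            dispersion >= 0, replicates_per_time >= 1,
            length(library_size_range) == 2, all(library_size_range > 0))
  base::structure(
    list(structure = structure, times = times,
         replicates_per_time = as.integer(replicates_per_time),
         archetypes = archetypes, dispersion = dispersion,
         library_size_range = library_size_range, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a time-course count matrix with planted temporal archetypes
#'
#' Each gene's expected CPM trajectory follows its archetype; the count in
#' sample s is drawn negative-binomially with mean
#' `mu_g(t) * library_size(s) / 1e6` and dispersion `phi`
#' (`phi = 0` gives Poisson counts). Deterministic given the config seed.
#'
#' The planted truth records, for every gene, the phase label its
#' *noiseless* standardized trajectory receives under the package's
#' centroid-classification rule, so recovery experiments compare like with
#' like (flat genes, which cannot be standardized, get `NA`).
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `counts` (tibble, `gene_id` + sample columns),
#'   `metadata` (sample tibble), `truth` (tibble `gene_id`, `archetype`,
#'   `expected_phase`).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  times <- cfg$times
  reps <- cfg$replicates_per_time
  md <- tidyr::expand_grid(time_hours = times, replicate = seq_len(reps))
  md <- tibble::tibble(
    sample_id = sprintf("%s_t%g_r%d", cfg$structure, md$time_hours, md$replicate),
    structure = cfg$structure,
    time_label = vapply(md$time_hours, time_label_for, "", structure = cfg$structure),
    time_hours = md$time_hours,
    replicate = md$replicate
  )
  n_samples <- nrow(md)
  libs <- round(runif(n_samples, cfg$library_size_range[1],
                      cfg$library_size_range[2]))

  pcfg <- phase_config(cfg$structure)
  gene_rows <- list()
  truth_rows <- list()
  counter <- 0
  for (a in seq_len(nrow(cfg$archetypes))) {
    row <- cfg$archetypes[a, ]
    mu_t <- archetype_mean_cpm(row, times)
    expected <- if (sd(mu_t) == 0) {
      NA_character_
    } else {
      classify_centroid((mu_t - mean(mu_t)) / sd(mu_t), times, pcfg)
    }
    mu_sample <- mu_t[match(md$time_hours, times)] * libs / 1e6
    for (g in seq_len(row$n_genes)) {
      counter <- counter + 1
      gid <- sprintf("%s_g%04d", row$label, g)
      counts <- if (cfg$dispersion == 0) {
        rpois(n_samples, mu_sample)
      } else {
        rnbinom(n_samples, mu = mu_sample, size = 1 / cfg$dispersion)
      }
      gene_rows[[counter]] <- counts
      truth_rows[[counter]] <- tibble::tibble(
        gene_id = gid, archetype = row$label, expected_phase = expected
      )
    }
  }
  truth <- dplyr::bind_rows(truth_rows)
  m <- do.call(rbind, gene_rows)
  colnames(m) <- md$sample_id
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = truth$gene_id),
                             tibble::as_tibble(m))
  list(counts = counts, metadata = md, truth = truth)
}

#' Archetype shape catalogues for paired two-structure simulation
#'
#' Unlike [default_archetypes()], the catalogue carries no gene counts: it
#' only maps archetype labels to trajectory shapes. The limb catalogue
#' splits the early response into a transient 3 h peak (back to baseline by
#' 1 day) and a slower 1-day peak, both falling in the `'early peak'` phase
#' bin.
#'
#' @param structure `"jaw"` or `"limb"`.
#' @return Tibble of archetype shape parameters.
#' @export
archetype_catalog <- function(structure = c("jaw", "limb")) {
  structure <- match.arg(structure)
  if (structure == "jaw") {
    dplyr::select(default_archetypes("jaw"), -"n_genes")
  } else {
    tibble::tribble(
      ~label,        ~shape,          ~peak_time, ~width, ~midpoint, ~slope, ~baseline_cpm, ~amplitude_fold,
      "peak_3hpa",   "gaussian_peak", 3,          3,      NA,        NA,     2,             25,
      "peak_1dpa",   "gaussian_peak", 24,         18,     NA,        NA,     2,             25,
      "peak_mid",    "gaussian_peak", 168,        80,     NA,        NA,     2,             25,
      "peak_late",   "gaussian_peak", 504,        90,     NA,        NA,     2,             25,
      "rise",        "logistic_rise", NA,         NA,     360,       110,    2,             25,
      "flat",        "flat",          NA,         NA,     NA,        NA,     50,            1,
      "intact_peak", "intact_peak",   NA,         30,     NA,        NA,     2,             25
    )
  }
}

#' Default jaw/limb archetype pairing for a shared gene universe
#'
#' Assigns every gene a temporal archetype in each structure, emulating the
#' study's cross-structure relationships: most early jaw genes are early in
#' the limb (a majority as 3 h transients), mid jaw genes split between the
#' early and mid limb response, steadily rising jaw genes sit mostly in the
#' mid limb phase, and a fraction of genes is informative in only one
#' structure (flat in the other).
#'
#' @return Tibble with columns `jaw`, `limb`, `n` (genes per combination).
#' @export
default_gene_pairing <- function() {
  tibble::tribble(
    ~jaw,          ~limb,         ~n,
    "peak_5dpi",   "peak_3hpa",   40,
    "peak_5dpi",   "peak_1dpa",   25,
    "peak_5dpi",   "peak_mid",    10,
    "peak_5dpi",   "flat",        25,
    "peak_14dpi",  "peak_3hpa",   25,
    "peak_14dpi",  "peak_1dpa",   20,
    "peak_14dpi",  "peak_mid",    35,
    "peak_14dpi",  "flat",        20,
    "rise",        "peak_mid",    50,
    "rise",        "rise",        25,
    "rise",        "flat",        25,
    "flat",        "flat",        60,
    "flat",        "peak_3hpa",   10,
    "flat",        "peak_mid",    20,
    "flat",        "rise",        10,
    "intact_peak", "intact_peak", 30,
    "intact_peak", "flat",        20,
    "flat",        "peak_late",   30
  )
}

# counts for one structure given per-gene archetype labels from a catalogue
simulate_structure_counts <- function(labels, catalog, structure, times,
                                      replicates_per_time, dispersion,
                                      library_size_range, seed,
                                      gene_ids) {
  set.seed(seed)
  grid <- tidyr::expand_grid(time_hours = times,
                             replicate = seq_len(replicates_per_time))
  labels_t <- vapply(grid$time_hours, time_label_for, "", structure = structure)
  md <- tibble::tibble(
    sample_id = sprintf("%s_t%g_r%d", structure, grid$time_hours, grid$replicate),
    structure = structure,
    time_label = labels_t,
    time_hours = grid$time_hours,
    replicate = grid$replicate
  )
  libs <- round(runif(nrow(md), library_size_range[1], library_size_range[2]))
  pcfg <- phase_config(structure)
  mu_by_arch <- lapply(split(catalog, catalog$label), function(row) {
    archetype_mean_cpm(row, times)
  })
  phase_by_arch <- vapply(mu_by_arch, function(mu) {
    if (sd(mu) == 0) NA_character_
    else classify_centroid((mu - mean(mu)) / sd(mu), times, pcfg)
  }, "")
  m <- matrix(0, length(labels), nrow(md), dimnames = list(gene_ids, md$sample_id))
  for (i in seq_along(labels)) {
    mu <- mu_by_arch[[labels[i]]][match(md$time_hours, times)] * libs / 1e6
    m[i, ] <- if (dispersion == 0) rpois(nrow(md), mu)
              else rnbinom(nrow(md), mu = mu, size = 1 / dispersion)
  }
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                             tibble::as_tibble(m))
  list(counts = counts, metadata = md,
       expected_phase = unname(phase_by_arch[labels]))
}

#' Simulate paired jaw and limb count matrices over one gene universe
#'
#' Generates the two structures' time courses for a single set of gene
#' identifiers whose jaw and limb archetypes are linked by a pairing table,
#' so cross-structure shared-gene and overlap statistics can be exercised
#' with known ground truth.
#'
#' @param pairing Pairing tibble (see [default_gene_pairing()]).
#' @param replicates_per_time Replicates per time point (default 2).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param library_size_range Per-sample library-size range (default 8-12M).
#' @param seed Integer seed (jaw and limb use derived sub-seeds).
#' @return A list with `jaw` and `limb` (each `counts` + `metadata`) and
#'   `truth` (tibble `gene_id`, `jaw_archetype`, `limb_archetype`,
#'   `jaw_expected_phase`, `limb_expected_phase`).
#' @export
simulate_paired_counts <- function(pairing = default_gene_pairing(),
                                   replicates_per_time = 2,
                                   dispersion = 0.05,
                                   library_size_range = c(8e6, 12e6),
                                   seed = 1L) {
  pairing <- tibble::as_tibble(pairing)
  stopifnot(all(c("jaw", "limb", "n") %in% names(pairing)),
            all(pairing$n >= 1))
  jaw_labels <- rep(pairing$jaw, pairing$n)
  limb_labels <- rep(pairing$limb, pairing$n)
  n <- length(jaw_labels)
  gene_ids <- sprintf("g%05d", seq_len(n))

  jaw <- simulate_structure_counts(
    jaw_labels, archetype_catalog("jaw"), "jaw", jaw_times(),
    replicates_per_time, dispersion, library_size_range,
    seed = seed + 11L, gene_ids = gene_ids)
  limb <- simulate_structure_counts(
    limb_labels, archetype_catalog("limb"), "limb", limb_times(),
    replicates_per_time, dispersion, library_size_range,
    seed = seed + 23L, gene_ids = gene_ids)

  truth <- tibble::tibble(
    gene_id = gene_ids,
    jaw_archetype = jaw_labels,
    limb_archetype = limb_labels,
    jaw_expected_phase = jaw$expected_phase,
    limb_expected_phase = limb$expected_phase
  )
  list(jaw = list(counts = jaw$counts, metadata = jaw$metadata),
       limb = list(counts = limb$counts, metadata = limb$metadata),
       truth = truth)
}

#' Simulate a defect-morphometry cohort
#'
#' Emulates the macroscopic closure dynamics of a lateral mandible
#' resection: a rapid contraction of the defect within the first day, a
#' plateau, a second closure phase from 7 dpi reaching zero area by 35 dpi,
#' and a stump-displacement angle that dips to a minimum at 35 dpi before
#' recovering. Defect areas at times where the closure curve is zero are
#' recorded as explicit zeros (tissue continuity observed), not noise.
#'
#' @param n_animals Animals followed at each early/mid time point (default 6).
#' @param n_animals_late Animals at 90 dpi (default 3).
#' @param times_dpi Observation days (default `c(0,1,3,5,7,14,21,35,90)`).
#' @param area_knots Piecewise-linear closure curve, tibble or matrix of
#'   (time_dpi, area_mm2).
#' @param angle_knots Piecewise-linear angle trajectory (time_dpi, degrees).
#' @param defect_length_mm Resected fragment length (default 5).
#' @param hemi_perimeter_mm,full_perimeter_mm Cohort mean perimeters at
#'   0 dpi (defaults 11.55 and 24.15, the scale of a 12 cm juvenile).
#' @param perimeter_sd Between-animal perimeter s.d. (default 0.4).
#' @param perimeter_ratio_knots Resected/intact full-perimeter ratio over
#'   time, (time_dpi, ratio); the default ends at 0.908 at 90 dpi.
#' @param noise_sd Measurement noise s.d. for areas (mm^2) and perimeters
#'   (mm); angle noise is `10 * noise_sd` degrees. Default 0.3.
#' @param seed Integer seed.
#' @return Tibble with one row per animal and time point: `animal_id`,
#'   `time_dpi`, `defect_area_mm2`, `angle_deg`, `defect_length`,
#'   `hemi_perimeter`, `full_perimeter`, `perimeter_intact`,
#'   `perimeter_resected`.
#' @export
simulate_morphometry <- function(n_animals = 6, n_animals_late = 3,
                                 times_dpi = c(0, 1, 3, 5, 7, 14, 21, 35, 90),
                                 area_knots = cbind(c(0, 1, 5, 7, 14, 35, 90),
                                                    c(8, 4.8, 4.5, 3.5, 1.2, 0, 0)),
                                 angle_knots = cbind(c(0, 5, 14, 35, 90),
                                                     c(165, 160, 150, 130, 155)),
                                 defect_length_mm = 5,
                                 hemi_perimeter_mm = 11.55,
                                 full_perimeter_mm = 24.15,
                                 perimeter_sd = 0.4,
                                 perimeter_ratio_knots = cbind(c(0, 35, 90),
                                                               c(0.80, 0.96, 0.908)),
                                 noise_sd = 0.3, seed = 1L) {
  if (n_animals < 1) stop("n_animals must be at least 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  area_fun <- function(t) approx(area_knots[, 1], area_knots[, 2], t, rule = 2)$y
  angle_fun <- function(t) approx(angle_knots[, 1], angle_knots[, 2], t, rule = 2)$y
  ratio_fun <- function(t) approx(perimeter_ratio_knots[, 1],
                                  perimeter_ratio_knots[, 2], t, rule = 2)$y

  animals <- tibble::tibble(
    animal_id = sprintf("ax%02d", seq_len(n_animals)),
    defect_length = defect_length_mm,
    hemi_perimeter = hemi_perimeter_mm + rnorm(n_animals, 0, perimeter_sd),
    full_perimeter = full_perimeter_mm + rnorm(n_animals, 0, perimeter_sd)
  )
  grid <- tidyr::expand_grid(animal_id = animals$animal_id, time_dpi = times_dpi)
  # only a subset of the cohort is followed to the final time point
  late <- max(times_dpi)
  keep_late <- animals$animal_id[seq_len(min(n_animals_late, n_animals))]
  grid <- grid[grid$time_dpi != late | grid$animal_id %in% keep_late, ]
  out <- dplyr::left_join(grid, animals, by = "animal_id")

  base_area <- area_fun(out$time_dpi)
  noisy_area <- pmax(0, base_area + rnorm(nrow(out), 0, noise_sd))
  out$defect_area_mm2 <- ifelse(base_area <= 0, 0, noisy_area)
  out$angle_deg <- angle_fun(out$time_dpi) + rnorm(nrow(out), 0, 10 * noise_sd)
  # intact controls keep growing; resected animals converge towards them
  out$perimeter_intact <- out$full_perimeter * (1 + 0.0012 * out$time_dpi) +
    rnorm(nrow(out), 0, noise_sd)
  out$perimeter_resected <- out$perimeter_intact * ratio_fun(out$time_dpi) +
    rnorm(nrow(out), 0, noise_sd)
  out
}
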