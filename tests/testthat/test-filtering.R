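make_cpm_tp <- function(values_by_gene, times = c(0, 120, 336, 840)) {
  # one "replicate" per time point so CPM samples equal the profile
  md <- tiny_metadata(times = times, reps = 1)
  m <- do.call(rbind, values_by_gene)
  cpm <- counts_from_matrix(m, md,
                            gene_ids = sprintf("g%03d", seq_along(values_by_gene)))
  tp <- average_replicates(cpm, md, "jaw")
  list(cpm = cpm, tp = tp)
}

test_that("low-information prefilter applies the mean and variance thresholds", {
  fx <- make_cpm_tp(list(
    c(0.5, 0.5, 0.5, 0.5),   # mean 0.5 < 0.8 -> removed
    c(10, 10, 10, 10),       # variance 0 < 0.4 -> removed
    c(5, 9, 2, 8)            # mean 6, variance 10 -> kept
  ))
  expect_identical(prefilter_low_info(fx$cpm), "g003")
  # hand oracle for the kept gene
  expect_equal(mean(c(5, 9, 2, 8)), 6)
  expect_equal(var(c(5, 9, 2, 8)), 10)

  one_sample <- fx$cpm[, 1:2]
  expect_error(prefilter_low_info(one_sample), "variance undefined")
})

test_that("strict filter applies the max threshold and min-dependent fold rule", {
  fx <- make_cpm_tp(list(
    c(5, 19.9, 8, 6),        # max 19.9, never exceeds 20 -> removed
    c(0.5, 30, 4, 2),        # min 0.5 -> multiplier 5; 30/0.5 = 60 -> kept
    c(6, 11, 7, 8)           # min 6 -> multiplier 2; 11/6 = 1.83 -> removed
  ))
  expect_identical(strict_filter(fx$tp), "g002")

  # the multiplier is a non-increasing step function of the minimum
  expect_equal(ratio_multiplier(c(0.2, 0.99, 1, 4.9, 5, 50)),
               c(5, 5, 3, 3, 2, 2))

  # the epsilon floor protects against zero minima
  fx0 <- make_cpm_tp(list(c(0, 30, 4, 2)))
  expect_identical(strict_filter(fx0$tp), "g001") # 30/0.1 = 300 > 5
})

test_that("threshold boundaries follow the stated strict/weak conventions", {
  cfg <- filter_config(theta_mean = 0.75, theta_var = 0.25, theta_max = 16)
  # mean exactly at the threshold is kept (only "< threshold" is removed)
  fx <- make_cpm_tp(list(c(0.5, 1.0, 0.5, 1.0)))   # mean 0.75, var 1/12
  expect_identical(prefilter_low_info(fx$cpm, filter_config(theta_mean = 0.75,
                                                            theta_var = 1 / 16)),
                   "g001")
  # max exactly at the threshold is removed (must strictly exceed)
  fx16 <- make_cpm_tp(list(c(4, 16, 8, 6)))
  expect_identical(strict_filter(fx16$tp, cfg), character(0))
  # ratio exactly equal to the multiplier is removed
  fx2 <- make_cpm_tp(list(c(12, 24, 13, 14), c(12, 25, 13, 14)))
  expect_identical(strict_filter(fx2$tp), "g002")
})

test_that("staged filtering equals exhaustive per-gene rule evaluation", {
  md <- tiny_metadata()
  set.seed(31)
  m <- matrix(rlnorm(200 * nrow(md), meanlog = 1, sdlog = 1.6), 200)
  cpm <- counts_from_matrix(round(m * 50), md) |> compute_cpm()
  tp <- average_replicates(cpm, md, "jaw")
  rep <- apply_filters(cpm, tp)

  # brute-force oracle: evaluate the four rules independently per gene
  cm <- as.matrix(cpm[-1])
  pm <- sapply(sort(unique(tp$time_hours)), function(t) {
    tp$value[tp$time_hours == t][match(cpm$gene_id, tp$gene_id[tp$time_hours == t])]
  })
  expected <- character(0)
  for (g in seq_len(200)) {
    x <- cm[g, ]
    p <- pm[g, ]
    if (mean(x) < 0.8) next
    if (var(x) < 0.4) next
    if (!(max(p) > 20)) next
    mult <- if (min(p) < 1) 5 else if (min(p) < 5) 3 else 2
    if (!(max(p) / max(min(p), 0.1) > mult)) next
    expected <- c(expected, cpm$gene_id[g])
  }
  expect_setequal(rep$kept_gene_ids, expected)
  expect_true(all(diff(c(rep$n_input, rep$stages$n_kept)) <= 0))

  # idempotence: filtering the survivors again changes nothing
  cpm2 <- dplyr::filter(cpm, gene_id %in% rep$kept_gene_ids)
  tp2 <- subset_profile(tp, rep$kept_gene_ids)
  expect_setequal(apply_filters(cpm2, tp2)$kept_gene_ids, rep$kept_gene_ids)

  # monotonicity: raising any threshold never enlarges the kept set
  for (cfg in list(filter_config(theta_mean = 2),
                   filter_config(theta_var = 2),
                   filter_config(theta_max = 50),
                   filter_config(ratio_multipliers = c(8, 5, 3)))) {
    expect_true(all(apply_filters(cpm, tp, cfg)$kept_gene_ids %in%
                      rep$kept_gene_ids))
  }

  # gene-id mismatch between the two inputs is a consistency error
  expect_error(apply_filters(cpm[-1, ], tp, filter_config()), "disagree")
})

test_that("an empty matrix yields an all-zero report", {
  md <- tiny_metadata(times = c(0, 120), reps = 1)
  cpm <- counts_from_matrix(matrix(numeric(0), 0, 2), md, gene_ids = character(0))
  tp <- new_time_profile(
    tibble::tibble(gene_id = character(0), time_hours = numeric(0),
                   value = numeric(0)), "jaw")
  rep <- apply_filters(cpm, tp)
  expect_equal(rep$n_input, 0)
  expect_equal(rep$stages$n_kept, c(0L, 0L, 0L, 0L))
  expect_length(rep$kept_gene_ids, 0)
})
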