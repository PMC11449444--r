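test_that("count simulation is deterministic and near-noiseless in the Poisson limit", {
  cfg <- synthetic_config("jaw", seed = 5)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$counts), sum(cfg$archetypes$n_genes))
  expect_equal(nrow(s1$metadata), 2 * length(jaw_times()))

  # phi = 0, deep sequencing: empirical CPM within 1% of truth everywhere
  arch <- tibble::tibble(label = "flat", shape = "flat", peak_time = NA,
                         width = NA, midpoint = NA, slope = NA,
                         n_genes = 20, baseline_cpm = 50, amplitude_fold = 1)
  cfg0 <- synthetic_config("jaw", archetypes = arch, dispersion = 0,
                           library_size_range = c(1e10, 1e10), seed = 2)
  s0 <- simulate_counts(cfg0)
  m <- as.matrix(s0$counts[-1])
  cpmv <- sweep(m, 2, colSums(m), "/") * 1e6
  # all genes are identical flat genes, so expected CPM is 1e6 / 20
  expect_true(all(abs(cpmv / (1e6 / 20) - 1) < 0.01))
})

test_that("simulated counts match negative-binomial moments", {
  # 10,000 draws of one flat gene at fixed mean
  arch <- tibble::tibble(label = "flat", shape = "flat", peak_time = NA,
                         width = NA, midpoint = NA, slope = NA,
                         n_genes = 1, baseline_cpm = 50, amplitude_fold = 1)
  cfg <- synthetic_config("jaw", times = c(0, 24), replicates_per_time = 5000,
                          archetypes = arch, dispersion = 0.05,
                          library_size_range = c(1e6, 1e6), seed = 9)
  s <- simulate_counts(cfg)
  x <- as.numeric(unlist(s$counts[1, -1]))
  m <- 50 # mean counts: 50 CPM at a 1e6 library
  expect_equal(mean(x), m, tolerance = 0.02)
  expect_equal(var(x), m + 0.05 * m^2, tolerance = 0.1)
})

test_that("planted truth labels derive from the noiseless archetype profiles", {
  s <- simulate_counts(synthetic_config("jaw", seed = 3))
  want <- c(peak_5dpi = "5 dpi peak", peak_14dpi = "14 dpi peak",
            rise = "general rise", intact_peak = "unassigned")
  lab <- unique(s$truth[, c("archetype", "expected_phase")])
  for (a in names(want)) {
    expect_equal(lab$expected_phase[lab$archetype == a], unname(want[[a]]))
  }
  expect_true(all(is.na(lab$expected_phase[lab$archetype == "flat"])))

  sl <- simulate_counts(synthetic_config("limb", seed = 3))
  labl <- unique(sl$truth[, c("archetype", "expected_phase")])
  expect_equal(labl$expected_phase[labl$archetype == "peak_early"], "early peak")
  expect_equal(labl$expected_phase[labl$archetype == "peak_mid"], "mid peak")
  expect_equal(labl$expected_phase[labl$archetype == "peak_late"], "late rise")
})

test_that("planted rising genes survive the strict filter by construction", {
  arch <- default_archetypes("jaw")
  rise <- arch[arch$label == "rise", ]
  rise$baseline_cpm <- 1
  rise$n_genes <- 40
  # a dominant constant background keeps library composition stable, so the
  # rise genes' CPM trajectories retain their planted fold change
  bg <- arch[arch$label == "flat", ]
  bg$n_genes <- 100
  bg$baseline_cpm <- 1000
  cfg <- synthetic_config("jaw", archetypes = rbind(rise, bg), seed = 11)
  s <- simulate_counts(cfg)
  cpm <- compute_cpm(s$counts)
  tp <- average_replicates(cpm, s$metadata, "jaw")
  kept <- strict_filter(tp)
  expect_gte(sum(grepl("^rise_", kept)) / 40, 0.9)
})

test_that("paired simulation shares one gene universe with linked archetypes", {
  p1 <- simulate_paired_counts(seed = 6)
  p2 <- simulate_paired_counts(seed = 6)
  expect_identical(p1$jaw$counts, p2$jaw$counts)
  expect_identical(p1$limb$counts, p2$limb$counts)

  # one identifier space, fully covered by the truth table
  expect_identical(p1$jaw$counts$gene_id, p1$limb$counts$gene_id)
  expect_identical(p1$truth$gene_id, p1$jaw$counts$gene_id)
  expect_equal(nrow(p1$truth), sum(default_gene_pairing()$n))

  # expected phases follow the pairing: a 3 h transient limb archetype is
  # an early-peak gene; flat genes have no phase
  tr <- p1$truth
  expect_true(all(tr$limb_expected_phase[tr$limb_archetype == "peak_3hpa"] ==
                    "early peak"))
  expect_true(all(tr$limb_expected_phase[tr$limb_archetype == "peak_1dpa"] ==
                    "early peak"))
  expect_true(all(is.na(tr$jaw_expected_phase[tr$jaw_archetype == "flat"])))
  expect_true(all(tr$jaw_expected_phase[tr$jaw_archetype == "peak_5dpi"] ==
                    "5 dpi peak"))

  # the full comparison runs: shared genes exist and the transient
  # fraction is computable from the limb profiles
  cfg <- pipeline_config(jaw = p1$jaw, limb = p1$limb, k = 6, seed = 6)
  res <- run_pipeline(cfg)
  expect_gt(res$comparison$shared$n_shared, 100)
  expect_false(is.na(res$comparison$transient_pct))
  expect_true(res$comparison$transient_pct >= 0 &&
                res$comparison$transient_pct <= 100)
})

test_that("morphometry simulation follows its closure curve", {
  m0 <- simulate_morphometry(noise_sd = 0, seed = 4)
  # zero noise puts areas exactly on the curve
  expect_equal(unique(m0$defect_area_mm2[m0$time_dpi == 0]), 8)
  expect_equal(unique(m0$defect_area_mm2[m0$time_dpi == 14]), 1.2)
  # the curve reaches zero at 35 dpi: explicit zero records from then on
  m1 <- simulate_morphometry(noise_sd = 0.3, seed = 4)
  expect_true(all(m1$defect_area_mm2[m1$time_dpi >= 35] == 0))
  # angle dips to its minimum at 35 dpi
  s <- summarize_morphometry(m0)
  expect_equal(s$time_dpi[which.min(s$mean_angle_deg)], 35)
  # determinism and the reduced 90 dpi cohort
  expect_identical(m1, simulate_morphometry(noise_sd = 0.3, seed = 4))
  expect_equal(sum(m1$time_dpi == 90), 3)
  expect_error(simulate_morphometry(noise_sd = -1), "non-negative")

  # cohort means recovered within 2 noise sd by the morphometry module
  set.seed(1)
  mm <- simulate_morphometry(n_animals = 6, noise_sd = 0.2, seed = 8)
  sm <- summarize_morphometry(mm)
  expect_lt(abs(sm$mean_defect_area_mm2[sm$time_dpi == 7] - 3.5), 2 * 0.2)
})
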