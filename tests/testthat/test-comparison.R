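# build a minimal phase_assignment directly from gene -> label maps
fake_pa <- function(map, structure = "jaw") {
  cfg <- phase_config(structure)
  structure(
    list(cluster_phase = tibble::tibble(),
         gene_phase = tibble::tibble(gene_id = names(map),
                                     label = unname(map)),
         labels = cfg$labels, structure = structure),
    class = "phase_assignment"
  )
}

test_that("shared-gene intersection and percentage behave as set arithmetic", {
  res <- intersect_goi(c("a", "b", "c"), c("b", "c", "d"))
  expect_identical(res$shared, c("b", "c"))
  expect_equal(res$pct_of_jaw, 100 * 2 / 3, tolerance = 1e-12)

  expect_equal(intersect_goi(c("a", "b"), c("x", "y"))$n_shared, 0)
  expect_equal(intersect_goi(c("a", "b"), c("x", "y"))$pct_of_jaw, 0)
  expect_equal(intersect_goi(c("a", "b"), c("b", "a"))$pct_of_jaw, 100)
  expect_error(intersect_goi(character(0), c("a")), "empty")
})

test_that("overlap percentages match brute-force set counting and conserve totals", {
  jaw <- fake_pa(c(a = "5 dpi peak", b = "5 dpi peak", c = "5 dpi peak",
                   d = "5 dpi peak", e = "14 dpi peak", f = "general rise"))
  limb <- fake_pa(c(a = "early peak", b = "early peak", c = "mid peak",
                    d = "unassigned", e = "mid peak", x = "late rise"),
                  structure = "limb")
  shared <- c("a", "b", "c", "d", "e")
  ov <- overlap_percentages(jaw, limb, shared)

  cell <- function(g, h) ov[ov$jaw_group == g & ov$limb_group == h, ]
  expect_equal(cell("5 dpi peak", "early peak")$pct, 50)
  expect_equal(cell("5 dpi peak", "mid peak")$pct, 25)
  expect_equal(cell("5 dpi peak", "late rise")$count, 0)
  # gene d sits in an unassigned limb cluster: 25% unaccounted
  denom <- attr(ov, "n_shared_in_jaw_group")
  expect_equal(denom$n_shared[denom$jaw_group == "5 dpi peak"], 4)
  acc <- sum(ov$count[ov$jaw_group == "5 dpi peak"])
  expect_equal(acc, 3)

  # exhaustive double-loop oracle over every cell
  for (g in jaw$labels) {
    for (h in limb$labels) {
      jg <- names(which(c(a = "5 dpi peak", b = "5 dpi peak", c = "5 dpi peak",
                          d = "5 dpi peak", e = "14 dpi peak",
                          f = "general rise") == g))
      lh <- names(which(c(a = "early peak", b = "early peak", c = "mid peak",
                          d = "unassigned", e = "mid peak",
                          x = "late rise") == h))
      want <- length(intersect(intersect(shared, jg), lh))
      expect_equal(cell(g, h)$count, want)
    }
  }

  # conservation: per jaw group, counted + unaccounted = shared in group
  for (g in jaw$labels) {
    n_g <- denom$n_shared[denom$jaw_group == g]
    expect_lte(sum(ov$count[ov$jaw_group == g]), n_g)
  }

  # permuting gene order changes nothing
  ov2 <- overlap_percentages(jaw, limb, rev(shared))
  expect_equal(tibble::as_tibble(ov2), tibble::as_tibble(ov))

  # empty denominators are reported missing; empty shared set all missing
  expect_true(all(is.na(cell("35 dpi peak", "early peak")$pct)))
  ov0 <- overlap_percentages(jaw, limb, character(0))
  expect_true(all(is.na(ov0$pct)))

  # every shared gene in one limb group => 100% there, 0 elsewhere
  limb_all <- fake_pa(setNames(rep("early peak", 5), letters[1:5]), "limb")
  ov1 <- overlap_percentages(jaw, limb_all, c("a", "b", "c", "d"))
  expect_equal(cell <- ov1$pct[ov1$jaw_group == "5 dpi peak"],
               c(100, 0, 0, 0))
})

test_that("early-transient fraction counts genes peaking at 3 h and back by 1 dpa", {
  times <- c(0, 3, 24, 168)
  Z <- rbind(
    std1(c(0, 2, -0.5, -0.4)),   # transient: peak 3 h, below intact at 24 h
    std1(c(-0.2, 2, -0.2, -0.4)),# transient: equality at 24 h counts
    std1(c(0, 2, 1.5, -0.5)),    # peak 3 h but still above intact at 24 h
    std1(c(0, 0.5, 2, -0.5)),    # peaks at 24 h
    std1(c(0, 2, -1, -0.6))      # transient
  )
  # make row 2's intact and 24 h values exactly equal
  Z[2, 3] <- Z[2, 1]
  zp <- zp_from_matrix(Z, times, structure = "limb")
  genes <- sprintf("g%03d", 1:5)
  expect_equal(early_transient_fraction(genes, zp), 60)

  # empty gene set is undefined, reported missing
  expect_true(is.na(early_transient_fraction(character(0), zp)))
  # required time points must be present
  zp_no24 <- zp_from_matrix(Z[, -3], c(0, 3, 168), structure = "limb")
  expect_error(early_transient_fraction(genes, zp_no24), "24")
  # unknown genes are an error
  expect_error(early_transient_fraction(c("nope"), zp), "absent")
})
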