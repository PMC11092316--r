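# A 10-bin single-chromosome world with two bands and a q-only arm layout
# keeps the majority-of-bases arithmetic fully checkable by hand.
region_world <- function() {
  g <- grid_1chr(10)
  bands <- tibble::tibble(
    chrom = 1,
    start = c(0, 1e6, 1.5e6, 3e6),
    end = c(1e6, 1.5e6, 3e6, 5e6),
    band = c("1p12", "1p11", "1q11", "1q12"),
    stain = c("gneg", "acen", "acen", "gneg"))
  map <- cytoband_map(bands)
  list(grid = g, map = map, overlap = bin_region_overlap(g, map))
}

test_that("the strict majority-of-bases rule drives band calls", {
  w <- region_world()
  # amplify 6 of the 10 bins: band 1q12 (bins 7-10) is 100% amplified,
  # band 1p12 (bins 1-2) untouched
  calls <- call_regions(manual_absolute_profile(
    w$grid, c(2, 2, 2, 2, 3, 3, 3, 3, 3, 3)), w$overlap)
  bc <- calls$band_calls
  expect_equal(bc$state[bc$band == "1q12"], "amplification")
  expect_equal(bc$state[bc$band == "1p12"], "none")
  # arm q = [1.5e6, 5e6): bins 4-10 contribute 3.5e6 assigned bases of
  # which 3e6 amplified (86%) -> arm called
  expect_equal(calls$arm_calls$state[calls$arm_calls$arm == "q"],
               "amplification")
})

test_that("exactly half the bases never calls, one bin past half does", {
  w <- region_world()
  # band 1q12 = [3e6, 5e6): bins 7-8 deleted = 1e6 of 2e6 bases = exactly 50%
  calls <- call_regions(manual_absolute_profile(
    w$grid, c(2, 2, 2, 2, 2, 2, 1, 1, 2, 2)), w$overlap)
  expect_equal(calls$band_calls$state[calls$band_calls$band == "1q12"],
               "none")
  # a third deleted bin crosses the strict threshold
  calls2 <- call_regions(manual_absolute_profile(
    w$grid, c(2, 2, 2, 2, 2, 2, 1, 1, 1, 2)), w$overlap)
  expect_equal(calls2$band_calls$state[calls2$band_calls$band == "1q12"],
               "deletion")
})

test_that("focal means band-altered without a same-direction arm call", {
  map <- synthetic_cytoband_grch38(chroms = 18)
  g <- make_bin_grid(dplyr::filter(grch38_autosomes(), chrom == 18))
  ov <- bin_region_overlap(g, map)
  b <- dplyr::filter(map$bands, band == "18q21.33")
  cn <- rep(2L, sum(g$usable))
  in_band <- which(g$start < b$end & g$end > b$start)
  cn[in_band] <- 3L
  calls <- call_regions(manual_absolute_profile(g, cn), ov)
  bc <- calls$band_calls
  expect_equal(bc$state[bc$band == "18q21.33"], "amplification")
  expect_true(bc$focal[bc$band == "18q21.33"])
  # whole q arm amplified -> same band no longer focal
  qarm <- dplyr::filter(map$arms, chrom == 18, arm == "q")
  cn2 <- rep(2L, sum(g$usable))
  cn2[g$start >= qarm$start] <- 3L
  calls2 <- call_regions(manual_absolute_profile(g, cn2), ov)
  bc2 <- calls2$band_calls
  expect_equal(bc2$state[bc2$band == "18q21.33"], "amplification")
  expect_false(bc2$focal[bc2$band == "18q21.33"])
  expect_equal(calls2$arm_calls$state[calls2$arm_calls$arm_name == "18q"],
               "amplification")
  # focality is idempotent
  expect_identical(classify_focal(calls2), calls2$band_calls)
})

test_that("burden metrics merge adjacent same-state alterations", {
  w <- region_world()
  flat <- manual_absolute_profile(w$grid, rep(2L, 10))
  b <- burden_metrics(flat)
  expect_equal(c(b$pga, b$n_cna), c(0, 0))
  # two runs: deletion bins 2-3, amplification bins 6-9 (segments built
  # separately merge when adjacent and identical in state+cn)
  prof <- manual_absolute_profile(w$grid, c(2, 1, 1, 2, 2, 3, 3, 3, 3, 2))
  b2 <- burden_metrics(prof)
  expect_equal(b2$n_cna, 2)
  expect_equal(b2$pga, 6 * 5e5 / 5e6)
  expect_equal(b2$altered_bases, 6 * 5e5)
})

test_that("whole-genome amplification counts one alteration per chromosome", {
  g <- make_bin_grid(toy_chrom_sizes())
  prof <- manual_absolute_profile(g, rep(3L, sum(g$usable)))
  b <- burden_metrics(prof)
  expect_equal(b$pga, 1)
  expect_equal(b$n_cna, 6) # one run per autosome in this genome
})

test_that("band-level and bin-level altered bases agree", {
  map <- synthetic_cytoband_grch38(chroms = c(18, 21))
  g <- make_bin_grid(dplyr::filter(grch38_autosomes(), chrom %in% c(18, 21)))
  ov <- bin_region_overlap(g, map)
  withr::with_seed(44, {
    cn <- sample(c(1L, 2L, 2L, 2L, 3L), sum(g$usable), replace = TRUE)
  })
  calls <- call_regions(manual_absolute_profile(g, cn), ov)
  # two routes to the same number: bin widths vs band-assigned fractions
  band_bases <- sum(calls$band_calls$assigned_bases *
                      (calls$band_calls$frac_amp + calls$band_calls$frac_del))
  expect_equal(band_bases, calls$altered_bases)
})

test_that("serial comparison performs direction-qualified set algebra", {
  w <- region_world()
  a <- call_regions(manual_absolute_profile(
    w$grid, c(3, 3, 2, 1, 1, 1, 1, 2, 2, 2)), w$overlap)
  b <- call_regions(manual_absolute_profile(
    w$grid, c(3, 3, 2, 1, 1, 1, 1, 3, 3, 3)), w$overlap)
  cmp <- compare_serial(a, b)
  expect_equal(nrow(cmp$shared), 2L) # 1p12 amp and 1q11 del persist
  expect_equal(cmp$gained$band, "1q12")
  expect_equal(cmp$gained$direction, "amplification")
  expect_equal(nrow(cmp$lost), 0L)
  same <- compare_serial(a, a)
  expect_equal(nrow(same$lost), 0L)
  expect_equal(nrow(same$gained), 0L)
  flat <- call_regions(manual_absolute_profile(w$grid, rep(2L, 10)), w$overlap)
  disjoint <- compare_serial(a, flat)
  expect_equal(nrow(disjoint$shared), 0L)
})

test_that("the fixture serial pair shows the shared/lost/gained structure", {
  fx <- cnaband:::fixture_bundle_data(seed = 5)
  ov <- bin_region_overlap(fx$grid, fx$map)
  cfg <- abs_cn_config()
  run <- function(id) {
    prof <- build_relative_profile(id, fx$counts[[id]], fx$grid, seed = 17)
    call_regions(call_absolute_profile(prof, cfg), ov)
  }
  cmp <- compare_serial(run("case12_primary"), run("case12_recurrence"))
  expect_equal(nrow(cmp$shared), 4L)
  expect_equal(cmp$lost$band, "13q34")
  expect_equal(nrow(cmp$gained), 2L)
})
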