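test_that("truth profiles validate their invariants", {
  ev <- tibble::tibble(chrom = 1, start = 0, end = 1e6, cn = 3L)
  expect_s3_class(truth_profile(ev, 0.5), "truth_profile")
  expect_error(truth_profile(ev, 1.5), "purity")
  expect_error(truth_profile(ev, 0), "purity")
  expect_error(truth_profile(dplyr::mutate(ev, cn = 2L), 0.5), "baseline")
  expect_error(truth_profile(dplyr::mutate(ev, cn = -1L), 0.5), "non-negative")
  overlapping <- tibble::tibble(chrom = c(1, 1), start = c(0, 5e5),
                                end = c(1e6, 2e6), cn = c(3L, 1L))
  expect_error(truth_profile(overlapping, 0.5), "overlap")
})

test_that("counts follow the tumour/normal mixture expectation", {
  g <- grid_1chr(100)
  flat <- truth_profile(tibble::tibble(chrom = integer(), start = double(),
                                       end = double(), cn = integer()),
                        purity = 1)
  cnt <- simulate_sample_counts(g, flat, noise_model(dispersion = 0, seed = 1))
  expect_equal(nrow(cnt), 100L)
  expect_equal(sum(cnt$count), 1e7, tolerance = 0.01)
  # dispersion -> 0 leaves only Poisson noise: per-bin counts within a few
  # tenths of a percent of the uniform expectation
  expect_lt(max(abs(cnt$count / mean(cnt$count) - 1)), 0.05)

  # one region at CN 4 with purity 0.5: expected level 1.5x the flanks
  tp <- truth_profile(tibble::tibble(chrom = 1, start = 10e6, end = 20e6,
                                     cn = 4L), purity = 0.5)
  cnt2 <- simulate_sample_counts(g, tp, noise_model(dispersion = 0, seed = 2))
  inside <- dplyr::between(cnt2$start, 10e6, 19.5e6)
  ratio <- mean(cnt2$count[inside]) / mean(cnt2$count[!inside])
  expect_equal(ratio, 1.5, tolerance = 0.01)

  bad <- truth_profile(tibble::tibble(chrom = 1, start = 0, end = 99e6,
                                      cn = 3L), purity = 0.5)
  expect_error(simulate_sample_counts(g, bad), "within the bin grid")
})

test_that("count noise matches negative-binomial moments", {
  g <- grid_1chr(100)
  flat <- truth_profile(tibble::tibble(chrom = integer(), start = double(),
                                       end = double(), cn = integer()),
                        purity = 1)
  nm <- noise_model(reads_per_sample = 1e6, dispersion = 0.02)
  withr::with_seed(7, {
    reps <- replicate(1000, simulate_sample_counts(g, flat, nm)$count[1])
  })
  mu <- 1e6 / 100
  expect_equal(mean(reps), mu, tolerance = 0.02)
  v_expected <- mu + 0.02 * mu^2
  # chi-square MC error on a variance over 1000 draws is ~4.5% (1 sd)
  expect_equal(var(reps), v_expected, tolerance = 0.15)
})

test_that("counts are reproducible under a fixed seed", {
  g <- grid_1chr(50)
  tp <- truth_profile(tibble::tibble(chrom = 1, start = 0, end = 5e6,
                                     cn = 3L), purity = 0.4)
  a <- simulate_sample_counts(g, tp, noise_model(seed = 11))
  b <- simulate_sample_counts(g, tp, noise_model(seed = 11))
  expect_identical(a, b)
})

test_that("gc bias is applied multiplicatively", {
  set.seed(3)
  ann <- tibble::tibble(chrom = 1, start = (0:99) * 5e5,
                        gc = runif(100, 0.3, 0.6))
  g <- make_bin_grid(tibble::tibble(chrom = 1, size = 5e7), annotations = ann)
  flat <- truth_profile(tibble::tibble(chrom = integer(), start = double(),
                                       end = double(), cn = integer()),
                        purity = 1)
  cnt <- simulate_sample_counts(
    g, flat, noise_model(dispersion = 0, gc_bias = c(2, -8), seed = 4))
  v <- cnt$count / mean(cnt$count)
  bias <- 1 + 2 * (g$gc - 0.45) - 8 * (g$gc - 0.45)^2
  expect_gt(cor(v, bias / mean(bias)), 0.98)
})

test_that("simulated truth keeps the genome-average copy number diploid", {
  g <- make_bin_grid(sim_chrom_sizes())
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      tp <- simulate_truth_profile(g, purity = 0.5)
    })
    cn <- cnaband:::bin_truth_cn(g, tp)
    frac <- mean(round(cn) != 2)
    expect_gte(frac, 0.10)
    expect_equal(weighted.mean(cn, g$width), 2, tolerance = 0.005)
  }
})

test_that("cohort simulation respects group frequencies", {
  map <- synthetic_cytoband_grch38(chroms = 18)
  g <- make_bin_grid(dplyr::filter(grch38_autosomes(), chrom == 18))
  freqs <- tibble::tibble(group = c("nFL", "PCFCL"), band = "18q21.33",
                          direction = "amplification", freq = c(0.313, 0.05))
  spec <- cohort_spec(c(nFL = 64, PCFCL = 20), freqs)
  co <- simulate_cohort(spec, g, map, seed = 5, counts = FALSE)
  expect_equal(nrow(co$samples), 84L)
  hits <- dplyr::count(co$truth_calls,
                       group = sub("_.*", "", sample_id))
  n_nfl <- hits$n[hits$group == "nFL"]
  # observed counts lie inside the exact binomial 99% interval of the spec
  ci <- qbinom(c(0.005, 0.995), 64, 0.313)
  expect_gte(n_nfl, ci[1]); expect_lte(n_nfl, ci[2])

  expect_error(
    simulate_cohort(cohort_spec(c(a = 2, b = 2),
                                dplyr::mutate(freqs, band = "5q99")),
                    g, map, seed = 1),
    "absent from the map")
})

test_that("zero frequencies give an all-flat cohort", {
  map <- synthetic_cytoband_grch38(chroms = 18)
  g <- make_bin_grid(dplyr::filter(grch38_autosomes(), chrom == 18))
  spec <- cohort_spec(c(a = 3, b = 3),
                      tibble::tibble(group = "a", band = "18q21.33",
                                     direction = "deletion", freq = 0))
  co <- simulate_cohort(spec, g, map, seed = 2, counts = FALSE)
  expect_equal(nrow(co$truth_calls), 0L)
  expect_true(all(co$truth_burden$pga == 0))
  expect_true(all(co$truth_burden$n_cna == 0))
})

test_that("cohort simulation is reproducible under its seed", {
  map <- synthetic_cytoband_grch38(chroms = 18)
  g <- make_bin_grid(dplyr::filter(grch38_autosomes(), chrom == 18))
  spec <- cohort_spec(c(a = 4, b = 4),
                      tibble::tibble(group = c("a", "b"), band = "18q21.33",
                                     direction = "amplification",
                                     freq = c(0.5, 0.5)))
  c1 <- simulate_cohort(spec, g, map, seed = 9, counts = FALSE)
  c2 <- simulate_cohort(spec, g, map, seed = 9, counts = FALSE)
  expect_identical(c1$truth_calls, c2$truth_calls)
  expect_identical(c1$samples, c2$samples)
})

test_that("fixture bundle is deterministic and structured as documented", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_bundle(d1, seed = 123)
  m2 <- write_fixture_bundle(d2, seed = 123)
  expect_equal(nrow(m1), 8L) # 6 count tables + truth.json + metadata.tsv
  h1 <- tools::md5sum(sort(list.files(d1, full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(d2, full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  prim <- names(truth$bands$case12_primary)
  rec <- names(truth$bands$case12_recurrence)
  expect_equal(length(intersect(prim, rec)), 4L)
  expect_equal(length(setdiff(prim, rec)), 1L)
  expect_equal(length(setdiff(rec, prim)), 2L)
})
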