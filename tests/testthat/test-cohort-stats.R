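test_that("fisher screen matches brute-force hypergeometric enumeration", {
  cases <- list(c(2, 5, 1, 6), c(1, 20, 20, 64), c(3, 20, 1, 64),
                c(0, 16, 5, 12), c(4, 9, 2, 11))
  for (cs in cases) {
    ct <- two_group_cohort(cs[1], cs[2], cs[3], cs[4])
    res <- fisher_screen(ct, "A", "B")
    row <- dplyr::filter(res, direction == "amplification")
    expect_equal(row$p_value, fisher_oracle(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-9)
    expect_equal(c(row$a_pos, row$a_n, row$b_pos, row$b_n), cs)
  }
})

test_that("fisher screen is symmetric and null under equal proportions", {
  ct <- two_group_cohort(5, 10, 5, 10)
  res <- dplyr::filter(fisher_screen(ct, "A", "B"),
                       direction == "amplification")
  expect_equal(res$p_value, 1)
  # swapping group labels leaves every p unchanged
  swapped <- dplyr::filter(fisher_screen(ct, "B", "A"),
                           direction == "amplification")
  expect_equal(swapped$p_value, res$p_value)
  ct2 <- two_group_cohort(3, 12, 9, 15)
  expect_equal(
    dplyr::filter(fisher_screen(ct2, "A", "B"), direction == "amplification")$p_value,
    dplyr::filter(fisher_screen(ct2, "B", "A"), direction == "amplification")$p_value)
  expect_error(fisher_screen(ct, "A", "missing"), "at least one")
})

test_that("first-sample-per-patient screening drops serial samples", {
  samples <- tibble::tibble(
    sample_id = c("p1a", "p1b", "p2a", "q1a", "q2a"),
    group = c("A", "A", "A", "B", "B"),
    patient_id = c("p1", "p1", "p2", "q1", "q2"))
  positives <- tibble::tibble(sample_id = c("p1b", "q1a"), band = "x",
                              direction = "amplification")
  ct <- cohort_table(samples, calls_from_positives(samples$sample_id, "x",
                                                   positives))
  all_res <- dplyr::filter(fisher_screen(ct, "A", "B"),
                           direction == "amplification")
  first_res <- dplyr::filter(fisher_screen(ct, "A", "B",
                                           samples_per_patient = "first"),
                             direction == "amplification")
  expect_equal(c(all_res$a_pos, all_res$a_n), c(1, 3))
  expect_equal(c(first_res$a_pos, first_res$a_n), c(0, 2))
})

test_that("rank-sum comparison is exact for small untied groups", {
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:6),
                            group = rep(c("A", "B"), each = 3))
  burden <- tibble::tibble(sample_id = samples$sample_id,
                           pga = c(1, 2, 3, 4, 5, 6) / 100)
  calls <- calls_from_positives(samples$sample_id, "x",
                                tibble::tibble(sample_id = character(),
                                               band = character(),
                                               direction = character()))
  ct <- cohort_table(samples, calls)
  res <- burden_compare(ct, burden, "pga", "A", "B")
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1) # 2 of the 20 assignments are as extreme
  expect_equal(res$median_a, 0.02)
  expect_equal(res$median_b, 0.05)
  # symmetric configuration: two-sided p = 1
  burden2 <- tibble::tibble(sample_id = samples$sample_id,
                            pga = c(1, 4, 6, 2, 3, 7) / 100)
  res2 <- burden_compare(ct, burden2, "pga", "A", "B")
  expect_equal(res2$p_value, 1)
})

test_that("rank-sum power against a shifted alternative matches theory", {
  # n = 10 + 10, shift = 1.5 sd: rank-sum power ~ 0.88 at alpha 0.05;
  # simulation must land within Monte-Carlo error of an oracle simulation
  withr::with_seed(55, {
    p_impl <- replicate(300, {
      xa <- rnorm(10); xb <- rnorm(10, 1.5)
      samples <- tibble::tibble(sample_id = sprintf("s%d", 1:20),
                                group = rep(c("A", "B"), each = 10))
      burden <- tibble::tibble(sample_id = samples$sample_id, m = c(xa, xb))
      ct <- cohort_table(samples,
                         calls_from_positives(samples$sample_id, "x",
                                              tibble::tibble(sample_id = character(),
                                                             band = character(),
                                                             direction = character())))
      burden_compare(ct, burden, "m", "A", "B")$p_value
    })
    p_oracle <- replicate(300, wilcox.test(rnorm(10), rnorm(10, 1.5))$p.value)
  })
  power_impl <- mean(p_impl < 0.05)
  power_oracle <- mean(p_oracle < 0.05)
  expect_lt(abs(power_impl - power_oracle), 0.08)
})

test_that("fish concordance reproduces predictive-value arithmetic", {
  res <- concordance_counts(
    fish = rep(c("pos", "neg", "pos", "neg"), c(4, 1, 2, 13)),
    lcwgs = rep(c(1, 1, 0, 0), c(4, 1, 2, 13)))
  expect_equal(res$ppv_pct, 80)
  expect_equal(res$npv_pct, 87)
  expect_equal(res$tp + res$fp + res$fn + res$tn, res$n_evaluable)
  perfect <- concordance_counts(c("pos", "pos", "neg"), c(1, 1, 0))
  expect_equal(c(perfect$ppv_pct, perfect$npv_pct), c(100, 100))
  none_called <- concordance_counts(c("pos", "neg"), c(0, 0))
  expect_true(is.na(none_called$ppv_pct))
  expect_error(concordance_counts(c(NA, NA), c(0, 1)), "evaluable")
  # order invariance
  withr::with_seed(66, {
    fish <- sample(rep(c("pos", "neg"), c(6, 14)))
    lcw <- rbinom(20, 1, 0.4)
    o <- sample(20)
    expect_equal(concordance_counts(fish, lcw),
                 concordance_counts(fish[o], lcw[o]))
  })
})

test_that("fish concordance reads calls from the cohort table", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20), group = "PCFCL",
    fish_1p36 = rep(c("pos", "neg", "pos", "neg"), c(4, 1, 2, 13)))
  positives <- tibble::tibble(sample_id = sprintf("s%02d", 1:5),
                              band = "1p36.32", direction = "deletion")
  ct <- cohort_table(samples, calls_from_positives(samples$sample_id,
                                                   "1p36.32", positives))
  res <- fish_concordance(ct)
  expect_equal(c(res$tp, res$fp, res$fn, res$tn), c(4, 1, 2, 13))
  expect_equal(c(res$ppv_pct, res$npv_pct), c(80, 87))
})

test_that("Kaplan-Meier and log-rank match a hand-computed example", {
  # 6 subjects: altered {2+, 4, 5+}, unaltered {1, 3, 6+} (+ = censored)
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6), group = "g",
    efs_time = c(2, 4, 5, 1, 3, 6),
    efs_event = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  positives <- tibble::tibble(sample_id = c("s1", "s2", "s3"), band = "x",
                              direction = "amplification")
  ct <- cohort_table(samples, calls_from_positives(samples$sample_id, "x",
                                                   positives))
  fit <- efs_analysis(ct, "x")
  # hand KM for the altered stratum: events only at t = 4 (2 at risk)
  km_alt <- dplyr::filter(tidy(fit), stratum == "altered", n_event > 0)
  expect_equal(km_alt$time, 4)
  expect_equal(km_alt$surv, 0.5)
  # hand log-rank over the event times:
  #  t=1: 6 at risk (3 altered)  -> e = 3/6, v = 3*3*5 / (36*5)
  #  t=3: 4 at risk (2 altered)  -> e = 2/4, v = 2*2*3 / (16*3)
  #  t=4: 3 at risk (2 altered)  -> e = 2/3, v = 2*1*2 / (9*2)
  # observed altered events = 1 (at t=4)
  exp_alt <- 3 / 6 + 2 / 4 + 2 / 3
  var_alt <- (3 * 3 * 5) / (36 * 5) + (2 * 2 * 3) / (16 * 3) +
    (2 * 1 * 2) / (9 * 2)
  chisq_hand <- (1 - exp_alt)^2 / var_alt
  expect_equal(fit$chisq, chisq_hand, tolerance = 1e-10)
  expect_equal(fit$p_value, pchisq(chisq_hand, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("identical survival in both strata gives a null log-rank", {
  samples <- tibble::tibble(
    sample_id = sprintf("s%d", 1:8), group = "g",
    efs_time = rep(c(1, 2, 3, 4), 2),
    efs_event = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  positives <- tibble::tibble(sample_id = sprintf("s%d", 1:4), band = "x",
                              direction = "amplification")
  ct <- cohort_table(samples, calls_from_positives(samples$sample_id, "x",
                                                   positives))
  fit <- efs_analysis(ct, "x")
  expect_equal(fit$chisq, 0, tolerance = 1e-12)
  expect_equal(fit$p_value, 1, tolerance = 1e-9)
  # a stratifier nobody carries is an error, not a silent degenerate fit
  ct2 <- cohort_table(samples,
                      calls_from_positives(samples$sample_id, "x",
                                           positives[0, ]))
  expect_error(efs_analysis(ct2, "x"), "zero samples")
})

test_that("log-rank power at hazard ratio 3 exceeds 80%", {
  withr::with_seed(77, {
    rejections <- replicate(500, {
      n <- 100
      t_alt <- rexp(n, 0.03); t_un <- rexp(n, 0.01)
      cens <- runif(2 * n, 0, 80)
      time <- pmin(c(t_alt, t_un), cens)
      event <- c(t_alt, t_un) <= cens
      samples <- tibble::tibble(sample_id = sprintf("s%d", 1:(2 * n)),
                                group = "g", efs_time = time,
                                efs_event = event)
      positives <- tibble::tibble(sample_id = sprintf("s%d", 1:n),
                                  band = "x", direction = "amplification")
      ct <- cohort_table(samples,
                         calls_from_positives(samples$sample_id, "x", positives))
      efs_analysis(ct, "x")$p_value < 0.05
    })
  })
  expect_gt(mean(rejections), 0.8)
})
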