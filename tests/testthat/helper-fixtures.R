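# Shared fixtures built in code. Everything derives from the package's own
# generators so no binary data is needed.

toy_grid <- make_bin_grid(toy_chrom_sizes())

extdata <- function(...) system.file("extdata", ..., package = "cnaband")

# A single-chromosome grid of n equal bins.
grid_1chr <- function(n, bin = 5e5) {
  make_bin_grid(tibble::tibble(chrom = 1, size = n * bin), bin_size = bin)
}

# A hand-built absolute profile on a given grid: `cn` is a vector of integer
# copy numbers, one per usable bin.
manual_absolute_profile <- function(grid, cn, sample_id = "manual",
                                    purity = 1) {
  stopifnot(length(cn) == sum(grid$usable))
  bins <- dplyr::filter(tibble::as_tibble(grid), .data$usable)
  state <- ifelse(cn >= 3, "amplification",
                  ifelse(cn <= 1, "deletion", "neutral"))
  bins <- dplyr::mutate(bins, r = NA_real_, segment_id = NA_integer_,
                        cn = cn, state = state)
  runs <- rle(paste(bins$chrom, state, cn))
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  segments <- purrr::map2(starts, ends, function(s, e) {
    tibble::tibble(chrom = bins$chrom[s], start = bins$start[s],
                   end = bins$end[e], start_bin = s, end_bin = e,
                   n_bins = e - s + 1L, seg_mean = NA_real_,
                   seg_mean_log2 = NA_real_,
                   cn_cont = cn[s], cn = cn[s], state = state[s])
  }) |> purrr::list_rbind()
  segments$segment_id <- seq_len(nrow(segments))
  fit <- structure(list(grid = tibble::tibble(purity = purity, error = 0),
                        local_minima = purity, purity = purity,
                        fallback = FALSE, ploidy = 2,
                        n_candidate_segments = nrow(segments)),
                   class = "fit_result")
  structure(list(sample_id = sample_id, purity = purity, ploidy = 2,
                 fit = fit, segments = segments, bins = bins,
                 subclonal = NULL),
            class = "absolute_profile")
}

# Long call table for a cohort_table from explicit positives: `positives` is
# a tibble (sample_id, band, direction); every sample gets 0/1 for each
# band-direction combination present in `bands`.
calls_from_positives <- function(sample_ids, bands, positives) {
  tidyr::crossing(sample_id = sample_ids, band = bands,
                  direction = c("amplification", "deletion")) |>
    dplyr::left_join(dplyr::mutate(positives, called = 1L),
                     by = c("sample_id", "band", "direction")) |>
    dplyr::mutate(called = dplyr::coalesce(.data$called, 0L))
}

# 2x2 cohort helper: group A with a_pos of a_n altered, group B with b_pos
# of b_n, single band/direction.
two_group_cohort <- function(a_pos, a_n, b_pos, b_n, band = "x",
                             direction = "amplification") {
  samples <- tibble::tibble(
    sample_id = c(sprintf("A%02d", seq_len(a_n)), sprintf("B%02d", seq_len(b_n))),
    group = rep(c("A", "B"), c(a_n, b_n)))
  positives <- tibble::tibble(
    sample_id = c(sprintf("A%02d", seq_len(a_pos)),
                  sprintf("B%02d", seq_len(b_pos))),
    band = band, direction = direction)
  if (a_pos + b_pos == 0) positives <- positives[0, ]
  cohort_table(samples, calls_from_positives(samples$sample_id, band, positives))
}

# Brute-force two-sided Fisher p by hypergeometric enumeration (oracle).
fisher_oracle <- function(a_pos, a_n, b_pos, b_n) {
  k <- a_pos + b_pos
  lo <- max(0, k - b_n); hi <- min(k, a_n)
  probs <- vapply(lo:hi, function(x) {
    dhyper(x, a_n, b_n, k)
  }, numeric(1))
  obs <- dhyper(a_pos, a_n, b_n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force max arc statistic (oracle for the compiled scan).
arc_stat_oracle <- function(x, min_width) {
  n <- length(x)
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 0:(n - min_width)) {
    if (i != 0 && i < min_width) next
    for (j in (i + min_width):n) {
      m <- j - i
      if (n - m < min_width) next
      if (j != n && n - j < min_width) next
      d <- abs(mean(x[(i + 1):j]) - mean(x[setdiff(1:n, (i + 1):j)]))
      stat <- d * sqrt(m * (n - m) / n)
      if (stat > best) { best <- stat; bi <- i; bj <- j }
    }
  }
  list(stat = best, i = bi, j = bj)
}
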