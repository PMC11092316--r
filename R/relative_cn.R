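#' Relative copy-number profiles: normalization and segmentation
#'
#' Raw bin counts are turned into a relative copy-number profile: unusable
#' bins are masked, counts are divided by bin width, optionally corrected
#' for GC content against a smooth GC fit, and scaled so the width-weighted
#' mean over usable bins is 1. The per-bin series is then segmented per
#' chromosome by recursive binary splitting on mean shifts, each split
#' accepted only when a permutation p-value falls below `alpha` (the
#' circular-binary-segmentation family of methods). Segmentation operates on
#' log2(r + 1e-3) after winsorizing bins at +/- 4 MAD; segment means are
#' reported back in linear space as the mean of their bins' relative values.
#'
#' @name relative_cn
NULL

#' Normalize bin counts to relative copy number
#'
#' @param counts Tibble with columns `chrom`, `start`, `end`, `count`,
#'   aligned 1:1 with the grid bins.
#' @param grid The [make_bin_grid()] grid the counts were produced on.
#' @param correct_gc Correct GC bias by dividing by a loess fit of the
#'   width-normalized counts against GC (requires `gc` in the grid).
#' @return Tibble of usable bins with columns `bin_id`, `chrom`, `start`,
#'   `end`, `width`, `r` (relative copy number, width-weighted mean 1).
#' @export
normalize_counts <- function(counts, grid, correct_gc = FALSE) {
  stopifnot(inherits(grid, "bin_grid"))
  counts <- as_tibble(counts)
  if (nrow(counts) != nrow(grid)) {
    abort(sprintf("counts (%d rows) do not align with grid (%d bins)",
                  nrow(counts), nrow(grid)))
  }
  counts <- counts |> mutate(chrom = parse_chrom(.data$chrom)) |>
    arrange(.data$chrom, .data$start)
  if (any(counts$chrom != grid$chrom) || any(counts$start != grid$start)) {
    abort("counts do not align with grid bins (chrom/start mismatch)")
  }
  if (all(counts$count == 0)) abort("all bin counts are zero")
  dat <- tibble(bin_id = grid$bin_id, chrom = grid$chrom, start = grid$start,
                end = grid$end, width = grid$width, gc = grid$gc,
                usable = grid$usable, count = counts$count) |>
    filter(.data$usable)
  v <- dat$count / dat$width
  if (correct_gc) {
    if (all(is.na(dat$gc))) abort("correct_gc = TRUE but the grid has no GC values")
    ok <- !is.na(dat$gc)
    fit <- loess(v[ok] ~ dat$gc[ok], span = 0.75, degree = 2)
    pred <- rep(NA_real_, length(v))
    pred[ok] <- predict(fit)
    pred[!ok | pred <= 0] <- median(v, na.rm = TRUE)
    v <- v / pred * median(v, na.rm = TRUE)
  }
  r <- v / weighted.mean(v, dat$width)
  dat |> transmute(.data$bin_id, .data$chrom, .data$start, .data$end,
                   .data$width, r = r)
}

# Recursive circular-binary segmentation of one chromosome's (winsorized,
# log-scale) bin series. The compiled arc scan finds the arc (i, j] whose
# mean differs most from its complement; a permutation test on the same
# statistic accepts the split, and the resulting pieces are segmented
# recursively. Returns sorted split positions (a segment ends after each).
segment_one_chrom <- function(x, alpha, min_width, nperm) {
  bounds <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_width) return(invisible(NULL))
    sc <- cbs_scan(x[lo:hi], min_width)
    if (!is.finite(sc$stat) || sc$stat <= 0) return(invisible(NULL))
    p <- cbs_perm_pvalue(x[lo:hi], sc$stat, min_width, nperm, alpha)
    if (p < alpha) {
      newb <- integer(0)
      if (sc$i > 0L) newb <- c(newb, lo + sc$i - 1L)
      if (sc$j < len) newb <- c(newb, lo + sc$j - 1L)
      if (!length(newb)) return(invisible(NULL))
      bounds <<- c(bounds, newb)
      pts <- c(lo - 1L, newb, hi)
      for (q in seq_len(length(pts) - 1L)) recurse(pts[q] + 1L, pts[q + 1L])
    }
    invisible(NULL)
  }
  recurse(1L, length(x))
  refine_bounds(x, sort(unique(bounds)), min_width)
}

# Local refinement of split positions: holding the number of segments
# fixed, each boundary is repositioned between its neighbours to minimize
# the residual sum of squares of the two adjacent segments. Repeated to
# convergence (deterministic); recovers boundary bins the accepted arc
# dragged along.
refine_bounds <- function(x, bounds, min_width) {
  if (!length(bounds)) return(bounds)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cq <- c(0, cumsum(x^2))
  rss <- function(a, b) { # inclusive 1-based range
    s <- cs[b + 1] - cs[a]
    (cq[b + 1] - cq[a]) - s^2 / (b - a + 1)
  }
  for (sweep in 1:10) {
    changed <- FALSE
    pts <- c(0L, bounds, n)
    for (q in seq_along(bounds)) {
      lo <- pts[q] + min_width
      hi <- pts[q + 2] - min_width
      if (lo > hi) next
      cand <- lo:hi
      tot <- vapply(cand, function(b) {
        rss(pts[q] + 1L, b) + rss(b + 1L, pts[q + 2]) }, numeric(1))
      best <- cand[which.min(tot)]
      if (best != bounds[q]) { bounds[q] <- best; changed <- TRUE }
      pts <- c(0L, bounds, n)
    }
    if (!changed) break
  }
  sort(unique(bounds))
}

#' Segment a relative copy-number profile
#'
#' @param rel Tibble of usable bins as returned by [normalize_counts()].
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param min_width Minimum segment width in bins (default 2).
#' @param nperm Permutations per split test (default 1000).
#' @param seed Optional seed making the permutation draws reproducible.
#' @return Tibble of segments: `segment_id`, `chrom`, `start`, `end`,
#'   `start_bin`, `end_bin` (row indices into `rel`), `n_bins`, `seg_mean`
#'   (linear mean of the bins' relative values), `seg_mean_log2`.
#' @export
segment_profile <- function(rel, alpha = 0.01, min_width = 2, nperm = 1000,
                            seed = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  rel <- as_tibble(rel)
  if (nrow(rel) == 0L) abort("no usable bins to segment")
  eps <- 1e-3
  y <- log2(rel$r + eps)
  med <- median(y); s <- mad(y)
  if (s > 0) y <- pmin(pmax(y, med - 4 * s), med + 4 * s)
  run <- function() {
    segs <- list()
    for (chr in unique(rel$chrom)) {
      idx <- which(rel$chrom == chr)
      n <- length(idx)
      bounds <- if (n >= 2L * min_width) {
        segment_one_chrom(y[idx], alpha, min_width, nperm)
      } else integer(0)
      lo <- c(1L, bounds + 1L)
      hi <- c(bounds, n)
      for (j in seq_along(lo)) {
        rows <- idx[lo[j]:hi[j]]
        segs[[length(segs) + 1L]] <- tibble(
          chrom = chr,
          start = rel$start[rows[1]],
          end = rel$end[rows[length(rows)]],
          start_bin = rows[1], end_bin = rows[length(rows)],
          n_bins = length(rows),
          seg_mean = mean(rel$r[rows]))
      }
    }
    list_rbind(segs)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out |> mutate(seg_mean_log2 = log2(.data$seg_mean + eps),
                segment_id = row_number()) |>
    select("segment_id", everything())
}

#' Build a relative copy-number profile for one sample
#'
#' Composes [normalize_counts()] and [segment_profile()] and records the
#' parameters used.
#'
#' @param sample_id Sample label.
#' @param counts Bin count tibble.
#' @param grid Bin grid.
#' @param correct_gc Passed to [normalize_counts()].
#' @param alpha,min_width,nperm,seed Passed to [segment_profile()].
#' @return A `relative_profile` object: list with `sample_id`, `bins`
#'   (usable-bin tibble with `r`), `segments` and `params`.
#' @export
build_relative_profile <- function(sample_id, counts, grid,
                                   correct_gc = FALSE, alpha = 0.01,
                                   min_width = 2, nperm = 1000, seed = NULL) {
  bins <- normalize_counts(counts, grid, correct_gc = correct_gc)
  if (nrow(bins) == 0L) abort("sample has no usable bins")
  segments <- segment_profile(bins, alpha = alpha, min_width = min_width,
                              nperm = nperm, seed = seed)
  structure(list(sample_id = sample_id, bins = bins, segments = segments,
                 params = list(correct_gc = correct_gc, alpha = alpha,
                               min_width = min_width, nperm = nperm,
                               seed = seed)),
            class = "relative_profile")
}

#' @export
print.relative_profile <- function(x, ...) {
  cat(sprintf("<relative_profile> %s: %d usable bins, %d segments\n",
              x$sample_id, nrow(x$bins), nrow(x$segments)))
  invisible(x)
}

#' Write segments as a SEG-like TSV
#'
#' Starts are exported 1-based inclusive, the convention of human-readable
#' segment tables.
#'
#' @param profile A `relative_profile` or `absolute_profile`.
#' @param path Output path.
#' @return Invisibly, the exported tibble.
#' @export
write_seg <- function(profile, path) {
  segs <- profile$segments |> mutate(start = .data$start + 1)
  out <- if (inherits(profile, "absolute_profile")) {
    segs |> transmute(sample = profile$sample_id, .data$chrom, .data$start,
                      .data$end, .data$n_bins, r = .data$seg_mean,
                      cn_cont = .data$cn_cont, cn = .data$cn,
                      state = .data$state,
                      purity_used = profile$purity,
                      fallback = profile$fit$fallback)
  } else {
    segs |> transmute(sample = profile$sample_id, .data$chrom, .data$start,
                      .data$end, .data$n_bins,
                      seg_mean_log2 = .data$seg_mean_log2,
                      seg_mean_linear = .data$seg_mean)
  }
  write_tsv(out, path, progress = FALSE)
  invisible(out)
}
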