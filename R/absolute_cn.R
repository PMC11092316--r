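#' Absolute copy number by fit-matrix purity search
#'
#' The bespoke step of the pipeline: relative segment levels are converted
#' into absolute integer copy numbers by inverting the tumour/normal mixture
#' signal, with the tumour purity estimated by a grid search. For every
#' candidate purity the continuous copy number of every non-neutral segment
#' is computed and its squared distance to the nearest non-negative integer,
#' weighted by the segment's bin count, is accumulated into a fit error;
#' purities where that error is locally minimal are candidate solutions and
#' the best local minimum is selected. Ploidy is fixed at 2 throughout:
#' hyperdiploid states are rare in follicular lymphoma, and a free ploidy
#' would be poorly identified at this coverage. Samples whose error curve
#' has no local minimum (typically flat profiles) fall back to purity 0.2 -
#' the most sensitive setting in the search range - so that alterations are
#' still detectable.
#'
#' @name absolute_cn
NULL

round_half_up <- function(x) floor(x + 0.5)

#' Convert relative to continuous absolute copy number
#'
#' Inverts the expected-signal mixture: a segment at relative level r in a
#' sample of purity rho and tumour ploidy psi has expected signal
#' proportional to `rho * cn + 2 * (1 - rho)` against a sample average of
#' `rho * psi + 2 * (1 - rho)`, so
#' `cn = (r * (rho * psi + 2 * (1 - rho)) - 2 * (1 - rho)) / rho`,
#' floored at 0.
#'
#' @param r Relative copy number value(s).
#' @param purity Tumour purity in (0, 1].
#' @param ploidy Tumour ploidy (fixed at 2 in this pipeline).
#' @return Continuous absolute copy number(s), >= 0.
#' @export
relative_to_absolute <- function(r, purity, ploidy = 2) {
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1) {
    abort("purity must be a single value in (0, 1]")
  }
  cn <- (r * (purity * ploidy + 2 * (1 - purity)) - 2 * (1 - purity)) / purity
  pmax(0, cn)
}

#' Configuration of the absolute copy-number caller
#'
#' @param purity_min,purity_max,purity_step Purity search grid (default
#'   0.20-1.00 in steps of 0.01).
#' @param flatness_threshold Segments with |r - 1| at or below this value are
#'   treated as copy-neutral and do not constrain the purity fit
#'   (default 0.05).
#' @param min_fit_bins Minimum segment length (bins) for a segment to
#'   constrain the purity fit (default 5): shorter segments have too noisy a
#'   mean and their rounding residuals would otherwise favour harmonic
#'   purity solutions.
#' @param subclonal_rerun Also compute a second profile at fixed purity 0.1,
#'   recovering potential subclonal alterations (default FALSE).
#' @param cn_cap Reported integer copy numbers are capped here (default 10).
#' @return A list of class `abs_cn_config`.
#' @export
abs_cn_config <- function(purity_min = 0.2, purity_max = 1.0,
                          purity_step = 0.01, flatness_threshold = 0.05,
                          min_fit_bins = 5, subclonal_rerun = FALSE,
                          cn_cap = 10) {
  stopifnot(purity_min > 0, purity_max <= 1, purity_min < purity_max,
            purity_step > 0, flatness_threshold >= 0, min_fit_bins >= 1,
            cn_cap >= 3)
  structure(list(purity_min = purity_min, purity_max = purity_max,
                 purity_step = purity_step,
                 flatness_threshold = flatness_threshold,
                 min_fit_bins = min_fit_bins,
                 subclonal_rerun = subclonal_rerun, cn_cap = cn_cap),
            class = "abs_cn_config")
}

#' Fit purity over a grid by the fit-matrix criterion
#'
#' @param segments Segment tibble with columns `seg_mean` and `n_bins`
#'   (as produced by [segment_profile()]).
#' @param purity_grid Ordered purity grid; defaults to the configured range.
#' @param ploidy Tumour ploidy, fixed at 2.
#' @param flatness_threshold,min_fit_bins See [abs_cn_config()].
#' @param fallback_purity Purity assigned when no local minimum exists
#'   (default 0.2).
#' @return A `fit_result`: list with `grid` (tibble `purity`, `error`),
#'   `local_minima`, `purity` (the selected rho*), `fallback` flag,
#'   `ploidy`, `n_candidate_segments`.
#' @export
build_fit_matrix <- function(segments, purity_grid = seq(0.2, 1, by = 0.01),
                             ploidy = 2, flatness_threshold = 0.05,
                             min_fit_bins = 5, fallback_purity = 0.2) {
  segments <- as_tibble(segments)
  if (nrow(segments) == 0L) abort("no segments to fit")
  if (length(purity_grid) == 0L) abort("purity grid is empty")
  purity_grid <- sort(unique(purity_grid))
  cand <- segments |> filter(abs(.data$seg_mean - 1) > flatness_threshold,
                             .data$n_bins >= min_fit_bins)
  err <- vapply(purity_grid, function(rho) {
    if (nrow(cand) == 0L) return(0)
    cn <- (cand$seg_mean * (rho * ploidy + 2 * (1 - rho)) - 2 * (1 - rho)) / rho
    resid <- cn - pmax(0, round_half_up(cn))
    sum(cand$n_bins * resid^2)
  }, numeric(1))
  k <- length(err)
  minima <- if (k >= 3 && nrow(cand) > 0) {
    which(err[2:(k - 1)] < err[1:(k - 2)] & err[2:(k - 1)] < err[3:k]) + 1L
  } else integer(0)
  if (length(minima)) {
    e <- err[minima]
    best <- minima[e == min(e)]
    sel <- max(purity_grid[best]) # exact tie in error -> higher purity
    fallback <- FALSE
  } else {
    sel <- fallback_purity
    fallback <- TRUE
  }
  structure(list(grid = tibble(purity = purity_grid, error = err),
                 local_minima = purity_grid[minima],
                 purity = sel, fallback = fallback, ploidy = ploidy,
                 n_candidate_segments = nrow(cand)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> purity = %.2f (%s; %d local minima, %d candidate segments)\n",
              x$purity, if (x$fallback) "fallback" else "fitted",
              length(x$local_minima), x$n_candidate_segments))
  invisible(x)
}

absolute_segments <- function(rel, purity, ploidy, cn_cap) {
  rel$segments |>
    mutate(cn_cont = relative_to_absolute(.data$seg_mean, purity, ploidy),
           cn = pmin(cn_cap, pmax(0, round_half_up(.data$cn_cont))),
           state = case_when(.data$cn >= 3 ~ "amplification",
                             .data$cn <= 1 ~ "deletion",
                             TRUE ~ "neutral"))
}

expand_bins <- function(rel, segments) {
  seg_of_bin <- integer(nrow(rel$bins))
  for (j in seq_len(nrow(segments))) {
    seg_of_bin[segments$start_bin[j]:segments$end_bin[j]] <- j
  }
  rel$bins |>
    mutate(segment_id = segments$segment_id[seg_of_bin],
           cn = segments$cn[seg_of_bin],
           state = segments$state[seg_of_bin])
}

#' Call absolute copy numbers for a relative profile
#'
#' Composes the purity fit, the mixture inversion, integer rounding and
#' state assignment. Segments with integer copy number at or above 3 are
#' amplifications; at or below 1, deletions; otherwise neutral. With
#' `subclonal_rerun` enabled a second profile at fixed purity 0.1 is
#' attached, the deterministic stand-in for a subclonal-sensitivity pass on
#' serially sampled patients.
#'
#' @param rel A [build_relative_profile()] result.
#' @param config An [abs_cn_config()].
#' @return An `absolute_profile`: list with `sample_id`, `purity`, `ploidy`,
#'   `fit` (a `fit_result`), `segments` (with `cn_cont`, `cn`, `state`),
#'   `bins` (per usable bin with `cn`, `state`) and optionally `subclonal`.
#' @export
call_absolute_profile <- function(rel, config = abs_cn_config()) {
  stopifnot(inherits(rel, "relative_profile"), inherits(config, "abs_cn_config"))
  fit <- build_fit_matrix(
    rel$segments,
    purity_grid = seq(config$purity_min, config$purity_max,
                      by = config$purity_step),
    flatness_threshold = config$flatness_threshold,
    min_fit_bins = config$min_fit_bins,
    fallback_purity = config$purity_min)
  segs <- absolute_segments(rel, fit$purity, fit$ploidy, config$cn_cap)
  out <- structure(list(sample_id = rel$sample_id, purity = fit$purity,
                        ploidy = fit$ploidy, fit = fit, segments = segs,
                        bins = expand_bins(rel, segs), subclonal = NULL),
                   class = "absolute_profile")
  if (isTRUE(config$subclonal_rerun)) {
    sub_segs <- absolute_segments(rel, 0.1, fit$ploidy, config$cn_cap)
    sub_fit <- structure(list(grid = fit$grid, local_minima = numeric(0),
                              purity = 0.1, fallback = FALSE,
                              ploidy = fit$ploidy,
                              n_candidate_segments = fit$n_candidate_segments),
                         class = "fit_result")
    out$subclonal <- structure(
      list(sample_id = paste0(rel$sample_id, "_subclonal"), purity = 0.1,
           ploidy = fit$ploidy, fit = sub_fit, segments = sub_segs,
           bins = expand_bins(rel, sub_segs), subclonal = NULL),
      class = "absolute_profile")
  }
  out
}

#' @export
print.absolute_profile <- function(x, ...) {
  cat(sprintf("<absolute_profile> %s: purity %.2f%s, %d segments (%d altered)\n",
              x$sample_id, x$purity,
              if (x$fit$fallback) " (fallback)" else "",
              nrow(x$segments), sum(x$segments$state != "neutral")))
  invisible(x)
}
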