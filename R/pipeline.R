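#' End-to-end pipeline helpers
#'
#' Convenience wrappers chaining normalization, segmentation, the purity
#' fit, absolute calling and region summarization for single samples and
#' whole cohorts.
#'
#' @name pipeline
NULL

#' Process one sample from bin counts to region calls
#'
#' @param sample_id Sample label.
#' @param counts Bin count tibble.
#' @param grid Bin grid.
#' @param overlap [bin_region_overlap()] index on the same grid.
#' @param config [abs_cn_config()].
#' @param seed Seed for the segmentation permutations.
#' @param ... Passed to [build_relative_profile()].
#' @return List with `relative`, `absolute` and `calls` (a
#'   `region_call_set`).
#' @export
process_sample <- function(sample_id, counts, grid, overlap,
                           config = abs_cn_config(), seed = NULL, ...) {
  rel <- build_relative_profile(sample_id, counts, grid, seed = seed, ...)
  abs <- call_absolute_profile(rel, config)
  calls <- call_regions(abs, overlap)
  list(relative = rel, absolute = abs, calls = calls)
}

#' Process every sample of a simulated cohort
#'
#' Runs [process_sample()] over a [simulate_cohort()] object (which must
#' have been generated with counts) and assembles the cohort call and
#' burden tables.
#'
#' @param cohort A `cna_cohort` with counts.
#' @param config [abs_cn_config()].
#' @param seed Base seed; sample i is segmented with seed + i.
#' @param ... Passed to [build_relative_profile()].
#' @return List with `results` (per-sample pipeline outputs), `table` (a
#'   [cohort_table()]) and `burden` (tibble).
#' @export
process_cohort <- function(cohort, config = abs_cn_config(), seed = 1, ...) {
  stopifnot(inherits(cohort, "cna_cohort"))
  if (is.null(cohort$counts)) {
    abort("cohort was simulated without counts; rerun with counts = TRUE")
  }
  overlap <- bin_region_overlap(cohort$grid, cohort$map)
  ids <- names(cohort$counts)
  results <- vector("list", length(ids))
  names(results) <- ids
  for (i in seq_along(ids)) {
    results[[i]] <- process_sample(ids[i], cohort$counts[[i]], cohort$grid,
                                   overlap, config = config,
                                   seed = seed + i, ...)
  }
  call_sets <- map(results, "calls")
  list(results = results,
       table = cohort_table(cohort$samples, cohort_call_table(call_sets)),
       burden = cohort_burden_table(call_sets))
}
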