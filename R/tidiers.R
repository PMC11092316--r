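#' Tidiers for pipeline result objects
#'
#' broom-convention `tidy()` (one row per component) and `glance()` (one-row
#' summary) methods for the pipeline's fitted objects.
#'
#' @name tidiers
NULL

#' @rdname tidiers
#' @param x A pipeline result object.
#' @param ... Unused.
#' @export
tidy.relative_profile <- function(x, ...) {
  x$segments |> mutate(sample_id = x$sample_id) |>
    select("sample_id", everything())
}

#' @rdname tidiers
#' @export
glance.relative_profile <- function(x, ...) {
  tibble(sample_id = x$sample_id, n_bins = nrow(x$bins),
         n_segments = nrow(x$segments),
         mad_r = mad(x$bins$r))
}

#' @rdname tidiers
#' @export
tidy.fit_result <- function(x, ...) x$grid

#' @rdname tidiers
#' @export
glance.fit_result <- function(x, ...) {
  tibble(purity = x$purity, fallback = x$fallback, ploidy = x$ploidy,
         n_local_minima = length(x$local_minima),
         n_candidate_segments = x$n_candidate_segments,
         min_error = if (nrow(x$grid)) min(x$grid$error) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.absolute_profile <- function(x, ...) {
  x$segments |> mutate(sample_id = x$sample_id, purity = x$purity) |>
    select("sample_id", everything())
}

#' @rdname tidiers
#' @export
glance.absolute_profile <- function(x, ...) {
  b <- burden_metrics(x)
  tibble(sample_id = x$sample_id, purity = x$purity,
         fallback = x$fit$fallback, pga = b$pga, n_cna = b$n_cna)
}

#' @rdname tidiers
#' @export
tidy.region_call_set <- function(x, ...) {
  x$band_calls |> mutate(sample_id = x$sample_id) |>
    select("sample_id", everything())
}

#' @rdname tidiers
#' @export
glance.region_call_set <- function(x, ...) {
  tibble(sample_id = x$sample_id, pga = x$pga, n_cna = x$n_cna,
         altered_bases = x$altered_bases,
         n_bands_altered = sum(x$band_calls$state != "none"),
         n_focal = sum(x$band_calls$focal %in% TRUE))
}

#' @rdname tidiers
#' @export
tidy.efs_fit <- function(x, ...) x$km

#' @rdname tidiers
#' @export
glance.efs_fit <- function(x, ...) {
  tibble(band = x$band, direction = x$direction, chisq = x$chisq,
         df = x$df, p_value = x$p_value)
}
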