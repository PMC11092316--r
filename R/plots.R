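#' Plots
#'
#' ggplot2 `autoplot()` methods for the pipeline's result objects: bin and
#' segment tracks along the genome, the purity error curve, and
#' Kaplan-Meier curves.
#'
#' @name plots
NULL

genome_track_data <- function(bins, segments) {
  offs <- bins |> group_by(.data$chrom) |>
    summarise(len = max(.data$end), .groups = "drop") |>
    mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)))
  list(
    bins = bins |> left_join(offs, by = "chrom") |>
      mutate(pos = (.data$start + .data$end) / 2 + .data$offset),
    segments = segments |> left_join(offs, by = "chrom") |>
      mutate(x0 = .data$start + .data$offset, x1 = .data$end + .data$offset),
    offs = offs
  )
}

#' @rdname plots
#' @param object A pipeline result object.
#' @param ... Unused.
#' @export
autoplot.relative_profile <- function(object, ...) {
  d <- genome_track_data(object$bins, object$segments)
  ggplot() +
    geom_point(data = d$bins, aes(x = .data$pos, y = .data$r),
               size = 0.3, alpha = 0.4, colour = "grey40") +
    geom_segment(data = d$segments,
                 aes(x = .data$x0, xend = .data$x1,
                     y = .data$seg_mean, yend = .data$seg_mean),
                 colour = "firebrick", linewidth = 0.9) +
    geom_vline(xintercept = d$offs$offset[-1], linetype = 3,
               colour = "grey70") +
    labs(x = "genome position", y = "relative copy number",
         title = object$sample_id) +
    theme_minimal()
}

#' @rdname plots
#' @export
autoplot.absolute_profile <- function(object, ...) {
  d <- genome_track_data(object$bins, object$segments)
  ggplot() +
    geom_segment(data = d$segments,
                 aes(x = .data$x0, xend = .data$x1, y = .data$cn_cont,
                     yend = .data$cn_cont, colour = .data$state),
                 linewidth = 1.2) +
    geom_vline(xintercept = d$offs$offset[-1], linetype = 3,
               colour = "grey70") +
    scale_colour_manual(values = c(amplification = "firebrick",
                                   deletion = "steelblue",
                                   neutral = "grey50")) +
    labs(x = "genome position", y = "absolute copy number",
         title = sprintf("%s (purity %.2f%s)", object$sample_id,
                         object$purity,
                         if (object$fit$fallback) ", fallback" else "")) +
    theme_minimal()
}

#' @rdname plots
#' @export
autoplot.fit_result <- function(object, ...) {
  ggplot(object$grid, aes(x = .data$purity, y = .data$error)) +
    geom_line() +
    geom_vline(xintercept = object$purity, colour = "firebrick",
               linetype = 2) +
    labs(x = "purity", y = "fit error",
         title = sprintf("purity fit: rho* = %.2f%s", object$purity,
                         if (object$fallback) " (fallback)" else "")) +
    theme_minimal()
}

#' @rdname plots
#' @export
autoplot.efs_fit <- function(object, ...) {
  km <- object$km |> group_by(.data$stratum) |>
    group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) |>
    ungroup()
  ggplot(km, aes(x = .data$time, y = .data$surv, colour = .data$stratum)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "months", y = "event-free survival",
         title = sprintf("%s %s: log-rank p = %.3g", object$band,
                         object$direction, object$p_value)) +
    theme_minimal()
}
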