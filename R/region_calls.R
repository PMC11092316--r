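#' Cytoband- and arm-level alteration calls and burden metrics
#'
#' Per-sample absolute profiles are summarized on cytobands and chromosome
#' arms: a region is called altered in a direction only when strictly more
#' than 50% of its assigned bases lie in bins carrying that state. An
#' altered band is focal when its containing arm is not called altered in
#' the same direction. Burden metrics are the proportion of the usable
#' autosomal genome altered (PGA) and the number of distinct alterations
#' (maximal runs of adjacent same-state altered bins within a chromosome,
#' merged across segmentation boundaries).
#'
#' @name region_calls
NULL

#' Call cytoband and arm alterations from an absolute profile
#'
#' @param abs An [call_absolute_profile()] result.
#' @param overlap A [bin_region_overlap()] index built on the same grid.
#' @return A `region_call_set`: list with `sample_id`, `band_calls` (tibble
#'   `band`, `chrom`, `arm`, `state`, `frac_amp`, `frac_del`,
#'   `assigned_bases`, `focal`), `arm_calls`, and burden fields `pga`,
#'   `n_cna`, `altered_bases`, `total_bases`.
#' @export
call_regions <- function(abs, overlap) {
  stopifnot(inherits(abs, "absolute_profile"), inherits(overlap, "region_overlap"))
  states <- abs$bins |> select("bin_id", "state")
  ov <- overlap$overlap |> left_join(states, by = "bin_id")
  if (anyNA(ov$state)) {
    abort("overlap index references bins missing from the profile; grids differ")
  }
  fracs <- ov |>
    group_by(.data$region_type, .data$region) |>
    summarise(
      amp_bases = sum(.data$bases[.data$state == "amplification"]),
      del_bases = sum(.data$bases[.data$state == "deletion"]),
      .groups = "drop") |>
    right_join(overlap$totals, by = c("region_type", "region")) |>
    mutate(
      amp_bases = coalesce(.data$amp_bases, 0),
      del_bases = coalesce(.data$del_bases, 0),
      frac_amp = ifelse(.data$assigned_bases > 0,
                        .data$amp_bases / .data$assigned_bases, 0),
      frac_del = ifelse(.data$assigned_bases > 0,
                        .data$del_bases / .data$assigned_bases, 0),
      state = case_when(.data$frac_amp > 0.5 ~ "amplification",
                        .data$frac_del > 0.5 ~ "deletion",
                        TRUE ~ "none"))
  band_calls <- fracs |> filter(.data$region_type == "band") |>
    transmute(band = .data$region, chrom = .data$chrom, arm = .data$arm,
              state = .data$state, frac_amp = .data$frac_amp,
              frac_del = .data$frac_del,
              assigned_bases = .data$assigned_bases)
  arm_calls <- fracs |> filter(.data$region_type == "arm") |>
    transmute(arm_name = .data$region, chrom = .data$chrom, arm = .data$arm,
              state = .data$state, frac_amp = .data$frac_amp,
              frac_del = .data$frac_del,
              assigned_bases = .data$assigned_bases)
  burden <- burden_metrics(abs)
  out <- structure(list(sample_id = abs$sample_id,
                        band_calls = band_calls, arm_calls = arm_calls,
                        pga = burden$pga, n_cna = burden$n_cna,
                        altered_bases = burden$altered_bases,
                        total_bases = burden$total_bases),
                   class = "region_call_set")
  out$band_calls <- classify_focal(out)
  out
}

#' Flag focal alterations
#'
#' An altered band is focal iff its containing arm is not called altered in
#' the same direction. The classification depends only on same-direction arm
#' status and is idempotent.
#'
#' @param calls A `region_call_set` with band and arm calls present.
#' @return The band-call tibble with a logical `focal` column (NA for
#'   unaltered bands).
#' @export
classify_focal <- function(calls) {
  stopifnot(inherits(calls, "region_call_set"))
  arm_state <- calls$arm_calls |> select("chrom", "arm", arm_st = "state")
  calls$band_calls |>
    left_join(arm_state, by = c("chrom", "arm")) |>
    mutate(focal = ifelse(.data$state == "none", NA,
                          .data$state != .data$arm_st)) |>
    select(-"arm_st")
}

#' Genomic burden metrics of an absolute profile
#'
#' PGA is the altered fraction of usable autosomal bases; the CNA count
#' merges adjacent altered bins of identical state within a chromosome into
#' single alterations, regardless of segmentation boundaries.
#'
#' @param abs An `absolute_profile`.
#' @return One-row tibble: `sample_id`, `pga`, `n_cna`, `altered_bases`,
#'   `total_bases`.
#' @export
burden_metrics <- function(abs) {
  stopifnot(inherits(abs, "absolute_profile"))
  b <- abs$bins
  altered <- b$state != "neutral"
  n <- nrow(b)
  new_run <- c(TRUE, b$state[-1] != b$state[-n] | b$chrom[-1] != b$chrom[-n])
  tibble(sample_id = abs$sample_id,
         pga = sum(b$width[altered]) / sum(b$width),
         n_cna = sum(new_run & altered),
         altered_bases = sum(b$width[altered]),
         total_bases = sum(b$width))
}

#' @export
print.region_call_set <- function(x, ...) {
  cat(sprintf("<region_call_set> %s: %d/%d bands altered, PGA %.3f, %d CNAs\n",
              x$sample_id, sum(x$band_calls$state != "none"),
              nrow(x$band_calls), x$pga, x$n_cna))
  invisible(x)
}

# Direction-qualified altered band set of a call set.
altered_band_set <- function(calls) {
  calls$band_calls |> filter(.data$state != "none") |>
    transmute(band = .data$band, direction = .data$state) |>
    arrange(.data$band, .data$direction)
}

#' Compare serial samples of one patient
#'
#' Set algebra on direction-qualified band calls: alterations shared by both
#' samples, lost between the first and the second, and newly gained in the
#' second.
#'
#' @param a,b `region_call_set`s of the earlier and later sample, called on
#'   the same cytoband map.
#' @return List of tibbles `shared`, `lost`, `gained`, each with columns
#'   `band` and `direction`, in deterministic (band, direction) order.
#' @export
compare_serial <- function(a, b) {
  stopifnot(inherits(a, "region_call_set"), inherits(b, "region_call_set"))
  if (!identical(sort(a$band_calls$band), sort(b$band_calls$band))) {
    abort("serial samples were called on different cytoband maps")
  }
  sa <- altered_band_set(a)
  sb <- altered_band_set(b)
  list(shared = inner_join(sa, sb, by = c("band", "direction")),
       lost = anti_join(sa, sb, by = c("band", "direction")),
       gained = anti_join(sb, sa, by = c("band", "direction")))
}

#' Bind the band calls of many samples into a cohort call table
#'
#' @param call_sets List of `region_call_set`s.
#' @return Long tibble `sample_id`, `band`, `direction`, `called` (0/1),
#'   with one row per sample x band x direction.
#' @export
cohort_call_table <- function(call_sets) {
  list_rbind(map(call_sets, function(cs) {
    cs$band_calls |>
      tidyr::crossing(direction = c("amplification", "deletion")) |>
      transmute(sample_id = cs$sample_id, band = .data$band,
                direction = .data$direction,
                called = as.integer(.data$state == .data$direction))
  }))
}

#' Bind burden metrics of many samples
#'
#' @param call_sets List of `region_call_set`s.
#' @return Tibble with one burden row per sample.
#' @export
cohort_burden_table <- function(call_sets) {
  list_rbind(map(call_sets, function(cs) {
    tibble(sample_id = cs$sample_id, pga = cs$pga, n_cna = cs$n_cna,
           altered_bases = cs$altered_bases)
  }))
}
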