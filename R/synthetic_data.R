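#' Synthetic low-coverage WGS data with known ground truth
#'
#' Every downstream stage of the pipeline is exercised on simulated bin
#' counts whose purity, integer copy numbers, band-level calls and survival
#' structure are known. The generative model mirrors the assay the pipeline
#' targets: a tumour/normal mixture signal per bin, an overdispersed
#' (negative-binomial) read-count draw at a configurable library size, and an
#' optional multiplicative GC bias.
#'
#' @name synthetic_data
NULL

#' Ground-truth copy-number profile of one sample
#'
#' @param events Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open bp) and `cn` (non-negative integer tumour copy number, never 2:
#'   events encode departures from the diploid baseline).
#' @param purity Tumour-cell fraction in (0, 1]; the assay design targets
#'   0.1-1.0.
#' @param label Optional sample label.
#' @return A `truth_profile` object.
#' @export
truth_profile <- function(events, purity, label = NULL) {
  events <- as_tibble(events)
  need <- c("chrom", "start", "end", "cn")
  if (!all(need %in% names(events))) {
    abort(paste0("events must have columns: ", paste(need, collapse = ", ")))
  }
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1) {
    abort("purity must be a single value in (0, 1]")
  }
  if (nrow(events)) {
    if (any(events$cn < 0) || any(events$cn != round(events$cn))) {
      abort("event cn must be a non-negative integer")
    }
    if (any(events$cn == 2)) abort("event cn must differ from the diploid baseline of 2")
    ev <- events |> arrange(.data$chrom, .data$start)
    same <- ev$chrom[-1] == ev$chrom[-nrow(ev)]
    if (any(same & ev$start[-1] < ev$end[-nrow(ev)])) {
      abort("events within a chromosome must not overlap")
    }
  }
  structure(list(events = events, purity = purity, baseline_cn = 2,
                 label = label),
            class = "truth_profile")
}

#' Count-noise model for simulated libraries
#'
#' @param reads_per_sample Target total read count of the library
#'   (default 1e7, a 10 M-read shallow WGS library).
#' @param dispersion Negative-binomial overdispersion: bin counts have
#'   variance mu + dispersion * mu^2. Zero is the noiseless limit: the
#'   expected (possibly non-integer) counts are returned as-is.
#' @param gc_bias Optional numeric length-2 vector `c(a, b)`: bins receive a
#'   multiplicative bias 1 + a*(gc - 0.45) + b*(gc - 0.45)^2 (floored at
#'   0.05).
#' @param seed Optional RNG seed applied inside [simulate_sample_counts()].
#' @return A `noise_model` object.
#' @export
noise_model <- function(reads_per_sample = 1e7, dispersion = 0.02,
                        gc_bias = NULL, seed = NULL) {
  if (!is.numeric(reads_per_sample) || reads_per_sample <= 0) {
    abort("reads_per_sample must be positive")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    abort("dispersion must be >= 0")
  }
  if (!is.null(gc_bias) && length(gc_bias) != 2L) {
    abort("gc_bias must be NULL or a length-2 numeric vector")
  }
  structure(list(reads_per_sample = reads_per_sample, dispersion = dispersion,
                 gc_bias = gc_bias, seed = seed),
            class = "noise_model")
}

# Length-weighted tumour copy number of every bin under a truth profile.
bin_truth_cn <- function(grid, truth) {
  stopifnot(inherits(grid, "bin_grid"), inherits(truth, "truth_profile"))
  cn <- rep(2, nrow(grid))
  ev <- truth$events
  if (nrow(ev) == 0L) return(cn)
  chrom_ends <- as_tibble(grid) |>
    group_by(.data$chrom) |> summarise(size = max(.data$end), .groups = "drop")
  chk <- ev |> left_join(chrom_ends, by = "chrom")
  if (anyNA(chk$size) || any(chk$start < 0) || any(chk$end > chk$size)) {
    abort("truth events must lie within the bin grid coordinates")
  }
  for (i in seq_len(nrow(ev))) {
    idx <- which(grid$chrom == ev$chrom[i] &
                   grid$end > ev$start[i] & grid$start < ev$end[i])
    if (!length(idx)) next
    ovl <- pmin(grid$end[idx], ev$end[i]) - pmax(grid$start[idx], ev$start[i])
    frac <- ovl / grid$width[idx]
    cn[idx] <- cn[idx] + frac * (ev$cn[i] - 2)
  }
  cn
}

#' Simulate per-bin read counts for one sample
#'
#' The expected count of bin b is proportional to
#' `width_b * (purity * cn_b + (1 - purity) * 2)`, scaled so the expected
#' library total equals `reads_per_sample`; counts are drawn
#' negative-binomially with the model's dispersion (zero dispersion returns
#' the expectations themselves). GC bias, if configured, multiplies the
#' expectation before scaling.
#'
#' @param grid A [make_bin_grid()] bin grid.
#' @param truth A [truth_profile()].
#' @param noise A [noise_model()].
#' @return A tibble with columns `chrom`, `start`, `end`, `count`, one row
#'   per grid bin (usable or not), reproducible when the noise model carries
#'   a seed.
#' @export
simulate_sample_counts <- function(grid, truth, noise = noise_model()) {
  stopifnot(inherits(grid, "bin_grid"), inherits(noise, "noise_model"))
  cn <- bin_truth_cn(grid, truth)
  rho <- truth$purity
  mix <- rho * cn + (1 - rho) * 2
  bias <- rep(1, nrow(grid))
  if (!is.null(noise$gc_bias)) {
    g <- ifelse(is.na(grid$gc), 0.45, grid$gc) - 0.45
    bias <- pmax(0.05, 1 + noise$gc_bias[1] * g + noise$gc_bias[2] * g^2)
  }
  mu <- grid$width * mix * bias
  mu <- mu / sum(mu) * noise$reads_per_sample
  if (noise$dispersion == 0) {
    # the noiseless limit: the expected counts themselves
    return(tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
                  count = mu))
  }
  draw <- function() rnbinom(length(mu), mu = mu, size = 1 / noise$dispersion)
  counts <- if (is.null(noise$seed)) draw() else with_seed(noise$seed, draw())
  tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
         count = counts)
}

#' Draw a random truth profile with a target altered fraction
#'
#' Events are placed on bin boundaries, sized uniformly in `event_bins` bins,
#' and their direction is chosen at each step to keep the genome-wide
#' copy-number mass balanced around the diploid baseline (so the sample-mean
#' normalization stays close to the diploid level, as in near-diploid
#' follicular lymphoma). Single-step events (CN 1 or 3) dominate; two-step
#' events (CN 0 or 4) occur with probability `two_step_prob`.
#'
#' @param grid Bin grid to place events on.
#' @param purity Tumour purity of the sample.
#' @param altered_frac Length-2 range; the realized altered-genome fraction
#'   target is drawn uniformly in it (default 0.20-0.35).
#' @param event_bins Length-2 range of event widths in bins.
#' @param two_step_prob Probability that an event departs two copies from
#'   baseline.
#' @param label Optional sample label.
#' @return A [truth_profile()].
#' @export
simulate_truth_profile <- function(grid, purity, altered_frac = c(0.20, 0.35),
                                   event_bins = c(35, 60),
                                   two_step_prob = 0.15, label = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  chroms <- as_tibble(grid) |>
    group_by(.data$chrom) |>
    summarise(size = max(.data$end), n_bins = n(), .groups = "drop")
  bs <- attr(grid, "bin_size")
  target <- runif(1, altered_frac[1], altered_frac[2])
  total_bins <- nrow(grid)
  events <- list()
  altered <- 0L
  place_event <- function(w, cn) {
    for (tries in 1:100) {
      chr <- sample(chroms$chrom, 1, prob = chroms$size)
      nb <- chroms$n_bins[chroms$chrom == chr]
      if (w >= nb) next
      s <- sample(0:(nb - w), 1) * bs
      e <- min(s + w * bs, chroms$size[chroms$chrom == chr])
      clash <- any(map_lgl(events, function(ev) {
        ev$chrom == chr && s < ev$end && e > ev$start
      }))
      if (clash) next
      events[[length(events) + 1L]] <<- tibble(chrom = chr, start = s,
                                               end = e, cn = cn)
      return(TRUE)
    }
    FALSE
  }
  # gains and losses come in width- and step-matched pairs so the
  # genome-average tumour copy number stays at the diploid baseline, the
  # regime the ploidy-2 mixture inversion targets; the first pair is always
  # single-copy (CN 1/3) - a profile made only of two-copy steps would be
  # scale-ambiguous (indistinguishable from doubled purity), a degeneracy
  # real tumours escape through their single-copy changes
  guard <- 0L
  while (altered < target * total_bins && guard < 200L) {
    guard <- guard + 1L
    w <- sample(seq(event_bins[1], event_bins[2]), 1)
    step <- if (length(events) > 0L && runif(1) < two_step_prob) 2L else 1L
    if (place_event(w, 2L + step) && place_event(w, 2L - step)) {
      altered <- altered + 2L * w
    }
  }
  truth_profile(list_rbind(events), purity = purity, label = label)
}

# ---- Cohorts ------------------------------------------------------------

#' Specification of a simulated two-group cohort
#'
#' @param n_per_group Named integer vector, group label -> sample count.
#' @param region_freqs Tibble with columns `group`, `band`, `direction`
#'   ("amplification"/"deletion") and `freq` in \[0, 1\]: the per-sample
#'   probability that the group carries that alteration.
#' @param purity_range Length-2 purity range sampled uniformly per sample.
#' @param noise A [noise_model()] shared by all samples.
#' @param efs_baseline_hazard Baseline event hazard per month for the
#'   exponential event-free-survival simulation.
#' @param efs_hr Optional tibble `band`, `direction`, `hr` of per-region
#'   hazard ratios multiplying the baseline hazard when the truth carries
#'   the alteration.
#' @param efs_censor_max Uniform censoring horizon in months.
#' @param fish_band Optional band name: samples get a simulated FISH result
#'   for deletion of that band, with the given sensitivity/specificity
#'   against the truth.
#' @param fish_sens,fish_spec FISH operating characteristics.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group, region_freqs,
                        purity_range = c(0.3, 0.9),
                        noise = noise_model(),
                        efs_baseline_hazard = 0.01,
                        efs_hr = NULL,
                        efs_censor_max = 120,
                        fish_band = NULL,
                        fish_sens = 0.9, fish_spec = 0.95) {
  if (is.null(names(n_per_group)) || any(n_per_group < 1)) {
    abort("n_per_group must be a named vector of positive counts")
  }
  region_freqs <- as_tibble(region_freqs)
  need <- c("group", "band", "direction", "freq")
  if (!all(need %in% names(region_freqs))) {
    abort(paste0("region_freqs must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(region_freqs$freq < 0 | region_freqs$freq > 1)) {
    abort("region frequencies must lie in [0, 1]")
  }
  if (!all(region_freqs$direction %in% c("amplification", "deletion"))) {
    abort("direction must be 'amplification' or 'deletion'")
  }
  structure(list(n_per_group = n_per_group, region_freqs = region_freqs,
                 purity_range = purity_range, noise = noise,
                 efs_baseline_hazard = efs_baseline_hazard, efs_hr = efs_hr,
                 efs_censor_max = efs_censor_max, fish_band = fish_band,
                 fish_sens = fish_sens, fish_spec = fish_spec),
            class = "cohort_spec")
}

# Snap a band interval to bin boundaries by rounding, so adjacent bands
# never claim the same bin and each band keeps the majority of its bases.
snap_band <- function(start, end, bin_size, chrom_size) {
  s <- round(start / bin_size) * bin_size
  e <- min(round(end / bin_size) * bin_size, chrom_size)
  if (e <= s) { # band narrower than a bin: take the covering bin
    s <- floor(start / bin_size) * bin_size
    e <- min(s + bin_size, chrom_size)
  }
  c(s, e)
}

#' Simulate a cohort of samples with known band-level truth
#'
#' Each sample draws its alterations independently per (band, direction)
#' according to the group's frequencies; drawn events cover the band's bins
#' at CN 3 (amplification) or CN 1 (deletion). The returned object carries
#' the ground-truth call matrix, truth burden metrics, per-sample purities,
#' simulated event-free survival and (optionally) the simulated bin counts.
#'
#' @param spec A [cohort_spec()].
#' @param grid A [make_bin_grid()] bin grid.
#' @param map A [cytoband_map()]; all bands referenced in the spec must
#'   exist in it.
#' @param seed Global seed; every sub-draw derives from it.
#' @param counts Generate bin counts (set FALSE for call-level simulations,
#'   e.g. null-calibration studies, where counts are not needed).
#' @return A `cna_cohort`: list with `samples` (metadata tibble), `counts`
#'   (named list of count tibbles or NULL), `truth_calls` (tibble
#'   `sample_id`, `band`, `direction` of positive calls), `truth_events`
#'   (named list of event tibbles), `truth_burden` (tibble `sample_id`,
#'   `pga`, `n_cna`, `altered_bases`), plus the grid, map and spec.
#' @export
simulate_cohort <- function(spec, grid, map, seed = 1, counts = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(grid, "bin_grid"),
            inherits(map, "cytoband_map"))
  unknown <- setdiff(spec$region_freqs$band, map$bands$band)
  if (length(unknown)) {
    abort(paste0("region_freqs reference bands absent from the map: ",
                 paste(unknown, collapse = ", ")))
  }
  bs <- attr(grid, "bin_size")
  chrom_ends <- as_tibble(grid) |>
    group_by(.data$chrom) |> summarise(size = max(.data$end), .groups = "drop")
  band_info <- map$bands |>
    semi_join(tibble(band = unique(spec$region_freqs$band)), by = "band") |>
    left_join(chrom_ends, by = "chrom")
  if (anyNA(band_info$size)) {
    abort("region_freqs reference bands on chromosomes absent from the grid")
  }
  with_seed(seed, {
    out_samples <- list(); out_counts <- list(); out_calls <- list()
    out_events <- list(); out_burden <- list()
    for (g in names(spec$n_per_group)) {
      freqs <- spec$region_freqs |> filter(.data$group == g)
      for (i in seq_len(spec$n_per_group[[g]])) {
        sid <- sprintf("%s_%02d", g, i)
        purity <- runif(1, spec$purity_range[1], spec$purity_range[2])
        drawn <- freqs |>
          mutate(hit = rbinom(n(), 1, .data$freq) == 1) |>
          filter(.data$hit)
        # a band drawn in both directions keeps the more frequent one
        drawn <- drawn |>
          group_by(.data$band) |>
          arrange(desc(.data$freq), .data$direction, .by_group = TRUE) |>
          slice(1) |>
          ungroup()
        ev <- drawn |>
          left_join(band_info |> select("band", "chrom", "start", "end", "size"),
                    by = "band")
        events <- if (nrow(ev)) {
          list_rbind(pmap(ev, function(band, direction, chrom, start, end,
                                       size, ...) {
            se <- snap_band(start, end, bs, size)
            tibble(chrom = chrom, start = se[1], end = se[2],
                   cn = if (direction == "amplification") 3L else 1L,
                   band = band)
          })) |> arrange(.data$chrom, .data$start)
        } else {
          tibble(chrom = integer(), start = double(), end = double(),
                 cn = integer(), band = character())
        }
        tp <- truth_profile(events |> select(-"band"), purity = purity,
                            label = sid)
        # truth burden on usable bins, same run-merging rule the caller uses
        cn_bins <- bin_truth_cn(grid, tp)
        ub <- which(grid$usable)
        st <- ifelse(round(cn_bins[ub]) >= 3, "amplification",
                     ifelse(round(cn_bins[ub]) <= 1, "deletion", "neutral"))
        altered <- st != "neutral"
        runs <- sum(altered & (c(TRUE, st[-1] != st[-length(st)] |
                                   grid$chrom[ub][-1] != grid$chrom[ub][-length(ub)])))
        out_burden[[sid]] <- tibble(
          sample_id = sid,
          pga = sum(grid$width[ub][altered]) / sum(grid$width[ub]),
          n_cna = runs,
          altered_bases = sum(grid$width[ub][altered]))
        # survival
        hr <- 1
        if (!is.null(spec$efs_hr) && nrow(ev)) {
          mh <- ev |> inner_join(as_tibble(spec$efs_hr),
                                 by = c("band", "direction"))
          if (nrow(mh)) hr <- prod(mh$hr)
        }
        t_ev <- rexp(1, spec$efs_baseline_hazard * hr)
        t_cn <- runif(1, 0, spec$efs_censor_max)
        fish <- NA_character_
        if (!is.null(spec$fish_band)) {
          truth_del <- any(drawn$band == spec$fish_band &
                             drawn$direction == "deletion")
          pos <- if (truth_del) runif(1) < spec$fish_sens else runif(1) > spec$fish_spec
          fish <- if (pos) "pos" else "neg"
        }
        out_samples[[sid]] <- tibble(
          sample_id = sid, group = g, patient_id = sid,
          recurrence_class = NA_character_, fish_1p36 = fish,
          efs_time = min(t_ev, t_cn), efs_event = t_ev <= t_cn,
          purity = purity)
        if (nrow(drawn)) {
          out_calls[[sid]] <- drawn |>
            transmute(sample_id = sid, band = .data$band,
                      direction = .data$direction)
        }
        out_events[[sid]] <- events
        if (counts) {
          out_counts[[sid]] <- simulate_sample_counts(grid, tp, spec$noise)
        }
      }
    }
    structure(list(
      samples = list_rbind(out_samples),
      counts = if (counts) out_counts else NULL,
      truth_calls = if (length(out_calls)) list_rbind(out_calls) else
        tibble(sample_id = character(), band = character(),
               direction = character()),
      truth_events = out_events,
      truth_burden = list_rbind(out_burden),
      grid = grid, map = map, spec = spec
    ), class = "cna_cohort")
  })
}

#' Expand a cohort's ground-truth calls into a full 0/1 call table
#'
#' Produces the long samples x (band, direction) table the cohort
#' statistics consume, directly from the simulated truth - useful for
#' studying the statistical layer in isolation from the copy-number
#' pipeline (e.g. null-calibration experiments).
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Long tibble `sample_id`, `band`, `direction`, `called`.
#' @export
truth_call_table <- function(cohort) {
  stopifnot(inherits(cohort, "cna_cohort"))
  bands <- unique(cohort$spec$region_freqs$band)
  tidyr::crossing(sample_id = cohort$samples$sample_id, band = bands,
                  direction = c("amplification", "deletion")) |>
    left_join(cohort$truth_calls |> mutate(called = 1L),
              by = c("sample_id", "band", "direction")) |>
    mutate(called = coalesce(.data$called, 0L))
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(sprintf("<cna_cohort> %d samples (%s), %d truth calls\n",
              nrow(x$samples),
              paste(names(x$spec$n_per_group), x$spec$n_per_group,
                    sep = "=", collapse = ", "),
              nrow(x$truth_calls)))
  invisible(x)
}

#' Write the deterministic test fixture bundle
#'
#' Generates a small, fully deterministic bundle used by the test suite:
#' six samples on a six-chromosome grid (purities cycling through 0.2, 0.4
#' and 0.8), including one serial pair whose recurrence retains four of the
#' five primary amplifications, loses one (13q34) and acquires two new
#' alterations - the shared/lost/gained structure seen in serially sampled
#' lymphomas that transform nodally.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Seed for the count noise.
#' @return Invisibly, a tibble manifest of the files written (per-sample
#'   count TSVs, `truth.json`, `metadata.tsv`).
#' @export
write_fixture_bundle <- function(outdir, seed = 20260101) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0) {
    abort(sprintf("cannot write to '%s'", outdir))
  }
  fx <- fixture_bundle_data(seed)
  files <- character()
  for (sid in names(fx$counts)) {
    f <- file.path(outdir, paste0(sid, ".counts.tsv"))
    write_tsv(fx$counts[[sid]], f, progress = FALSE)
    files <- c(files, f)
  }
  truth <- list(
    purity = fx$purity,
    events = lapply(fx$truth, function(tp) as.list(tp$events)),
    bands = fx$bands
  )
  f <- file.path(outdir, "truth.json")
  write_json(truth, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  f <- file.path(outdir, "metadata.tsv")
  write_tsv(fx$metadata, f, progress = FALSE)
  files <- c(files, f)
  invisible(tibble(file = files))
}

# Build the fixture bundle in memory (shared by write_fixture_bundle and
# tests that want the objects without touching disk).
fixture_bundle_data <- function(seed = 20260101) {
  sizes <- grch38_autosomes() |> filter(.data$chrom %in% c(1, 2, 7, 12, 13, 18))
  grid <- make_bin_grid(sizes, bin_size = 5e5)
  map <- synthetic_cytoband_grch38(chroms = c(1, 2, 7, 12, 13, 18))
  bs <- attr(grid, "bin_size")
  chrom_ends <- as_tibble(grid) |>
    group_by(.data$chrom) |> summarise(size = max(.data$end), .groups = "drop")
  band_events <- function(bands, cns) {
    info <- map$bands |> filter(.data$band %in% bands) |>
      left_join(chrom_ends, by = "chrom") |>
      arrange(match(.data$band, bands))
    list_rbind(pmap(list(info$chrom, info$start, info$end, info$size, cns),
                    function(chrom, start, end, size, cn) {
                      se <- snap_band(start, end, bs, size)
                      tibble(chrom = chrom, start = se[1], end = se[2], cn = cn)
                    }))
  }
  first_q_band <- function(chr) {
    map$bands |> filter(.data$chrom == chr, .data$arm == "q",
                        .data$stain != "acen") |>
      arrange(.data$start) |> slice(2) |> pull("band")
  }
  # serial pair: 5 primary amplifications; recurrence keeps 4, loses 13q34,
  # gains a 1q amplification and a 7q11.22 deletion
  primary_bands <- c("2p15", "2p16.1", "12q13.13", "12q14.3", "13q34")
  recur_bands <- c("2p15", "2p16.1", "12q13.13", "12q14.3",
                   first_q_band(1), "7q11.22")
  recur_cns <- c(3L, 3L, 3L, 3L, 3L, 1L)
  singles <- list(
    s1 = list(bands = c("18q21.33"), cns = 3L, purity = 0.2),
    s2 = list(bands = c("1p36.23", "12q13.13"), cns = c(1L, 3L), purity = 0.4),
    s3 = list(bands = c("2p15", "13q14.11"), cns = c(3L, 1L), purity = 0.8),
    s4 = list(bands = character(), cns = integer(), purity = 0.4)
  )
  truth <- list()
  for (nm in names(singles)) {
    sp <- singles[[nm]]
    ev <- if (length(sp$bands)) band_events(sp$bands, sp$cns) else
      tibble(chrom = integer(), start = double(), end = double(), cn = integer())
    truth[[nm]] <- truth_profile(ev, purity = sp$purity, label = nm)
  }
  truth[["case12_primary"]] <- truth_profile(
    band_events(primary_bands, rep(3L, 5)), purity = 0.8,
    label = "case12_primary")
  truth[["case12_recurrence"]] <- truth_profile(
    band_events(recur_bands, recur_cns), purity = 0.8,
    label = "case12_recurrence")
  bands <- c(lapply(singles, function(s) as.list(setNames(s$cns, s$bands))),
             list(case12_primary = as.list(setNames(rep(3L, 5), primary_bands)),
                  case12_recurrence = as.list(setNames(recur_cns, recur_bands))))
  counts <- list()
  purity <- list()
  for (i in seq_along(truth)) {
    nm <- names(truth)[i]
    counts[[nm]] <- simulate_sample_counts(
      grid, truth[[nm]],
      noise_model(reads_per_sample = 1e7, dispersion = 0.01, seed = seed + i))
    purity[[nm]] <- truth[[nm]]$purity
  }
  metadata <- tibble(
    sample_id = names(truth),
    group = c(rep("single", 4), "serial", "serial"),
    patient_id = c("s1", "s2", "s3", "s4", "case12", "case12"),
    recurrence_class = c(rep(NA_character_, 4), "primary", "recurrence"),
    fish_1p36 = NA_character_,
    efs_time = c(24, 36, 18, 48, 37, 12),
    efs_event = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  )
  list(grid = grid, map = map, truth = truth, counts = counts,
       purity = purity, bands = bands, metadata = metadata)
}
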