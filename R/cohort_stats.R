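#' Cohort-level statistics
#'
#' Distinctive alterations between patient groups are screened with the
#' two-sided Fisher exact test, one test per (cytoband, direction), with no
#' multiple-testing correction - the convention of the screening analyses
#' this pipeline reproduces; a Benjamini-Hochberg column is emitted
#' alongside as supplementary output. Burden metrics are compared with the
#' Wilcoxon rank-sum test, concordance against an orthogonal FISH assay is
#' summarized as predictive values, and event-free survival is analyzed
#' with the Kaplan-Meier estimator and the log-rank test.
#'
#' @name cohort_stats
NULL

#' Assemble a cohort table
#'
#' @param samples Metadata tibble with at least `sample_id` and `group`;
#'   optional `patient_id`, `recurrence_class`, `fish_1p36` ("pos"/"neg"/NA),
#'   `efs_time` (months), `efs_event` (logical).
#' @param calls Long call tibble (`sample_id`, `band`, `direction`, `called`)
#'   as produced by [cohort_call_table()].
#' @return A `cohort_table` object.
#' @export
cohort_table <- function(samples, calls) {
  samples <- as_tibble(samples)
  calls <- as_tibble(calls)
  stopifnot(all(c("sample_id", "group") %in% names(samples)),
            all(c("sample_id", "band", "direction", "called") %in% names(calls)))
  if (anyDuplicated(samples$sample_id)) abort("duplicated sample_id in metadata")
  orphan <- setdiff(calls$sample_id, samples$sample_id)
  if (length(orphan)) {
    abort(paste0("calls reference samples missing from metadata: ",
                 paste(utils::head(orphan, 5), collapse = ", ")))
  }
  structure(list(samples = samples, calls = calls), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d samples, %d band-direction columns\n",
              nrow(x$samples),
              nrow(distinct(x$calls, .data$band, .data$direction))))
  invisible(x)
}

# Restrict a cohort table to the first sample per patient when requested.
select_samples <- function(table, samples_per_patient) {
  s <- table$samples
  if (samples_per_patient == "first" && "patient_id" %in% names(s)) {
    s <- s |> group_by(.data$patient_id) |> slice(1) |> ungroup()
  }
  s
}

#' Fisher exact enrichment screen between two groups
#'
#' For each (band, direction) column the 2x2 table of altered vs unaltered
#' samples in the two groups is tested with the conventional two-sided
#' Fisher exact rule (summing hypergeometric probabilities at or below the
#' observed table's). P-values are reported uncorrected, mirroring the
#' screening convention; a BH-adjusted column is provided as supplementary
#' output only.
#'
#' @param table A [cohort_table()].
#' @param group_a,group_b Group labels to contrast.
#' @param samples_per_patient "all" (default) or "first": with "first", only
#'   the first sample per `patient_id` enters the screen, removing the
#'   distortion of serial samples.
#' @return Tibble sorted by p: `band`, `direction`, `a_pos`, `a_n`, `b_pos`,
#'   `b_n`, `odds_ratio` (conditional MLE), `p_value`, `q_value` (BH).
#' @export
fisher_screen <- function(table, group_a, group_b,
                          samples_per_patient = c("all", "first")) {
  stopifnot(inherits(table, "cohort_table"))
  samples_per_patient <- match.arg(samples_per_patient)
  s <- select_samples(table, samples_per_patient)
  ids_a <- s$sample_id[s$group == group_a]
  ids_b <- s$sample_id[s$group == group_b]
  if (!length(ids_a) || !length(ids_b)) {
    abort("both groups must contain at least one sample")
  }
  res <- table$calls |>
    filter(.data$sample_id %in% c(ids_a, ids_b)) |>
    mutate(in_a = .data$sample_id %in% ids_a) |>
    group_by(.data$band, .data$direction) |>
    summarise(a_pos = sum(.data$called[.data$in_a]),
              a_n = length(ids_a),
              b_pos = sum(.data$called[!.data$in_a]),
              b_n = length(ids_b), .groups = "drop")
  tested <- res |>
    mutate(test = pmap(list(.data$a_pos, .data$a_n, .data$b_pos, .data$b_n),
                       function(ap, an, bp, bn) {
                         ft <- fisher.test(matrix(c(ap, an - ap, bp, bn - bp),
                                                  nrow = 2))
                         tibble(odds_ratio = unname(ft$estimate),
                                p_value = ft$p.value)
                       })) |>
    tidyr::unnest("test") |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$band, .data$direction)
  tested
}

#' Compare burden metrics between two groups
#'
#' Wilcoxon rank-sum test, exact when the two groups total at most 20
#' samples without ties, otherwise the normal approximation with tie
#' correction.
#'
#' @param table A [cohort_table()].
#' @param burden Burden tibble (`sample_id` plus metric columns), e.g. from
#'   [cohort_burden_table()].
#' @param metric Column of `burden` to compare (e.g. "pga", "n_cna").
#' @param group_a,group_b Group labels.
#' @param samples_per_patient See [fisher_screen()].
#' @return One-row tibble with per-group medians and IQRs and the two-sided
#'   rank-sum p-value.
#' @export
burden_compare <- function(table, burden, metric, group_a, group_b,
                           samples_per_patient = c("all", "first")) {
  stopifnot(inherits(table, "cohort_table"))
  samples_per_patient <- match.arg(samples_per_patient)
  s <- select_samples(table, samples_per_patient) |>
    inner_join(as_tibble(burden), by = "sample_id")
  xa <- s[[metric]][s$group == group_a]
  xb <- s[[metric]][s$group == group_b]
  if (!length(xa) || !length(xb)) abort("both groups must be non-empty")
  exact <- (length(xa) + length(xb)) <= 20 && !anyDuplicated(c(xa, xb))
  wt <- suppressWarnings(wilcox.test(xa, xb, exact = exact, correct = !exact))
  qa <- quantile(xa, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- quantile(xb, c(0.25, 0.5, 0.75), names = FALSE)
  tibble(metric = metric,
         median_a = qa[2], iqr_lo_a = qa[1], iqr_hi_a = qa[3], n_a = length(xa),
         median_b = qb[2], iqr_lo_b = qb[1], iqr_hi_b = qb[3], n_b = length(xb),
         p_value = wt$p.value, exact = exact)
}

#' Concordance of sequencing-based 1p36 calls with FISH
#'
#' FISH is the reference standard: TP are samples positive by both, FP
#' positive by sequencing only, FN by FISH only, TN by neither. Samples with
#' missing FISH results are excluded. Predictive values are reported as
#' percentages rounded to integers; a predictive value whose denominator is
#' zero is NA, not 0.
#'
#' @param table A [cohort_table()] whose samples carry `fish_1p36`.
#' @param band,direction The sequencing call column to evaluate (default
#'   deletion of "1p36.32").
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `ppv_pct`, `npv_pct`,
#'   `n_evaluable`.
#' @export
fish_concordance <- function(table, band = "1p36.32", direction = "deletion") {
  stopifnot(inherits(table, "cohort_table"))
  if (!"fish_1p36" %in% names(table$samples)) {
    abort("samples must carry a fish_1p36 column")
  }
  seqcall <- table$calls |>
    filter(.data$band == !!band, .data$direction == !!direction) |>
    select("sample_id", "called")
  dat <- table$samples |>
    filter(.data$fish_1p36 %in% c("pos", "neg")) |>
    left_join(seqcall, by = "sample_id") |>
    mutate(called = coalesce(.data$called, 0L))
  if (nrow(dat) == 0L) abort("no samples with evaluable FISH results")
  tp <- sum(dat$fish_1p36 == "pos" & dat$called == 1)
  fp <- sum(dat$fish_1p36 == "neg" & dat$called == 1)
  fn <- sum(dat$fish_1p36 == "pos" & dat$called == 0)
  tn <- sum(dat$fish_1p36 == "neg" & dat$called == 0)
  ppv <- if (tp + fp > 0) round(100 * tp / (tp + fp)) else NA_real_
  npv <- if (tn + fn > 0) round(100 * tn / (tn + fn)) else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         ppv_pct = ppv, npv_pct = npv, n_evaluable = nrow(dat))
}

#' Concordance counts from explicit call vectors
#'
#' Convenience surface for evaluating predictive values directly from
#' paired reference/test call vectors.
#'
#' @param fish Character vector of "pos"/"neg"/NA reference results.
#' @param lcwgs Logical/0-1 vector of sequencing calls, same length.
#' @return Same shape as [fish_concordance()].
#' @export
concordance_counts <- function(fish, lcwgs) {
  stopifnot(length(fish) == length(lcwgs))
  keep <- fish %in% c("pos", "neg")
  if (!any(keep)) abort("no samples with evaluable FISH results")
  fish <- fish[keep]; lcwgs <- as.integer(lcwgs[keep])
  tp <- sum(fish == "pos" & lcwgs == 1); fp <- sum(fish == "neg" & lcwgs == 1)
  fn <- sum(fish == "pos" & lcwgs == 0); tn <- sum(fish == "neg" & lcwgs == 0)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn,
         ppv_pct = if (tp + fp > 0) round(100 * tp / (tp + fp)) else NA_real_,
         npv_pct = if (tn + fn > 0) round(100 * tn / (tn + fn)) else NA_real_,
         n_evaluable = length(fish))
}

#' Event-free survival by alteration status
#'
#' Kaplan-Meier product-limit curves per stratum and the two-group log-rank
#' test (1 df chi-square). Event-free survival runs from diagnosis to
#' recurrence, antilymphoma therapy or death, whichever occurs first; the
#' metadata's `efs_time`/`efs_event` encode that composite endpoint.
#'
#' @param table A [cohort_table()] with positive `efs_time` and logical
#'   `efs_event` for every sample.
#' @param band,direction Stratifying alteration.
#' @return An `efs_fit`: list with `km` (tidy tibble of the product-limit
#'   curves: `stratum`, `time`, `n_risk`, `n_event`, `surv`), `chisq`, `df`,
#'   `p_value`, `n_per_stratum`.
#' @export
efs_analysis <- function(table, band, direction = "amplification") {
  stopifnot(inherits(table, "cohort_table"))
  s <- table$samples
  if (!all(c("efs_time", "efs_event") %in% names(s))) {
    abort("samples must carry efs_time and efs_event")
  }
  if (any(!is.finite(s$efs_time)) || any(s$efs_time <= 0)) {
    abort("efs_time must be positive for all samples")
  }
  calls <- table$calls |>
    filter(.data$band == !!band, .data$direction == !!direction) |>
    select("sample_id", "called")
  dat <- s |> left_join(calls, by = "sample_id") |>
    mutate(called = coalesce(.data$called, 0L),
           stratum = ifelse(.data$called == 1, "altered", "unaltered"))
  n_strat <- table(factor(dat$stratum, levels = c("unaltered", "altered")))
  if (any(n_strat == 0)) {
    abort(sprintf("stratum with zero samples for %s %s", band, direction))
  }
  sf <- survfit(Surv(efs_time, efs_event) ~ stratum, data = dat)
  strata_names <- sub("^stratum=", "", rep(names(sf$strata), sf$strata))
  km <- tibble(stratum = strata_names, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, surv = sf$surv)
  if (length(unique(dat$stratum)) > 1 && sum(dat$efs_event) > 0) {
    sd <- survdiff(Surv(efs_time, efs_event) ~ stratum, data = dat)
    chisq <- unname(sd$chisq)
    df <- length(sd$n) - 1L
    p <- pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- 0; df <- 1L; p <- 1
  }
  structure(list(band = band, direction = direction, km = km, chisq = chisq,
                 df = df, p_value = p,
                 n_per_stratum = as.integer(n_strat)),
            class = "efs_fit")
}

#' @export
print.efs_fit <- function(x, ...) {
  cat(sprintf("<efs_fit> %s %s: log-rank chi-square %.3f (df %d), p = %.3g\n",
              x$band, x$direction, x$chisq, x$df, x$p_value))
  invisible(x)
}
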