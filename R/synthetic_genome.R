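#' Synthetic GRCh38-patterned cytoband map
#'
#' Builds an in-code, genome-wide cytoband map for simulation and testing. It
#' is synthetic, not the UCSC table: chromosome lengths are the real GRCh38
#' autosome lengths, centromere positions are approximate, and a curated set
#' of anchor bands carries the real names and approximate coordinates of the
#' cytobands most relevant to follicular-lymphoma copy-number work (e.g.
#' 18q21.33 at the BCL2 locus, 9p21.3 at CDKN2A/B, 2p15 at XPO1). The
#' remaining sequence is filled with equal-width filler bands numbered from
#' 51 upward (e.g. "4q52.1") so that filler names can never collide with a
#' real cytoband name.
#'
#' @param chroms Autosomes to include (default 1:22).
#' @param filler_width Approximate width of filler bands in bp (default 15 Mb).
#' @return A [cytoband_map()].
#' @export
synthetic_cytoband_grch38 <- function(chroms = 1:22, filler_width = 15e6) {
  sizes <- grch38_autosomes() |> filter(.data$chrom %in% chroms)
  if (nrow(sizes) == 0L) abort("no valid autosomes requested")
  cen_frac <- c(0.497, 0.385, 0.455, 0.263, 0.267, 0.350, 0.377, 0.312,
                0.310, 0.298, 0.395, 0.267, 0.155, 0.160, 0.190, 0.407,
                0.300, 0.230, 0.440, 0.440, 0.280, 0.290)
  anchors <- tibble(
    chrom = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 6L, 6L, 7L, 9L, 10L, 12L, 12L,
              13L, 13L, 13L, 18L),
    start = c(2.3e6, 7.2e6, 9.2e6, 54.7e6, 61.1e6, 138.7e6, 142.8e6,
              93.1e6, 135.2e6, 67.5e6, 19.9e6, 89.6e6, 51.3e6, 65.1e6,
              39.6e6, 46.7e6, 109.6e6, 61.6e6),
    end = c(5.4e6, 9.2e6, 12.7e6, 61.1e6, 64.1e6, 142.8e6, 149.2e6,
            99.5e6, 139.0e6, 72.7e6, 25.3e6, 92.4e6, 53.7e6, 67.3e6,
            44.6e6, 50.3e6, 114364328, 63.9e6),
    name = c("p36.32", "p36.23", "p36.22", "p16.1", "p15", "q23", "q24",
             "q16.1", "q23.3", "q11.22", "p21.3", "q23.32", "q13.13",
             "q14.3", "q14.11", "q14.2", "q34", "q21.33")
  )
  half_cen <- 2e6
  bands <- vector("list", nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    chr <- sizes$chrom[i]
    L <- sizes$size[i]
    cen <- round(cen_frac[chr] * L / 1e5) * 1e5
    arm_bands <- function(arm, a0, a1) {
      anc <- anchors |>
        filter(.data$chrom == chr, substr(.data$name, 1, 1) == arm,
               .data$start >= a0, .data$end <= a1) |>
        arrange(.data$start)
      brk0 <- sort(unique(c(a0, anc$start, anc$end, a1)))
      out <- list()
      k <- 51L
      for (j in seq_len(length(brk0) - 1L)) {
        lo <- brk0[j]; hi <- brk0[j + 1L]
        hit <- anc$start == lo & anc$end == hi
        if (any(hit)) {
          out[[length(out) + 1L]] <- tibble(start = lo, end = hi,
                                            name = anc$name[hit][1])
        } else {
          npc <- max(1L, ceiling((hi - lo) / filler_width))
          cuts <- round(seq(lo, hi, length.out = npc + 1L) / 1e5) * 1e5
          cuts[1] <- lo; cuts[npc + 1L] <- hi
          for (p in seq_len(npc)) {
            out[[length(out) + 1L]] <- tibble(
              start = cuts[p], end = cuts[p + 1L],
              name = sprintf("%s%d.1", arm, k))
            k <- k + 1L
          }
        }
      }
      list_rbind(out)
    }
    p <- arm_bands("p", 0, cen - half_cen)
    q <- arm_bands("q", cen + half_cen, L)
    chr_bands <- bind_rows(
      p,
      tibble(start = cen - half_cen, end = cen, name = "p11"),
      tibble(start = cen, end = cen + half_cen, name = "q11"),
      q
    ) |> arrange(.data$start)
    chr_bands$stain <- rep_len(c("gneg", "gpos50"), nrow(chr_bands))
    chr_bands$stain[chr_bands$name %in% c("p11", "q11")] <- "acen"
    bands[[i]] <- chr_bands |>
      transmute(chrom = chr, start = .data$start, end = .data$end,
                band = paste0(chr, .data$name), stain = .data$stain)
  }
  cytoband_map(list_rbind(bands))
}

# Small genome used by fast simulation-heavy tests: six autosomes, real
# chromosome identities, shortened lengths (~460 bins at 500 kb).
#' Reduced chromosome-size table for fast simulations
#'
#' Six autosomes with shortened lengths, giving roughly 460 bins at the
#' default 500-kb bin size. Purity-recovery and calibration simulations use
#' this genome so that replicated runs stay fast; the coordinate logic is
#' identical to the full-genome case.
#'
#' @return A tibble with columns `chrom` and `size`.
#' @export
toy_chrom_sizes <- function() {
  tibble(chrom = 1:6, size = c(50e6, 45e6, 40e6, 35e6, 30e6, 25e6))
}

#' Simulation genome for purity-recovery studies
#'
#' Twenty-two autosomes of 80 Mb each (3520 bins at 500 kb). The genome is
#' large enough that simulated tumours carry many independent alteration
#' events - which is what conditions the purity fit - and each event stays
#' a modest fraction of its chromosome, so the permutation null of the
#' segmentation scan is not dominated by the signal itself; per-chromosome
#' length is still short enough to keep replicated permutation runs fast.
#'
#' @return A tibble with columns `chrom` and `size`.
#' @export
sim_chrom_sizes <- function() {
  tibble(chrom = 1:22, size = rep(80e6, 22))
}
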