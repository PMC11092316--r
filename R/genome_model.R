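#' Genome coordinate model: bin grids, cytobands and chromosome arms
#'
#' The pipeline reports copy-number alterations on a fixed tiling of the
#' autosomes into equal-width bins (500 kb by default) and summarizes them on
#' cytobands and chromosome arms. This file owns those coordinate systems and
#' the bin-to-region overlap index every region-level statement relies on.
#' Coordinates are 0-based half-open internally (the UCSC dialect); exported
#' human-readable tables use 1-based inclusive starts.
#'
#' @name genome_model
NULL

# Autosome order used everywhere: chromosomes are stored as integers 1..22.
parse_chrom <- function(x) {
  out <- suppressWarnings(as.integer(sub("^chr", "", as.character(x))))
  out[!(out %in% 1:22)] <- NA_integer_
  out
}

#' GRCh38 autosome lengths
#'
#' Chromosome sizes (bp) of the 22 human autosomes in the GRCh38 primary
#' assembly, the coordinate frame the default 500-kb bin grid tiles.
#'
#' @return A tibble with columns `chrom` (integer 1-22) and `size` (bp).
#' @export
grch38_autosomes <- function() {
  tibble(
    chrom = 1:22,
    size = c(
      248956422L, 242193529L, 198295559L, 190214555L, 181538259L,
      170805979L, 159345973L, 145138636L, 138394717L, 133797422L,
      135086622L, 133275309L, 114364328L, 107043718L, 101991189L,
      90338345L, 83257441L, 80373285L, 58617616L, 64444167L,
      46709983L, 50818468L
    )
  )
}

#' Read a two-column chrom.sizes table
#'
#' Non-autosomal entries (sex chromosomes, scaffolds) are dropped with a
#' warning: the pipeline analyzes autosomes only.
#'
#' @param path Path to a tab-separated file with columns chromosome and size.
#' @return A tibble with columns `chrom` (integer) and `size` (bp).
#' @export
read_chrom_sizes <- function(path) {
  raw <- read_tsv(path, col_names = c("chrom", "size"),
                  col_types = cols(chrom = col_character(), size = col_double()),
                  progress = FALSE)
  chrom <- parse_chrom(raw$chrom)
  if (anyNA(chrom)) {
    warn(paste0("dropping non-autosomal chromosomes: ",
                paste(unique(raw$chrom[is.na(chrom)]), collapse = ", ")))
  }
  out <- tibble(chrom = chrom, size = raw$size) |>
    filter(!is.na(.data$chrom)) |>
    arrange(.data$chrom)
  if (nrow(out) == 0L) abort("no autosomes found in chrom.sizes file")
  out
}

# ---- CytobandMap --------------------------------------------------------

#' Construct a cytoband map from a band table
#'
#' Validates band contiguity within chromosomes and derives chromosome-arm
#' intervals from the centromeric `acen` bands: the p arm runs from 0 to the
#' first acen base, the q arm from the last acen base to the chromosome end.
#'
#' @param bands Tibble with columns `chrom` (integer 1-22), `start`, `end`
#'   (0-based half-open bp), `band` (full band name, e.g. "18q21.33") and
#'   `stain` (UCSC Giemsa stain, `acen` marking centromeric bands).
#' @return An object of class `cytoband_map`: a list with tibbles `bands`
#'   (with an `arm` column parsed from the band name) and `arms`
#'   (`chrom`, `arm`, `arm_name`, `start`, `end`).
#' @export
cytoband_map <- function(bands) {
  stopifnot(is.data.frame(bands))
  need <- c("chrom", "start", "end", "band", "stain")
  if (!all(need %in% names(bands))) {
    abort(paste0("band table must have columns: ", paste(need, collapse = ", ")))
  }
  bands <- as_tibble(bands) |>
    mutate(chrom = as.integer(.data$chrom),
           start = as.double(.data$start), end = as.double(.data$end)) |>
    arrange(.data$chrom, .data$start)
  if (any(bands$end <= bands$start)) abort("bands must have end > start")
  by_chr <- split(bands, bands$chrom)
  for (b in by_chr) {
    if (any(b$start[-1] != b$end[-nrow(b)])) {
      abort(sprintf("bands on chromosome %d are not contiguous", b$chrom[1]))
    }
  }
  arm <- sub("^[0-9]+", "", bands$band)
  arm <- substr(arm, 1, 1)
  if (!all(arm %in% c("p", "q"))) {
    abort("band names must carry a p/q arm designator (e.g. '18q21.33')")
  }
  bands$arm <- arm
  arms <- lapply(by_chr, function(b) {
    acen <- b$stain == "acen"
    if (!any(acen)) {
      abort(sprintf("chromosome %d has no acen band; cannot derive arms", b$chrom[1]))
    }
    tibble(
      chrom = b$chrom[1],
      arm = c("p", "q"),
      start = c(min(b$start), max(b$end[acen])),
      end = c(min(b$start[acen]), max(b$end))
    )
  })
  arms <- list_rbind(arms) |>
    filter(.data$end > .data$start) |>
    mutate(arm_name = paste0(.data$chrom, .data$arm)) |>
    select("chrom", "arm", "arm_name", "start", "end")
  structure(list(bands = bands, arms = arms), class = "cytoband_map")
}

#' Read a UCSC cytoBand table
#'
#' Parses the 5-column tab-separated UCSC `cytoBand.txt` dialect
#' (chrom, start, end, band, gieStain; 0-based half-open). Band names are
#' prefixed with the chromosome number ("q21.33" on chr18 becomes
#' "18q21.33"). Non-autosomal chromosomes are dropped with a warning.
#'
#' @param path Path to the cytoBand file (plain text or gzipped).
#' @return A [cytoband_map()] object.
#' @export
read_cytoband_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    abort(sprintf("malformed cytoBand row at line %d: expected 5 tab-separated columns, found %d",
                  which(nf != 5L)[1], nf[nf != 5L][1]))
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.double(m[, 2]))
  end <- suppressWarnings(as.double(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    abort(sprintf("malformed cytoBand row at line %d: non-numeric coordinates", bad[1]))
  }
  chrom <- parse_chrom(m[, 1])
  if (anyNA(chrom)) {
    warn(paste0("dropping bands on non-autosomal chromosomes: ",
                paste(unique(m[is.na(chrom), 1]), collapse = ", ")))
  }
  keep <- !is.na(chrom)
  cytoband_map(tibble(
    chrom = chrom[keep],
    start = start[keep],
    end = end[keep],
    band = paste0(chrom[keep], m[keep, 4]),
    stain = m[keep, 5]
  ))
}

#' @export
print.cytoband_map <- function(x, ...) {
  cat(sprintf("<cytoband_map> %d bands, %d arms on %d autosomes\n",
              nrow(x$bands), nrow(x$arms), length(unique(x$bands$chrom))))
  invisible(x)
}

# ---- BinGrid ------------------------------------------------------------

#' Tile autosomes into fixed-width bins
#'
#' Produces the deterministic end-to-end tiling of each autosome into
#' `bin_size` windows (the last bin of a chromosome may be shorter). Sex
#' chromosomes in the input are excluded with a warning; all burden
#' denominators downstream are therefore autosomal by construction. A bin is
#' flagged `usable` when its mappability is at or above `mappability_floor`
#' and it is not blacklisted.
#'
#' @param chrom_sizes Tibble with columns `chrom` and `size` (bp), e.g.
#'   [grch38_autosomes()], or a named vector chrom -> size.
#' @param bin_size Bin width in bp (default 500 kb).
#' @param annotations Optional tibble with columns `chrom`, `start` and any of
#'   `gc` (fraction), `mappability` (fraction), `blacklist` (logical), joined
#'   onto the grid by bin start.
#' @param mappability_floor Minimum mappability for a usable bin (default 0.5).
#' @return A `bin_grid`: a tibble with columns `bin_id`, `chrom`, `start`,
#'   `end`, `width`, `gc`, `mappability`, `blacklist`, `usable`, carrying the
#'   bin size and floor as attributes.
#' @export
make_bin_grid <- function(chrom_sizes, bin_size = 5e5, annotations = NULL,
                          mappability_floor = 0.5) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), size = unname(chrom_sizes))
  }
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "size") %in% names(chrom_sizes)))
  if (nrow(chrom_sizes) == 0L) abort("chrom_sizes is empty")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    abort("bin_size must be a single positive number")
  }
  chrom <- parse_chrom(chrom_sizes$chrom)
  if (anyNA(chrom)) {
    warn(paste0("excluding non-autosomal chromosomes from the bin grid: ",
                paste(unique(chrom_sizes$chrom[is.na(chrom)]), collapse = ", ")))
  }
  sizes <- tibble(chrom = chrom, size = as.double(chrom_sizes$size)) |>
    filter(!is.na(.data$chrom)) |>
    arrange(.data$chrom)
  if (nrow(sizes) == 0L) abort("chrom_sizes contains no autosomes")
  grid <- sizes |>
    mutate(starts = map(.data$size, ~ seq(0, .x - 1, by = bin_size))) |>
    tidyr::unnest_longer("starts") |>
    transmute(chrom = .data$chrom, start = .data$starts,
              end = pmin(.data$starts + bin_size, .data$size)) |>
    mutate(width = .data$end - .data$start, gc = NA_real_,
           mappability = 1, blacklist = FALSE)
  if (!is.null(annotations)) {
    ann <- as_tibble(annotations) |> mutate(chrom = parse_chrom(.data$chrom))
    keep <- intersect(c("gc", "mappability", "blacklist"), names(ann))
    ann <- ann |> select("chrom", "start", all_of(keep))
    joined <- grid |> select("chrom", "start") |>
      left_join(ann, by = c("chrom", "start"))
    if ("gc" %in% keep) grid$gc <- joined$gc
    if ("mappability" %in% keep) {
      grid$mappability <- coalesce(joined$mappability, 1)
    }
    if ("blacklist" %in% keep) {
      grid$blacklist <- coalesce(joined$blacklist, FALSE)
    }
  }
  grid <- grid |>
    mutate(usable = .data$mappability >= mappability_floor & !.data$blacklist,
           bin_id = row_number()) |>
    select("bin_id", "chrom", "start", "end", "width", "gc",
           "mappability", "blacklist", "usable")
  structure(grid, class = c("bin_grid", class(grid)),
            bin_size = bin_size, mappability_floor = mappability_floor)
}

#' Index the overlap between a bin grid and cytoband/arm regions
#'
#' For every cytoband and chromosome arm, records which usable bins overlap it
#' and how many bases each contributes. Assigned bases partition the usable
#' binned genome: summed over bands (or over arms) they equal the usable
#' genome length intersected with the band map, with no double counting.
#' Regions overlapping no usable bin (e.g. acrocentric p arms under a
#' mappability blacklist) are retained with zero assigned bases and are never
#' callable.
#'
#' @param grid A [make_bin_grid()] bin grid.
#' @param map A [cytoband_map()].
#' @return A `region_overlap` object: list with `overlap` (tibble
#'   `region_type`, `region`, `chrom`, `arm`, `bin_id`, `bases`) and `totals`
#'   (tibble `region_type`, `region`, `chrom`, `arm`, `assigned_bases`).
#' @export
bin_region_overlap <- function(grid, map) {
  stopifnot(inherits(grid, "bin_grid"), inherits(map, "cytoband_map"))
  bins <- as_tibble(grid) |> filter(.data$usable)
  regions <- bind_rows(
    map$bands |> transmute(region_type = "band", region = .data$band,
                           chrom = .data$chrom, arm = .data$arm,
                           start = .data$start, end = .data$end),
    map$arms |> transmute(region_type = "arm", region = .data$arm_name,
                          chrom = .data$chrom, arm = .data$arm,
                          start = .data$start, end = .data$end)
  )
  ov <- inner_join(regions, bins, by = "chrom", suffix = c("", ".bin"),
                   relationship = "many-to-many") |>
    mutate(bases = pmax(0, pmin(.data$end, .data$end.bin) -
                           pmax(.data$start, .data$start.bin))) |>
    filter(.data$bases > 0) |>
    select("region_type", "region", "chrom", "arm", "bin_id", "bases") |>
    arrange(.data$region_type, .data$chrom, .data$bin_id)
  if (nrow(ov) == 0L) abort("bin grid and cytoband map do not overlap at all")
  totals <- regions |>
    left_join(ov |> group_by(.data$region_type, .data$region) |>
                summarise(assigned_bases = sum(.data$bases), .groups = "drop"),
              by = c("region_type", "region")) |>
    mutate(assigned_bases = coalesce(.data$assigned_bases, 0)) |>
    select("region_type", "region", "chrom", "arm", "assigned_bases")
  structure(list(overlap = ov, totals = totals), class = "region_overlap")
}

#' @export
print.region_overlap <- function(x, ...) {
  cat(sprintf("<region_overlap> %d bin-region pairs over %d regions\n",
              nrow(x$overlap), nrow(x$totals)))
  invisible(x)
}
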