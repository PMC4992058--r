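# Regions are kept as tibbles in BED convention: 0-based half-open
# [start, end). Conversion to 1-based GRanges happens only at the
# countOverlaps boundary.
as_regions <- function(regions) {
  if (!is.data.frame(regions)) {
    abort("`regions` must be a data frame with chrom, start, end, region_id.")
  }
  missing_cols <- setdiff(c("chrom", "start", "end", "region_id"),
                          names(regions))
  if (length(missing_cols) > 0) {
    abort(paste0("`regions` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  regions <- tibble::as_tibble(regions)
  if (!"strand" %in% names(regions)) regions$strand <- "."
  if (any(regions$start < 0) || any(regions$start >= regions$end)) {
    abort("Regions must satisfy 0 <= start < end.")
  }
  if (anyDuplicated(regions$region_id)) {
    abort("`region_id` values must be unique.")
  }
  regions
}

#' Read paired-end fragments from a SAM/BAM file
#'
#' Loads one record per sequenced fragment — the leftmost mate of each
#' aligned pair, identified by its positive template length — with the
#' fields needed for filtering and midpoint counting. SAM input is converted
#' on the fly.
#'
#' @param path Path to a SAM or BAM file.
#' @return A tibble with columns `chrom`, `pos` (0-based leftmost fragment
#'   position), `tlen` (absolute template length), `mapq` and `flag`.
#'   Records without a positive template length (unpaired or rightmost
#'   mates) are skipped; the number skipped is reported as attribute
#'   `n_skipped`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) abort(paste0("Cannot read alignments: ", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("rname", "pos", "mapq", "flag", "isize")
  rec <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  keep <- !is.na(rec$isize) & rec$isize > 0 & !is.na(rec$pos)
  n_skipped <- sum(!keep)
  out <- tibble::tibble(chrom = as.character(rec$rname[keep]),
                        pos = rec$pos[keep] - 1L,
                        tlen = abs(rec$isize[keep]),
                        mapq = rec$mapq[keep],
                        flag = rec$flag[keep])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter fragments on mapping quality, template length and flags
#'
#' Keeps fragments with mapping quality at least `mapq_min`, absolute
#' template length inside the closed interval `tlen_range`, and none of the
#' `exclude_flags` bits set. The defaults retain mono-nucleosome-sized
#' fragments (120-240 bp, both bounds inclusive), require mapping quality
#' 20, and drop duplicate-marked fragments (flag bit 1024). The three
#' filters commute, so their order is immaterial.
#'
#' @param fragments Fragment tibble from [read_fragments()] (columns `tlen`,
#'   `mapq`, `flag`).
#' @param mapq_min Minimum mapping quality.
#' @param tlen_range Closed \[min, max\] interval on absolute template
#'   length.
#' @param exclude_flag Integer bitmask; fragments with any of these flag
#'   bits set are dropped.
#' @return The retained rows of `fragments`.
#' @export
filter_fragments <- function(fragments, mapq_min = 20L,
                             tlen_range = c(120L, 240L),
                             exclude_flag = 1024L) {
  stopifnot(is.data.frame(fragments),
            all(c("tlen", "mapq", "flag") %in% names(fragments)),
            length(tlen_range) == 2, tlen_range[1] <= tlen_range[2])
  atl <- abs(fragments$tlen)
  keep <- fragments$mapq >= mapq_min &
    atl >= tlen_range[1] & atl <= tlen_range[2] &
    bitwAnd(as.integer(fragments$flag), as.integer(exclude_flag)) == 0L
  fragments[keep, , drop = FALSE]
}

#' Fragment midpoints
#'
#' The counting position of a fragment: its leftmost position plus half the
#' absolute template length, rounded down (0-based). Invariant to which mate
#' was inspected since it uses the leftmost position and |tlen|.
#'
#' @param fragments Fragment tibble (columns `pos`, `tlen`).
#' @param point `"midpoint"` (default) or `"start"` (leftmost position).
#' @return Integer vector of 0-based genomic positions.
#' @export
fragment_midpoints <- function(fragments, point = c("midpoint", "start")) {
  point <- match.arg(point)
  if (any(fragments$tlen == 0)) {
    abort("Fragment with zero template length has no defined midpoint.")
  }
  if (point == "start") return(as.integer(fragments$pos))
  as.integer(fragments$pos + abs(fragments$tlen) %/% 2)
}

#' Count fragment midpoints in regions
#'
#' Counts, for each region, the filtered-fragment counting points m with
#' `start <= m < end` (0-based half-open, BED convention). Regions may
#' overlap; each is counted independently. The result is deterministic and
#' independent of fragment order.
#'
#' @param fragments Fragment tibble (after [filter_fragments()]).
#' @param regions Region tibble with `chrom`, `start`, `end`, `region_id`
#'   (0-based half-open).
#' @param point Passed to [fragment_midpoints()].
#' @return A tibble `region_id`, `count` in the input region order. If a
#'   region chromosome carries no fragments a warning is raised and the
#'   count is 0.
#' @export
count_fragments <- function(fragments, regions,
                            point = c("midpoint", "start")) {
  regions <- as_regions(regions)
  point <- match.arg(point)
  missing_chrom <- setdiff(unique(regions$chrom), unique(fragments$chrom))
  if (length(missing_chrom) > 0) {
    warn(paste0("No fragments on chromosome(s): ",
                paste(missing_chrom, collapse = ", "), "; counts are 0."))
  }
  lv <- unique(c(regions$chrom, fragments$chrom))
  gr_regions <- GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = lv),
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  if (nrow(fragments) == 0) {
    return(tibble::tibble(region_id = regions$region_id,
                          count = rep(0L, nrow(regions))))
  }
  mids <- fragment_midpoints(fragments, point)
  gr_mids <- GenomicRanges::GRanges(
    seqnames = factor(fragments$chrom, levels = lv),
    ranges = IRanges::IRanges(start = mids + 1L, width = 1L))
  tibble::tibble(region_id = regions$region_id,
                 count = GenomicRanges::countOverlaps(gr_regions, gr_mids))
}

#' Build treatment/control count tables over a region set
#'
#' Convenience wrapper: reads, filters and midpoint-counts two alignment
#' files over a common region set and returns a table ready for [enrich()].
#'
#' @param treatment_path,control_path SAM/BAM paths.
#' @param regions Region tibble (0-based half-open).
#' @param mapq_min,tlen_range,exclude_flag Passed to [filter_fragments()].
#' @param point Passed to [count_fragments()].
#' @return A tibble `region_id`, `r` (control), `s` (treatment).
#' @export
count_pair <- function(treatment_path, control_path, regions,
                       mapq_min = 20L, tlen_range = c(120L, 240L),
                       exclude_flag = 1024L,
                       point = c("midpoint", "start")) {
  point <- match.arg(point)
  regions <- as_regions(regions)
  one <- function(path) {
    fr <- filter_fragments(read_fragments(path), mapq_min = mapq_min,
                           tlen_range = tlen_range,
                           exclude_flag = exclude_flag)
    count_fragments(fr, regions, point = point)$count
  }
  tibble::tibble(region_id = regions$region_id,
                 r = one(control_path), s = one(treatment_path))
}
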