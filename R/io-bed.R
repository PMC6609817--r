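#' Read a BED file into a region mask
#'
#' Reads a 3+ column BED (0-based half-open), merges overlapping intervals
#' per chromosome, and returns a tidy mask tibble. Used for exclusion masks
#' such as repeats, segmental duplications and non-diploid copy-number
#' intervals.
#'
#' @param path BED path.
#' @param label Mask label recorded on every interval (e.g. "repeats",
#'   "cnv").
#' @return A tibble `chrom`, `start`, `end`, `label` with sorted,
#'   non-overlapping, non-empty intervals per chromosome.
#' @export
read_bed <- function(path, label = "mask") {
  if (!file.exists(path)) abort(sprintf("BED not found: %s", path))
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !grepl("^(track|browser|#)", raw)]
  if (length(raw) == 0) return(region_mask(tibble(chrom = character(), start = integer(), end = integer()), label))
  parts <- strsplit(raw, "\t| +")
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad)) abort(sprintf("malformed BED line %d in %s", bad[1], path))
  df <- tibble(
    chrom = vapply(parts, `[[`, character(1), 1),
    start = suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2))),
    end = suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 3)))
  )
  if (anyNA(df$start) || anyNA(df$end)) {
    abort(sprintf(
      "malformed BED line %d in %s",
      which(is.na(df$start) | is.na(df$end))[1], path
    ))
  }
  region_mask(df, label)
}

#' Build a merged region mask from an interval tibble
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param label Mask label.
#' @return Merged mask tibble (`chrom`, `start`, `end`, `label`).
#' @export
region_mask <- function(intervals, label = "mask") {
  if (nrow(intervals) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(), label = character()))
  }
  stopifnot(all(intervals$end > intervals$start))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end)
  ))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    label = label
  ) |> dplyr::arrange(.data$chrom, .data$start)
}

#' Test positions for mask membership
#'
#' @param mask Mask tibble from [read_bed()] or [region_mask()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Logical vector: does each position fall inside the mask?
#' @export
mask_overlaps <- function(mask, chrom, pos) {
  if (nrow(mask) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
  s <- GenomicRanges::GRanges(mask$chrom, IRanges::IRanges(mask$start + 1L, mask$end))
  ## disjoint seqlevels between query and mask are expected, not a problem
  suppressWarnings(IRanges::overlapsAny(q, s))
}

#' Total masked length
#' @param mask Mask tibble.
#' @return Total covered bases across chromosomes.
#' @export
mask_width <- function(mask) {
  sum(as.numeric(mask$end - mask$start))
}
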