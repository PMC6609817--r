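#' Read barcoded alignments from a BAM file into a tibble
#'
#' Loads reads overlapping a region from a coordinate-sorted, indexed BAM
#' file produced by a linked-read aligner. The molecular barcode is parsed
#' from the barcode tag (default `BX`); an aligner haplotype tag (`HP`) is
#' carried along when present but never required — haplotype assignment is
#' recomputed from the phased VCF. Unmapped reads are excluded. Positions are
#' converted to the package's 0-based half-open convention.
#'
#' Reads flagged duplicate, secondary or supplementary are returned (flags
#' preserved) but are excluded from depth and allele counts downstream.
#'
#' @param path Path to an indexed BAM file.
#' @param region Optional region as a list/tibble with `chrom`, `start`,
#'   `end` (0-based half-open), e.g. `genome_region("chr1", 0, 1e6)`. When
#'   `NULL`, the whole file is read.
#' @param barcode_tag SAM tag holding the molecular barcode (default "BX").
#' @return A tibble with one row per aligned read: `read_name`, `chrom`,
#'   `start`, `end` (0-based half-open reference span), `cigar`, `seq`,
#'   `qual` (phred+33 string), `mapq`, flag columns (`is_reverse`,
#'   `is_duplicate`, `is_secondary`, `is_supplementary`, `is_proper_pair`,
#'   `is_read1`), `mate_start`, `barcode`, `hp_tag`, `pair_id`.
#' @export
read_alignments <- function(path, region = NULL, barcode_tag = "BX") {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  bai <- paste0(path, ".bai")
  if (!is.null(region) && !file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", path))) {
    abort(sprintf(
      "BAM index not found for %s; create it with Rsamtools::indexBam() or `samtools index`",
      path
    ))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mpos", "seq", "qual")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(what = what, tag = c(barcode_tag, "HP"), flag = flag)
  } else {
    region <- as_region(region)
    gr <- GenomicRanges::GRanges(
      region$chrom,
      IRanges::IRanges(region$start + 1L, region$end)
    )
    param <- Rsamtools::ScanBamParam(
      what = what, tag = c(barcode_tag, "HP"),
      flag = flag, which = gr
    )
  }
  res <- Rsamtools::scanBam(path, param = param)
  ## concatenate list-of-regions result
  pick <- function(field) do.call(c, lapply(res, function(x) x[[field]]))
  qname <- pick("qname")
  if (length(qname) == 0) return(empty_reads())
  fl <- pick("flag")
  seqs <- do.call(c, lapply(res, function(x) as.character(x$seq)))
  quals <- do.call(c, lapply(res, function(x) as.character(x$qual)))
  bx <- do.call(c, lapply(res, function(x) {
    v <- x$tag[[barcode_tag]]
    if (is.null(v)) rep(NA_character_, length(x$qname)) else as.character(v)
  }))
  hp <- do.call(c, lapply(res, function(x) {
    v <- x$tag[["HP"]]
    if (is.null(v)) rep(NA_integer_, length(x$qname)) else as.integer(v)
  }))
  cigar <- pick("cigar")
  start0 <- as.integer(pick("pos")) - 1L
  out <- tibble(
    read_name = qname,
    chrom = as.character(pick("rname")),
    start = start0,
    end = start0 + cigar_ref_width(cigar),
    cigar = cigar,
    seq = seqs,
    qual = quals,
    mapq = as.integer(pick("mapq")),
    is_reverse = bitwAnd(fl, 16L) > 0L,
    is_duplicate = bitwAnd(fl, 1024L) > 0L,
    is_secondary = bitwAnd(fl, 256L) > 0L,
    is_supplementary = bitwAnd(fl, 2048L) > 0L,
    is_proper_pair = bitwAnd(fl, 2L) > 0L,
    is_read1 = bitwAnd(fl, 64L) > 0L,
    mate_start = as.integer(pick("mpos")) - 1L,
    barcode = bx,
    hp_tag = hp,
    pair_id = qname
  )
  if (!is.null(region)) {
    out <- dplyr::filter(out, .data$end > region$start, .data$start < region$end)
  }
  validate_reads(out)
  dplyr::arrange(out, .data$chrom, .data$start)
}

empty_reads <- function() {
  tibble(
    read_name = character(), chrom = character(), start = integer(),
    end = integer(), cigar = character(), seq = character(), qual = character(),
    mapq = integer(), is_reverse = logical(), is_duplicate = logical(),
    is_secondary = logical(), is_supplementary = logical(),
    is_proper_pair = logical(), is_read1 = logical(), mate_start = integer(),
    barcode = character(), hp_tag = integer(), pair_id = character()
  )
}

#' Validate the read-tibble invariants
#'
#' Checks that base and quality strings have equal length, that the
#' query-consuming CIGAR length matches the sequence length, and that
#' coordinates and mapping qualities are in range.
#'
#' @param reads A read tibble as returned by [read_alignments()].
#' @return The input, invisibly; aborts on violation.
#' @export
validate_reads <- function(reads) {
  assert_cols(reads, c("read_name", "chrom", "start", "cigar", "seq", "qual", "mapq"),
    "read tibble")
  if (nrow(reads) == 0) return(invisible(reads))
  if (!all(nchar(reads$seq) == nchar(reads$qual))) {
    abort("read invariant violated: nchar(seq) != nchar(qual)")
  }
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(reads$cigar)
  if (!all(qw == nchar(reads$seq))) {
    abort("read invariant violated: query-consuming CIGAR length != nchar(seq)")
  }
  if (any(reads$start < 0L)) abort("read invariant violated: start < 0")
  if (any(reads$mapq < 0L | reads$mapq > 60L)) {
    abort("read invariant violated: mapq outside [0, 60]")
  }
  invisible(reads)
}

#' Describe a genomic region
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return A one-row tibble with columns `chrom`, `start`, `end`.
#' @export
genome_region <- function(chrom, start, end) {
  stopifnot(end >= start, start >= 0)
  tibble(chrom = as.character(chrom), start = as.integer(start), end = as.integer(end))
}

as_region <- function(region) {
  if (is.list(region) && all(c("chrom", "start", "end") %in% names(region))) {
    return(genome_region(region$chrom[1], region$start[1], region$end[1]))
  }
  abort("region must have fields chrom, start, end (0-based half-open)")
}

#' Write a read tibble to SAM and convert to an indexed BAM
#'
#' Emits a coordinate-sorted SAM with `BX` barcode tags and converts it with
#' [Rsamtools::asBam()], producing `<stem>.bam` and its index.
#'
#' @param reads Read tibble (as from the simulator or [read_alignments()]).
#' @param path Output path ending in `.bam`.
#' @param seq_lengths Named integer vector of chromosome lengths.
#' @return The BAM path, invisibly.
#' @export
write_bam <- function(reads, path, seq_lengths) {
  stopifnot(grepl("\\.bam$", path))
  sam <- sub("\\.bam$", ".sam", path)
  write_sam(reads, sam, seq_lengths)
  stem <- sub("\\.bam$", "", path)
  Rsamtools::asBam(sam, destination = stem, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(path)
}

#' Write a read tibble as SAM text
#'
#' @inheritParams write_bam
#' @param path Output `.sam` path.
#' @return The path, invisibly.
#' @export
write_sam <- function(reads, path, seq_lengths) {
  reads <- dplyr::arrange(reads, .data$chrom, .data$start)
  hdr <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths), as.integer(seq_lengths))
  )
  flag <- 0L +
    16L * as.integer(reads$is_reverse %||% FALSE) +
    1024L * as.integer(reads$is_duplicate %||% FALSE) +
    256L * as.integer(reads$is_secondary %||% FALSE) +
    2048L * as.integer(reads$is_supplementary %||% FALSE)
  paired <- !is.na(reads$mate_start)
  mate_rev <- !reads$is_reverse ## FR pairs
  flag <- flag + ifelse(paired,
    1L + 2L * as.integer(reads$is_proper_pair) +
      32L * as.integer(mate_rev) +
      ifelse(reads$is_read1, 64L, 128L),
    0L
  )
  tlen <- ifelse(paired,
    ifelse(reads$is_read1, reads$mate_start + nchar(reads$seq) - reads$start,
      -(reads$end - pmin(reads$start, reads$mate_start))),
    0L
  )
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
    reads$read_name, flag, reads$chrom, reads$start + 1L, reads$mapq,
    reads$cigar,
    ifelse(paired, "=", "*"),
    ifelse(paired, reads$mate_start + 1L, 0L),
    as.integer(tlen),
    reads$seq, reads$qual,
    ifelse(is.na(reads$barcode), "", paste0("\tBX:Z:", reads$barcode))
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}
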