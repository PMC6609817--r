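#' Group barcoded reads into long-fragment molecules
#'
#' Reads sharing a molecular barcode on one chromosome are grouped into one
#' fragment (molecule) unless consecutive reads of that barcode are separated
#' by more than `max_gap` bp, in which case the barcode yields multiple
#' fragments — the standard guard against barcode reuse across distant
#' molecules. Barcode-less reads become singleton fragments.
#'
#' @param reads Read tibble (see [read_alignments()]).
#' @param max_gap Maximum allowed gap (bp) between the end of one read and
#'   the start of the next within a molecule. Default 50 kb.
#' @return The read tibble with a `fragment_id` column added.
#' @seealso [fragment_table()], [assign_haplotypes()]
#' @export
group_fragments <- function(reads, max_gap = 50000) {
  if (nrow(reads) == 0) {
    return(dplyr::mutate(reads, fragment_id = character(0)))
  }
  bc <- ifelse(is.na(reads$barcode),
    paste0(".nobx.", seq_len(nrow(reads))), reads$barcode
  )
  ord <- order(reads$chrom, bc, reads$start, reads$end)
  r <- reads[ord, ]
  bco <- bc[ord]
  key <- paste(r$chrom, bco, sep = "\r")
  n <- nrow(r)
  new_group <- c(TRUE, key[-1] != key[-n])
  ## running max end within each barcode group, lagged by one read
  prev_end <- integer(n)
  cm <- r$end[1]
  prev_end[1] <- NA_integer_
  if (n > 1) {
    for (i in 2:n) {
      if (new_group[i]) {
        prev_end[i] <- NA_integer_
        cm <- r$end[i]
      } else {
        prev_end[i] <- cm
        cm <- max(cm, r$end[i])
      }
    }
  }
  split_here <- new_group | (r$start - prev_end > max_gap)
  fid <- sprintf("F%06d", cumsum(split_here))
  reads$fragment_id <- NA_character_
  reads$fragment_id[ord] <- fid
  reads
}

#' Summarise fragments from a grouped read tibble
#'
#' @param reads Read tibble with `fragment_id` (from [group_fragments()]).
#' @return One row per fragment: `fragment_id`, `barcode`, `chrom`, `start`,
#'   `end` (half-open span over all reads), `n_reads`.
#' @export
fragment_table <- function(reads) {
  assert_cols(reads, "fragment_id", "read tibble")
  ## data.table grouping: fragment counts reach the hundreds of thousands
  ## when fragments are read pairs, where dplyr grouping dominates runtime
  dt <- data.table::data.table(
    fragment_id = reads$fragment_id, barcode = reads$barcode,
    chrom = reads$chrom, start = reads$start, end = reads$end
  )
  res <- dt[, list(
    barcode = barcode[1L], chrom = chrom[1L],
    start = min(start), end = max(end), n_reads = .N
  ), by = "fragment_id"]
  dplyr::arrange(as_tibble(res), .data$fragment_id)
}

#' Assign fragments to haplotypes by voting over phased heterozygotes
#'
#' For each phased het covered by any read of a fragment with base quality
#' at least `min_bq`, a vote goes to H1 if the observed base equals the H1
#' allele, to H2 if it equals the H2 allele, and nowhere otherwise. Bases
#' observed twice at one het by overlapping mates count once (the mate with
#' the higher base quality wins). Votes are tallied per phase set; the
#' fragment's working haplotype is taken from its dominant phase set (most
#' total votes) by strict majority, with ties — of votes within a set, or of
#' conflicting equally-supported phase sets — resolved to `unassigned`.
#'
#' @param reads Read tibble with `fragment_id`.
#' @param hets Phased-het tibble (`chrom`, `pos`, `h1`, `h2`, `phase_set`).
#' @param min_bq Minimum base quality for a vote (default 20).
#' @return Fragment tibble ([fragment_table()] columns) plus `votes_h1`,
#'   `votes_h2`, `haplotype` (`"H1"`, `"H2"` or `"unassigned"`).
#' @export
assign_haplotypes <- function(reads, hets, min_bq = 20) {
  frags <- fragment_table(reads)
  empty <- dplyr::mutate(frags,
    votes_h1 = 0L, votes_h2 = 0L, haplotype = "unassigned"
  )
  if (nrow(reads) == 0 || nrow(hets) == 0) return(empty)
  ## exclude reads that never enter counts from voting too
  use <- !reads$is_duplicate & !reads$is_secondary & !reads$is_supplementary
  rd <- reads[use, , drop = FALSE]
  if (nrow(rd) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(rd$chrom, IRanges::IRanges(rd$start + 1L, rd$end)),
    GenomicRanges::GRanges(hets$chrom, IRanges::IRanges(hets$pos + 1L, hets$pos + 1L))
  )
  if (length(hits) == 0) return(empty)
  ri <- S4Vectors::queryHits(hits)
  hi <- S4Vectors::subjectHits(hits)
  off <- query_offset(rd$cigar[ri], rd$start[ri], hets$pos[hi])
  keep <- !is.na(off)
  ri <- ri[keep]; hi <- hi[keep]; off <- off[keep]
  base <- substr(rd$seq[ri], off + 1L, off + 1L)
  bq <- qual_at(rd$qual[ri], off + 1L)
  keep <- !is.na(bq) & bq >= min_bq
  ri <- ri[keep]; hi <- hi[keep]
  base <- base[keep]; bq <- bq[keep]
  if (length(ri) == 0) return(empty)
  votes <- tibble(
    fragment_id = rd$fragment_id[ri],
    pair_id = rd$pair_id[ri],
    het = hi,
    phase_set = hets$phase_set[hi],
    base = base,
    bq = bq,
    vote = dplyr::case_when(
      base == hets$h1[hi] ~ "H1",
      base == hets$h2[hi] ~ "H2",
      TRUE ~ NA_character_
    )
  )
  ## overlapping mates: one observation per (pair, het), higher bq wins
  votes <- votes |>
    dplyr::arrange(dplyr::desc(.data$bq)) |>
    dplyr::distinct(.data$pair_id, .data$het, .keep_all = TRUE) |>
    dplyr::filter(!is.na(.data$vote))
  if (nrow(votes) == 0) return(empty)
  per_set <- votes |>
    dplyr::count(.data$fragment_id, .data$phase_set, .data$vote) |>
    tidyr::pivot_wider(
      names_from = "vote", values_from = "n",
      values_fill = 0L
    )
  if (!"H1" %in% names(per_set)) per_set$H1 <- 0L
  if (!"H2" %in% names(per_set)) per_set$H2 <- 0L
  per_set <- per_set |>
    dplyr::mutate(
      total = .data$H1 + .data$H2,
      hap = dplyr::case_when(
        .data$H1 > .data$H2 ~ "H1",
        .data$H2 > .data$H1 ~ "H2",
        TRUE ~ "unassigned"
      )
    )
  dominant <- per_set |>
    dplyr::group_by(.data$fragment_id) |>
    dplyr::arrange(dplyr::desc(.data$total), .data$phase_set, .by_group = TRUE) |>
    dplyr::summarise(
      votes_h1 = dplyr::first(.data$H1),
      votes_h2 = dplyr::first(.data$H2),
      haplotype = if (sum(.data$total == max(.data$total)) > 1 &&
        dplyr::n_distinct(.data$hap[.data$total == max(.data$total)]) > 1) {
        "unassigned"
      } else {
        dplyr::first(.data$hap)
      },
      .groups = "drop"
    )
  out <- dplyr::left_join(frags, dominant, by = "fragment_id") |>
    dplyr::mutate(
      votes_h1 = dplyr::coalesce(.data$votes_h1, 0L),
      votes_h2 = dplyr::coalesce(.data$votes_h2, 0L),
      haplotype = dplyr::coalesce(.data$haplotype, "unassigned")
    )
  ## a tie in the dominant set reports tied votes but stays unassigned
  out$haplotype[out$votes_h1 == out$votes_h2 & out$haplotype != "unassigned"] <- "unassigned"
  attr(out, "phase_votes") <- per_set
  out
}

#' Build mode-specific fragments and haplotype assignments
#'
#' The three model variants differ only in what counts as a "fragment":
#' `full` uses barcode-defined long molecules; `short_only` redefines
#' fragments as paired-end read pairs, so a read is assigned to a haplotype
#' only when one of its own ends overlaps a phased het; `no_phasing` leaves
#' every read unassigned.
#'
#' @param reads Read tibble.
#' @param hets Phased-het tibble.
#' @param mode One of `"full"`, `"short_only"`, `"no_phasing"`.
#' @param max_gap Molecule split gap for `full` mode.
#' @param min_bq Vote base-quality floor.
#' @return List with `reads` (with `fragment_id`) and `fragments`
#'   (assignment tibble from [assign_haplotypes()]).
#' @export
build_fragments <- function(reads, hets, mode = c("full", "short_only", "no_phasing"),
                            max_gap = 50000, min_bq = 20) {
  mode <- match.arg(mode)
  if (mode == "full") {
    reads <- group_fragments(reads, max_gap = max_gap)
  } else if (mode == "short_only") {
    reads$fragment_id <- paste0("P:", reads$chrom, ":", reads$pair_id)
  } else {
    reads$fragment_id <- paste0("R:", seq_len(max(nrow(reads), 0)))
  }
  if (mode == "no_phasing") {
    frags <- dplyr::mutate(fragment_table(reads),
      votes_h1 = 0L, votes_h2 = 0L, haplotype = "unassigned"
    )
  } else {
    frags <- assign_haplotypes(reads, hets, min_bq = min_bq)
  }
  list(reads = reads, fragments = frags, mode = mode)
}
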