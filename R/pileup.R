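## Mismatch discovery against the reference.
##
## Returns one row per (read, reference position) where the read base
## differs from the reference: read (row index into `reads`), pos (0-based),
## base, bq. Pure-match CIGARs take a vectorised matrix-comparison path in
## chunks; gapped/clipped CIGARs fall back to a per-read walk.
mismatch_table <- function(reads, reference, chunk_size = 20000L) {
  ref <- as_ref_string(reference)
  n <- nrow(reads)
  if (n == 0) {
    return(tibble(read = integer(), pos = integer(), base = character(), bq = integer()))
  }
  simple <- grepl("^[0-9]+M$", reads$cigar)
  acc <- list()
  ai <- 1L
  idx_simple <- which(simple)
  if (length(idx_simple)) {
    widths <- nchar(reads$seq[idx_simple])
    for (w in unique(widths)) {
      ii_all <- idx_simple[widths == w]
      for (chunk in split(ii_all, ceiling(seq_along(ii_all) / chunk_size))) {
        ## byte-level comparison of concatenated reads vs reference windows
        rawseq <- charToRaw(paste(reads$seq[chunk], collapse = ""))
        refwin <- substring(ref, reads$start[chunk] + 1L, reads$start[chunk] + w)
        rawref <- charToRaw(paste(refwin, collapse = ""))
        d <- which(rawseq != rawref)
        if (length(d)) {
          row <- (d - 1L) %/% w + 1L
          col <- (d - 1L) %% w + 1L
          r <- chunk[row]
          rawq <- charToRaw(paste(reads$qual[chunk], collapse = ""))
          acc[[ai]] <- tibble(
            read = r,
            pos = reads$start[r] + col - 1L,
            base = strsplit(rawToChar(rawseq[d]), "", fixed = TRUE)[[1]],
            bq = as.integer(rawq[d]) - 33L
          )
          ai <- ai + 1L
        }
      }
    }
  }
  for (i in which(!simple)) {
    ops <- GenomicAlignments::explodeCigarOps(reads$cigar[i])[[1]]
    lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar[i])[[1]]
    rp <- reads$start[i]
    qp <- 0L
    for (j in seq_along(ops)) {
      op <- ops[j]
      l <- lens[j]
      if (op %in% c("M", "=", "X")) {
        rb <- strsplit(substring(ref, rp + 1L, rp + l), "", fixed = TRUE)[[1]]
        qb <- strsplit(substr(reads$seq[i], qp + 1L, qp + l), "", fixed = TRUE)[[1]]
        d <- which(rb != qb)
        if (length(d)) {
          acc[[ai]] <- tibble(
            read = i,
            pos = rp + d - 1L,
            base = qb[d],
            bq = qual_at(reads$qual[i], qp + d)
          )
          ai <- ai + 1L
        }
        rp <- rp + l
        qp <- qp + l
      } else if (op %in% c("I", "S")) {
        qp <- qp + l
      } else if (op %in% c("D", "N")) {
        rp <- rp + l
      }
    }
  }
  if (length(acc) == 0) {
    return(tibble(read = integer(), pos = integer(), base = character(), bq = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(acc), .data$pos)
}

## reads eligible for depth/allele counts
counted_mask <- function(reads, min_mapq) {
  !reads$is_duplicate & !reads$is_secondary & !reads$is_supplementary &
    reads$mapq >= min_mapq
}

## stacked per-read detail at a set of sites; one row per counted read base.
## `sites` is a tibble with pos (0-based) and optionally alt (candidate).
build_site_detail <- function(reads, sites, reference, fragments = NULL,
                              min_mapq = 30, min_bq = 20, read_mm = NULL) {
  ref <- as_ref_string(reference)
  empty <- tibble(
    site = integer(), pos = integer(), read = integer(), base = character(),
    bq = integer(), mapq = integer(), is_reverse = logical(),
    is_proper_pair = logical(), cycle_frac = double(), clip_len = integer(),
    n_mm = integer(), pair_id = character(), fragment_id = character(),
    haplotype = character(), votes_h1 = integer(), votes_h2 = integer()
  )
  if (nrow(reads) == 0 || nrow(sites) == 0) return(empty)
  cm <- counted_mask(reads, min_mapq)
  rd_idx <- which(cm)
  if (length(rd_idx) == 0) return(empty)
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(reads$start[rd_idx] + 1L, reads$end[rd_idx]),
    IRanges::IRanges(sites$pos + 1L, sites$pos + 1L)
  )
  if (length(hits) == 0) return(empty)
  ri <- rd_idx[S4Vectors::queryHits(hits)]
  si <- S4Vectors::subjectHits(hits)
  off <- query_offset(reads$cigar[ri], reads$start[ri], sites$pos[si])
  keep <- !is.na(off)
  ri <- ri[keep]; si <- si[keep]; off <- off[keep]
  if (length(ri) == 0) return(empty)
  base <- substr(reads$seq[ri], off + 1L, off + 1L)
  bq <- qual_at(reads$qual[ri], off + 1L)
  keep <- !is.na(bq) & bq >= min_bq & base %in% DNA_BASES
  ri <- ri[keep]; si <- si[keep]; off <- off[keep]
  base <- base[keep]; bq <- bq[keep]
  if (length(ri) == 0) return(empty)
  qw <- nchar(reads$seq[ri])
  cyc <- ifelse(reads$is_reverse[ri], qw - 1L - off, off)
  if (is.null(read_mm)) {
    mmt <- mismatch_table(reads, ref)
    read_mm <- integer(nrow(reads))
    if (nrow(mmt)) {
      tb <- table(mmt$read)
      read_mm[as.integer(names(tb))] <- as.integer(tb)
    }
  }
  det <- tibble(
    site = si,
    pos = sites$pos[si],
    read = ri,
    base = base,
    bq = bq,
    mapq = reads$mapq[ri],
    is_reverse = reads$is_reverse[ri],
    is_proper_pair = reads$is_proper_pair[ri],
    cycle_frac = ifelse(qw > 1L, cyc / (qw - 1L), 0),
    clip_len = softclip_len(reads$cigar[ri]),
    n_mm = read_mm[ri],
    pair_id = reads$pair_id[ri],
    fragment_id = if ("fragment_id" %in% names(reads)) reads$fragment_id[ri] else NA_character_
  )
  if (!is.null(fragments) && nrow(fragments)) {
    det <- dplyr::left_join(
      det,
      dplyr::select(fragments, "fragment_id", "haplotype", "votes_h1", "votes_h2"),
      by = "fragment_id"
    )
  } else {
    det$haplotype <- NA_character_
    det$votes_h1 <- 0L
    det$votes_h2 <- 0L
  }
  det$haplotype <- dplyr::coalesce(det$haplotype, "unassigned")
  det$votes_h1 <- dplyr::coalesce(det$votes_h1, 0L)
  det$votes_h2 <- dplyr::coalesce(det$votes_h2, 0L)
  det
}

#' Summarise per-site haplotype evidence at candidate positions
#'
#' Builds the per-site pileup summary the model consumes: depth and allele
#' counts over counted reads (duplicates, secondary and supplementary
#' alignments excluded; mapping- and base-quality floors applied), the
#' candidate mosaic allele and its fraction (MAF), per-haplotype allele
#' counts via each read's fragment assignment, the haplotype-discordant
#' reads (assigned reads carrying the candidate allele), and the fraction of
#' counted reads on assigned fragments.
#'
#' In `short_only` mode fragments are paired-end read pairs; in `no_phasing`
#' mode every read is unassigned and `discordant_count` is 0 by definition.
#'
#' @param reads Read tibble (with `fragment_id` when `fragments` given; see
#'   [build_fragments()]).
#' @param pos Integer vector of 0-based candidate positions (one chromosome
#'   at a time).
#' @param reference Reference sequence for that chromosome (string,
#'   `DNAString`, or `DNAStringSet` whose first element is used).
#' @param fragments Fragment assignment tibble from [assign_haplotypes()] /
#'   [build_fragments()]; `NULL` treats all reads as unassigned.
#' @param candidate_allele Optional character vector (recycled) fixing the
#'   candidate allele per site; by default the most frequent non-reference
#'   base, ties broken alphabetically.
#' @param mode Model variant; `no_phasing` forces all reads unassigned.
#' @param min_mapq,min_bq Count floors.
#' @return A tibble with one row per site: `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `maf`, `phased_fraction`, `n_h1`, `n_h2`, `n_un`,
#'   `alt_h1`, `alt_h2`, `alt_un`, `discordant_count`, `majority_hap`, and a
#'   `detail` list-column holding the per-read evidence table.
#' @export
site_phase_summary <- function(reads, pos, reference, fragments = NULL,
                               candidate_allele = NULL,
                               mode = c("full", "short_only", "no_phasing"),
                               min_mapq = 30, min_bq = 20) {
  mode <- match.arg(mode)
  ref <- as_ref_string(reference)
  pos <- as.integer(pos)
  sites <- tibble(pos = pos)
  if (!is.null(candidate_allele)) {
    sites$alt_fixed <- rep_len(candidate_allele, nrow(sites))
  }
  if (mode == "no_phasing") fragments <- NULL
  det <- build_site_detail(reads, sites, ref, fragments,
    min_mapq = min_mapq, min_bq = min_bq
  )
  if (mode == "no_phasing" && nrow(det)) det$haplotype <- "unassigned"
  refbase <- if (length(pos)) substring(ref, pos + 1L, pos + 1L) else character(0)
  out <- summarize_site_detail(det, sites, refbase,
    chrom = if (nrow(reads)) reads$chrom[1] else NA_character_
  )
  attr(out, "mode") <- mode
  out
}

## aggregate a stacked detail table into the per-site observation tibble
summarize_site_detail <- function(det, sites, refbase, chrom) {
  n_sites <- nrow(sites)
  base_obs <- tibble(
    chrom = chrom,
    site = seq_len(n_sites),
    pos = sites$pos,
    ref = refbase
  )
  if (nrow(det) == 0) {
    out <- base_obs |>
      dplyr::mutate(
        alt = NA_character_, depth = 0L, alt_count = 0L, maf = 0,
        phased_fraction = 0, n_h1 = 0L, n_h2 = 0L, n_un = 0L,
        alt_h1 = 0L, alt_h2 = 0L, alt_un = 0L, discordant_count = 0L,
        majority_hap = "unassigned",
        detail = rep(list(tibble()), n_sites)
      )
    return(dplyr::select(out, -"site"))
  }
  det$refbase <- refbase[det$site]
  ## candidate allele: fixed if supplied, else top non-reference base
  if ("alt_fixed" %in% names(sites)) {
    det$alt <- sites$alt_fixed[det$site]
  } else {
    cand <- det |>
      dplyr::filter(.data$base != .data$refbase) |>
      dplyr::count(.data$site, .data$base) |>
      dplyr::arrange(.data$site, dplyr::desc(.data$n), .data$base) |>
      dplyr::distinct(.data$site, .keep_all = TRUE) |>
      dplyr::select("site", alt = "base")
    det <- dplyr::left_join(det, cand, by = "site")
  }
  det$is_alt <- !is.na(det$alt) & det$base == det$alt
  det$assigned <- det$haplotype %in% c("H1", "H2")
  agg <- det |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      alt = dplyr::first(.data$alt),
      depth = dplyr::n(),
      alt_count = sum(.data$is_alt),
      phased_fraction = mean(.data$assigned),
      n_h1 = sum(.data$haplotype == "H1"),
      n_h2 = sum(.data$haplotype == "H2"),
      n_un = sum(!.data$assigned),
      alt_h1 = sum(.data$is_alt & .data$haplotype == "H1"),
      alt_h2 = sum(.data$is_alt & .data$haplotype == "H2"),
      alt_un = sum(.data$is_alt & !.data$assigned),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      maf = ifelse(.data$depth > 0, .data$alt_count / .data$depth, 0),
      discordant_count = .data$alt_h1 + .data$alt_h2,
      majority_hap = dplyr::case_when(
        .data$alt_h1 > .data$alt_h2 ~ "H1",
        .data$alt_h2 > .data$alt_h1 ~ "H2",
        TRUE ~ "unassigned"
      )
    )
  nested <- det |>
    dplyr::group_by(.data$site) |>
    tidyr::nest(.key = "detail") |>
    dplyr::ungroup()
  out <- base_obs |>
    dplyr::left_join(agg, by = "site") |>
    dplyr::left_join(nested, by = "site") |>
    dplyr::mutate(
      depth = dplyr::coalesce(.data$depth, 0L),
      alt_count = dplyr::coalesce(.data$alt_count, 0L),
      maf = dplyr::coalesce(.data$maf, 0),
      phased_fraction = dplyr::coalesce(.data$phased_fraction, 0),
      dplyr::across(
        dplyr::all_of(c("n_h1", "n_h2", "n_un", "alt_h1", "alt_h2", "alt_un", "discordant_count")),
        ~ dplyr::coalesce(.x, 0L)
      ),
      majority_hap = dplyr::coalesce(.data$majority_hap, "unassigned"),
      detail = purrr::map(.data$detail, ~ if (is.null(.x)) tibble() else .x)
    )
  dplyr::select(out, -"site")
}
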