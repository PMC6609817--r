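#' Candidate-site scan configuration
#'
#' Thresholds for step 1 of the pipeline: which genomic sites carry enough
#' data for the model. Defaults are tuned so a ~30X linked-read regime
#' passes comfortably; all are exposed here.
#'
#' @param min_depth Minimum counted depth (default 16).
#' @param min_candidate_reads Minimum reads carrying the candidate allele
#'   (default 2).
#' @param min_maf,max_maf Candidate-allele fraction window (defaults 0.03
#'   and 0.75).
#' @param min_phased_fraction Minimum fraction of counted reads on
#'   haplotype-assigned fragments (default 0.25; not applied in
#'   `no_phasing` mode, where it is identically 0).
#' @param min_mapq,min_bq Count floors (defaults 30 and 20).
#' @param exclude_germline Drop candidate sites at any germline variant
#'   call (default `TRUE`; those sites are the model's negatives).
#' @param max_gap Molecule split gap passed to [group_fragments()].
#' @return A `scan_config` list.
#' @export
scan_config <- function(min_depth = 16L, min_candidate_reads = 2L,
                        min_maf = 0.03, max_maf = 0.75,
                        min_phased_fraction = 0.25,
                        min_mapq = 30L, min_bq = 20L,
                        exclude_germline = TRUE, max_gap = 50000L) {
  stopifnot(
    min_maf >= 0, max_maf <= 1, min_maf <= max_maf,
    min_depth >= 0, min_candidate_reads >= 0, min_phased_fraction >= 0
  )
  structure(
    list(
      min_depth = as.integer(min_depth),
      min_candidate_reads = as.integer(min_candidate_reads),
      min_maf = min_maf, max_maf = max_maf,
      min_phased_fraction = min_phased_fraction,
      min_mapq = as.integer(min_mapq), min_bq = as.integer(min_bq),
      exclude_germline = isTRUE(exclude_germline),
      max_gap = as.integer(max_gap)
    ),
    class = "scan_config"
  )
}

#' Does a site observation pass the candidate filter?
#'
#' @param obs Site-observation tibble (rows from [site_phase_summary()]).
#' @param germline Optional germline tibble (`chrom`, `pos`,
#'   `genotype_class`); with `exclude_germline`, sites present there as
#'   `het` or `hom_alt` fail.
#' @param cfg A [scan_config()].
#' @param mode Model variant; the phased-fraction floor is skipped in
#'   `no_phasing` mode.
#' @return Logical vector over rows of `obs`.
#' @export
passes_site_filter <- function(obs, germline = NULL, cfg = scan_config(),
                               mode = "full") {
  ok <- obs$depth >= cfg$min_depth &
    obs$alt_count >= cfg$min_candidate_reads &
    obs$maf >= cfg$min_maf & obs$maf <= cfg$max_maf &
    !is.na(obs$alt)
  if (mode != "no_phasing") {
    ok <- ok & obs$phased_fraction >= cfg$min_phased_fraction
  }
  if (cfg$exclude_germline && !is.null(germline) && nrow(germline)) {
    g <- dplyr::filter(germline, .data$genotype_class %in% c("het", "hom_alt"))
    key <- paste(obs$chrom, obs$pos)
    ok <- ok & !(key %in% paste(g$chrom, g$pos))
  }
  ok
}

#' Scan a region for candidate mosaic sites
#'
#' Step 1 of the pipeline. Finds every position where at least
#' `min_candidate_reads` counted reads carry the same non-reference base,
#' builds the full per-site haplotype summary there, and keeps positions
#' passing [passes_site_filter()], in coordinate order. The scan is a
#' deterministic sweep: output is invariant to input read order.
#'
#' @param reads Read tibble (one chromosome).
#' @param reference Reference sequence for that chromosome.
#' @param hets Phased-het tibble (for haplotype assignment).
#' @param germline Germline tibble for exclusion (may be `NULL`).
#' @param cfg A [scan_config()].
#' @param mode Model variant.
#' @param fragments Optional precomputed [build_fragments()] result to
#'   reuse across calls.
#' @return Site-observation tibble (see [site_phase_summary()]) of passing
#'   candidates, with a `pass` attribute-free contract: every row passed.
#' @export
scan_candidates <- function(reads, reference, hets, germline = NULL,
                            cfg = scan_config(),
                            mode = c("full", "short_only", "no_phasing"),
                            fragments = NULL) {
  mode <- match.arg(mode)
  ref <- as_ref_string(reference)
  empty <- site_phase_summary(empty_reads(), integer(0), ref, mode = mode)
  if (nrow(reads) == 0) return(empty)
  reads <- dplyr::arrange(reads, .data$chrom, .data$start)
  if (is.null(fragments)) {
    fragments <- build_fragments(reads, hets,
      mode = mode,
      max_gap = cfg$max_gap, min_bq = cfg$min_bq
    )
  }
  rd <- fragments$reads
  mmt <- mismatch_table(rd, ref)
  cm <- counted_mask(rd, cfg$min_mapq)
  mmt <- mmt[cm[mmt$read] & mmt$bq >= cfg$min_bq & mmt$base %in% DNA_BASES, ]
  if (nrow(mmt) == 0) return(empty)
  shortlist <- mmt |>
    dplyr::count(.data$pos, .data$base) |>
    dplyr::filter(.data$n >= cfg$min_candidate_reads) |>
    dplyr::arrange(.data$pos, dplyr::desc(.data$n), .data$base) |>
    dplyr::distinct(.data$pos, .keep_all = TRUE)
  if (nrow(shortlist) == 0) return(empty)
  ## cheap depth prefilter from raw coverage (an upper bound on counted depth)
  cov <- IRanges::coverage(
    IRanges::IRanges(rd$start[cm] + 1L, rd$end[cm])
  )
  covv <- as.integer(cov)
  depth_ub <- ifelse(shortlist$pos + 1L <= length(covv), covv[shortlist$pos + 1L], 0L)
  shortlist <- shortlist[depth_ub >= cfg$min_depth, ]
  if (nrow(shortlist) == 0) return(empty)
  obs <- site_phase_summary(
    rd, shortlist$pos, ref,
    fragments = fragments$fragments,
    candidate_allele = shortlist$base,
    mode = mode, min_mapq = cfg$min_mapq, min_bq = cfg$min_bq
  )
  out <- obs[passes_site_filter(obs, germline, cfg, mode = mode), ]
  attr(out, "mode") <- mode
  out
}
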