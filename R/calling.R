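#' Calling configuration
#'
#' Thresholds for steps 4-6: scoring, the haplotype-discordant-read
#' requirement, and the alignment-error heuristic.
#'
#' @param score_threshold Forest score required for PASS (default 0.5).
#' @param min_discordant Minimum haplotype-discordant reads (default 4; in
#'   `no_phasing` mode, where discordant reads are undefined, the candidate
#'   read count is held to the same floor).
#' @param clip_len Soft-clip length (bp) that counts as "clipped" for the
#'   alignment filter (default 5).
#' @param max_clip_frac Maximum tolerated fraction of clipped candidate
#'   reads (default 0.5).
#' @param max_mean_mismatch Maximum mean mismatches per candidate read,
#'   excluding the candidate base (default 3).
#' @param max_improper_frac Maximum tolerated fraction of improperly paired
#'   candidate reads (default 0.5).
#' @param homopolymer_len Reference homopolymer run length at or above
#'   which the site fails (default 10).
#' @return A `call_config` list.
#' @export
call_config <- function(score_threshold = 0.5, min_discordant = 4L,
                        clip_len = 5L, max_clip_frac = 0.5,
                        max_mean_mismatch = 3, max_improper_frac = 0.5,
                        homopolymer_len = 10L) {
  structure(
    list(
      score_threshold = score_threshold,
      min_discordant = as.integer(min_discordant),
      clip_len = as.integer(clip_len),
      max_clip_frac = max_clip_frac,
      max_mean_mismatch = max_mean_mismatch,
      max_improper_frac = max_improper_frac,
      homopolymer_len = as.integer(homopolymer_len)
    ),
    class = "call_config"
  )
}

#' Score sites with a trained model
#'
#' Pure function: one score per row, order preserved, no state mutated.
#' Refuses feature tibbles whose names or order differ from the ones
#' recorded in the artifact.
#'
#' @param model A `mosaic_model`.
#' @param features Feature tibble from [extract_features()] under the
#'   model's mode.
#' @return Numeric scores in `[0, 1]`.
#' @export
score_sites <- function(model, features) {
  stopifnot(inherits(model, "mosaic_model"))
  if (!identical(names(features), model$feature_names)) {
    abort(paste0(
      "feature names do not match the model artifact; expected exactly: ",
      paste(model$feature_names, collapse = ", ")
    ))
  }
  if (nrow(features) == 0) return(numeric(0))
  pr <- predict(model$forest,
    data = as.data.frame(features),
    num.threads = 1
  )$predictions
  as.numeric(pr[, "positive"])
}

#' Annotate calls with region-mask failures
#'
#' A call overlapping any interval of a mask gains that mask's failure
#' label (`region_<label>`); no calls are deleted — filter provenance is
#' preserved.
#'
#' @param calls Call tibble with `chrom`, `pos`, `filters_failed`
#'   list-column.
#' @param masks A list of mask tibbles (see [region_mask()]); each mask's
#'   `label` column names its failure (label "repeat"/"repeats" maps to
#'   `region_repeat`, "cnv" to `region_cnv`).
#' @return `calls` with updated `filters_failed` and `pass`.
#' @export
apply_region_filters <- function(calls, masks) {
  if (nrow(calls) == 0 || length(masks) == 0) return(calls)
  for (mask in masks) {
    if (nrow(mask) == 0) next
    lbl <- mask$label[1]
    lbl <- if (lbl %in% c("repeat", "repeats")) {
      "region_repeat"
    } else if (lbl == "cnv") {
      "region_cnv"
    } else {
      paste0("region_", lbl)
    }
    hit <- mask_overlaps(mask, calls$chrom, calls$pos)
    calls$filters_failed[hit] <- lapply(
      calls$filters_failed[hit], function(f) union(f, lbl)
    )
  }
  calls$pass <- vapply(calls$filters_failed, length, integer(1)) == 0L
  calls
}

#' Alignment-error heuristic for one site's candidate reads
#'
#' Flags sites whose candidate-read evidence looks like mis-mapping rather
#' than a variant. Fails if any of: (a) the fraction of candidate reads
#' with a soft-clip of at least `clip_len` bp exceeds `max_clip_frac`;
#' (b) mean mismatches per candidate read, excluding the candidate base,
#' exceeds `max_mean_mismatch`; (c) the fraction of improperly paired
#' candidate reads exceeds `max_improper_frac`; (d) the position lies
#' within a reference homopolymer run of at least `homopolymer_len` bp.
#'
#' @param detail Per-read detail tibble for the site (the `detail`
#'   list-column of [site_phase_summary()] output) — candidate reads are
#'   rows whose `base` equals `alt`.
#' @param alt Candidate allele.
#' @param pos Site position (0-based).
#' @param reference Reference sequence.
#' @param cfg A [call_config()].
#' @return List: `pass` (logical) and `diagnostics` (named numerics:
#'   `clip_frac`, `mean_mismatch`, `improper_frac`, `homopolymer`).
#' @export
alignment_error_filter <- function(detail, alt, pos, reference, cfg = call_config()) {
  ref <- as_ref_string(reference)
  cand <- detail[!is.na(detail$base) & detail$base == alt, , drop = FALSE]
  clip_frac <- if (nrow(cand)) mean(cand$clip_len >= cfg$clip_len) else 0
  mean_mm <- if (nrow(cand)) mean(pmax(cand$n_mm - 1L, 0L)) else 0
  improper <- if (nrow(cand)) mean(!cand$is_proper_pair) else 0
  homop <- in_homopolymer(ref, pos, cfg$homopolymer_len)
  fail <- clip_frac > cfg$max_clip_frac ||
    mean_mm > cfg$max_mean_mismatch ||
    improper > cfg$max_improper_frac ||
    homop
  list(
    pass = !fail,
    diagnostics = c(
      clip_frac = clip_frac, mean_mismatch = mean_mm,
      improper_frac = improper, homopolymer = as.numeric(homop)
    )
  )
}

#' Call mosaic SNVs end to end
#'
#' Runs the full pipeline on one chromosome of data: candidate scan,
#' feature extraction, forest scoring, the haplotype-discordant-read floor,
#' region masks and the alignment-error filter. Every scored candidate
#' appears exactly once in the output, either PASS or with a non-empty set
#' of failed filters.
#'
#' @param reads Read tibble.
#' @param reference Reference sequence for the chromosome.
#' @param hets,germline Output of [read_phased_vcf()].
#' @param model A trained `mosaic_model` (its mode drives the run).
#' @param masks List of mask tibbles (may be empty).
#' @param scan_cfg A [scan_config()].
#' @param call_cfg A [call_config()].
#' @param fragments Optional precomputed [build_fragments()] (mode must
#'   match the model).
#' @return A `mosaic_calls` tibble: `chrom`, `pos`, `ref`, `alt`, `score`,
#'   `maf`, `depth`, `alt_count`, `discordant_count`, `haplotype`,
#'   `filters_failed` (list), `pass`; stage counts in `attr(, "report")`.
#' @export
call_variants <- function(reads, reference, hets, germline, model,
                          masks = list(), scan_cfg = scan_config(),
                          call_cfg = call_config(), fragments = NULL) {
  stopifnot(inherits(model, "mosaic_model"))
  mode <- model$mode
  ref <- as_ref_string(reference)
  if (is.null(fragments)) {
    fragments <- build_fragments(reads, hets,
      mode = mode,
      max_gap = scan_cfg$max_gap, min_bq = scan_cfg$min_bq
    )
  } else if (!identical(fragments$mode, mode)) {
    abort(sprintf(
      "fragments were built in mode '%s' but the model requires '%s'",
      fragments$mode, mode
    ))
  }
  obs <- scan_candidates(reads, ref, hets, germline,
    cfg = scan_cfg,
    mode = mode, fragments = fragments
  )
  report <- c(candidates = nrow(obs))
  feats <- extract_features(obs, mode)
  score <- score_sites(model, feats)
  calls <- tibble(
    chrom = obs$chrom, pos = obs$pos, ref = obs$ref, alt = obs$alt,
    score = score, maf = obs$maf, depth = obs$depth,
    alt_count = obs$alt_count, discordant_count = obs$discordant_count,
    haplotype = obs$majority_hap,
    filters_failed = rep(list(character(0)), nrow(obs))
  )
  ## score threshold
  low <- calls$score < call_cfg$score_threshold
  calls$filters_failed[low] <- lapply(calls$filters_failed[low], union, "low_score")
  ## haplotype-discordant floor (candidate-read floor without phasing)
  disc <- if (mode == "no_phasing") calls$alt_count else calls$discordant_count
  under <- disc < call_cfg$min_discordant
  calls$filters_failed[under] <- lapply(calls$filters_failed[under], union, "min_discordant")
  report["after_score"] <- sum(!low)
  report["after_discordant"] <- sum(!low & !under)
  ## region masks
  calls$pass <- vapply(calls$filters_failed, length, integer(1)) == 0L
  calls <- apply_region_filters(calls, masks)
  report["after_region"] <- sum(calls$pass)
  ## alignment-error heuristic (only candidates still alive need checking,
  ## but provenance is recorded for all)
  if (nrow(calls)) {
    homop <- in_homopolymer(ref, obs$pos, call_cfg$homopolymer_len)
    for (i in seq_len(nrow(calls))) {
      d <- obs$detail[[i]]
      cand <- d[!is.na(d$base) & d$base == obs$alt[i], , drop = FALSE]
      fail <- homop[i]
      if (!fail && nrow(cand)) {
        fail <- mean(cand$clip_len >= call_cfg$clip_len) > call_cfg$max_clip_frac ||
          mean(pmax(cand$n_mm - 1L, 0L)) > call_cfg$max_mean_mismatch ||
          mean(!cand$is_proper_pair) > call_cfg$max_improper_frac
      }
      if (fail) {
        calls$filters_failed[[i]] <- union(calls$filters_failed[[i]], "alignment_error")
      }
    }
  }
  calls$pass <- vapply(calls$filters_failed, length, integer(1)) == 0L
  report["pass"] <- sum(calls$pass)
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos)
  attr(calls, "report") <- report
  class(calls) <- c("mosaic_calls", class(calls))
  calls
}
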