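FEATURES_SITE <- c(
  "depth", "maf",
  "mean_bq_alt", "sd_bq_alt", "mean_bq_other", "sd_bq_other",
  "mean_mapq_alt", "mean_mapq_other",
  "frac_alt_reverse", "mean_alt_cycle", "frac_alt_clipped",
  "mean_alt_mismatch",
  "has_alt", "has_other"
)

FEATURES_FRAGMENT <- c(
  "phased_fraction",
  "alt_h1", "alt_h2", "alt_unassigned",
  "frac_alt_h1", "frac_alt_h2", "frac_alt_unassigned",
  "discordant_count", "hap_concentration", "major_hap_alt_frac",
  "n_alt_fragments", "mean_votes_alt_fragment",
  "has_assigned_alt", "has_major_hap"
)

#' Feature names for a model variant, in fixed order
#'
#' The `full` and `short_only` variants share one feature list (the same
#' definitions computed over molecule-level vs pair-level fragments); the
#' `no_phasing` variant is the strict site-level subset. The order is stable
#' and recorded inside every model artifact, so scoring refuses mismatched
#' feature sets.
#'
#' Undefined ratios (zero denominators) are encoded as 0 with a paired 0/1
#' presence indicator (`has_alt`, `has_other`, `has_assigned_alt`,
#' `has_major_hap`), which decision forests split on naturally.
#'
#' @param mode One of `"full"`, `"short_only"`, `"no_phasing"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(mode = c("full", "short_only", "no_phasing")) {
  mode <- match.arg(mode)
  if (mode == "no_phasing") FEATURES_SITE else c(FEATURES_SITE, FEATURES_FRAGMENT)
}

#' Extract the fixed-order feature vector for each site observation
#'
#' Site-level features (all variants): depth; candidate-allele fraction;
#' mean/SD base quality of candidate vs other reads; mean mapping quality of
#' candidate vs other reads; fraction of candidate reads on the reverse
#' strand; mean normalised sequencing-cycle position of the candidate
#' allele; fraction of candidate reads with a soft-clip; mean per-read
#' mismatch count of candidate reads excluding the candidate base itself.
#'
#' Fragment-level features (`full`, `short_only`): phased fraction;
#' candidate-read counts and fractions on H1/H2/unassigned; haplotype-
#' discordant read count; haplotype concentration (majority-haplotype share
#' among assigned candidate reads — 1.0 is the mosaic signature, ~0.5 the
#' error signature); candidate allele fraction within the majority
#' haplotype; number of distinct fragments carrying the candidate allele;
#' mean phased-het votes per candidate fragment.
#'
#' @param obs Site-observation tibble from [site_phase_summary()] or
#'   [scan_candidates()], built under the same `mode`.
#' @param mode Model variant.
#' @return Tibble with one row per observation and columns
#'   `feature_names(mode)`, all finite.
#' @export
extract_features <- function(obs, mode = c("full", "short_only", "no_phasing")) {
  mode <- match.arg(mode)
  obs_mode <- attr(obs, "mode")
  if (!is.null(obs_mode) && !identical(obs_mode, mode)) {
    abort(sprintf(
      "observations were built in mode '%s' but features requested for mode '%s'",
      obs_mode, mode
    ))
  }
  n <- nrow(obs)
  if (n == 0) {
    out <- as_tibble(setNames(
      lapply(feature_names(mode), function(x) double(0)),
      feature_names(mode)
    ))
    return(out)
  }
  det <- obs |>
    dplyr::transmute(.site = dplyr::row_number(), alt_allele = .data$alt, detail = .data$detail) |>
    tidyr::unnest("detail")
  if (nrow(det)) {
    det$is_alt <- !is.na(det$alt_allele) & det$base == det$alt_allele
    site_agg <- det |>
      dplyr::group_by(.data$.site) |>
      dplyr::summarise(
        mean_bq_alt = mean(.data$bq[.data$is_alt]),
        sd_bq_alt = stats::sd(.data$bq[.data$is_alt]),
        mean_bq_other = mean(.data$bq[!.data$is_alt]),
        sd_bq_other = stats::sd(.data$bq[!.data$is_alt]),
        mean_mapq_alt = mean(.data$mapq[.data$is_alt]),
        mean_mapq_other = mean(.data$mapq[!.data$is_alt]),
        frac_alt_reverse = mean(.data$is_reverse[.data$is_alt]),
        mean_alt_cycle = mean(.data$cycle_frac[.data$is_alt]),
        frac_alt_clipped = mean(.data$clip_len[.data$is_alt] > 0L),
        mean_alt_mismatch = mean(pmax(.data$n_mm[.data$is_alt] - 1L, 0L)),
        has_alt = as.numeric(any(.data$is_alt)),
        has_other = as.numeric(any(!.data$is_alt)),
        n_alt_fragments = dplyr::n_distinct(.data$fragment_id[.data$is_alt]),
        mean_votes_alt_fragment = {
          v <- (.data$votes_h1 + .data$votes_h2)[.data$is_alt]
          f <- .data$fragment_id[.data$is_alt]
          if (length(v)) mean(v[!duplicated(f)]) else NA_real_
        },
        .groups = "drop"
      )
  } else {
    site_agg <- tibble(.site = integer(0))
  }
  feat <- tibble(.site = seq_len(n)) |>
    dplyr::left_join(site_agg, by = ".site")
  for (col in setdiff(names(site_agg), ".site")) {
    if (!col %in% names(feat)) feat[[col]] <- NA_real_
    feat[[col]][!is.finite(feat[[col]])] <- 0
  }
  for (col in c(
    "mean_bq_alt", "sd_bq_alt", "mean_bq_other", "sd_bq_other",
    "mean_mapq_alt", "mean_mapq_other", "frac_alt_reverse",
    "mean_alt_cycle", "frac_alt_clipped", "mean_alt_mismatch",
    "has_alt", "has_other", "n_alt_fragments", "mean_votes_alt_fragment"
  )) {
    if (!col %in% names(feat)) feat[[col]] <- 0
    feat[[col]][is.na(feat[[col]])] <- 0
  }
  feat$depth <- as.numeric(obs$depth)
  feat$maf <- as.numeric(obs$maf)
  if (mode != "no_phasing") {
    assigned_alt <- obs$alt_h1 + obs$alt_h2
    major_n <- ifelse(obs$majority_hap == "H1", obs$n_h1,
      ifelse(obs$majority_hap == "H2", obs$n_h2, 0L)
    )
    major_alt <- ifelse(obs$majority_hap == "H1", obs$alt_h1,
      ifelse(obs$majority_hap == "H2", obs$alt_h2, 0L)
    )
    feat$phased_fraction <- obs$phased_fraction
    feat$alt_h1 <- as.numeric(obs$alt_h1)
    feat$alt_h2 <- as.numeric(obs$alt_h2)
    feat$alt_unassigned <- as.numeric(obs$alt_un)
    feat$frac_alt_h1 <- ifelse(obs$alt_count > 0, obs$alt_h1 / obs$alt_count, 0)
    feat$frac_alt_h2 <- ifelse(obs$alt_count > 0, obs$alt_h2 / obs$alt_count, 0)
    feat$frac_alt_unassigned <- ifelse(obs$alt_count > 0, obs$alt_un / obs$alt_count, 0)
    feat$discordant_count <- as.numeric(obs$discordant_count)
    feat$hap_concentration <- ifelse(
      assigned_alt > 0, pmax(obs$alt_h1, obs$alt_h2) / assigned_alt, 0
    )
    feat$major_hap_alt_frac <- ifelse(major_n > 0, major_alt / major_n, 0)
    feat$has_assigned_alt <- as.numeric(assigned_alt > 0)
    feat$has_major_hap <- as.numeric(obs$majority_hap != "unassigned")
  }
  out <- feat[, feature_names(mode)]
  stopifnot(all(vapply(out, function(x) all(is.finite(x)), logical(1))))
  out
}

#' Write a feature matrix with site identity as headered TSV
#'
#' @param obs Site-observation tibble.
#' @param features Feature tibble from [extract_features()] (same rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(obs, features, path) {
  stopifnot(nrow(obs) == nrow(features))
  df <- dplyr::bind_cols(
    dplyr::select(obs, "chrom", "pos", "ref", "alt"),
    features
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
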