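#' MAF-stratified precision and recall against known truth
#'
#' A PASS call is a true positive when a truth site matches its exact
#' position and allele (no window rescue — SNVs are point events).
#' Precision per bin is computed over calls, binned by their observed
#' allele fraction; recall per bin is computed over truth sites, binned by
#' true MAF. When `min_support` is given, the recall denominator is
#' restricted to truth sites with at least that many observed
#' mosaic-allele reads — the support-aware denominator used when callers
#' require a minimum number of supporting reads.
#'
#' @param calls Call tibble (`chrom`, `pos`, `alt`, `maf`, `pass`); only
#'   PASS calls are evaluated.
#' @param truth Truth tibble (`chrom`, `pos`, `alt`, `maf`, and
#'   `alt_support` when `min_support` is used).
#' @param maf_bins Right-closed bin edges on (0, 0.5], default width 0.05.
#' @param min_support Optional minimum observed alt-read support for the
#'   recall denominator.
#' @return A `mosaic_eval` object; see [tidy.mosaic_eval()] and
#'   [glance.mosaic_eval()].
#' @export
precision_recall <- function(calls, truth, maf_bins = seq(0, 0.5, by = 0.05),
                             min_support = NULL) {
  if (is.unsorted(maf_bins) || anyDuplicated(maf_bins)) {
    abort("maf_bins must be strictly increasing bin edges")
  }
  pc <- dplyr::filter(calls, .data$pass)
  key <- function(df) paste(df$chrom, df$pos, df$alt)
  truth_keys <- key(truth)
  pc$is_tp <- key(pc) %in% truth_keys
  denom <- truth
  if (!is.null(min_support)) {
    assert_cols(truth, "alt_support", "truth")
    denom <- dplyr::filter(truth, .data$alt_support >= min_support)
  }
  denom$found <- key(denom) %in% key(pc)
  bin_of <- function(x) {
    cut(x, breaks = maf_bins, include.lowest = FALSE, right = TRUE)
  }
  pc$bin <- bin_of(pmin(pc$maf, max(maf_bins)))
  denom$bin <- bin_of(denom$maf)
  lv <- levels(bin_of(numeric(0)))
  per_bin <- tibble(bin = factor(lv, levels = lv)) |>
    dplyr::left_join(
      pc |> dplyr::group_by(.data$bin) |>
        dplyr::summarise(
          n_calls = dplyr::n(), tp_calls = sum(.data$is_tp),
          .groups = "drop"
        ),
      by = "bin"
    ) |>
    dplyr::left_join(
      denom |> dplyr::group_by(.data$bin) |>
        dplyr::summarise(
          n_truth = dplyr::n(), found = sum(.data$found),
          .groups = "drop"
        ),
      by = "bin"
    ) |>
    dplyr::mutate(
      dplyr::across(
        dplyr::all_of(c("n_calls", "tp_calls", "n_truth", "found")),
        ~ dplyr::coalesce(.x, 0L)
      ),
      precision = ifelse(.data$n_calls > 0, .data$tp_calls / .data$n_calls, 0),
      recall = ifelse(.data$n_truth > 0, .data$found / .data$n_truth, 0),
      f_score = ifelse(.data$precision + .data$recall > 0,
        2 * .data$precision * .data$recall / (.data$precision + .data$recall), 0
      )
    )
  tp <- sum(pc$is_tp)
  fp <- sum(!pc$is_tp)
  fn <- sum(!denom$found)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (nrow(denom) > 0) sum(denom$found) / nrow(denom) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(
    list(
      per_bin = per_bin,
      overall = tibble(
        tp = tp, fp = fp, fn = fn,
        n_calls = nrow(pc), n_truth = nrow(denom),
        precision = precision, recall = recall, f_score = f
      ),
      bin_edges = maf_bins,
      min_support = min_support %||% NA_integer_
    ),
    class = "mosaic_eval"
  )
}

#' @export
print.mosaic_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<mosaic_eval> precision %.3f recall %.3f F %.3f (TP %d FP %d FN %d%s)\n",
    o$precision, o$recall, o$f_score, o$tp, o$fp, o$fn,
    if (is.na(x$min_support)) "" else sprintf("; recall denominator: support >= %d", x$min_support)
  ))
  invisible(x)
}

#' Per-bin metrics of an evaluation
#' @param x A `mosaic_eval`.
#' @param ... Unused.
#' @return Tibble with one row per MAF bin.
#' @export
tidy.mosaic_eval <- function(x, ...) x$per_bin

#' One-row summary of an evaluation
#' @param x A `mosaic_eval`.
#' @param ... Unused.
#' @return One-row tibble with overall TP/FP/FN, precision, recall, F.
#' @export
glance.mosaic_eval <- function(x, ...) x$overall

#' Region-stratified evaluation
#'
#' Restricts calls and truth to each mask in turn and evaluates, mirroring
#' per-annotation metric tables (genes, exons, repeats, ...).
#'
#' @inheritParams precision_recall
#' @param masks List of mask tibbles (see [region_mask()]).
#' @return Named list of `mosaic_eval`, one per mask label.
#' @export
stratify_by_region <- function(calls, truth, masks,
                               maf_bins = seq(0, 0.5, by = 0.05),
                               min_support = NULL) {
  out <- lapply(masks, function(mask) {
    cin <- calls[mask_overlaps(mask, calls$chrom, calls$pos), , drop = FALSE]
    tin <- truth[mask_overlaps(mask, truth$chrom, truth$pos), , drop = FALSE]
    precision_recall(cin, tin, maf_bins = maf_bins, min_support = min_support)
  })
  names(out) <- vapply(masks, function(m) {
    if (nrow(m)) m$label[1] else "empty"
  }, character(1))
  out
}

#' Validate calls against independent deep coverage
#'
#' Orthogonal validation rule: a call is `validated` when the deep assay
#' shows at least `min_depth` aligned reads at the locus with at least
#' `min_alt` reads supporting the mosaic allele, and the site is not a
#' germline call in either of two germline call sets (e.g. tumor and
#' normal). Loci with fewer than `min_depth` deep reads are `unevaluable`.
#'
#' @param calls Call tibble (`chrom`, `pos`, `alt`); typically PASS calls.
#' @param deep Deep pileup tibble (`chrom`, `pos`, `depth`, `alt_count`),
#'   e.g. from [simulate_deep_panel()].
#' @param germline_a,germline_b Germline tibbles (`chrom`, `pos`,
#'   `genotype_class`) from the two samples; `NULL` skips that check.
#' @param min_depth Minimum deep coverage to evaluate (default 50).
#' @param min_alt Minimum deep reads supporting the allele (default 4).
#' @return `calls` with a `validation` column:
#'   `"validated"`, `"unvalidated"`, or `"unevaluable"`.
#' @export
wes_validate <- function(calls, deep, germline_a = NULL, germline_b = NULL,
                         min_depth = 50L, min_alt = 4L) {
  key <- function(df) paste(df$chrom, df$pos)
  i <- match(key(calls), key(deep))
  depth <- ifelse(is.na(i), 0L, deep$depth[i])
  altc <- ifelse(is.na(i), 0L, deep$alt_count[i])
  germ_keys <- character(0)
  for (g in list(germline_a, germline_b)) {
    if (!is.null(g) && nrow(g)) {
      gg <- dplyr::filter(g, .data$genotype_class %in% c("het", "hom_alt"))
      germ_keys <- union(germ_keys, key(gg))
    }
  }
  is_germ <- key(calls) %in% germ_keys
  calls$validation <- dplyr::case_when(
    depth < min_depth ~ "unevaluable",
    altc >= min_alt & !is_germ ~ "validated",
    TRUE ~ "unvalidated"
  )
  calls
}
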