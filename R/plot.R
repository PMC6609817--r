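#' Plot MAF-stratified precision and recall
#'
#' Bars show counts (truth sites per bin); lines show precision and recall
#' per bin — the standard summary for allele-fraction-stratified benchmarks.
#'
#' @param object A `mosaic_eval` from [precision_recall()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mosaic_eval <- function(object, ...) {
  pb <- object$per_bin
  max_n <- max(pb$n_truth, 1L)
  df <- pb |>
    tidyr::pivot_longer(
      dplyr::all_of(c("precision", "recall")),
      names_to = "metric", values_to = "value"
    )
  ggplot(pb, aes(x = .data$bin)) +
    geom_col(aes(y = .data$n_truth / max_n), fill = "grey80") +
    geom_line(
      data = df,
      aes(
        y = .data$value, colour = .data$metric,
        group = .data$metric
      )
    ) +
    geom_point(data = df, aes(y = .data$value, colour = .data$metric)) +
    scale_y_continuous(
      name = "precision / recall",
      sec.axis = sec_axis(~ . * max_n, name = "truth sites per bin")
    ) +
    labs(x = "mosaic allele fraction bin", colour = NULL) +
    theme_minimal()
}

#' Plot candidate scores against observed allele fraction
#'
#' @param object A `mosaic_calls` tibble from [call_variants()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mosaic_calls <- function(object, ...) {
  ggplot(object, aes(x = .data$maf, y = .data$score, colour = .data$pass)) +
    geom_point(alpha = 0.6) +
    labs(
      x = "observed allele fraction", y = "forest score",
      colour = "PASS"
    ) +
    theme_minimal()
}
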