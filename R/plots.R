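#' Volcano plot of a differential-connectivity table
#'
#' log10 fold change against -log10 p-value, coloured by DC class when the
#' table has been classified (red = disease-specific, blue =
#' control-specific, grey = unclassified, mirroring the network map's
#' colour convention).
#'
#' @param object A `dc_tbl` from [run_dc()] or [classify_dc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dc_tbl
#' @export
autoplot.dc_tbl <- function(object, ...) {
  df <- as_tibble(object)
  df$dc_class <- df$dc_class %||% "unclassified"
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$raw_fc), y = -log10(.data$raw_p),
    colour = .data$dc_class
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      disease_specific = "#c0392b", control_specific = "#2f6db3",
      unclassified = "grey70"
    )) +
    ggplot2::labs(x = "log10 fold change (disease / control)",
                  y = "-log10 Raw.p", colour = "DC class") +
    ggplot2::theme_minimal()
}

#' Running-sum plot of a GSEA enrichment score
#'
#' @param object An `es_result` from [enrichment_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot es_result
#' @export
autoplot.es_result <- function(object, ...) {
  df <- tibble(rank = seq_along(object$running_sum),
               running_sum = object$running_sum)
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$running_sum)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_hline(yintercept = object$es, linetype = 3,
                        colour = "#c0392b") +
    ggplot2::labs(x = "rank in list", y = "running enrichment score") +
    ggplot2::theme_minimal()
}

#' Dot plot of GSEA results
#'
#' Terms against normalized enrichment score; dot size shows the set size
#' and colour the permutation p-value.
#'
#' @param object A `gsea_tbl` from [gsea()].
#' @param top Show at most this many terms (smallest p first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsea_tbl
#' @export
autoplot.gsea_tbl <- function(object, top = 20, ...) {
  df <- utils::head(as_tibble(object)[order(object$pvalue), ], top)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$nes, y = stats::reorder(.data$term_id, .data$nes),
    size = .data$set_size, colour = .data$pvalue
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "#c0392b", high = "grey70") +
    ggplot2::labs(x = "NES", y = NULL, size = "setSize", colour = "p") +
    ggplot2::theme_minimal()
}

#' Chaperome-member / term association map of iGSEA results
#'
#' Bipartite dot plot of retained associations, coloured by DC pool
#' (red = disease-specific, blue = control-specific).
#'
#' @param object An `igsea_tbl` from [run_igsea()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot igsea_tbl
#' @export
autoplot.igsea_tbl <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$chaperome_member, y = .data$term_id,
    colour = .data$pool, size = -log10(.data$p_adjust)
  )) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(
      disease_specific = "#c0392b", control_specific = "#2f6db3"
    )) +
    ggplot2::labs(x = "chaperome member", y = "term",
                  size = "-log10 adj. p", colour = "pool") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
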