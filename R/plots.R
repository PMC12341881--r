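# ggplot2 displays for the main result types. Each autoplot() returns a
# ggplot object the caller can restyle.

.genome_positions <- function(df) {
  df <- dplyr::arrange(df, .data$chr, .data$start)
  offsets <- df |>
    dplyr::group_by(.data$chr) |>
    dplyr::summarise(len = max(.data$end), .groups = "drop") |>
    dplyr::mutate(offset = dplyr::lag(cumsum(.data$len), default = 0))
  dplyr::left_join(df, offsets, by = "chr") |>
    dplyr::mutate(gpos = .data$offset + (.data$start + .data$end) / 2)
}

#' Manhattan-style plot of window %EGV
#'
#' @param object A `window_summary` from [window_egv()].
#' @param threshold QTL threshold line (default 1%).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.window_summary <- function(object, threshold = 1, ...) {
  df <- .genome_positions(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$gpos, .data$pct_egv,
                                   colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genome position", y = "% of genetic variance") +
    ggplot2::theme_minimal()
}

#' Plot of window Ad values from a pleiotropy scan
#'
#' @param object A `pleiotropy_windows` from [window_sign_probs()].
#' @param threshold Flagging threshold line (default 0.02).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.pleiotropy_windows <- function(object, threshold = 0.02, ...) {
  df <- .genome_positions(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$gpos, .data$ad,
                                   colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c("grey35", "firebrick")) +
    ggplot2::labs(x = "genome position", y = "Ad = |PP_pos - PP_neg|") +
    ggplot2::theme_minimal()
}

#' Top-term display of an enrichment run
#'
#' @param object An `enrichment_result`.
#' @param n_terms Number of terms to show (default 20).
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, n_terms = 20, ...) {
  df <- head(object[order(object$q.value), ], n_terms)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(.data$nes, .data$term,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "darkorange")) +
    ggplot2::labs(x = "normalised enrichment score", y = NULL,
                  fill = "FDR <= 0.25") +
    ggplot2::theme_minimal()
}

#' Variance-component display of a REML fit
#'
#' @param object A `reml_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.reml_fit <- function(object, ...) {
  df <- tibble::tibble(term = names(object$theta),
                       variance = unname(object$theta),
                       se = unname(object$se))
  df$term <- factor(df$term, levels = df$term)
  ggplot2::ggplot(df, ggplot2::aes(.data$term, .data$variance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$variance - .data$se,
                                        ymax = .data$variance + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "variance component") +
    ggplot2::theme_minimal()
}

#' PIP Manhattan plot for a BayesB chain
#'
#' @param chain A `bayesb_chain`.
#' @return A ggplot of per-SNP posterior inclusion probabilities.
#' @export
plot_pip <- function(chain) {
  df <- chain$snps
  df$start <- df$pos; df$end <- df$pos
  df <- .genome_positions(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$gpos, .data$pip,
                                   colour = factor(.data$chr %% 2))) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genome position", y = "posterior inclusion probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
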