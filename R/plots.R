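# ggplot2 views of the result objects.

state_fill <- c(RED = "#d73027", YELLOW = "#fee08b", BLUE = "#4575b4",
                BLACK = "#252525", GREEN = "#1a9850", UNKNOWN = "#ffffff")

#' Plot a k-mer fingerprint
#'
#' Dot-and-segment plot of per-k-mer log2 enrichment, ordered as the panel.
#'
#' @param object A [fingerprint()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kmer_fingerprint
#' @export
autoplot.kmer_fingerprint <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      kmer = factor(.data$kmer, levels = .data$kmer))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kmer, y = .data$enrichment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$kmer, yend = 0)) +
    ggplot2::geom_point(size = 3, ggplot2::aes(colour = .data$label)) +
    ggplot2::labs(x = NULL, y = "log2 enrichment vs background",
                  colour = "k-mer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a summit-centred profile
#'
#' Smoothed mean minor-groove width or GC content against position relative
#' to the peak summit.
#'
#' @param object A [summit_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot summit_profile
#' @export
autoplot.summit_profile <- function(object, ...) {
  ylab <- if (attr(object, "mode") == "mgw") {
    "mean minor groove width (Å)"
  } else {
    "mean GC content"
  }
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rel_pos, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "position relative to summit (bp)", y = ylab,
                  title = attr(object, "set_name")) +
    ggplot2::theme_minimal()
}

#' Plot chromatin-state prevalence
#'
#' Stacked bar of the fraction of total peak length per colour state.
#'
#' @param object A [state_prevalence()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot state_prevalence
#' @export
autoplot.state_prevalence <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      set = attr(object, "set_name") %||% "peaks")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$fraction,
                                   fill = .data$state)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = state_fill) +
    ggplot2::labs(x = NULL, y = "fraction of total peak length") +
    ggplot2::theme_minimal()
}

#' Plot motif-set enrichment scores
#'
#' One point per motif, ranked by enrichment score (log10 of the reciprocal
#' Poisson p-value).
#'
#' @param object A [motif_set_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motif_enrichment
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      motif = stats::reorder(.data$motif, -.data$rank))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$motif)) +
    ggplot2::geom_point(size = 3, colour = "grey20") +
    ggplot2::labs(x = "enrichment score, log10(1/p)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of per-peak median signal
#'
#' @param object A [peak_median_signal()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot peak_signal_summary
#' @export
autoplot.peak_signal_summary <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      set = attr(object, "set_name") %||% "peaks")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$median_signal)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL,
                  y = paste0("median ", attr(object, "track_name"),
                             " signal per peak")) +
    ggplot2::theme_minimal()
}
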