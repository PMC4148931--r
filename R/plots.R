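# ggplot2 autoplot methods for the main result types.

#' Plot a differential-expression table
#'
#' Mean TPM (log10) against log2 fold change, colored by call direction;
#' the dashed lines mark the fold-change threshold.
#'
#' @param object A `hypoxamir_de` tibble from [call_differential()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hypoxamir_de
#' @export
autoplot.hypoxamir_de <- function(object, ...) {
  thr <- object$threshold[1] %||% 1.5
  df <- dplyr::mutate(as_tibble(object),
                      mean_tpm = (.data$tpm_n + .data$tpm_h) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mean_tpm + 0.5),
                                   y = .data$log2_fc,
                                   colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = c(-log2(thr), log2(thr)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "log10 mean TPM", y = "log2 fold change (hyp/nor)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot HRE hit positions along promoters
#'
#' One row per miRNA; points mark motif matches at their signed upstream
#' offsets (nt before the precursor 5' end), shaped by strand.
#'
#' @param object An `hre_hits` tibble from [scan_hre()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hre_hits
#' @export
autoplot.hre_hits <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mirna,
                                   shape = .data$strand)) +
    ggplot2::geom_point(size = 2.5, colour = "#8e44ad") +
    ggplot2::labs(x = "offset from precursor 5' end (nt)", y = NULL,
                  shape = "motif strand") +
    ggplot2::theme_minimal()
}

#' Plot the per-class read composition of a run
#'
#' Stacked percentage bars of annotation classes per condition; mature
#' miRNAs typically dominate a small-RNA library.
#'
#' @param object A `hypoxamir_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hypoxamir_run
#' @export
autoplot.hypoxamir_run <- function(object, ...) {
  df <- object$summary$classes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$pct,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of reads", fill = "class") +
    ggplot2::theme_minimal()
}
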