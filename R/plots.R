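#' Histogram of normalized drop fluorescence
#'
#' Mirrors the detector histograms of a drop screen: counts of drops per
#' normalized-fluorescence bin, with the sorting threshold marked.
#'
#' @param x A `drop_population` or `sort_result`.
#' @param threshold Gate to draw; defaults to the config's threshold.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_fluorescence <- function(x, threshold = NULL, binwidth = 0.05) {
  drops <- if (inherits(x, "sort_result")) x$drops else x$drops
  threshold <- threshold %||% x$config$threshold
  if (all(is.na(drops$fluorescence))) {
    stop("fluorescence not assigned", call. = FALSE)
  }
  ggplot2::ggplot(drops[drops$gate_pass, ],
                  ggplot2::aes(x = .data$fluorescence)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Normalized fluorescence", y = "Drop count") +
    ggplot2::theme_minimal()
}

#' Per-position amino-acid frequencies of a sequencing pool
#'
#' @param freq_table A [tabulate_codons()] result.
#' @return A ggplot object, one panel per randomised position.
#' @export
plot_position_frequencies <- function(freq_table) {
  stopifnot(inherits(freq_table, "frequency_table"))
  ggplot2::ggplot(freq_table$per_position,
                  ggplot2::aes(x = .data$residue, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~position, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Residue", y = "Frequency",
                  title = paste0("Pool: ", freq_table$pool)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.enrichment_table
#' @export
plot_enrichment <- function(object, top_n = 20L, ...) {
  autoplot.enrichment_table(object, top_n = top_n, ...)
}

#' Plot an enrichment table
#'
#' Lollipop chart of the top peptides by fold-enrichment (bright over
#' input pool frequency).
#'
#' @param object An `enrichment_table`.
#' @param top_n Number of top-ranked peptides to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.enrichment_table <- function(object, top_n = 20L, ...) {
  d <- object |>
    dplyr::filter(.data$flag == "ok", !is.na(.data$fold)) |>
    dplyr::slice_min(.data$rank, n = top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$peptide, .data$fold), y = .data$fold
  )) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$peptide, y = 0,
                                       yend = .data$fold), colour = "grey60") +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Fold enrichment (bright / input)") +
    ggplot2::theme_minimal()
}

#' Tidy an enrichment table
#'
#' @param x An `enrichment_table`.
#' @param ... Unused.
#' @return A plain tibble with one row per peptide.
#' @export
tidy.enrichment_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "enrichment_table")
  tibble::as_tibble(out)
}

#' One-row summary of an enrichment table
#'
#' @param x An `enrichment_table`.
#' @param ... Unused.
#' @return A one-row tibble: number of peptides, top peptide and its fold,
#'   and how many peptides lacked input-pool support.
#' @export
glance.enrichment_table <- function(x, ...) {
  ok <- x[x$flag == "ok" & !is.na(x$fold), ]
  tibble::tibble(
    n_peptides = nrow(x),
    top_peptide = if (nrow(ok) > 0) ok$peptide[which.max(ok$fold)] else NA_character_,
    max_fold = if (nrow(ok) > 0) max(ok$fold) else NA_real_,
    n_undefined_input = sum(x$flag == "undefined_input")
  )
}

#' Turn a dropscreen result into a plain tibble
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model-level summary of a dropscreen result
#'
#' @param x A result object.
#' @param ... Passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
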