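#' Per-substrate screen scatter plot
#'
#' The standard screen panel: genes arranged alphabetically on the x axis,
#' -log10 raw p-value on the y axis, significant genes (BH q at or below the
#' cutoff) highlighted.
#'
#' @param hits A `gps_hits` tibble.
#' @param q_cutoff Highlighting threshold on `q_bh`.
#' @param label_top Label the top `label_top` genes per substrate.
#' @return A ggplot object (facetted by substrate).
#' @export
plot_screen_hits <- function(hits, q_cutoff = 0.05, label_top = 1L) {
  d <- hit_scatter_data(hits) |>
    mutate(significant = .data$q_bh <= q_cutoff)
  labels <- d |>
    group_by(.data$substrate) |>
    slice_max(.data$neg_log10_p, n = label_top, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 1.2, show.legend = FALSE) +
    ggplot2::geom_text(data = labels, ggplot2::aes(label = .data$gene),
                       vjust = -0.6, size = 2.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::facet_wrap(~substrate, scales = "free_y") +
    ggplot2::labs(x = "genes (alphabetical)",
                  y = expression(-log[10] ~ italic(p))) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' @rdname plot_screen_hits
#' @param object,x A `gps_hits` tibble.
#' @param ... Passed on to [plot_screen_hits()].
#' @export
autoplot.gps_hits <- function(object, ...) plot_screen_hits(object, ...)

#' Saturation-mutagenesis heat map
#'
#' Position-by-residue delta-PSI heat map in the field's usual orientation:
#' positions (plus the C-terminal "Add" column) on the x axis, residues in
#' the canonical order on the y axis, deeper red for stronger stabilisation.
#' Identity cells (mutation equal to the wild-type residue) are drawn as dots.
#'
#' @param object A `satmut_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.satmut_matrix <- function(object, ...) {
  L <- nchar(attr(object, "wt_seq"))
  d <- as_tibble(object) |>
    mutate(
      xlab = ifelse(.data$row_type == "add", "Add",
                    paste0(.data$wt_aa, .data$position)),
      residue = factor(.data$residue, levels = rev(AA_ORDER))
    )
  d$xlab <- factor(d$xlab, levels = unique(d$xlab[order(d$position)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$xlab, y = .data$residue)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$delta_psi),
                       colour = "grey85", linewidth = 0.1) +
    ggplot2::geom_point(data = filter(d, .data$identity), size = 0.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 na.value = "grey95",
                                 name = expression(Delta * "PSI")) +
    ggplot2::labs(x = "wild-type residue / position", y = "mutated to",
                  title = attr(object, "peptide_id")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 7))
}

#' Distribution of PSI values
#'
#' Overlaid density of PSI per condition, the usual first look at a
#' comparative stability screen (e.g. control versus CRL-inhibitor treated).
#'
#' @param psi_tables Named list of [compute_psi()] tibbles (names become
#'   condition labels), or a single tibble.
#' @return A ggplot object.
#' @export
plot_psi_distribution <- function(psi_tables) {
  if (is.data.frame(psi_tables)) psi_tables <- list(psi = psi_tables)
  d <- purrr::imap_dfr(psi_tables, function(t, nm) {
    mutate(as_tibble(t), condition = nm)
  }) |>
    filter(!is.na(.data$psi))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$psi, colour = .data$condition)) +
    ggplot2::geom_density() +
    ggplot2::coord_cartesian(xlim = c(1, 6)) +
    ggplot2::labs(x = "protein stability index (PSI)", y = "density") +
    ggplot2::theme_bw()
}
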