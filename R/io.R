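# TSV/JSON glue shared by the pipeline and the command-line wrapper.
# Every intermediate is a plain, diff-able TSV with documented headers.

#' Read a reference table from TSV
#'
#' Expected columns: `id`, `sequence`, optionally `label` (e.g. target gene)
#' and `group`.
#'
#' @param path TSV path.
#' @param kind Reference kind; see [reference_set()].
#' @return A [reference_set()].
#' @export
read_reference_tsv <- function(path, kind = "substrate") {
  reference_set(readr::read_tsv(path, show_col_types = FALSE), kind = kind)
}

#' Write and read long count tables
#'
#' Long format: `substrate`, `guide`, `sample`, `count` (plus any extra
#' columns present).
#'
#' @param counts Count tibble.
#' @param path TSV path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns a tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(as_tibble(counts), path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export a guide->gene map or PSI/hit tables as TSV
#'
#' @param x Tibble to write.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Export scatter-plot data for a hit-calling result
#'
#' Genes are arranged alphabetically with an x index and the y value is
#' -log10 of the raw p-value, mirroring the standard per-substrate screen
#' scatter panels.
#'
#' @param hits A `gps_hits` tibble.
#' @return Tibble `substrate`, `gene`, `x`, `neg_log10_p`, `q_bh`.
#' @export
hit_scatter_data <- function(hits) {
  as_tibble(hits) |>
    group_by(.data$substrate) |>
    arrange(.data$gene, .by_group = TRUE) |>
    mutate(x = row_number(), neg_log10_p = -log10(.data$p_raw)) |>
    ungroup() |>
    select("substrate", "gene", "x", "neg_log10_p", "q_bh")
}
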