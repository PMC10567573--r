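#' Assign barcodes to ORFs by majority vote over link reads
#'
#' Each barcode is assigned to the plurality ORF among its link reads,
#' provided the assignment passes a minimum total-read and purity (top count
#' over total) threshold; tied pluralities and threshold failures are left
#' unassigned with a reason. Barcodes whose reads are split confidently
#' between ORFs would conflate stability profiles downstream, hence the
#' conservative defaults.
#'
#' @param links Tibble with columns `barcode`, `orf`, `n` (link-read counts),
#'   e.g. from [simulate_barcode_links()] or a deconvoluted link-read table.
#' @param min_count Minimum total link reads for an assignment.
#' @param min_purity Minimum fraction of link reads supporting the top ORF.
#' @return Tibble with one row per barcode: `barcode`, `orf` (`NA` when
#'   unassigned), `purity`, `total_links`, `assigned`, `reason`.
#' @export
#' @examples
#' assign_barcodes(tibble::tibble(barcode = "b1", orf = c("A", "B"),
#'                                n = c(9, 1)))
assign_barcodes <- function(links, min_count = 3L, min_purity = 0.8) {
  links <- as_tibble(links)
  stopifnot(all(c("barcode", "orf", "n") %in% names(links)))
  if (any(links$n < 0)) abort("link counts must be non-negative.")
  check_fraction(min_purity, "min_purity")

  links |>
    group_by(.data$barcode) |>
    summarise(
      total_links = sum(.data$n),
      top_n = max(.data$n),
      tie = sum(.data$n == max(.data$n)) > 1L,
      top_orf = .data$orf[which.max(.data$n)],
      .groups = "drop"
    ) |>
    mutate(
      purity = ifelse(.data$total_links > 0,
                      .data$top_n / .data$total_links, 0),
      reason = dplyr::case_when(
        .data$total_links < min_count ~ "low_count",
        .data$tie ~ "tie",
        .data$purity < min_purity ~ "low_purity",
        TRUE ~ NA_character_
      ),
      assigned = is.na(.data$reason),
      orf = ifelse(.data$assigned, .data$top_orf, NA_character_)
    ) |>
    select("barcode", "orf", "purity", "total_links", "assigned", "reason")
}
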