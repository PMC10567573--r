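#' Build a position-by-residue delta-PSI matrix from saturation mutagenesis
#'
#' Each mutant's stabilisation is its PSI minus the median PSI of all
#' unmutated (wild-type replicate) constructs. The result is an L x 20
#' substitution grid plus a 20-wide "Add" row for single C-terminal residue
#' additions. Cells where the "mutation" equals the wild-type residue are
#' flagged non-informative (`identity = TRUE`) and excluded from position
#' summaries.
#'
#' @param psi Tibble with columns `type` (`wt`/`sub`/`add`), `position`,
#'   `mut_aa`, `psi` and (for substitutions) `wt_aa`; [simulate_satmut()]
#'   output is accepted directly, as is any PSI table carrying these mutation
#'   annotations.
#' @param peptide_id Identifier carried into the result.
#' @return A `satmut_matrix` object: a long tibble (`position`, `wt_aa`,
#'   `residue`, `delta_psi`, `n_obs`, `identity`, `row_type`) with attributes
#'   `wt_seq`, `wt_median_psi`, `peptide_id` and the canonical residue order.
#'   Positions are 1-based from the N-terminus; `offset_c` gives the position
#'   as a negative offset from the C-terminus (-1 = last residue), the frame
#'   in which terminal degrons are usually discussed.
#' @export
build_satmut_matrix <- function(psi, peptide_id = "peptide") {
  psi <- as_tibble(psi)
  stopifnot(all(c("type", "position", "mut_aa", "psi") %in% names(psi)))
  wt <- psi[psi$type == "wt", ]
  if (!nrow(wt)) abort("no wild-type entries; cannot centre the matrix.")
  wt_median <- median(wt$psi, na.rm = TRUE)

  subs <- psi[psi$type == "sub", ]
  wt_aa_of <- subs |>
    distinct(.data$position, .data$wt_aa) |>
    arrange(.data$position)
  L <- max(wt_aa_of$position)
  wt_seq <- paste(wt_aa_of$wt_aa[match(seq_len(L), wt_aa_of$position)],
                  collapse = "")

  sub_cells <- subs |>
    group_by(.data$position, .data$wt_aa, residue = .data$mut_aa) |>
    summarise(delta_psi = mean(.data$psi, na.rm = TRUE) - wt_median,
              n_obs = sum(!is.na(.data$psi)), .groups = "drop")

  grid <- tidyr::expand_grid(position = seq_len(L), residue = AA_ORDER) |>
    left_join(wt_aa_of, by = "position") |>
    left_join(sub_cells, by = c("position", "wt_aa", "residue")) |>
    mutate(identity = .data$residue == .data$wt_aa,
           delta_psi = ifelse(.data$identity, NA_real_, .data$delta_psi),
           n_obs = tidyr::replace_na(.data$n_obs, 0L),
           row_type = "substitution")

  adds <- psi[psi$type == "add", ]
  add_row <- tibble(position = L + 1L, residue = AA_ORDER) |>
    left_join(
      adds |>
        group_by(residue = .data$mut_aa) |>
        summarise(delta_psi = mean(.data$psi, na.rm = TRUE) - wt_median,
                  n_obs = sum(!is.na(.data$psi)), .groups = "drop"),
      by = "residue"
    ) |>
    mutate(wt_aa = NA_character_, identity = FALSE,
           n_obs = tidyr::replace_na(.data$n_obs, 0L), row_type = "add")

  out <- bind_rows(grid, add_row) |>
    mutate(offset_c = ifelse(.data$row_type == "add", NA_integer_,
                             .data$position - L - 1L)) |>
    select("position", "offset_c", "wt_aa", "residue", "delta_psi",
           "n_obs", "identity", "row_type")
  structure(out, wt_seq = wt_seq, wt_median_psi = wt_median,
            peptide_id = peptide_id, residue_order = AA_ORDER,
            class = c("satmut_matrix", class(out)))
}

#' Call degron-critical positions from a saturation-mutagenesis matrix
#'
#' A position is degron-critical when the median stabilisation across its
#' informative substitutions is at least `tau`: mutating a residue the E3
#' requires stabilises the peptide regardless of what it is mutated to. The
#' C-terminal addition row is summarised the same way into an
#' addition-sensitivity flag (a hallmark of C-degrons, whose recognition
#' requires the degron residue at the extreme terminus).
#'
#' @param matrix A [build_satmut_matrix()] result.
#' @param tau Threshold in delta-PSI units (called when median >= tau).
#' @return A list with `positions` (tibble `position`, `offset_c`, `wt_aa`,
#'   `median_delta`, `critical`, ranked by median stabilisation) and
#'   `addition_sensitive` (logical; `add_median_delta` attribute holds the
#'   value).
#' @export
call_degron_positions <- function(matrix, tau = 0.5) {
  stopifnot(inherits(matrix, "satmut_matrix"))
  pos <- matrix |>
    filter(.data$row_type == "substitution", !.data$identity,
           !is.na(.data$delta_psi)) |>
    group_by(.data$position, .data$offset_c, .data$wt_aa) |>
    summarise(median_delta = median(.data$delta_psi), .groups = "drop") |>
    mutate(critical = .data$median_delta >= tau) |>
    arrange(desc(.data$median_delta))
  add_med <- matrix |>
    filter(.data$row_type == "add", !is.na(.data$delta_psi)) |>
    pull(.data$delta_psi)
  add_med <- if (length(add_med)) median(add_med) else NA_real_
  structure(
    list(positions = pos,
         addition_sensitive = isTRUE(add_med >= tau),
         add_median_delta = add_med,
         tau = tau),
    class = "degron_calls"
  )
}

#' @export
print.degron_calls <- function(x, ...) {
  crit <- x$positions$position[x$positions$critical]
  cat("<degron_calls>\n")
  cat(sprintf("  critical positions (tau = %g): %s\n", x$tau,
              if (length(crit)) paste(crit, collapse = ", ") else "none"))
  cat(sprintf("  C-terminal addition sensitive: %s (median delta-PSI %.2f)\n",
              x$addition_sensitive, x$add_median_delta))
  invisible(x)
}
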