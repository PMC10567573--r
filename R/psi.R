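#' Normalise a binned count table for sequencing depth
#'
#' Each sample's (bin's) counts are rescaled so that every bin total equals
#' the mean bin total, removing differences in sequencing depth between the
#' sorted populations. Tables with a single sample pass through unchanged.
#'
#' @param counts Long count tibble with columns `sample`, `count` plus any
#'   entity columns (`substrate`, `guide`, ...).
#' @return The input tibble with an added `norm` column (depth-normalised
#'   counts). Zero-total samples keep `norm = 0` and are reported in the
#'   `zero_samples` attribute.
#' @export
normalize_depth <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(all(c("sample", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("counts must be non-negative.")
  totals <- counts |>
    group_by(.data$sample) |>
    summarise(total = sum(.data$count), .groups = "drop")
  if (all(totals$total == 0)) abort("all samples have zero total counts.")
  target <- mean(totals$total)
  scale <- setNames(ifelse(totals$total > 0, target / totals$total, 0),
                    totals$sample)
  out <- mutate(counts, norm = .data$count * scale[.data$sample])
  if (length(unique(counts$sample)) == 1L) {
    out$norm <- as.numeric(out$count)  # single-population tables untouched
  }
  attr(out, "zero_samples") <- totals$sample[totals$total == 0]
  out
}

#' Compute protein stability index (PSI) per entity
#'
#' For each entity (substrate, substrate-guide pair, barcode or ORF), PSI is
#' the sum over the six sorting bins of the entity's depth-normalised read
#' proportion in that bin multiplied by the bin number, giving a score from 1
#' (maximally unstable; all reads in bin 1) to 6 (maximally stable; all reads
#' in bin 6). Entities whose total raw reads fall below `min_reads` are
#' reported with `psi = NA`, since low-coverage profiles are dominated by
#' sampling noise.
#'
#' @param counts Long tibble with columns `sample`, `count` and (if absent)
#'   a `norm` column added via [normalize_depth()].
#' @param entity Character vector of entity-identifying columns; defaults to
#'   every column other than `sample`, `count`, `norm`.
#' @param min_reads Minimum raw reads per entity for a reported PSI.
#' @param bins Sample names of the six bins, in stability order.
#' @return Tibble with the entity columns, `psi` and `n_reads`, one row per
#'   entity.
#' @export
#' @examples
#' x <- tibble::tibble(substrate = "S1", sample = paste0("bin", 1:6),
#'                     count = c(0, 0, 0, 0, 0, 100))
#' compute_psi(x, min_reads = 1)
compute_psi <- function(counts, entity = NULL, min_reads = 30,
                        bins = BIN_NAMES) {
  counts <- as_tibble(counts)
  if (!"norm" %in% names(counts)) counts <- normalize_depth(counts)
  if (is.null(entity)) {
    entity <- setdiff(names(counts), c("sample", "count", "norm"))
  }
  if (!length(entity)) abort("no entity columns to aggregate over.")
  unknown <- setdiff(unique(counts$sample), bins)
  if (length(unknown)) {
    abort(sprintf("samples not in the bin set: %s",
                  paste(unknown, collapse = ", ")))
  }
  counts |>
    mutate(bin_no = match(.data$sample, bins)) |>
    group_by(across(dplyr::all_of(entity))) |>
    summarise(
      psi = if (sum(.data$norm) > 0) {
        sum(.data$norm * .data$bin_no) / sum(.data$norm)
      } else NA_real_,
      n_reads = sum(.data$count),
      .groups = "drop"
    ) |>
    mutate(psi = ifelse(.data$n_reads < min_reads, NA_real_, .data$psi))
}

#' Stability change between two conditions
#'
#' Delta-PSI is the treatment PSI minus the control PSI for each shared
#' entity; positive values mean the entity was stabilised by the treatment
#' (e.g. stabilisation under the pan-CRL inhibitor MLN4924 marks CRL
#' substrates). Entities missing on either side get `NA`.
#'
#' @param treated,control PSI tibbles from [compute_psi()] over the same
#'   entity columns.
#' @param by Entity columns to join on; defaults to the common columns other
#'   than `psi`/`n_reads`.
#' @return Tibble with the entity columns, `psi_treated`, `psi_control` and
#'   `delta_psi`.
#' @export
delta_psi <- function(treated, control, by = NULL) {
  treated <- as_tibble(treated)
  control <- as_tibble(control)
  if (is.null(by)) {
    by <- setdiff(intersect(names(treated), names(control)),
                  c("psi", "n_reads"))
  }
  if (!length(by)) abort("no shared entity columns to join on.")
  dplyr::full_join(
    select(treated, dplyr::all_of(by), psi_treated = "psi"),
    select(control, dplyr::all_of(by), psi_control = "psi"),
    by = by
  ) |>
    mutate(delta_psi = .data$psi_treated - .data$psi_control)
}

#' Aggregate barcode-level PSI to ORF level
#'
#' Each ORF carries several independent barcodes which act as internal
#' replicates; the ORF-level PSI is the median of its barcode PSIs and the
#' reported dispersion is the median absolute deviation. Barcodes absent from
#' the map are never pooled and are returned in the `unmapped` attribute.
#'
#' @param psi_barcode PSI tibble with a `barcode` column (from
#'   [compute_psi()]).
#' @param barcode_map Tibble with columns `barcode`, `orf` (e.g. from
#'   [assign_barcodes()]).
#' @return Tibble with `orf`, `psi`, `dispersion` (MAD), `n_barcodes`.
#' @export
aggregate_barcodes <- function(psi_barcode, barcode_map) {
  psi_barcode <- as_tibble(psi_barcode)
  barcode_map <- as_tibble(barcode_map)
  stopifnot("barcode" %in% names(psi_barcode),
            all(c("barcode", "orf") %in% names(barcode_map)))
  joined <- left_join(psi_barcode, barcode_map[, c("barcode", "orf")],
                      by = "barcode")
  unmapped <- joined$barcode[is.na(joined$orf)]
  out <- joined |>
    filter(!is.na(.data$orf), !is.na(.data$psi)) |>
    group_by(.data$orf) |>
    summarise(
      psi = median(.data$psi),
      dispersion = if (n() > 1L) mad(.data$psi) else 0,
      n_barcodes = n(),
      .groups = "drop"
    )
  attr(out, "unmapped") <- unmapped
  out
}

#' Select stabilised entities above a delta-PSI threshold
#'
#' Entities whose stabilisation strictly exceeds the threshold (default 0.5
#' PSI units, the convention used to call candidate CRL substrates), sorted
#' by decreasing stabilisation.
#'
#' @param delta A [delta_psi()] tibble.
#' @param threshold Strict lower bound on `delta_psi`.
#' @return The filtered, sorted tibble.
#' @export
select_stabilized <- function(delta, threshold = 0.5) {
  delta <- as_tibble(delta)
  stopifnot("delta_psi" %in% names(delta))
  delta |>
    filter(!is.na(.data$delta_psi), .data$delta_psi > threshold) |>
    arrange(desc(.data$delta_psi))
}
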