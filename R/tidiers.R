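#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for hit-calling results
#'
#' `tidy()` returns the per-(substrate, gene) test results as a plain tibble;
#' `glance()` returns a one-row summary (substrates analysed, genes tested,
#' significant hits at q <= 0.05).
#'
#' @param x A `gps_hits` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gps_hits <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.gps_hits
#' @export
glance.gps_hits <- function(x, ...) {
  d <- as_tibble(x)
  tibble(
    mode = attr(x, "mode") %||% NA_character_,
    n_substrates = dplyr::n_distinct(d$substrate),
    n_tests = nrow(d),
    n_significant = sum(d$q_bh <= 0.05, na.rm = TRUE),
    min_p = if (nrow(d)) min(d$p_raw) else NA_real_
  )
}

#' Tidy and glance methods for overlap permutation results
#'
#' @param x An `overlap_result`.
#' @param ... Unused.
#' @return A tibble; `tidy()` has one row per null summary statistic,
#'   `glance()` one row with the headline numbers.
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble(
    term = c("observed", "null_mean", "null_sd",
             names(x$null_quantiles)),
    value = c(x$observed, x$null_mean, x$null_sd,
              unname(x$null_quantiles))
  )
}

#' @rdname tidy.overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, p_value = x$p_value, n_perm = x$n_perm,
         n_hits = x$n_hits, scheme = x$scheme)
}

#' Tidy method for saturation-mutagenesis matrices
#'
#' @param x A `satmut_matrix`.
#' @param ... Unused.
#' @return The long matrix as a plain tibble.
#' @export
tidy.satmut_matrix <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname tidy.satmut_matrix
#' @export
glance.satmut_matrix <- function(x, ...) {
  d <- as_tibble(x)
  tibble(
    peptide_id = attr(x, "peptide_id"),
    length = nchar(attr(x, "wt_seq")),
    wt_median_psi = attr(x, "wt_median_psi"),
    max_delta = max(d$delta_psi, na.rm = TRUE),
    n_observed = sum(d$n_obs > 0)
  )
}
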