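#' Bundled control sgRNA sequences
#'
#' The validated control protospacers used in individual knockout
#' experiments (safe-harbour AAVS1 plus adaptor-targeting guides), shipped
#' as reference data for tests and examples.
#'
#' @return A [reference_set()] of kind `"guide"`.
#' @export
control_guides <- function() {
  path <- system.file("extdata", "sgrna_controls.tsv", package = "multigps",
                      mustWork = TRUE)
  read_reference_tsv(path, kind = "guide")
}

#' The inert C-terminal appendage used for interior peptide tiles
#'
#' @return The 10-mer amino-acid string appended to non-terminal tiles so
#'   that tiling does not create artificial C-terminal degrons.
#' @export
tile_appendage <- function() "RIARAKASTN"
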