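#' Configuration for a simulated multiplex GPS/CRISPR screen
#'
#' Describes the generative model for one multiplexed screen: a library of
#' GFP-fusion substrates crossed with an sgRNA library targeting E3 ligase
#' genes, cell-level reporter stability on a continuous log(GFP/DsRed) axis,
#' partial-penetrance knockouts that stabilise cognate substrates, FACS gating
#' (six equal bins, or a single top gate), optional stable-filler spike-in and
#' multinomial sequencing of each sorted population.
#'
#' The latent stability axis is scaled so that, for the default near-uniform
#' baseline distribution, adjacent sextile gates sit approximately one unit
#' apart; planted effect sizes expressed in PSI units therefore translate
#' roughly one-to-one into latent shifts.
#'
#' @param n_substrates Number of library substrates.
#' @param genes Character vector of E3 gene identifiers targeted by the sgRNA
#'   library.
#' @param guides_per_gene sgRNAs per gene (the screens here used 6 for peptide
#'   libraries and 4 for adaptor panels).
#' @param cognate_map Tibble with columns `substrate`, `gene`, `effect` giving
#'   the planted E3-substrate relationships; `effect` is the stabilisation (in
#'   PSI units) conferred by a successful knockout. May be empty (null screen).
#' @param baseline_stability Numeric vector of per-substrate latent locations,
#'   recycled or named by substrate; `NULL` draws them uniformly on
#'   `[1, 6]` from the seeded stream.
#' @param cell_noise_sd Cell-to-cell standard deviation of the latent
#'   log-reporter ratio.
#' @param knockout_efficacy Probability that a guide-carrying cell has a
#'   functional knockout; scalar (all guides) or vector of length
#'   `length(genes) * guides_per_gene`.
#' @param cells_per_combo Cells simulated for every substrate-guide
#'   combination (library representation).
#' @param reads_per_bin Sequencing reads sampled per sorted population.
#' @param sort_mode `"six_bin"` (partition the whole population into sextiles)
#'   or `"one_bin"` (sort the top `gate_fraction` into one tube and sequence it
#'   against the unsorted reference).
#' @param gate_fraction Fraction of cells captured by the top gate in
#'   `one_bin` mode.
#' @param filler_fraction Fraction of the sorted population contributed by
#'   stable-filler cells (reserved substrate id `"FILLER"`), used to broaden a
#'   narrow stability distribution before six-bin sorting. The screens here
#'   spiked filler at ~30% when needed; the default is 0.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical simulations.
#'
#' @return An object of class `screen_sim_config` (a validated list).
#' @seealso [simulate_screen()]
#' @export
#' @examples
#' cfg <- screen_sim_config(
#'   n_substrates = 4, genes = paste0("E3_", 1:8), guides_per_gene = 4,
#'   cognate_map = tibble::tibble(substrate = "S1", gene = "E3_1", effect = 2),
#'   reads_per_bin = 5000, seed = 1
#' )
screen_sim_config <- function(n_substrates,
                              genes,
                              guides_per_gene = 6,
                              cognate_map = NULL,
                              baseline_stability = NULL,
                              cell_noise_sd = 0.3,
                              knockout_efficacy = 0.8,
                              cells_per_combo = 100,
                              reads_per_bin = 100000,
                              sort_mode = c("six_bin", "one_bin"),
                              gate_fraction = 0.05,
                              filler_fraction = 0,
                              seed = 1L) {
  n_substrates <- check_count(n_substrates, "n_substrates")
  if (!is.character(genes) || length(genes) < 1L || anyDuplicated(genes)) {
    abort("`genes` must be a character vector of unique gene ids.")
  }
  guides_per_gene <- check_count(guides_per_gene, "guides_per_gene")
  cells_per_combo <- check_count(cells_per_combo, "cells_per_combo")
  reads_per_bin <- check_count(reads_per_bin, "reads_per_bin")
  sort_mode <- match.arg(sort_mode)
  check_fraction(gate_fraction, "gate_fraction")
  check_fraction(filler_fraction, "filler_fraction")
  if (filler_fraction >= 1) abort("`filler_fraction` must be < 1.")
  if (!is.numeric(cell_noise_sd) || cell_noise_sd < 0) {
    abort("`cell_noise_sd` must be a non-negative number.")
  }

  substrates <- sprintf("S%03d", seq_len(n_substrates))
  n_guides <- length(genes) * guides_per_gene

  if (is.null(cognate_map)) {
    cognate_map <- tibble(substrate = character(), gene = character(),
                          effect = numeric())
  }
  cognate_map <- as_tibble(cognate_map)
  stopifnot(all(c("substrate", "gene", "effect") %in% names(cognate_map)))
  if (!all(cognate_map$gene %in% genes)) {
    abort("`cognate_map` references genes absent from the guide library.")
  }
  if (!all(cognate_map$substrate %in% substrates)) {
    abort("`cognate_map` references substrates outside S001..Snnn.")
  }
  if (any(!is.finite(cognate_map$effect))) {
    abort("planted effects must be finite.")
  }

  if (length(knockout_efficacy) == 1L) {
    knockout_efficacy <- rep(knockout_efficacy, n_guides)
  }
  if (length(knockout_efficacy) != n_guides ||
      any(knockout_efficacy < 0 | knockout_efficacy > 1)) {
    abort("`knockout_efficacy` must be in [0,1], length 1 or one per guide.")
  }

  if (!is.null(baseline_stability)) {
    if (length(baseline_stability) == 1L) {
      baseline_stability <- rep(baseline_stability, n_substrates)
    }
    if (length(baseline_stability) != n_substrates ||
        any(!is.finite(baseline_stability))) {
      abort("`baseline_stability` must be finite, length 1 or one per substrate.")
    }
  }

  structure(
    list(
      substrates = substrates,
      genes = genes,
      guides_per_gene = guides_per_gene,
      cognate_map = cognate_map,
      baseline_stability = baseline_stability,
      cell_noise_sd = cell_noise_sd,
      knockout_efficacy = knockout_efficacy,
      cells_per_combo = cells_per_combo,
      reads_per_bin = reads_per_bin,
      sort_mode = sort_mode,
      gate_fraction = gate_fraction,
      filler_fraction = filler_fraction,
      seed = as.integer(seed)
    ),
    class = "screen_sim_config"
  )
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat("<screen_sim_config>\n")
  cat(sprintf("  %d substrates x %d genes x %d guides/gene (%s mode)\n",
              length(x$substrates), length(x$genes), x$guides_per_gene,
              x$sort_mode))
  cat(sprintf("  planted pairs: %d; cells/combo: %d; reads/bin: %d; seed: %d\n",
              nrow(x$cognate_map), x$cells_per_combo, x$reads_per_bin, x$seed))
  invisible(x)
}

#' Ground-truth degron model for saturation-mutagenesis simulation
#'
#' Encodes which positions of a wild-type peptide are required for degradation:
#' mutating a critical position away from the wild-type residue stabilises the
#' peptide by the stated effect, and appending any residue at the C-terminus
#' stabilises it by `addition_effect` (C-degron behaviour, where recognition
#' requires the degron residue at the extreme terminus).
#'
#' @param peptide Wild-type amino-acid sequence (one-letter codes).
#' @param critical_positions Named numeric vector: names are 1-based positions,
#'   values the stabilisation (delta-PSI units, >= 0) when that position is
#'   mutated.
#' @param addition_effect Stabilisation when any single residue is appended at
#'   the C-terminus (0 for internal degrons).
#' @param noise_sd Observation noise of simulated PSI values.
#' @param baseline_psi PSI of the wild-type (degraded) peptide.
#' @return An object of class `degron_model`.
#' @seealso [simulate_satmut()]
#' @export
degron_model <- function(peptide, critical_positions = numeric(),
                         addition_effect = 0, noise_sd = 0.1,
                         baseline_psi = 2) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) >= 1)
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  if (!all(aa %in% AA_ORDER)) abort("`peptide` contains non-standard residues.")
  pos <- as.integer(names(critical_positions))
  if (length(critical_positions)) {
    if (any(is.na(pos)) || any(pos < 1 | pos > nchar(peptide))) {
      abort("`critical_positions` names must be positions within the peptide.")
    }
    if (any(critical_positions < 0)) abort("effects must be >= 0.")
  }
  if (addition_effect < 0) abort("`addition_effect` must be >= 0.")
  if (baseline_psi < 1 || baseline_psi > 6) abort("`baseline_psi` must lie in [1,6].")
  structure(
    list(peptide = peptide, critical_positions = critical_positions,
         addition_effect = addition_effect, noise_sd = noise_sd,
         baseline_psi = baseline_psi),
    class = "degron_model"
  )
}
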