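# one representative codon per residue, for deterministic reverse translation
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

#' Reverse-translate a peptide with a fixed codon table
#'
#' Deterministic one-codon-per-residue encoding, used to give simulated
#' peptide substrates a coding DNA sequence for read simulation.
#'
#' @param peptides Character vector of amino-acid sequences.
#' @return Character vector of coding DNA sequences.
#' @export
reverse_translate <- function(peptides) {
  vapply(peptides, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(CODON_OF))
    if (length(bad)) abort(sprintf("non-standard residues: %s",
                                   paste(unique(bad), collapse = ", ")))
    paste(CODON_OF[aa], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Tile a protein into overlapping peptide substrates
#'
#' Produces 24-mer tiles at 6-residue intervals along the protein, plus a
#' final tile anchored at the native C-terminus. Interior tiles receive a
#' common C-terminal appendage (default the inert 10-mer `RIARAKASTN`) so
#' that the tiling itself does not create artificial C-terminal degrons; the
#' C-terminal tile retains the native terminus and is left unappended.
#'
#' @param protein_seq Amino-acid sequence (length >= `tile_len`).
#' @param tile_len Tile length in residues.
#' @param step Interval between tile starts.
#' @param appendage C-terminal appendage for interior tiles.
#' @param id_prefix Prefix for tile identifiers.
#' @return Tibble with columns `tile_id`, `start`, `end`, `c_terminal`,
#'   `peptide` (the native window) and `sequence` (the emitted construct,
#'   appendage included where applicable).
#' @export
#' @examples
#' generate_tiles(paste(rep("ACDEFGHIKLMP", 3), collapse = ""))
generate_tiles <- function(protein_seq, tile_len = 24L, step = 6L,
                           appendage = "RIARAKASTN", id_prefix = "tile") {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  L <- nchar(protein_seq)
  tile_len <- check_count(tile_len, "tile_len")
  step <- check_count(step, "step")
  if (L < tile_len) abort("protein shorter than `tile_len`.")

  last_start <- L - tile_len + 1L
  interior <- seq.int(1L, by = step, length.out = max(0L, ceiling((last_start - 1L) / step)))
  interior <- interior[interior < last_start]
  starts <- c(interior, last_start)
  peptide <- substr(rep(protein_seq, length(starts)), starts,
                    starts + tile_len - 1L)
  c_terminal <- starts == last_start
  tibble(
    tile_id = sprintf("%s_%03d", id_prefix, starts),
    start = starts,
    end = starts + tile_len - 1L,
    c_terminal = c_terminal,
    peptide = peptide,
    sequence = ifelse(c_terminal, peptide, paste0(peptide, appendage))
  )
}

#' Simulate a saturation-mutagenesis stability screen
#'
#' Emits wild-type replicates, every single-residue substitution (L x 19) and
#' all 20 single C-terminal additions of a peptide, with true stabilisation
#' effects taken from a [degron_model()]: substitutions at critical positions
#' and (for C-degrons) any C-terminal addition stabilise the peptide. The
#' observed PSI of each variant is baseline + summed planted effect + Gaussian
#' noise, clamped to the PSI range [1, 6].
#'
#' @param model A [degron_model()].
#' @param wt_replicates Number of wild-type replicate constructs.
#' @param seed Integer seed.
#' @return Tibble with columns `variant_id`, `type` (`wt`/`sub`/`add`),
#'   `position`, `wt_aa`, `mut_aa`, `true_delta`, `psi`.
#' @export
simulate_satmut <- function(model, wt_replicates = 10L, seed = 1L) {
  stopifnot(inherits(model, "degron_model"))
  wt_replicates <- check_count(wt_replicates, "wt_replicates")
  aa <- strsplit(model$peptide, "", fixed = TRUE)[[1]]
  L <- length(aa)

  subs <- tidyr::expand_grid(position = seq_len(L), mut_aa = AA_ORDER) |>
    mutate(wt_aa = aa[.data$position]) |>
    filter(.data$mut_aa != .data$wt_aa)
  crit <- model$critical_positions
  subs$true_delta <- 0
  if (length(crit)) {
    hit <- match(subs$position, as.integer(names(crit)))
    subs$true_delta <- ifelse(is.na(hit), 0, unname(crit)[hit])
  }

  variants <- bind_rows(
    tibble(variant_id = sprintf("WT_%02d", seq_len(wt_replicates)),
           type = "wt", position = NA_integer_, wt_aa = NA_character_,
           mut_aa = NA_character_, true_delta = 0),
    subs |>
      mutate(variant_id = sprintf("%s%d%s", .data$wt_aa, .data$position,
                                  .data$mut_aa),
             type = "sub") |>
      select("variant_id", "type", "position", "wt_aa", "mut_aa",
             "true_delta"),
    tibble(variant_id = paste0("Add_", AA_ORDER), type = "add",
           position = L + 1L, wt_aa = NA_character_, mut_aa = AA_ORDER,
           true_delta = model$addition_effect)
  )

  variants$psi <- with_seed(substream_seed(seed, "satmut"), {
    pmin(6, pmax(1, model$baseline_psi + variants$true_delta +
                   rnorm(nrow(variants), 0, model$noise_sd)))
  })
  variants
}

#' Simulate barcode-to-ORF link reads
#'
#' Models the paired-end shotgun sequencing used to associate random 22-nt
#' barcodes with their upstream ORFs: each barcode belongs to exactly one
#' ORF, and each link read reports the true ORF with probability
#' `1 - chimera_rate`, otherwise a uniformly chosen other ORF (template
#' switching during library amplification).
#'
#' @param n_orfs Number of ORFs.
#' @param barcodes_per_orf_mean Mean unique barcodes per ORF (the barcoded
#'   ORFeome libraries here averaged between four and five).
#' @param link_reads Link reads per barcode.
#' @param chimera_rate Probability that a link read reports the wrong ORF.
#' @param seed Integer seed.
#' @return A list with `links` (tibble `barcode`, `orf`, `n`) and `truth`
#'   (tibble `barcode`, `true_orf`).
#' @export
simulate_barcode_links <- function(n_orfs, barcodes_per_orf_mean = 4.5,
                                   link_reads = 20L, chimera_rate = 0,
                                   seed = 1L) {
  n_orfs <- check_count(n_orfs, "n_orfs")
  link_reads <- check_count(link_reads, "link_reads")
  check_fraction(chimera_rate, "chimera_rate")
  orfs <- sprintf("ORF%04d", seq_len(n_orfs))

  with_seed(substream_seed(seed, "barcode_links"), {
    n_bc <- pmax(1L, stats::rpois(n_orfs, barcodes_per_orf_mean))
    true_orf <- rep(orfs, n_bc)
    n_total <- length(true_orf)
    bc_seqs <- random_dna_refs(seq_len(n_total), width = 22L,
                               seed = substream_seed(seed, "barcode_seqs"))
    truth <- tibble(barcode = bc_seqs$sequence, true_orf = true_orf)

    links <- purrr::map_dfr(seq_len(n_total), function(i) {
      wrong <- rbinom(1L, link_reads, chimera_rate)
      obs <- c(rep(truth$true_orf[i], link_reads - wrong),
               if (wrong > 0 && n_orfs > 1L) {
                 sample(setdiff(orfs, truth$true_orf[i]), wrong,
                        replace = TRUE)
               } else if (wrong > 0) {
                 rep(truth$true_orf[i], wrong)  # single-ORF edge case
               })
      tibble(barcode = truth$barcode[i], orf = obs)
    }) |>
      count(.data$barcode, .data$orf, name = "n")
    list(links = links, truth = truth)
  })
}

#' Generate a synthetic interaction edge list from planted screen truth
#'
#' Builds a synthetic stand-in for a physical-interaction database: the edge
#' set contains every planted (gene, substrate) pair plus random decoy edges
#' drawn from the non-planted gene-substrate combinations.
#'
#' @param truth A `sim_truth` manifest (from [simulate_screen()]) or a tibble
#'   of planted pairs with columns `gene`, `substrate`.
#' @param n_extra_random_edges Number of decoy edges to add.
#' @param seed Integer seed.
#' @return Tibble with columns `a` (gene), `b` (substrate), `source`
#'   (`planted` or `decoy`); no duplicate pairs.
#' @export
generate_interaction_edges <- function(truth, n_extra_random_edges = 0L,
                                       seed = 1L) {
  if (inherits(truth, "sim_truth")) {
    planted <- truth$planted
    genes <- unique(truth$guide_library$gene)
    substrates <- truth$config$substrates
  } else {
    planted <- as_tibble(truth)
    genes <- unique(planted$gene)
    substrates <- unique(planted$substrate)
  }
  n_extra_random_edges <- check_count(n_extra_random_edges,
                                      "n_extra_random_edges", min = 0L)
  edges <- tibble(a = planted$gene, b = planted$substrate,
                  source = "planted")
  if (n_extra_random_edges > 0L) {
    pool <- tidyr::expand_grid(a = genes, b = substrates) |>
      anti_join(edges[, c("a", "b")], by = c("a", "b"))
    if (n_extra_random_edges > nrow(pool)) {
      abort("not enough non-planted pairs for the requested decoys.")
    }
    decoys <- with_seed(substream_seed(seed, "edges"), {
      pool[sample.int(nrow(pool), n_extra_random_edges), ]
    })
    edges <- bind_rows(edges, mutate(decoys, source = "decoy"))
  }
  distinct(edges, .data$a, .data$b, .keep_all = TRUE)
}
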