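#' Expand a screen configuration into its guide library
#'
#' @param config A [screen_sim_config()].
#' @return Tibble with columns `guide`, `gene`, `efficacy`.
#' @export
guide_library <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  tibble(
    guide = paste0(rep(config$genes, each = config$guides_per_gene), "_sg",
                   rep(seq_len(config$guides_per_gene), length(config$genes))),
    gene = rep(config$genes, each = config$guides_per_gene),
    efficacy = config$knockout_efficacy
  )
}

#' Simulate a multiplex GPS/CRISPR screen
#'
#' Draws cell-level log(GFP/DsRed) stability values for every substrate-guide
#' combination, stabilises cognate-knockout cells with partial penetrance,
#' spikes in stable-filler cells where configured, sets FACS gates from pooled
#' population quantiles (sextiles in `six_bin` mode; the `1 - gate_fraction`
#' quantile in `one_bin` mode), and sequences each sorted population as a
#' multinomial sample of fixed depth.
#'
#' @param config A [screen_sim_config()].
#' @param keep_cells Retain per-cell latent values and bin assignments in the
#'   truth manifest (memory-hungry; default `FALSE`).
#' @return A list with elements
#'   \describe{
#'     \item{counts}{Long tibble `substrate`, `guide`, `gene`, `sample`,
#'       `count` (zero cells omitted). Samples are `bin1..bin6` in `six_bin`
#'       mode, `sorted`/`reference` in `one_bin` mode. Filler cells appear
#'       under the reserved substrate id `"FILLER"`.}
#'     \item{truth}{`sim_truth` manifest: planted pairs, per-guide efficacy,
#'       gate boundaries, per-substrate baselines and the configuration.}
#'   }
#' @export
#' @examples
#' cfg <- screen_sim_config(2, c("A", "B"), guides_per_gene = 2,
#'                          reads_per_bin = 2000, seed = 7)
#' sim <- simulate_screen(cfg)
#' head(sim$counts)
simulate_screen <- function(config, keep_cells = FALSE) {
  stopifnot(inherits(config, "screen_sim_config"))
  lib <- guide_library(config)
  n_s <- length(config$substrates)
  n_g <- nrow(lib)
  cells <- config$cells_per_combo

  baseline <- config$baseline_stability
  if (is.null(baseline)) {
    # substrate libraries in this assay are actively degraded proteins, so
    # default baselines span the unstable-to-intermediate range; stable
    # filler (not library baselines) is what broadens the top of the
    # distribution before a six-bin sort
    baseline <- with_seed(substream_seed(config$seed, "baseline"),
                          runif(n_s, 1.5, 4.5))
  }
  names(baseline) <- config$substrates

  combos <- tibble(
    substrate = rep(config$substrates, each = n_g),
    guide = rep(lib$guide, n_s),
    gene = rep(lib$gene, n_s),
    efficacy = rep(lib$efficacy, n_s),
    mu = rep(baseline, each = n_g),
    effect = 0
  )
  if (nrow(config$cognate_map)) {
    key <- paste(combos$substrate, combos$gene)
    ck <- paste(config$cognate_map$substrate, config$cognate_map$gene)
    idx <- match(key, ck)
    combos$effect <- ifelse(is.na(idx), 0, config$cognate_map$effect[idx])
  }
  n_combo <- nrow(combos)
  n_cells <- n_combo * cells

  latent <- with_seed(substream_seed(config$seed, "cells"), {
    x <- rnorm(n_cells, mean = rep(combos$mu, each = cells),
               sd = config$cell_noise_sd)
    hot <- which(combos$effect != 0)
    if (length(hot)) {
      cell_idx <- as.vector(outer(seq_len(cells), (hot - 1L) * cells, `+`))
      ko <- rbinom(length(cell_idx), 1L,
                   rep(combos$efficacy[hot], each = cells))
      x[cell_idx] <- x[cell_idx] +
        rep(combos$effect[hot], each = cells) * ko
    }
    x
  })

  # stable filler: broadens the pooled distribution before six-bin sorting
  n_fill <- round(config$filler_fraction / (1 - config$filler_fraction) * n_cells)
  if (n_fill > 0) {
    filler <- with_seed(substream_seed(config$seed, "filler"), {
      list(latent = rnorm(n_fill, mean = 6.5, sd = config$cell_noise_sd),
           guide = sample.int(n_g, n_fill, replace = TRUE))
    })
    filler_combos <- tibble(
      substrate = "FILLER", guide = lib$guide, gene = lib$gene,
      efficacy = NA_real_, mu = 6.5, effect = 0
    )
    combo_of_cell <- c(rep(seq_len(n_combo), each = cells),
                       n_combo + filler$guide)
    pooled <- c(latent, filler$latent)
    combos <- bind_rows(combos, filler_combos)
  } else {
    combo_of_cell <- rep(seq_len(n_combo), each = cells)
    pooled <- latent
  }
  n_all_combo <- nrow(combos)

  if (config$sort_mode == "six_bin") {
    gates <- unname(quantile(pooled, probs = (1:5) / 6, names = FALSE))
    bin <- findInterval(pooled, gates) + 1L
    cell_counts <- matrix(
      tabulate((combo_of_cell - 1L) * 6L + bin, nbins = n_all_combo * 6L),
      nrow = n_all_combo, ncol = 6L, byrow = TRUE
    )
    colnames(cell_counts) <- BIN_NAMES
  } else {
    gates <- unname(quantile(pooled, probs = 1 - config$gate_fraction,
                             names = FALSE))
    in_gate <- pooled > gates
    bin <- as.integer(in_gate) + 1L  # 2 = sorted
    cell_counts <- cbind(
      sorted = tabulate(combo_of_cell[in_gate], nbins = n_all_combo),
      reference = tabulate(combo_of_cell, nbins = n_all_combo)
    )
  }

  read_counts <- with_seed(substream_seed(config$seed, "sequencing"), {
    apply(cell_counts, 2L, function(p) {
      if (sum(p) == 0) return(integer(length(p)))
      as.integer(rmultinom(1L, config$reads_per_bin, p))
    })
  })
  colnames(read_counts) <- colnames(cell_counts)

  counts <- bind_cols(combos[, c("substrate", "guide", "gene")],
                      as_tibble(read_counts)) |>
    tidyr::pivot_longer(cols = dplyr::all_of(colnames(read_counts)),
                        names_to = "sample", values_to = "count") |>
    filter(.data$count > 0) |>
    arrange(.data$sample, .data$substrate, .data$guide)

  truth <- structure(
    list(
      planted = config$cognate_map,
      guide_library = lib,
      gates = gates,
      baseline = tibble(substrate = config$substrates,
                        baseline = unname(baseline)),
      sort_mode = config$sort_mode,
      config = config,
      cells = if (keep_cells) {
        tibble(combo = combo_of_cell, latent = pooled, bin = bin)
      }
    ),
    class = "sim_truth"
  )
  list(counts = counts, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %s sort; %d planted pairs; gates: %s\n", x$sort_mode,
              nrow(x$planted), paste(signif(x$gates, 4), collapse = ", ")))
  invisible(x)
}
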