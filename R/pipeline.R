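#' Validate a pipeline configuration
#'
#' A configuration describes one end-to-end run: either a simulated screen
#' (a `simulate` block of [screen_sim_config()] arguments) or existing count
#' tables (`counts_tsv`), the sorting mode, analysis thresholds and an output
#' directory. Validation fails before any stage runs: `six_bin` inputs must
#' provide all six bins, `one_bin` inputs the sorted and reference samples.
#'
#' @param config A named list, or a path to a YAML/JSON file holding one.
#' @return The validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config$mode <- match.arg(config$mode %||% "six_bin",
                           c("six_bin", "one_bin"))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% abort("`out_dir` is required.")
  config$min_reads <- config$min_reads %||% 30
  config$q_cutoff <- config$q_cutoff %||% 0.05
  config$n_perm <- config$n_perm %||% 10000L
  if (is.null(config$simulate) && is.null(config$counts_tsv)) {
    abort("config must provide either a `simulate` block or `counts_tsv`.")
  }
  if (!is.null(config$counts_tsv) && !file.exists(config$counts_tsv)) {
    abort(sprintf("counts file does not exist: %s", config$counts_tsv))
  }
  if (!is.null(config$guide_map_tsv) && !file.exists(config$guide_map_tsv)) {
    abort(sprintf("guide map file does not exist: %s", config$guide_map_tsv))
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the multiplex screen pipeline end to end
#'
#' Executes the configured stages in dependency order: obtain counts
#' (simulate a screen, or load a TSV), validate them against the sorting
#' mode, compute per-combination PSI (six-bin) or guide enrichments
#' (one-bin), call gene-level hits per substrate and summarise. Every output
#' is a TSV under `out_dir`, and a `manifest.json` records the parameters,
#' seed and md5 of every file so that a rerun with the same configuration is
#' byte-identical.
#'
#' @param config A [pipeline_config()] (or anything it accepts).
#' @return The manifest, invisibly (list with `outputs`, `parameters`,
#'   `seed`).
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()

  # --- stage: counts ---------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% config$seed
    sim_args$sort_mode <- config$mode
    if (!is.null(sim_args$cognate_map)) {
      sim_args$cognate_map <- as_tibble(sim_args$cognate_map)
    }
    cfg <- do.call(screen_sim_config, sim_args)
    sim <- simulate_screen(cfg)
    counts <- sim$counts
    guide_map <- sim$truth$guide_library[, c("guide", "gene")]
    truth_path <- file.path(config$out_dir, "truth_planted.tsv")
    write_table_tsv(sim$truth$planted, truth_path)
    outputs <- c(outputs, truth_path)
  } else {
    counts <- read_counts_tsv(config$counts_tsv)
    if (is.null(config$guide_map_tsv)) {
      abort("`guide_map_tsv` is required with `counts_tsv` input.")
    }
    guide_map <- readr::read_tsv(config$guide_map_tsv,
                                 show_col_types = FALSE)
  }

  samples <- unique(counts$sample)
  if (config$mode == "six_bin") {
    missing <- setdiff(BIN_NAMES, samples)
    if (length(missing)) {
      abort(sprintf("six_bin mode requires all six bins; missing: %s",
                    paste(missing, collapse = ", ")))
    }
  } else {
    missing <- setdiff(c("sorted", "reference"), samples)
    if (length(missing)) {
      abort(sprintf("one_bin mode requires sorted and reference samples; missing: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  counts_path <- file.path(config$out_dir, "counts.tsv")
  write_counts_tsv(counts, counts_path)
  outputs <- c(outputs, counts_path)

  # --- stage: stability / enrichment -----------------------------------
  library_counts <- filter(counts, .data$substrate != "FILLER")
  if (config$mode == "six_bin") {
    psi <- library_counts |>
      normalize_depth() |>
      compute_psi(entity = c("substrate", "guide"),
                  min_reads = config$min_reads)
    psi_path <- file.path(config$out_dir, "psi.tsv")
    write_table_tsv(psi, psi_path)
    outputs <- c(outputs, psi_path)
    hits <- call_hits_6bin(psi, guide_map = guide_map)
  } else {
    substrates <- unique(library_counts$substrate)
    hits <- purrr::map_dfr(substrates, function(s) {
      d <- filter(library_counts, .data$substrate == s)
      so <- filter(d, .data$sample == "sorted")
      re <- filter(d, .data$sample == "reference")
      # substrates that never reached the gate (or dropped out of the
      # library) cannot be tested in one-bin mode
      if (sum(so$count) == 0 || sum(re$count) == 0) {
        return(tibble())
      }
      call_hits_1bin(so, re, guide_map = guide_map,
                     n_perm = config$n_perm, seed = config$seed,
                     substrate = s)
    })
    class(hits) <- c("gps_hits", class(hits))
    attr(hits, "mode") <- "one_bin"
  }

  hits_path <- file.path(config$out_dir, "hits.tsv")
  write_table_tsv(hits, hits_path)
  scatter_path <- file.path(config$out_dir, "hits_scatter.tsv")
  write_table_tsv(hit_scatter_data(hits), scatter_path)
  outputs <- c(outputs, hits_path, scatter_path)

  summary <- summarize_screens(hits, control_gene = config$control_gene,
                               q_cutoff = config$q_cutoff)
  untested <- setdiff(unique(library_counts$substrate), summary$substrate)
  if (length(untested)) {
    summary <- bind_rows(summary, tibble(
      set = "screen", substrate = untested, top_gene = "no test",
      top_q = NA_real_, control_significant = NA, n_genes_tested = 0L
    ))
  }
  summary_path <- file.path(config$out_dir, "summary.tsv")
  write_table_tsv(summary, summary_path)
  outputs <- c(outputs, summary_path)

  manifest <- list(
    parameters = unclass(config)[setdiff(names(config), "out_dir")],
    seed = config$seed,
    mode = config$mode,
    outputs = lapply(
      setNames(outputs, basename(outputs)),
      function(p) list(path = basename(p), md5 = unname(tools::md5sum(p)))
    )
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(manifest, list(manifest_path = manifest_path)))
}
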