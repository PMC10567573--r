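#' Permutation test for overlap between screen hits and an interaction edge list
#'
#' Counts how many called (gene, substrate) hits are present in a
#' physical-interaction edge list, then compares that overlap with the
#' overlaps of random screens. A random screen redraws, for each observed
#' hit, the gene uniformly from the gene universe while keeping the substrate
#' fixed (`scheme = "redraw"`); alternatively the gene column is shuffled as
#' a permutation across the hits (`scheme = "shuffle"`). The empirical
#' one-sided p-value carries an add-one correction so it can never be zero.
#'
#' @param hits Tibble with columns `gene`, `substrate` (the called pairs).
#' @param edges Tibble with two identifier columns `a`, `b`; matching is on
#'   the unordered pair.
#' @param gene_universe Character vector of genes a screen could have called
#'   (typically the sgRNA library's gene set).
#' @param n_perm Number of random screens.
#' @param seed Integer seed.
#' @param scheme Null construction: `"redraw"` or `"shuffle"`.
#' @return An `overlap_result` list: `observed`, `p_value`, `null_mean`,
#'   `null_sd`, `null_quantiles`, `n_perm`, `n_hits`, `scheme`, `seed`.
#' @export
permutation_overlap_test <- function(hits, edges, gene_universe,
                                     n_perm = 10000L, seed = 1L,
                                     scheme = c("redraw", "shuffle")) {
  scheme <- match.arg(scheme)
  hits <- as_tibble(hits)
  edges <- as_tibble(edges)
  stopifnot(all(c("gene", "substrate") %in% names(hits)),
            ncol(edges) >= 2L)
  n_perm <- check_count(n_perm, "n_perm")
  if (!length(gene_universe)) abort("`gene_universe` is empty.")
  if (!all(hits$gene %in% gene_universe)) {
    abort("every hit gene must be in `gene_universe`.")
  }

  pair_key <- function(x, y) {
    paste(pmin(x, y), pmax(x, y), sep = "\r")
  }
  edge_keys <- unique(pair_key(as.character(edges[[1]]),
                               as.character(edges[[2]])))
  overlap_of <- function(genes) {
    sum(pair_key(genes, hits$substrate) %in% edge_keys)
  }
  observed <- overlap_of(hits$gene)
  n_hits <- nrow(hits)

  null_overlap <- with_seed(substream_seed(seed, "overlap_perm"), {
    vapply(seq_len(n_perm), function(i) {
      genes <- switch(scheme,
        redraw = sample(gene_universe, n_hits, replace = TRUE),
        shuffle = sample(hits$gene))
      overlap_of(genes)
    }, numeric(1))
  })

  structure(
    list(
      observed = observed,
      p_value = (1 + sum(null_overlap >= observed)) / (n_perm + 1),
      null_mean = mean(null_overlap),
      null_sd = sd(null_overlap),
      null_quantiles = quantile(null_overlap, c(0.025, 0.5, 0.975)),
      n_perm = n_perm,
      n_hits = n_hits,
      scheme = scheme,
      seed = as.integer(seed)
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap_result>\n")
  cat(sprintf("  observed overlap: %d of %d hits\n", x$observed, x$n_hits))
  cat(sprintf("  null: mean %.2f, sd %.2f (%d %s permutations)\n",
              x$null_mean, x$null_sd, x$n_perm, x$scheme))
  cat(sprintf("  empirical p = %.4g\n", x$p_value))
  invisible(x)
}
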