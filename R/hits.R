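#' Mann-Whitney U test with an explicit exact/approximate policy
#'
#' Computes the U statistic for `x` versus `y` and a one-sided (or
#' two-sided) p-value. The exact null tail (via the exact Mann-Whitney
#' distribution) is used when `length(x) <= 8`, the combined sample size is
#' at most 25 and there are no ties; otherwise the normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"greater"` (x tends larger; the stabilisation
#'   direction in these screens), `"less"` or `"two.sided"`.
#' @return A list with `statistic` (U for `x`), `p_value`, and `exact`
#'   (logical; which branch was used).
#' @export
#' @examples
#' mann_whitney(c(5.7, 5.8, 5.9, 6.0), 1:8)
mann_whitney <- function(x, y, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) abort("both samples must be non-empty.")

  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  exact <- n1 <= 8L && (n1 + n2) <= 25L && !has_ties

  if (exact) {
    p <- switch(alternative,
      greater = pwilcox(u - 1, n1, n2, lower.tail = FALSE),
      less = pwilcox(u, n1, n2),
      two.sided = {
        if (u > n1 * n2 / 2) {
          min(1, 2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE))
        } else {
          min(1, 2 * pwilcox(u, n1, n2))
        }
      })
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    if (sigma == 0) {
      p <- 1  # all observations tied: no evidence in either direction
    } else {
      p <- switch(alternative,
        greater = pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE),
        less = pnorm((u - mu + 0.5) / sigma),
        two.sided = {
          z <- (u - mu - sign(u - mu) * 0.5) / sigma
          min(1, 2 * pnorm(abs(z), lower.tail = FALSE))
        })
    }
  }
  list(statistic = unname(u), p_value = min(1, max(0, p)), exact = exact)
}

#' Gene-level hit calling from six-bin stability profiles
#'
#' For one substrate and a guide-level PSI table, tests every E3 gene by
#' comparing the PSI values of the substrate paired with that gene's guides
#' against the substrate paired with all other guides (Mann-Whitney, one-sided
#' towards stabilisation), then adjusts p-values by Benjamini-Hochberg across
#' genes within each substrate. Genes with fewer than two informative (non-NA)
#' guide PSIs are skipped and reported in the `skipped` attribute.
#'
#' @param psi Tibble with columns `substrate`, `guide`, `psi` and either a
#'   `gene` column or a `guide_map` argument.
#' @param guide_map Optional tibble `guide`, `gene`; required when `psi` has
#'   no `gene` column.
#' @param alternative Test direction; default `"greater"` (knockout of the
#'   cognate E3 stabilises the substrate).
#' @param min_guides Minimum informative guides per gene.
#' @return A `gps_hits` tibble with columns `substrate`, `gene`,
#'   `n_guides_used`, `statistic` (U), `p_raw`, `q_bh`, `delta_mean` (mean
#'   PSI of the gene's guides minus all others) and `direction`. The
#'   `skipped` attribute lists (substrate, gene) pairs with too few guides.
#' @export
call_hits_6bin <- function(psi, guide_map = NULL,
                           alternative = "greater", min_guides = 2L) {
  psi <- as_tibble(psi)
  stopifnot(all(c("substrate", "guide", "psi") %in% names(psi)))
  if (!"gene" %in% names(psi)) {
    if (is.null(guide_map)) abort("supply `gene` in `psi` or a `guide_map`.")
    psi <- left_join(psi, guide_map[, c("guide", "gene")], by = "guide")
  }
  psi <- filter(psi, .data$substrate != "FILLER")
  if (all(is.na(psi$psi))) abort("all PSI values are missing.")

  skipped <- list()
  results <- list()
  for (s in unique(psi$substrate)) {
    d <- psi[psi$substrate == s & !is.na(psi$psi), ]
    tally <- table(d$gene)
    testable <- names(tally)[tally >= min_guides]
    skip <- setdiff(unique(psi$gene[psi$substrate == s]), testable)
    if (length(skip)) {
      skipped[[s]] <- tibble(substrate = s, gene = skip,
                             reason = "fewer informative guides than required")
    }
    if (length(testable) < 2L) next
    rows <- purrr::map_dfr(testable, function(g) {
      in_g <- d$gene == g
      mw <- mann_whitney(d$psi[in_g], d$psi[!in_g],
                         alternative = alternative)
      tibble(substrate = s, gene = g, n_guides_used = sum(in_g),
             statistic = mw$statistic, p_raw = mw$p_value,
             delta_mean = mean(d$psi[in_g]) - mean(d$psi[!in_g]))
    })
    rows$q_bh <- p.adjust(rows$p_raw, method = "BH")
    results[[s]] <- rows
  }
  out <- bind_rows(results)
  if (nrow(out)) {
    out <- out |>
      mutate(direction = ifelse(.data$delta_mean >= 0, "stabilized",
                                "destabilized")) |>
      select("substrate", "gene", "n_guides_used", "statistic", "p_raw",
             "q_bh", "delta_mean", "direction") |>
      arrange(.data$substrate, .data$p_raw)
  } else {
    out <- tibble(substrate = character(), gene = character(),
                  n_guides_used = integer(), statistic = numeric(),
                  p_raw = numeric(), q_bh = numeric(),
                  delta_mean = numeric(), direction = character())
  }
  structure(out, skipped = bind_rows(skipped), mode = "six_bin",
            class = c("gps_hits", class(out)))
}

#' Gene-level hit calling from one-bin sorted/reference counts
#'
#' For one substrate, scores each guide by its log2 enrichment in the sorted
#' population over the reference population (pseudocount-protected library
#' proportions), then scores each gene by the mean rank of its guides among
#' all guides. The null distribution of the mean rank is obtained by
#' reassigning guide-to-gene labels: exhaustively when the number of distinct
#' assignments is at most `max_exhaustive`, otherwise by seeded Monte-Carlo
#' permutation (with add-one correction). This fills the role played by
#' MAGeCK in one-bin screen analysis with a fully specified rank-permutation
#' procedure; it is not expected to reproduce MAGeCK scores.
#'
#' @param sorted_counts,reference_counts Tibbles with columns `guide`,
#'   `count` for one substrate (extra columns ignored).
#' @param guide_map Tibble `guide`, `gene`.
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @param pseudocount Added to every count before forming proportions.
#' @param seed Integer seed for Monte-Carlo permutations.
#' @param substrate Substrate label carried into the result.
#' @param max_exhaustive Enumeration bound on `choose(n_guides, k)`.
#' @return A `gps_hits` tibble with `statistic` = mean enrichment rank,
#'   `p_raw`, `q_bh` (BH across genes), `delta_mean` = mean guide log2
#'   enrichment of the gene minus all other guides.
#' @export
call_hits_1bin <- function(sorted_counts, reference_counts, guide_map,
                           n_perm = 10000L, pseudocount = 0.5, seed = 1L,
                           substrate = "substrate",
                           max_exhaustive = 50000) {
  sorted_counts <- as_tibble(sorted_counts)
  reference_counts <- as_tibble(reference_counts)
  guide_map <- as_tibble(guide_map)
  stopifnot(all(c("guide", "count") %in% names(sorted_counts)),
            all(c("guide", "count") %in% names(reference_counts)),
            all(c("guide", "gene") %in% names(guide_map)))

  d <- guide_map |>
    left_join(rename(sorted_counts[, c("guide", "count")], s = "count"),
              by = "guide") |>
    left_join(rename(reference_counts[, c("guide", "count")], r = "count"),
              by = "guide") |>
    mutate(s = tidyr::replace_na(.data$s, 0L),
           r = tidyr::replace_na(.data$r, 0L))
  ts <- sum(d$s); tr <- sum(d$r)
  if (ts == 0 || tr == 0) abort("zero total counts in one population.")

  d$score <- log2((d$s + pseudocount) / (ts + pseudocount * nrow(d))) -
    log2((d$r + pseudocount) / (tr + pseudocount * nrow(d)))
  d$rk <- rank(d$score)  # high rank = enriched in the sorted population
  N <- nrow(d)

  genes <- unique(d$gene)
  rows <- purrr::map_dfr(genes, function(g) {
    in_g <- d$gene == g
    k <- sum(in_g)
    obs <- mean(d$rk[in_g])
    n_comb <- choose(N, k)
    if (n_comb <= max_exhaustive) {
      sets <- combn(N, k)
      null_means <- colMeans(matrix(d$rk[sets], nrow = k))
      p <- sum(null_means >= obs - 1e-12) / n_comb
      exact <- TRUE
    } else {
      null_means <- with_seed(substream_seed(seed, paste0("perm_", g)), {
        vapply(seq_len(n_perm),
               function(i) mean(d$rk[sample.int(N, k)]), numeric(1))
      })
      p <- (1 + sum(null_means >= obs - 1e-12)) / (n_perm + 1)
      exact <- FALSE
    }
    tibble(substrate = substrate, gene = g, n_guides_used = k,
           statistic = obs, p_raw = p, exact = exact,
           delta_mean = mean(d$score[in_g]) - mean(d$score[!in_g]))
  })
  rows$q_bh <- p.adjust(rows$p_raw, method = "BH")
  out <- rows |>
    mutate(direction = ifelse(.data$delta_mean >= 0, "enriched",
                              "depleted")) |>
    select("substrate", "gene", "n_guides_used", "statistic", "p_raw",
           "q_bh", "delta_mean", "direction", "exact") |>
    arrange(.data$p_raw)
  structure(out, mode = "one_bin", class = c("gps_hits", class(out)))
}

#' Summarise hit-calling results across substrates
#'
#' Reports, per substrate, the top-ranked gene and whether a designated
#' positive-control gene (e.g. the core Cullin *CUL3* in BTB-adaptor screens)
#' is significant at the given q cutoff. Multiple result sets (e.g. sort 1
#' and sort 2 of a twice-sorted screen) can be summarised side by side by
#' passing a named list.
#'
#' @param results A `gps_hits` tibble, or a named list of them.
#' @param control_gene Positive-control gene id (optional).
#' @param q_cutoff Significance threshold on BH-adjusted p-values.
#' @return A `screen_summary` tibble with one row per substrate (and per
#'   result set): `top_gene`, `top_q`, `control_significant`, `n_genes_tested`.
#' @export
summarize_screens <- function(results, control_gene = NULL, q_cutoff = 0.05) {
  if (is.data.frame(results)) results <- list(screen = results)
  out <- purrr::imap_dfr(results, function(res, nm) {
    res <- as_tibble(res)
    if (!nrow(res)) {
      return(tibble(set = nm, substrate = NA_character_,
                    top_gene = NA_character_, top_q = NA_real_,
                    control_significant = NA, n_genes_tested = 0L))
    }
    res |>
      group_by(.data$substrate) |>
      summarise(
        set = nm,
        top_gene = .data$gene[which.min(.data$p_raw)],
        top_q = min(.data$q_bh),
        control_significant = if (is.null(control_gene)) NA else {
          any(.data$gene == control_gene & .data$q_bh <= q_cutoff)
        },
        n_genes_tested = n(),
        .groups = "drop"
      )
  })
  attr(out, "q_cutoff") <- q_cutoff
  attr(out, "control_gene") <- control_gene
  class(out) <- c("screen_summary", class(out))
  out
}
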