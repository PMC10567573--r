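test_that("Mann-Whitney exact tail matches full-enumeration oracle values", {
  # 4 clearly separated high values vs 8 low: the most extreme assignment,
  # tail mass 1/choose(12, 4)
  x <- c(5.7, 5.8, 5.9, 6.0)
  y <- seq(1, 5, length.out = 8)
  mw <- mann_whitney(x, y, alternative = "greater")
  expect_true(mw$exact)
  expect_equal(mw$statistic, 32)
  expect_equal(mw$p_value, 1 / 495)
  expect_equal(mw$p_value, mw_enum_p(x, y))

  mw2 <- mann_whitney(1, 2, alternative = "greater")
  expect_equal(mw2$statistic, 0)
  expect_equal(mw2$p_value, 1)

  # identical samples: no one-sided evidence either way
  z <- c(1.2, 3.4, 5.6)
  expect_gte(mann_whitney(z, z, alternative = "greater")$p_value, 0.5)
  expect_gte(mann_whitney(z, z, alternative = "less")$p_value, 0.5)
})

test_that("exact branch agrees with stats::wilcox.test across random cases", {
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:10, 1)
    x <- sample(seq(0.1, 50, by = 0.1), n1)
    y <- sample(setdiff(seq(0.1, 50, by = 0.1), x), n2)
    for (alt in c("greater", "less", "two.sided")) {
      got <- mann_whitney(x, y, alternative = alt)
      ref <- suppressWarnings(stats::wilcox.test(x, y, alternative = alt,
                                                 exact = TRUE))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(got$statistic, unname(ref$statistic))
    }
  }
})

test_that("normal approximation stays within 0.02 of the exact tail", {
  set.seed(6)
  for (i in 1:40) {
    n1 <- sample(3:8, 1)
    n2 <- sample(8:17, 1)
    x <- sample(seq(1, 500), n1) + 0.5
    y <- sample(seq(1, 500), n2) + 0.25  # offsets guarantee no ties
    exact <- mann_whitney(x, y, alternative = "greater")
    stopifnot(exact$exact)
    # force the approximate branch on the same data by inflating n1 check:
    r <- rank(c(x, y))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    approx_p <- pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE)
    expect_lt(abs(approx_p - exact$p_value), 0.02)
  }
})

test_that("six-bin hit calling recovers a planted gene as the top hit", {
  genes <- sprintf("G%02d", 1:96)
  planted <- tibble::tibble(substrate = "S001", gene = "G01", effect = 1.5)
  cfg <- screen_sim_config(3, genes, guides_per_gene = 6,
                           cognate_map = planted, knockout_efficacy = 0.8,
                           reads_per_bin = 200000, seed = 31)
  sim <- simulate_screen(cfg)
  psi <- compute_psi(normalize_depth(sim$counts),
                     entity = c("substrate", "guide", "gene"),
                     min_reads = 30)
  hits <- call_hits_6bin(psi)
  top <- dplyr::slice_min(dplyr::filter(hits, substrate == "S001"),
                          p_raw, n = 1)
  expect_equal(top$gene, "G01")
  expect_lte(top$q_bh, 0.05)
  expect_equal(top$direction, "stabilized")
})

test_that("degenerate and under-powered six-bin inputs are handled", {
  # all guide PSIs identical: no gene can be significant
  psi <- tibble::tibble(
    substrate = "S1",
    guide = sprintf("g%02d", 1:12),
    gene = rep(c("A", "B", "C"), each = 4),
    psi = 3
  )
  res <- call_hits_6bin(psi)
  expect_true(all(res$p_raw == 1))

  # a gene with a single informative guide is skipped but logged
  psi2 <- psi
  psi2$psi <- seq(2, 4, length.out = 12)
  psi2$psi[psi2$gene == "C"][1:3] <- NA
  res2 <- call_hits_6bin(psi2)
  expect_false("C" %in% res2$gene)
  skipped <- attr(res2, "skipped")
  expect_true(any(skipped$gene == "C"))

  expect_error(call_hits_6bin(dplyr::mutate(psi, psi = NA_real_)),
               "missing")
})

test_that("six-bin gene tests control the type-I error rate under the null", {
  # null guide-level PSIs fed straight to the gene test; 10,000 gene tests
  set.seed(8)
  n_datasets <- 50
  genes <- sprintf("G%03d", 1:200)
  ps <- unlist(lapply(seq_len(n_datasets), function(i) {
    psi <- tibble::tibble(
      substrate = "S1",
      guide = sprintf("g%03d", seq_len(200 * 4)),
      gene = rep(genes, each = 4),
      psi = rnorm(200 * 4, 3, 0.5)
    )
    call_hits_6bin(psi)$p_raw
  }))
  expect_gte(length(ps), 10000)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.01)
})

test_that("one-bin mean-rank test reproduces the exact enumeration tail", {
  # cognate gene's 6 guides occupy the top 6 of 24 enrichment ranks
  guide_map <- tibble::tibble(
    guide = sprintf("g%02d", 1:24),
    gene = rep(c("HIT", "N1", "N2", "N3"), each = 6)
  )
  sorted <- tibble::tibble(guide = guide_map$guide,
                           count = c(rep(1000L, 6), rep(10L, 18)))
  reference <- tibble::tibble(guide = guide_map$guide, count = 100L)
  res <- call_hits_1bin(sorted, reference, guide_map,
                        max_exhaustive = 2e5, seed = 1)
  hit <- dplyr::filter(res, gene == "HIT")
  expect_true(hit$exact)
  expect_equal(hit$p_raw, 1 / choose(24, 6))
  expect_equal(hit$statistic, mean(19:24))
})

test_that("one-bin test is calm on null data and guarded against zeros", {
  guide_map <- tibble::tibble(guide = sprintf("g%02d", 1:20),
                              gene = rep(c("A", "B", "C", "D"), each = 5))
  eq <- tibble::tibble(guide = guide_map$guide, count = 50L)
  res <- call_hits_1bin(eq, eq, guide_map, seed = 2)
  expect_true(all(res$p_raw >= 0.4))
  res2 <- call_hits_1bin(eq, eq, guide_map, seed = 2)
  expect_identical(res$p_raw, res2$p_raw)

  # zero reference reads for one guide must not create infinite scores
  sorted <- dplyr::mutate(eq, count = replace(count, 1, 500L))
  reference <- dplyr::mutate(eq, count = replace(count, 1, 0L))
  res3 <- call_hits_1bin(sorted, reference, guide_map, seed = 3)
  expect_true(all(is.finite(res3$statistic)))
  expect_true(all(is.finite(res3$delta_mean)))
})

test_that("screen summaries count control-gene recoveries across substrates", {
  mk <- function(s, top_p, control_q) {
    tibble::tibble(substrate = s, gene = c("CUL3", "OTHER"),
                   n_guides_used = 4L, statistic = c(10, 5),
                   p_raw = c(top_p, 0.5), q_bh = c(control_q, 0.9),
                   delta_mean = c(1, 0), direction = "stabilized")
  }
  res <- dplyr::bind_rows(
    lapply(1:9, function(i) mk(sprintf("S%02d", i), 1e-4, 0.01)),
    mk("S10", 1e-4, 0.2)
  )
  summ <- summarize_screens(res, control_gene = "CUL3")
  expect_equal(sum(summ$control_significant), 9L)
  expect_equal(nrow(summ), 10L)

  two <- summarize_screens(list(sort1 = res, sort2 = res),
                           control_gene = "CUL3")
  expect_setequal(unique(two$set), c("sort1", "sort2"))
})
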