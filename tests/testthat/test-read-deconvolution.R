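anchor <- "GGAGGATCCGGTTCA"

test_that("anchor location honours stagger offsets and mismatch tolerance", {
  insert <- "ACGTACGTACGT"
  hit <- locate_and_trim(paste0("CGT", anchor, insert), anchor)
  expect_equal(hit$insert, insert)
  expect_equal(hit$offset, 3L)

  miss <- locate_and_trim(paste0("CGT", "TTTTTTTTTTTTTTT", insert), anchor)
  expect_true(is.na(miss$insert))

  mutated <- anchor
  substr(mutated, 5, 5) <- "A"
  one_mm <- locate_and_trim(paste0(mutated, insert), anchor,
                            anchor_mismatch_tol = 1)
  expect_equal(one_mm$insert, insert)
  zero_tol <- locate_and_trim(paste0(mutated, insert), anchor,
                              anchor_mismatch_tol = 0)
  expect_true(is.na(zero_tol$insert))
})

test_that("reference matching is exact-first with unique-best Hamming fallback", {
  refs <- reference_set(
    tibble::tibble(id = c("A", "B", "C"),
                   sequence = c("ACGTACGT", "ACGTACGA", "TTTTTTTT")),
    kind = "guide"
  )
  expect_equal(match_reference("ACGTACGT", refs), "A")
  # distance 1 from both A and B -> ambiguous
  expect_equal(match_reference("ACGTACGC", refs), "<ambiguous>")
  # distance 2 from everything at tol 1 -> no hit
  expect_true(is.na(match_reference("ACGTAAAA", refs, max_mismatch = 1)))
  # N counts as a mismatch
  expect_equal(match_reference("TTTTTTTN", refs), "C")
  expect_true(is.na(match_reference("TTTTTTNN", refs, max_mismatch = 1)))
  # insert shorter than every reference
  expect_true(is.na(match_reference("ACG", refs)))
})

test_that("matching agrees with a brute-force all-pairs Hamming oracle", {
  set.seed(42)
  refs <- random_dna_refs(sprintf("R%02d", 1:40), 18, seed = 9)
  refs <- reference_set(refs, kind = "substrate")
  bases <- c("A", "C", "G", "T")
  inserts <- vapply(1:400, function(i) {
    s <- refs$sequence[sample.int(40, 1)]
    nmut <- sample(0:3, 1)
    for (p in sample.int(18, nmut)) {
      substr(s, p, p) <- sample(bases, 1)
    }
    # random tail beyond the reference-length prefix must be ignored
    paste0(s, paste(sample(bases, sample(0:4, 1), replace = TRUE),
                    collapse = ""))
  }, character(1))
  for (tol in 0:2) {
    expect_identical(match_reference(inserts, refs, max_mismatch = tol),
                     brute_force_match(inserts, refs, tol))
  }
})

test_that("simulated reads deconvolute back to the exact input counts", {
  cfg <- small_screen_config(seed = 21, filler_fraction = 0.3)
  sim <- simulate_screen(cfg)
  refs <- screen_refs(cfg, seed = 5)
  reads <- simulate_reads(sim$counts, refs$substrates, refs$guides)

  rebuilt <- dplyr::bind_rows(lapply(split(reads, reads$sample), function(d) {
    build_count_table(d, refs$substrates, refs$guides,
                      sample_name = d$sample[[1]], max_mismatch = 0,
                      filler_ids = character())
  }))
  orig <- dplyr::arrange(sim$counts[, c("substrate", "guide", "sample",
                                        "count")],
                         sample, substrate, guide)
  got <- dplyr::arrange(tibble::as_tibble(rebuilt)[, c("substrate", "guide",
                                                       "sample", "count")],
                        sample, substrate, guide)
  expect_equal(as.data.frame(got), as.data.frame(orig),
               ignore_attr = TRUE)
})

test_that("QC accounting identity holds and filler is excluded from the matrix", {
  cfg <- small_screen_config(seed = 22, filler_fraction = 0.3)
  sim <- simulate_screen(cfg)
  refs <- screen_refs(cfg, seed = 6)
  layout <- read_layout(error_rate = 0.01)
  reads <- simulate_reads(sim$counts, refs$substrates, refs$guides,
                          layout = layout, seed = 13)
  d <- reads[reads$sample == "bin6", ]  # filler cells concentrate at the top
  tab <- build_count_table(d, refs$substrates, refs$guides,
                           sample_name = "bin6")
  qc <- qc_stats(tab)
  expect_equal(qc$assigned + qc$fwd_unassigned + qc$rev_unassigned +
                 qc$ambiguous + qc$filler, qc$total)
  expect_gt(qc$filler, 0)
  expect_false("FILLER" %in% tab$substrate)
})

test_that("raising the mismatch tolerance never decreases assigned pairs", {
  cfg <- small_screen_config(seed = 23)
  sim <- simulate_screen(cfg)
  refs <- screen_refs(cfg, seed = 7)
  reads <- simulate_reads(sim$counts, refs$substrates, refs$guides,
                          layout = read_layout(error_rate = 0.02), seed = 3)
  d <- reads[reads$sample == "bin2", ][1:2000, ]
  assigned <- vapply(0:2, function(tol) {
    qc_stats(build_count_table(d, refs$substrates, refs$guides,
                               max_mismatch = tol))$assigned
  }, integer(1))
  expect_true(all(diff(assigned) >= 0))
})

test_that("substrates are read from the forward mate and guides from the reverse", {
  cfg <- small_screen_config(seed = 24)
  refs <- screen_refs(cfg, seed = 8)
  counts <- tibble::tibble(substrate = "S001", guide = "E3_1_sg1",
                           sample = "bin1", count = 4L)
  reads <- simulate_reads(counts, refs$substrates, refs$guides)
  swapped <- dplyr::mutate(reads, tmp = r1, r1 = r2, r2 = tmp)
  ok <- build_count_table(reads, refs$substrates, refs$guides)
  bad <- build_count_table(swapped, refs$substrates, refs$guides)
  expect_equal(sum(ok$count), 4L)
  expect_equal(qc_stats(bad)$assigned, 0L)
})

test_that("stagger offsets cycle 0..7, each used twice over 16 reads", {
  cfg <- small_screen_config(seed = 25)
  refs <- screen_refs(cfg, seed = 9)
  counts <- tibble::tibble(substrate = "S001", guide = "E3_1_sg1",
                           sample = "bin1", count = 16L)
  reads <- simulate_reads(counts, refs$substrates, refs$guides)
  offs <- locate_and_trim(reads$r1, read_layout()$anchor_fwd)$offset
  expect_equal(as.integer(table(offs)), rep(2L, 8))
})

test_that("FASTQ round trip preserves read pairs (plain and gzip)", {
  cfg <- small_screen_config(seed = 26)
  refs <- screen_refs(cfg, seed = 10)
  counts <- tibble::tibble(substrate = c("S001", "S002"),
                           guide = "E3_2_sg1", sample = "bin1",
                           count = c(3L, 2L))
  reads <- simulate_reads(counts, refs$substrates, refs$guides)
  r1 <- tempfile(fileext = ".fastq")
  r2 <- tempfile(fileext = ".fastq.gz")
  write_fastq_pairs(reads, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_equal(back$r1, reads$r1)
  expect_equal(back$r2, reads$r2)
  unlink(c(r1, r2))
})

test_that("empty input produces an empty table with zeroed QC", {
  refs <- screen_refs(small_screen_config(), seed = 11)
  tab <- build_count_table(tibble::tibble(r1 = character(),
                                          r2 = character()),
                           refs$substrates, refs$guides)
  expect_equal(nrow(tab), 0L)
  expect_equal(qc_stats(tab)$total, 0L)
})
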