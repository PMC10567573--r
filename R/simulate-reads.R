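DEFAULT_ANCHOR_FWD <- "GGAGGATCCGGTTCA"   # constant between GFP and substrate
DEFAULT_ANCHOR_REV <- "CACCGAGTCGGTGCT"   # constant upstream of protospacer
STAGGER_PAD <- "TCGATCA"                  # source of 0-7 nt stagger prefixes

#' Read-structure layout for simulated amplicon reads
#'
#' @param anchor_fwd Constant sequence preceding the substrate insert on the
#'   forward read.
#' @param anchor_rev Constant sequence preceding the protospacer on the
#'   reverse read.
#' @param stagger_max Maximum stagger offset; amplification uses a pool of
#'   `stagger_max + 1` primers differing by one added nucleotide so that reads
#'   start out of phase and retain base diversity on the sequencer.
#' @param error_rate Per-base substitution error probability.
#' @return A list of class `read_layout`.
#' @export
read_layout <- function(anchor_fwd = DEFAULT_ANCHOR_FWD,
                        anchor_rev = DEFAULT_ANCHOR_REV,
                        stagger_max = 7L, error_rate = 0) {
  stopifnot(nchar(anchor_fwd) >= 8, nchar(anchor_rev) >= 8)
  check_fraction(error_rate, "error_rate")
  stagger_max <- check_count(stagger_max, "stagger_max", min = 0L)
  if (stagger_max > nchar(STAGGER_PAD)) {
    abort(sprintf("`stagger_max` cannot exceed %d.", nchar(STAGGER_PAD)))
  }
  structure(list(anchor_fwd = anchor_fwd, anchor_rev = anchor_rev,
                 stagger_max = stagger_max, error_rate = error_rate),
            class = "read_layout")
}

#' Generate random DNA reference sequences
#'
#' Convenience generator for simulated substrate or guide reference tables.
#'
#' @param ids Character vector of identifiers.
#' @param width Sequence length in nt (22 for ORF barcodes, 20-21 for
#'   protospacers, longer for peptide-coding inserts).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `sequence`.
#' @export
random_dna_refs <- function(ids, width, seed = 1L) {
  stopifnot(!anyDuplicated(ids))
  width <- check_count(width, "width")
  with_seed(substream_seed(seed, "refs"), {
    seqs <- vapply(seq_along(ids), function(i) {
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = "")
    }, character(1))
    # regenerate any collisions so ids map to unique sequences
    while (anyDuplicated(seqs)) {
      dup <- which(duplicated(seqs))
      seqs[dup] <- vapply(dup, function(i) {
        paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
              collapse = "")
      }, character(1))
    }
    tibble(id = as.character(ids), sequence = seqs)
  })
}

#' Simulate paired amplicon reads from a substrate-by-guide count table
#'
#' Emits one read pair per counted read. The forward read carries a cycling
#' stagger pad (offsets 0..`stagger_max`, in read order), the forward anchor
#' and the substrate sequence; the reverse read carries the reverse anchor and
#' the guide protospacer. Optional uniform substitution errors are applied to
#' both mates.
#'
#' @param counts Long count tibble with columns `substrate`, `guide`,
#'   `sample`, `count` (e.g. from [simulate_screen()]).
#' @param substrate_refs,guide_refs Tibbles with columns `id`, `sequence`.
#' @param layout A [read_layout()].
#' @param seed Integer seed (used only when `error_rate > 0`).
#' @return Tibble with columns `sample`, `read_id`, `r1`, `r2`.
#' @seealso [build_count_table()] for the inverse operation,
#'   [write_fastq_pairs()] to serialise.
#' @export
simulate_reads <- function(counts, substrate_refs, guide_refs,
                           layout = read_layout(), seed = 1L) {
  stopifnot(inherits(layout, "read_layout"))
  counts <- as_tibble(counts)
  stopifnot(all(c("substrate", "guide", "sample", "count") %in% names(counts)))
  sub_seq <- setNames(substrate_refs$sequence, substrate_refs$id)
  gd_seq <- setNames(guide_refs$sequence, guide_refs$id)
  missing_s <- setdiff(unique(counts$substrate), names(sub_seq))
  missing_g <- setdiff(unique(counts$guide), names(gd_seq))
  if (length(missing_s) || length(missing_g)) {
    abort(sprintf("missing reference sequences for: %s",
                  paste(c(missing_s, missing_g), collapse = ", ")))
  }

  idx <- rep(seq_len(nrow(counts)), counts$count)
  n <- length(idx)
  if (n == 0L) {
    return(tibble(sample = character(), read_id = character(),
                  r1 = character(), r2 = character()))
  }
  offsets <- (seq_len(n) - 1L) %% (layout$stagger_max + 1L)
  pads <- substr(rep(STAGGER_PAD, n), 1L, offsets)
  r1 <- paste0(pads, layout$anchor_fwd, sub_seq[counts$substrate[idx]])
  r2 <- paste0(layout$anchor_rev, gd_seq[counts$guide[idx]])

  if (layout$error_rate > 0) {
    with_seed(substream_seed(seed, "read_errors"), {
      r1 <- add_substitutions(r1, layout$error_rate)
      r2 <- add_substitutions(r2, layout$error_rate)
    })
  }

  tibble(
    sample = counts$sample[idx],
    read_id = sprintf("read_%07d", seq_len(n)),
    r1 = unname(r1), r2 = unname(r2)
  )
}

# uniform substitution errors; the substituted base is always different
add_substitutions <- function(reads, rate) {
  lens <- nchar(reads)
  n_err <- rbinom(length(reads), lens, rate)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(lens[i], n_err[i])
    for (p in pos) {
      cur <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, cur), 1L)
    }
  }
  reads
}

#' Write paired reads as FASTQ files
#'
#' @param reads Tibble from [simulate_reads()] (columns `read_id`, `r1`, `r2`).
#' @param r1_path,r2_path Output paths; a `.gz` suffix triggers compression.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  s1 <- Biostrings::DNAStringSet(setNames(reads$r1, reads$read_id))
  s2 <- Biostrings::DNAStringSet(setNames(reads$r2, reads$read_id))
  gz1 <- grepl("\\.gz$", r1_path)
  gz2 <- grepl("\\.gz$", r2_path)
  Biostrings::writeXStringSet(s1, r1_path, format = "fastq", compress = gz1)
  Biostrings::writeXStringSet(s2, r2_path, format = "fastq", compress = gz2)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ files into a read-pair tibble
#'
#' @param r1_path,r2_path FASTQ paths (gzip accepted).
#' @return Tibble with columns `read_id`, `r1`, `r2`.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  s1 <- Biostrings::readDNAStringSet(r1_path, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(r2_path, format = "fastq")
  if (length(s1) != length(s2)) abort("R1 and R2 have different read counts.")
  tibble(read_id = names(s1), r1 = unname(as.character(s1)),
         r2 = unname(as.character(s2)))
}
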