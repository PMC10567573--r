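#' Build a validated reference set
#'
#' A reference set maps library insert sequences to identifiers: peptide
#' substrates are identified by their coding DNA, barcoded ORFs by their
#' 22-nt barcode, and guides by their protospacer. Matching uses the
#' reference-length prefix of the trimmed insert, so references of mixed
#' lengths are permitted.
#'
#' @param x Tibble (or data frame) with columns `id`, `sequence`; optional
#'   columns `label` (e.g. target gene for guides) and `group`.
#' @param kind One of `"substrate"`, `"guide"`, `"barcode"`.
#' @return Tibble of class `reference_set` with attribute `kind`.
#' @export
reference_set <- function(x, kind = c("substrate", "guide", "barcode")) {
  kind <- match.arg(kind)
  x <- as_tibble(x)
  stopifnot(all(c("id", "sequence") %in% names(x)))
  x$sequence <- toupper(x$sequence)
  if (anyDuplicated(x$id)) abort("reference ids must be unique.")
  if (any(is.na(x$sequence) | nchar(x$sequence) == 0)) {
    abort("reference sequences must be non-empty.")
  }
  if (any(grepl("[^ACGTN]", x$sequence))) {
    abort("reference sequences may only contain A/C/G/T/N.")
  }
  structure(x, kind = kind, class = c("reference_set", class(x)))
}

#' Locate a constant anchor and trim a read to its insert
#'
#' Scans offsets `0..max_offset` (the stagger window introduced by the pooled
#' amplification primers) for the anchor within a mismatch tolerance, and
#' returns the read suffix following the anchor. Failure is a return state
#' (`NA`), not an error; failed reads are tallied in QC downstream.
#'
#' @param reads Character vector of reads.
#' @param anchor Constant anchor sequence (length >= 8).
#' @param max_offset Largest stagger offset scanned.
#' @param anchor_mismatch_tol Mismatches tolerated within the anchor.
#' @return A list with `insert` (character, `NA` on failure) and `offset`
#'   (integer offset where the anchor was found, `NA` on failure).
#' @export
locate_and_trim <- function(reads, anchor, max_offset = 7L,
                            anchor_mismatch_tol = 1L) {
  if (nchar(anchor) < 8) abort("`anchor` must be at least 8 nt.")
  anchor <- toupper(anchor)
  n <- length(reads)
  la <- nchar(anchor)
  insert <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  pending <- seq_len(n)
  for (off in 0:max_offset) {
    if (!length(pending)) break
    cand <- substr(reads[pending], off + 1L, off + la)
    ok <- nchar(cand) == la & hamming_dist(cand, anchor) <= anchor_mismatch_tol
    ok[is.na(ok)] <- FALSE
    hit <- pending[ok]
    if (length(hit)) {
      insert[hit] <- substr(reads[hit], off + la + 1L, nchar(reads[hit]))
      offset[hit] <- off
      pending <- pending[!ok]
    }
  }
  list(insert = insert, offset = offset)
}

#' Match trimmed inserts against a reference set
#'
#' Exact prefix lookup first; failing that, the unique best Hamming match
#' within `max_mismatch` over the reference-length prefix of the insert.
#' `N` bases count as mismatches. Ties for best distance are reported as
#' ambiguous rather than resolved, so near-identical paralogue references
#' never cross-contaminate each other's counts.
#'
#' @param inserts Character vector of trimmed inserts (`NA` allowed).
#' @param refs A [reference_set()] (or tibble with `id`, `sequence`).
#' @param max_mismatch Hamming tolerance for inexact matches.
#' @return Character vector of reference ids, with `NA` for no hit and
#'   `"<ambiguous>"` for ties.
#' @export
match_reference <- function(inserts, refs, max_mismatch = 1L) {
  refs <- as_tibble(refs)
  if (!nrow(refs)) abort("`refs` must be non-empty.")
  lens <- sort(unique(nchar(refs$sequence)))
  out <- rep(NA_character_, length(inserts))
  best_d <- rep(NA_integer_, length(inserts))
  usable <- which(!is.na(inserts))

  for (L in lens) {
    sub <- refs[nchar(refs$sequence) == L, ]
    idx <- usable[nchar(inserts[usable]) >= L]
    if (!length(idx)) next
    prefix <- substr(inserts[idx], 1L, L)

    # exact lookup
    hit <- match(prefix, sub$sequence)
    exact <- !is.na(hit)
    out <- assign_match(out, best_d, idx[exact], sub$id[hit[exact]], 0L)
    best_d <- attr(out, "best_d")

    # Hamming fallback only for reads not already exactly matched at this length
    rest <- idx[!exact]
    rest <- rest[is.na(best_d[rest]) | best_d[rest] > 0L]
    if (length(rest) && max_mismatch > 0L) {
      pr <- substr(inserts[rest], 1L, L)
      dmat <- vapply(sub$sequence,
                     function(s) hamming_dist(pr, s),
                     integer(length(rest)))
      dmat <- matrix(dmat, nrow = length(rest))
      for (j in seq_along(rest)) {
        d <- dmat[j, ]
        dm <- min(d)
        if (dm <= max_mismatch) {
          id <- if (sum(d == dm) > 1L) "<ambiguous>" else sub$id[which.min(d)]
          out <- assign_match(out, best_d, rest[j], id, dm)
          best_d <- attr(out, "best_d")
        }
      }
    }
  }
  attr(out, "best_d") <- NULL
  out
}

# record a candidate match, keeping the best distance across reference lengths;
# equal distances to different ids become ambiguous
assign_match <- function(out, best_d, idx, ids, d) {
  if (length(idx)) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      id <- if (length(ids) > 1L) ids[k] else ids
      if (is.na(best_d[i]) || d < best_d[i]) {
        out[i] <- id
        best_d[i] <- d
      } else if (d == best_d[i] && !identical(out[i], id)) {
        out[i] <- "<ambiguous>"
      }
    }
  }
  attr(out, "best_d") <- best_d
  out
}

#' Deconvolute read pairs into a substrate-by-guide count table
#'
#' Trims the forward read to the substrate insert and the reverse read to the
#' protospacer, matches both against their reference sets, and counts a pair
#' only when both ends match uniquely. All other pairs are routed to QC
#' categories; reads assigned to filler substrates are tallied but excluded
#' from the count matrix.
#'
#' @param pairs Tibble with columns `r1`, `r2` (and optionally `read_id`).
#' @param substrate_refs,guide_refs [reference_set()] tables (plain tibbles
#'   with `id`, `sequence` also accepted).
#' @param sample_name Label for the sample/bin being counted.
#' @param anchor_fwd,anchor_rev Constant anchors preceding each insert.
#' @param max_mismatch Hamming tolerance for reference matching.
#' @param max_offset,anchor_mismatch_tol Passed to [locate_and_trim()].
#' @param filler_ids Substrate ids treated as stable filler (excluded from
#'   the matrix, tallied in QC).
#' @return A `combo_counts` tibble (`substrate`, `guide`, `sample`, `count`)
#'   whose `qc` attribute (see [qc_stats()]) satisfies
#'   assigned + fwd_unassigned + rev_unassigned + ambiguous + filler = total.
#' @export
build_count_table <- function(pairs, substrate_refs, guide_refs,
                              sample_name = "sample",
                              anchor_fwd = DEFAULT_ANCHOR_FWD,
                              anchor_rev = DEFAULT_ANCHOR_REV,
                              max_mismatch = 1L, max_offset = 7L,
                              anchor_mismatch_tol = 1L,
                              filler_ids = "FILLER") {
  pairs <- as_tibble(pairs)
  total <- nrow(pairs)
  if (total == 0L) {
    qc <- tibble(sample = sample_name, total = 0L, assigned = 0L,
                 fwd_unassigned = 0L, rev_unassigned = 0L, ambiguous = 0L,
                 filler = 0L)
    out <- tibble(substrate = character(), guide = character(),
                  sample = character(), count = integer())
    return(structure(out, qc = qc, offsets = integer(),
                     class = c("combo_counts", class(out))))
  }
  stopifnot(all(c("r1", "r2") %in% names(pairs)))

  fwd <- locate_and_trim(pairs$r1, anchor_fwd, max_offset, anchor_mismatch_tol)
  rev <- locate_and_trim(pairs$r2, anchor_rev, max_offset = 0L,
                         anchor_mismatch_tol = anchor_mismatch_tol)
  sub_id <- match_reference(fwd$insert, substrate_refs, max_mismatch)
  gd_id <- match_reference(rev$insert, guide_refs, max_mismatch)

  fwd_bad <- is.na(sub_id)
  rev_bad <- !fwd_bad & is.na(gd_id)
  amb <- !fwd_bad & !rev_bad &
    (sub_id == "<ambiguous>" | gd_id == "<ambiguous>")
  filler <- !fwd_bad & !rev_bad & !amb & sub_id %in% filler_ids
  good <- !fwd_bad & !rev_bad & !amb & !filler

  qc <- tibble(
    sample = sample_name,
    total = total,
    assigned = sum(good),
    fwd_unassigned = sum(fwd_bad),
    rev_unassigned = sum(rev_bad),
    ambiguous = sum(amb),
    filler = sum(filler)
  )

  out <- tibble(substrate = sub_id[good], guide = gd_id[good]) |>
    count(.data$substrate, .data$guide, name = "count") |>
    mutate(sample = sample_name, .before = "count")

  structure(out, qc = qc,
            offsets = table(factor(fwd$offset, levels = 0:max_offset)),
            class = c("combo_counts", class(out)))
}

#' QC accounting for a deconvoluted count table
#'
#' @param x A `combo_counts` table from [build_count_table()], or a list of
#'   them.
#' @return Tibble with one row per sample: total pairs, assigned,
#'   fwd/rev-unassigned, ambiguous and filler-excluded counts.
#' @export
qc_stats <- function(x) {
  if (inherits(x, "combo_counts")) return(attr(x, "qc"))
  if (is.list(x)) return(bind_rows(lapply(x, function(el) attr(el, "qc"))))
  abort("`x` must be a combo_counts table or a list of them.")
}
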