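# Shared fixtures: everything is generated in code at test time.

# a small screen with one planted pair, equal library representation
small_screen_config <- function(seed = 1L, sort_mode = "six_bin", ...) {
  screen_sim_config(
    n_substrates = 3, genes = paste0("E3_", 1:5), guides_per_gene = 4,
    cognate_map = tibble::tibble(substrate = "S001", gene = "E3_1",
                                 effect = 2),
    reads_per_bin = 30000, seed = seed, sort_mode = sort_mode, ...
  )
}

# references sized like the real libraries: peptide-coding substrates and
# 20-nt protospacers
screen_refs <- function(config, seed = 1L) {
  list(
    substrates = random_dna_refs(c(config$substrates, "FILLER"), 60,
                                 seed = seed),
    guides = random_dna_refs(guide_library(config)$guide, 20,
                             seed = seed + 1L)
  )
}

# brute-force all-pairs Hamming matcher: the independent oracle for
# match_reference
brute_force_match <- function(inserts, refs, max_mismatch) {
  vapply(inserts, function(ins) {
    if (is.na(ins)) return(NA_character_)
    d <- vapply(refs$sequence, function(s) {
      L <- nchar(s)
      if (nchar(ins) < L) return(NA_integer_)
      sum(strsplit(substr(ins, 1, L), "")[[1]] != strsplit(s, "")[[1]])
    }, integer(1))
    if (all(is.na(d)) || min(d, na.rm = TRUE) > max_mismatch) {
      return(NA_character_)
    }
    best <- which(d == min(d, na.rm = TRUE))
    if (length(best) > 1L) "<ambiguous>" else refs$id[best]
  }, character(1), USE.NAMES = FALSE)
}

# independent PSI oracle: plain weighted mean per entity on a wide table
psi_oracle <- function(wide_norm) {
  apply(wide_norm, 1, function(r) {
    if (sum(r) == 0) return(NA_real_)
    sum(r * seq_along(r)) / sum(r)
  })
}

# exact Mann-Whitney tail by full enumeration over rank subsets
mw_enum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(u_all >= u_obs - 1e-9)
}
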