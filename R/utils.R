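# Internal helpers shared across modules.

#' Derive a deterministic per-stage seed from one global seed
#'
#' All stochastic stages draw from independent substreams derived from a single
#' integer seed, so that one `seed` argument reproduces an entire run while
#' stages remain insensitive to the order in which other stages consume random
#' numbers.
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. `"cells"`, `"reads"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # small multiplicative hash of the stage label, folded into 31 bits
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Hamming distance between equal-length DNA strings
#'
#' Position-wise mismatch count; `N` (or any non-identical character) counts
#' as a mismatch. Vectorised over `x`.
#'
#' @param x Character vector of sequences.
#' @param y Single sequence of the same nchar as the elements of `x`.
#' @return Integer vector of mismatch counts (`NA` for length mismatches).
#' @keywords internal
hamming_dist <- function(x, y) {
  ly <- nchar(y)
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & nchar(x) == ly
  if (!any(ok)) return(out)
  yc <- strsplit(y, "", fixed = TRUE)[[1]]
  mm <- integer(sum(ok))
  xs <- x[ok]
  for (i in seq_len(ly)) {
    mm <- mm + (substr(xs, i, i) != yc[i])
  }
  out[ok] <- mm
  out
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1].", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

BIN_NAMES <- paste0("bin", 1:6)
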