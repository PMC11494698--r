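#' @keywords internal
"_PACKAGE"

#' The twenty standard amino acids
#'
#' One-letter codes for the standard proteinogenic amino acids, the alphabet
#' used throughout for motif sequences and n-grams.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Approximate background amino-acid frequencies in plant proteomes
# (Swiss-Prot-like composition, renormalized over the 20 standard residues).
# Used only to draw "background" residues in simulated motifs.
AA_BACKGROUND_FREQ <- c(
  A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0672, F = 0.0386,
  G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0581, L = 0.0965,
  M = 0.0241, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
  S = 0.0660, T = 0.0535, V = 0.0687, W = 0.0110, Y = 0.0292
)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never disturb the global stream.
#'
#' @param seed Integer scalar seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive per-stage seeds from one master seed
#'
#' Fans one master seed out into `n` reproducible stage seeds (all below
#' 2^31), so every pipeline stage draws from its own substream.
#'
#' @param seed Integer master seed.
#' @param n Number of stage seeds required.
#' @return Integer vector of length `n`.
#' @export
fanout_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Overlapping occurrence count of a literal pattern (one per start position).
count_overlapping <- function(x, pattern) {
  n <- nchar(x)
  k <- nchar(pattern)
  if (n < k) return(0L)
  starts <- seq_len(n - k + 1L)
  sum(substring(x, starts, starts + k - 1L) == pattern)
}

assert_peptide <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || anyNA(sequence) || any(!nzchar(sequence))) {
    stop(what, " must be a non-empty character string", call. = FALSE)
  }
  bad <- grepl(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), sequence)
  if (any(bad)) {
    stop(what, " contains non-amino-acid characters: ",
         paste(sequence[bad], collapse = ", "), call. = FALSE)
  }
  invisible(sequence)
}
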