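# Pairwise percent identity between motif peptides, via global alignment.

# Simple +1/-1 substitution matrix over the 20 standard amino acids.
identity_submat <- function() {
  m <- matrix(-1, length(AA_STANDARD), length(AA_STANDARD),
              dimnames = list(AA_STANDARD, AA_STANDARD))
  diag(m) <- 1
  m
}

#' Global percent identity of two peptides
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -1 and a
#' linear gap cost of 1 per gap column (no free end gaps), via
#' [Biostrings::pairwiseAlignment()]. Identity is the number of identical
#' aligned columns divided by the full alignment length (gap columns
#' included), times 100 — a conservative denominator that can only lower
#' identities.
#'
#' @param a,b Non-empty peptide strings.
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(a, b) {
  assert_peptide(a, "a")
  assert_peptide(b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = identity_submat(), gapOpening = 0, gapExtension = 1
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}

#' Pairwise identity matrix
#'
#' @param sequences Named character vector of peptides (>= 2).
#' @return Symmetric matrix of percent identities, diagonal 100, with the
#'   sequence names as dimnames.
#' @export
identity_matrix <- function(sequences) {
  if (length(sequences) < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(sequences))
  k <- length(sequences)
  m <- matrix(100, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- global_identity(sequences[[i]], sequences[[j]])
    }
  }
  m
}

#' Maximum off-diagonal pairwise identity
#'
#' @param sequences Named character vector of peptides (>= 2); duplicated
#'   sequences are allowed (and yield 100).
#' @return List with `value` (percent identity) and `pair` (the two ids;
#'   ties break by id order).
#' @export
max_pairwise_identity <- function(sequences) {
  m <- identity_matrix(sequences)
  diag(m) <- -Inf
  idx <- which(m == max(m), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(value = max(m),
       pair = c(rownames(m)[idx[1, 1]], colnames(m)[idx[1, 2]]))
}
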