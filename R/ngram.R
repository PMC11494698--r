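# Amino-acid n-gram analysis: decomposition, strength-quartile partition,
# per-quartile tallies and the strong/moderate/weak classification rules.

#' Decompose a peptide into overlapping n-grams
#'
#' @param sequence Peptide string.
#' @param n Gram length (2, 3 or 4).
#' @return Character vector of all `nchar(sequence) - n + 1` overlapping
#'   substrings in order; empty when the sequence is shorter than `n`.
#' @export
decompose_ngrams <- function(sequence, n) {
  stopifnot(length(sequence) == 1L, n %in% 2:4)
  assert_peptide(sequence)
  L <- nchar(sequence)
  if (L < n) return(character(0))
  starts <- seq_len(L - n + 1L)
  substring(sequence, starts, starts + n - 1L)
}

#' Partition constructs into strength quartiles
#'
#' Ranks non-control constructs by repression strength (`1 - relative_gfp`)
#' in decreasing order and splits them into four near-equal groups, Q1 the
#' strongest. When the count is not divisible by four, the remainder goes to
#' the stronger quartiles first; ties in strength break by construct id, so
#' the partition is deterministic.
#'
#' @param summaries A `construct_summary` data frame.
#' @param controls Construct ids excluded from the partition.
#' @return Object of class `quartile_partition`: list of four character
#'   vectors `Q1`..`Q4` of construct ids.
#' @export
quartile_partition <- function(summaries, controls = c("Gal4", "SRDX")) {
  dat <- summaries[!summaries$construct_id %in% controls, , drop = FALSE]
  n <- nrow(dat)
  if (n < 4) stop("need at least 4 non-control constructs", call. = FALSE)
  strength <- 1 - dat$relative_gfp
  ord <- order(-strength, dat$construct_id)
  ids <- dat$construct_id[ord]
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- base + as.integer(seq_len(4L) <= extra)
  stops <- cumsum(sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  out <- lapply(seq_len(4L), function(q) ids[starts[q]:stops[q]])
  names(out) <- paste0("Q", 1:4)
  structure(out, class = "quartile_partition")
}

#' Tally n-grams per strength quartile
#'
#' Counts overlapping n-gram occurrences (n = 2, 3, 4) within each quartile's
#' sequences, converts counts to within-quartile frequencies (count divided
#' by the quartile's total number of grams of the same length), and forms
#' representation ratios against the pooled frequency over all four
#' quartiles. Frequencies rather than raw counts are used so quartiles with
#' unequal total sequence length are comparable. A quartile with no grams of
#' a given length yields `NA` ratios for those grams.
#'
#' @param motifs A `motif_library` (or any data frame with `id`, `sequence`).
#' @param partition A `quartile_partition` over ids present in `motifs`.
#' @param n_values Gram lengths to tally.
#' @return Data frame of class `ngram_table`: `gram`, `n`, `count_q1`..`count_q4`,
#'   `total_count`, `freq_q1`..`freq_q4`, `overall_freq`, `ratio_q1`..`ratio_q4`.
#' @export
build_ngram_table <- function(motifs, partition, n_values = 2:4) {
  seqs <- stats::setNames(motifs$sequence, motifs$id)
  missing <- setdiff(unlist(partition), names(seqs))
  if (length(missing) > 0) {
    stop("partition ids without sequences: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per_n <- lapply(n_values, function(n) {
    counts <- lapply(1:4, function(q) {
      grams <- unlist(lapply(seqs[partition[[q]]], decompose_ngrams, n = n),
                      use.names = FALSE)
      table(grams)
    })
    totals <- vapply(counts, sum, numeric(1))
    all_grams <- sort(unique(unlist(lapply(counts, names))))
    if (length(all_grams) == 0) return(NULL)
    cnt <- vapply(counts, function(tb) {
      v <- as.numeric(tb[all_grams]); v[is.na(v)] <- 0; v
    }, numeric(length(all_grams)))
    cnt <- matrix(cnt, nrow = length(all_grams))
    freq <- sweep(cnt, 2, totals, "/")   # NaN where a quartile has no grams
    total_count <- rowSums(cnt)
    overall <- total_count / sum(totals)
    ratio <- freq / overall
    out <- data.frame(gram = all_grams, n = n, stringsAsFactors = FALSE)
    colnames(cnt) <- paste0("count_q", 1:4)
    colnames(freq) <- paste0("freq_q", 1:4)
    colnames(ratio) <- paste0("ratio_q", 1:4)
    cbind(out, cnt, total_count = total_count, freq,
          overall_freq = overall, ratio)
  })
  tab <- do.call(rbind, per_n)
  rownames(tab) <- NULL
  # an empty quartile gives 0/0 = NaN frequencies; record those as NA
  for (col in c(paste0("freq_q", 1:4), paste0("ratio_q", 1:4))) {
    tab[[col]][is.nan(tab[[col]])] <- NA
  }
  class(tab) <- c("ngram_table", "data.frame")
  tab
}

#' Classify n-grams by quartile representation
#'
#' Applies the strength rules to the representation ratios: *strong* grams
#' are at least 2x over-represented in the strongest quartile and
#' under-represented (ratio < 1) in the weakest; *weak* grams the opposite;
#' *moderate* grams deviate by no more than 25% from the pooled frequency in
#' every quartile; everything else (including grams with undefined ratios
#' from an empty quartile) is *unclassified*.
#'
#' @param table An `ngram_table`.
#' @return The table with a `class` factor column appended
#'   (levels strong, moderate, weak, unclassified).
#' @export
classify_ngrams <- function(table) {
  r1 <- table$ratio_q1; r2 <- table$ratio_q2
  r3 <- table$ratio_q3; r4 <- table$ratio_q4
  strong <- !is.na(r1) & !is.na(r4) & r1 >= 2 & r4 < 1
  weak <- !is.na(r1) & !is.na(r4) & r4 >= 2 & r1 < 1
  moderate <- !is.na(r1) & !is.na(r2) & !is.na(r3) & !is.na(r4) &
    r1 >= 0.75 & r1 <= 1.25 & r2 >= 0.75 & r2 <= 1.25 &
    r3 >= 0.75 & r3 <= 1.25 & r4 >= 0.75 & r4 <= 1.25
  if (any(is.na(r1) | is.na(r2) | is.na(r3) | is.na(r4))) {
    warning("some quartiles have no grams of a given length; ",
            "affected grams left unclassified", call. = FALSE)
  }
  cls <- rep("unclassified", nrow(table))
  cls[moderate] <- "moderate"
  cls[strong] <- "strong"
  cls[weak] <- "weak"
  table$class <- factor(cls, levels = c("strong", "moderate", "weak",
                                        "unclassified"))
  table
}

#' Extract the gram sets of each class
#'
#' @param table A classified `ngram_table` (output of [classify_ngrams()]).
#' @return Named list of character vectors: `strong`, `moderate`, `weak`.
#' @export
ngram_class_sets <- function(table) {
  if (is.null(table$class)) stop("table has no class column; run classify_ngrams first",
                                 call. = FALSE)
  list(
    strong = table$gram[table$class == "strong"],
    moderate = table$gram[table$class == "moderate"],
    weak = table$gram[table$class == "weak"]
  )
}
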