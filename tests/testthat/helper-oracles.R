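# Independent brute-force oracles used to validate the analytical routines.
# Each is written from the definition, not from the implementation it checks.

# Exact 2x2 test by direct enumeration of the hypergeometric support with
# choose(); margins fixed at the observed values.
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  xs <- max(0, r1 + c1 - N):min(r1, c1)
  prob <- vapply(xs, function(x) {
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1)
  }, numeric(1))
  p_obs <- prob[xs == tab[1, 1]]
  list(
    p_one_sided = min(1, sum(prob[xs >= tab[1, 1]])),
    p_two_sided = min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
  )
}

# Dunn z statistics computed from first principles: ranks by counting,
# tie correction from the multiset of values.
dunn_brute <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  N <- length(values)
  # mid-rank of each value by definition
  r <- vapply(values, function(v) {
    sum(values < v) + (sum(values == v) + 1) / 2
  }, numeric(1))
  tie_term <- 0
  for (v in unique(values)) {
    t <- sum(values == v)
    tie_term <- tie_term + (t^3 - t)
  }
  var_factor <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  ids <- names(groups)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      a <- ids[i]; b <- ids[j]
      z <- (mean(r[labels == a]) - mean(r[labels == b])) /
        sqrt(var_factor * (1 / sum(labels == a) + 1 / sum(labels == b)))
      out[[paste(a, b, sep = "|")]] <- z
    }
  }
  out
}

# Enumerate every global alignment of two short peptides; returns the
# maximum score (match +1, mismatch -1, gap column -1) and the percent
# identities attained by the optimal-score alignments.
align_brute <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  rows <- list()
  rec <- function(i, j, score, match, cols) {
    if (i > length(A) && j > length(B)) {
      rows[[length(rows) + 1L]] <<- c(score, match, cols)
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      m <- A[i] == B[j]
      rec(i + 1L, j + 1L, score + if (m) 1 else -1, match + m, cols + 1L)
    }
    if (i <= length(A)) rec(i + 1L, j, score - 1, match, cols + 1L)
    if (j <= length(B)) rec(i, j + 1L, score - 1, match, cols + 1L)
  }
  rec(1L, 1L, 0, 0L, 0L)
  m <- do.call(rbind, rows)
  best <- max(m[, 1])
  opt <- m[m[, 1] == best, , drop = FALSE]
  list(max_score = best, identities = sort(unique(100 * opt[, 2] / opt[, 3])))
}

# Exhaustive threshold search straight from the definition: candidate cuts
# at midpoints between consecutive sorted distinct values plus outer caps,
# all strictly increasing triples, accuracy by binning and matching.
thresholds_brute <- function(values, predicted) {
  d <- sort(unique(values))
  cand <- c(d[1] - 1, (d[-length(d)] + d[-1]) / 2, d[length(d)] + 1)
  best <- -1
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (j < i) next
      for (k in seq_along(cand)) {
        if (k < j) next
        th <- cand[c(i, j, k)] + c(0, 1e-9, 2e-9)  # keep strictly increasing
        cls <- 1L + findInterval(values, th)
        best <- max(best, mean(cls == predicted))
      }
    }
  }
  best
}

# Minimal motif-library data frame for assay fixtures.
make_motifs <- function(ids, sequences, strengths,
                        library = rep("naturalEAR", length(ids))) {
  out <- data.frame(id = ids, sequence = sequences, library = library,
                    true_strength = strengths, stringsAsFactors = FALSE)
  class(out) <- c("motif_library", "data.frame")
  out
}

# Zero-noise ground-truth model with fixed planted grams, for hand-checkable
# fixtures.
make_model <- function(strong = character(0), weak = character(0),
                       neutral = character(0), effect_size = 0.3,
                       baseline_log_fluor = log(1000),
                       tech_noise_sd = 0, bio_noise_sd = 0) {
  structure(
    list(alphabet = AA_STANDARD, strong_grams = strong, weak_grams = weak,
         neutral_grams = neutral, baseline_log_fluor = baseline_log_fluor,
         effect_size = effect_size, tech_noise_sd = tech_noise_sd,
         bio_noise_sd = bio_noise_sd, seed = 1L),
    class = "ground_truth_model"
  )
}
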