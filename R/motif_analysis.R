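# Canonical EAR-pattern scanning, exact enrichment testing, length-strength
# analysis, and the rank-based Dunn post-hoc test.

#' Scan peptides for the canonical EAR patterns
#'
#' Reports presence of the two canonical EAR repression patterns: `LxLxL`
#' (leucines at positions 1, 3, 5 of any 5-residue window) and `DLNxxP`.
#' Overlapping matches count as presence only.
#'
#' @param sequence Character vector of uppercase peptide sequences.
#' @param construct_id Optional ids (defaults to names or an index).
#' @return Data frame with `construct_id`, `has_LxLxL`, `has_DLNxxP`,
#'   `has_both`.
#' @export
scan_canonical <- function(sequence, construct_id = NULL) {
  assert_peptide(sequence)
  if (is.null(construct_id)) {
    construct_id <- if (!is.null(names(sequence))) names(sequence)
                    else sprintf("seq%d", seq_along(sequence))
  }
  lxlxl <- grepl("L.L.L", sequence)
  dlnxxp <- grepl("DLN..P", sequence)
  data.frame(construct_id = construct_id, has_LxLxL = lxlxl,
             has_DLNxxP = dlnxxp, has_both = lxlxl & dlnxxp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exact test of association in a 2x2 table
#'
#' Fisher's exact test computed directly from the hypergeometric
#' distribution of the top-left cell with all margins fixed. The one-sided
#' p-value is the upper tail (enrichment of the top-left cell); the
#' two-sided p-value sums the probabilities of all tables whose point
#' probability does not exceed the observed one (minimum-likelihood rule).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p_one_sided` and `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("table must be a 2x2 matrix of non-negative integers", call. = FALSE)
  }
  if (sum(tab) == 0) stop("all-zero table: test undefined", call. = FALSE)
  x <- tab[1, 1]
  m <- sum(tab[, 1])          # first-column margin
  n_ <- sum(tab[, 2])         # second-column margin
  k <- sum(tab[1, ])          # first-row margin
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(x, m, n_, k)
  p_one <- sum(probs[support >= x])
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_one_sided = min(1, p_one), p_two_sided = min(1, p_two))
}

#' Relate motif length to repression strength
#'
#' Joins construct summaries to their peptide sequences, computes repression
#' strength as `1 - relative_gfp`, and returns per-length box statistics
#' (25th/50th/75th percentiles) plus the Spearman rank correlation between
#' length and strength. Named constructs (e.g. the SRDX control) can be
#' excluded to check the robustness of the correlation.
#'
#' @param summaries A `construct_summary` data frame.
#' @param sequences Named character vector mapping `construct_id` to peptide.
#' @param exclude Construct ids to drop before the analysis.
#' @return List with `by_length` (data frame: `length`, `n`, `q25`, `median`,
#'   `q75`), `spearman_rho` (`NA` when all lengths are equal), `n_constructs`.
#' @export
length_strength <- function(summaries, sequences, exclude = character(0)) {
  keep <- summaries$construct_id %in% names(sequences) &
    !summaries$construct_id %in% exclude
  dat <- summaries[keep, , drop = FALSE]
  if (nrow(dat) == 0) stop("no constructs with sequences", call. = FALSE)
  len <- nchar(sequences[dat$construct_id])
  strength <- 1 - dat$relative_gfp
  by_length <- do.call(rbind, lapply(sort(unique(len)), function(L) {
    q <- stats::quantile(strength[len == L], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(length = L, n = sum(len == L), q25 = q[1], median = q[2],
               q75 = q[3])
  }))
  rho <- if (length(unique(len)) < 2) {
    message("all motif lengths equal; rank correlation undefined")
    NA_real_
  } else {
    stats::cor(len, strength, method = "spearman")
  }
  list(by_length = by_length, spearman_rho = rho, n_constructs = nrow(dat))
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z statistics on the joint ranks of all observations (the
#' Kruskal-Wallis post-hoc comparison) with the standard tie correction,
#' and Bonferroni-adjusted two-sided p-values. Groups with fewer than two
#' values are excluded with a warning.
#'
#' @param groups Named list of numeric vectors (replicate values per group).
#' @param correction Multiple-comparison correction; only `"bonferroni"`.
#' @return Data frame with `group1`, `group2`, `z`, `p_raw`, `p_adj`.
#' @export
dunn_test <- function(groups, correction = c("bonferroni")) {
  correction <- match.arg(correction)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    warning("excluding groups with fewer than 2 values: ",
            paste(names(groups)[sizes < 2], collapse = ", "), call. = FALSE)
    groups <- groups[sizes >= 2]
  }
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  ids <- names(groups)
  pairs <- utils::combn(ids, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = a, group2 = b, z = z, p_raw = p,
               p_adj = min(1, p * m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
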