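# Reporter-assay quantification: technical-replicate aggregation, construct
# summaries relative to the Gal4 baseline, repressor classification,
# cross-library normalization, and delta-delta-Cq relative expression.

#' Collapse technical replicates into biological data points
#'
#' Averages the leaf-disk reads of each plant so every (construct, plant)
#' pair contributes exactly one biological value, the unit all downstream
#' statistics operate on.
#'
#' @param plate Data frame with columns `construct_id`, `plant_id`,
#'   `fluorescence` (one row per leaf disk).
#' @return Data frame with columns `construct_id`, `plant_id`, `bio_value`,
#'   ordered by construct then plant.
#' @export
aggregate_replicates <- function(plate) {
  required <- c("construct_id", "plant_id", "fluorescence")
  if (!all(required %in% names(plate))) {
    stop("plate table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(plate) == 0) stop("plate table is empty", call. = FALSE)
  agg <- stats::aggregate(fluorescence ~ construct_id + plant_id, data = plate,
                          FUN = mean)
  names(agg)[names(agg) == "fluorescence"] <- "bio_value"
  agg <- agg[order(agg$construct_id, agg$plant_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Summarize one construct against the Gal4 baseline
#'
#' @param bio_values Numeric vector of per-plant biological values (AU).
#' @param gal4_mean Mean biological fluorescence of the Gal4 control (> 0).
#' @return One-row data frame with `n_bio`, `mean_fluor`, `sem` (sample SD
#'   over biological replicates divided by sqrt(n); `NA` when n < 2),
#'   `relative_gfp` and `is_repressor`.
#' @export
summarize_construct <- function(bio_values, gal4_mean) {
  if (!is.numeric(gal4_mean) || length(gal4_mean) != 1 || gal4_mean <= 0) {
    stop("gal4_mean must be a positive scalar", call. = FALSE)
  }
  n <- length(bio_values)
  m <- mean(bio_values)
  sem <- if (n >= 2) stats::sd(bio_values) / sqrt(n) else NA_real_
  rel <- m / gal4_mean
  data.frame(n_bio = n, mean_fluor = m, sem = sem, relative_gfp = rel,
             is_repressor = classify_repressor(rel))
}

#' Repressor classification at the 50% GFP-reduction threshold
#'
#' A construct is a repressor when its relative GFP is at most 0.5 (the
#' boundary is included so the rule is deterministic).
#'
#' @param relative_gfp Relative GFP (Gal4 = 1), positive.
#' @return Logical vector.
#' @export
classify_repressor <- function(relative_gfp) {
  if (any(relative_gfp <= 0, na.rm = TRUE)) {
    stop("relative_gfp must be positive", call. = FALSE)
  }
  relative_gfp <= 0.5
}

#' Quantify a plate table into per-construct summaries
#'
#' Runs [aggregate_replicates()] and [summarize_construct()] over every
#' construct, using the named Gal4 control's biological mean as the baseline.
#' Constructs with `relative_gfp > 1` (apparent activators) are retained and
#' flagged, never classified as repressors.
#'
#' @param plate Plate table (see [aggregate_replicates()]).
#' @param gal4_id Construct id of the Gal4 baseline control.
#' @return Data frame of class `construct_summary` with one row per
#'   construct: `construct_id`, `n_bio`, `mean_fluor`, `sem`, `relative_gfp`,
#'   `is_repressor`, `is_activator`.
#' @export
quantify_assay <- function(plate, gal4_id = "Gal4") {
  bio <- aggregate_replicates(plate)
  if (!gal4_id %in% bio$construct_id) {
    stop("plate table lacks the baseline control '", gal4_id, "'",
         call. = FALSE)
  }
  gal4_mean <- mean(bio$bio_value[bio$construct_id == gal4_id])
  ids <- unique(bio$construct_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    s <- summarize_construct(bio$bio_value[bio$construct_id == id], gal4_mean)
    cbind(data.frame(construct_id = id, stringsAsFactors = FALSE), s)
  }))
  out$is_activator <- out$relative_gfp > 1
  rownames(out) <- NULL
  class(out) <- c("construct_summary", "data.frame")
  out
}

#' Two-anchor cross-library normalization
#'
#' Rescales mean fluorescence so the shared controls anchor the scale:
#' Gal4 maps to 0 and SRDX to 1. Scores above 1 (stronger than SRDX) and
#' below 0 (activators) are permitted.
#'
#' @param mean_fluor Construct mean fluorescence (AU), vectorized.
#' @param gal4_mean,srdx_mean Control means within the same library
#'   (`gal4_mean > srdx_mean > 0`).
#' @return Normalized score(s).
#' @export
normalize_cross_library <- function(mean_fluor, gal4_mean, srdx_mean) {
  if (srdx_mean <= 0 || gal4_mean <= srdx_mean) {
    stop("degenerate controls: need gal4_mean > srdx_mean > 0", call. = FALSE)
  }
  (gal4_mean - mean_fluor) / (gal4_mean - srdx_mean)
}

#' Delta-delta-Cq relative expression
#'
#' Computes per-sample `delta_cq = cq_target - cq_reference`, exponentiates
#' (`2^-delta_cq`, amplification efficiency assumed exactly 2), and rescales
#' so the wild-type samples' mean expression is exactly 1. Samples missing
#' either gene are dropped with a warning.
#'
#' @param cq Data frame with columns `sample_id`, `genotype`, `gene`, `cq`.
#' @param target,reference Gene names in `cq$gene`.
#' @param wildtype_ids Character vector of wild-type `sample_id`s (or a
#'   genotype name present in `cq$genotype`).
#' @return Data frame with `sample_id`, `genotype`, `delta_cq`, `expression`.
#' @export
delta_delta_cq <- function(cq, target = "target", reference = "reference",
                           wildtype_ids) {
  required <- c("sample_id", "gene", "cq")
  if (!all(required %in% names(cq))) {
    stop("cq table must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (length(wildtype_ids) == 0) {
    stop("wildtype_ids must be non-empty", call. = FALSE)
  }
  if ("genotype" %in% names(cq) && all(wildtype_ids %in% cq$genotype)) {
    wildtype_ids <- unique(cq$sample_id[cq$genotype %in% wildtype_ids])
  }
  samples <- unique(cq$sample_id)
  rows <- lapply(samples, function(sid) {
    sub <- cq[cq$sample_id == sid, , drop = FALSE]
    ct <- sub$cq[sub$gene == target]
    cr <- sub$cq[sub$gene == reference]
    if (length(ct) != 1 || length(cr) != 1) {
      warning("sample '", sid, "' lacks exactly one Cq per gene; dropped",
              call. = FALSE)
      return(NULL)
    }
    data.frame(
      sample_id = sid,
      genotype = if ("genotype" %in% names(sub)) sub$genotype[1] else NA_character_,
      delta_cq = ct - cr,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no complete samples", call. = FALSE)
  wt <- out$sample_id %in% wildtype_ids
  if (!any(wt)) stop("no wild-type samples present in the Cq table", call. = FALSE)
  expr <- 2^(-out$delta_cq)
  out$expression <- expr / mean(expr[wt])
  rownames(out) <- NULL
  out
}
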