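# Synthetic assay data: ground-truth models, motif libraries, plate-reader
# fluorescence and qPCR Cq tables with the statistical structure the
# downstream quantification assumes.

GAL4_CONTROL_SEQ <- "MKLLSSIEQA"        # placeholder peptide for the DBD-only control
SRDX_CONTROL_SEQ <- "LDLDLELRLGFA"     # the canonical strong EAR-type repressor
SRDX_TRUE_STRENGTH <- 0.9

#' Build a ground-truth model for simulated repression assays
#'
#' Plants two disjoint sets of amino-acid n-grams (lengths 2-4): "strong"
#' grams push repression up (each occurrence contributes effect `-effect_size`
#' to the summed latent effect), "weak" grams push it down (`+effect_size`).
#' The model also fixes the Gal4-level baseline fluorescence and the
#' biological (per-plant) and technical (per-leaf-disk) log-scale noise.
#'
#' In addition to the effect-bearing grams, the model plants a few *neutral*
#' family dipeptides with effect zero: recurring residue content shared by
#' all library members regardless of strength, as family-characteristic
#' composition is in a natural motif family. These are what the downstream
#' classifier can legitimately call "moderate".
#'
#' @param n_strong,n_weak Numbers of planted strong / weak grams (>= 0).
#' @param n_neutral Number of neutral family dipeptides (>= 0).
#' @param effect_size Latent effect magnitude per gram occurrence (> 0, but
#'   0 allowed for degenerate null models).
#' @param tech_noise_sd,bio_noise_sd Log-scale lognormal noise SDs (>= 0).
#' @param baseline_log_fluor Log of the Gal4 baseline fluorescence (AU).
#' @param gram_lengths Candidate planted-gram lengths, subset of 2:4.
#' @param alphabet Amino-acid alphabet.
#' @param seed Integer seed; identical seeds give byte-identical models.
#' @return An object of class `ground_truth_model`.
#' @export
generate_ground_truth <- function(n_strong, n_weak, n_neutral = 2L,
                                  effect_size = 0.3,
                                  tech_noise_sd = 0.05, bio_noise_sd = 0.05,
                                  baseline_log_fluor = log(1000),
                                  gram_lengths = 2:4,
                                  alphabet = AA_STANDARD, seed = 1L) {
  stopifnot(n_strong >= 0, n_weak >= 0, n_neutral >= 0)
  if (effect_size < 0) stop("effect_size must be non-negative", call. = FALSE)
  if (tech_noise_sd < 0 || bio_noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (!all(gram_lengths %in% 2:4)) {
    stop("gram_lengths must be within 2:4", call. = FALSE)
  }
  n_total <- n_strong + n_weak + n_neutral
  grams <- character(0)
  if (n_total > 0) {
    grams <- with_seed(seed, {
      out <- character(0)
      while (length(out) < n_total) {
        # neutral family grams are dipeptides; effect grams span 2-4
        len <- if (length(out) < n_strong + n_weak) sample(gram_lengths, 1L)
               else 2L
        g <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
        if (!g %in% out) out <- c(out, g)
      }
      out
    })
  }
  structure(
    list(
      alphabet = alphabet,
      strong_grams = if (n_strong > 0) grams[seq_len(n_strong)] else character(0),
      weak_grams = if (n_weak > 0) grams[n_strong + seq_len(n_weak)] else character(0),
      neutral_grams = if (n_neutral > 0) grams[n_strong + n_weak + seq_len(n_neutral)]
                      else character(0),
      baseline_log_fluor = baseline_log_fluor,
      effect_size = effect_size,
      tech_noise_sd = tech_noise_sd,
      bio_noise_sd = bio_noise_sd,
      seed = as.integer(seed)
    ),
    class = "ground_truth_model"
  )
}

#' Latent repression strength of a peptide under a ground-truth model
#'
#' Scans the sequence for planted-gram occurrences (overlapping, one per
#' start position), sums their effects, and maps the sum through a bounded
#' monotone logistic link onto the repression scale `[-0.6, 1]` (fraction of
#' GFP reduction; negative values are activation). A sequence with no planted
#' grams sits at the link's baseline `g(0) = 0.2`.
#'
#' @param sequence Peptide string.
#' @param model A `ground_truth_model`.
#' @return Repression strength in `[-0.6, 1]`.
#' @export
motif_true_strength <- function(sequence, model) {
  assert_peptide(sequence)
  e <- model$effect_size
  s <- 0
  for (g in model$strong_grams) s <- s - e * count_overlapping(sequence, g)
  for (g in model$weak_grams)  s <- s + e * count_overlapping(sequence, g)
  strength_link(s)
}

# Deterministic dose of neutral family grams for a motif of length L at
# library index i: short motifs carry one (alternating over the set so all
# grams accrue equal totals), medium motifs carry the full set, long motifs
# one extra. Keeps the per-position density of each family gram roughly
# flat across lengths, as family-characteristic composition is.
neutral_units <- function(L, i, grams) {
  k <- length(grams)
  if (k == 0) return(character(0))
  units <- if (L >= 9) grams else grams[[(i %% k) + 1L]]
  if (L >= 13) units <- c(units, grams[[((i + 1L) %% k) + 1L]])
  units
}

# Monotone decreasing link: summed latent effect -> repression in [-0.6, 1].
# Bounded and differentiable; the scale is set so a handful of planted-gram
# occurrences at the default effect size traverses the assay's observed
# dynamic range (from a ~50% fluorescence increase to >90% GFP loss).
STRENGTH_LINK_SCALE <- 0.6

strength_link <- function(s) {
  -0.6 + 1.6 * stats::plogis(-s / STRENGTH_LINK_SCALE)
}

#' Simulate a motif library with planted sequence effects
#'
#' Draws `n_constructs` peptide motifs. Each motif is one of three types:
#' repressor-type (tokens are planted strong grams with probability
#' `planted_density`, background residues otherwise), activator-type (same
#' with weak grams), or background (background residues only). Background
#' residues follow natural amino-acid frequencies. This polarization mirrors
#' a natural repression-motif library, where constructs are either functional
#' repressors or essentially inert, and it puts the planted-gram signal in
#' the per-quartile frequencies the n-gram classifier reads. `true_strength`
#' is then computed from the realized sequence via [motif_true_strength()],
#' so overlapping planted grams contribute additively per start position.
#' Gal4 (baseline) and SRDX (strong repressor) controls are appended.
#'
#' @param n_constructs Number of library motifs (>= 1), controls excluded.
#' @param model A `ground_truth_model`.
#' @param length_dist Non-empty integer vector of motif lengths; lengths are
#'   drawn uniformly from it (an empirical length list; lengths >= 2).
#' @param composition List with elements `p_strong`, `p_weak` (type
#'   probabilities; background gets the remainder) and `planted_density`.
#' @param seed Integer seed.
#' @return Data frame of class `motif_library` with columns `id`, `sequence`,
#'   `library`, `true_strength`.
#' @export
generate_motif_library <- function(n_constructs, model,
                                   length_dist = 5:16,
                                   composition = list(p_strong = 0.35,
                                                      p_weak = 0.35,
                                                      planted_density = 0.8),
                                   seed = 1L) {
  stopifnot(n_constructs >= 1)
  if (length(length_dist) == 0) {
    stop("length_dist must be a non-empty set of lengths", call. = FALSE)
  }
  if (any(length_dist < 2)) stop("motif lengths must be >= 2", call. = FALSE)
  p_strong <- composition$p_strong
  p_weak <- composition$p_weak
  dens <- composition$planted_density
  stopifnot(p_strong >= 0, p_weak >= 0, p_strong + p_weak <= 1,
            dens >= 0, dens <= 1)

  seqs <- with_seed(seed, {
    vapply(seq_len(n_constructs), function(i) {
      L <- if (length(length_dist) == 1L) length_dist else sample(length_dist, 1L)
      type <- sample(c("strong", "weak", "background"), 1L,
                     prob = c(p_strong, p_weak, 1 - p_strong - p_weak))
      grams <- switch(type,
                      strong = model$strong_grams,
                      weak = model$weak_grams,
                      background = character(0))
      # family-typical neutral grams: deterministic, roughly
      # length-proportional dose, independent of strength type; the filler
      # around them carries the planted effect grams
      neutral <- neutral_units(L, i, model$neutral_grams)
      core_len <- L - sum(nchar(neutral))
      filler <- character(0)
      while (sum(nchar(filler)) < core_len) {
        if (length(grams) > 0 && stats::runif(1) < dens) {
          tok <- grams[[sample.int(length(grams), 1L)]]
        } else {
          tok <- sample(names(AA_BACKGROUND_FREQ), 1L, prob = AA_BACKGROUND_FREQ)
        }
        filler <- c(filler, tok)
      }
      over <- sum(nchar(filler)) - core_len
      if (over > 0) {
        last <- filler[length(filler)]
        filler[length(filler)] <- substr(last, 1L, nchar(last) - over)
      }
      # neutral grams go between filler tokens so assembly units stay intact
      tokens <- filler[nzchar(filler)]
      for (g in neutral) {
        gap <- sample.int(length(tokens) + 1L, 1L) - 1L
        tokens <- append(tokens, g, after = gap)
      }
      substr(paste(tokens, collapse = ""), 1L, L)
    }, character(1))
  })

  lib <- data.frame(
    id = sprintf("EAR%03d", seq_len(n_constructs)),
    sequence = seqs,
    library = "naturalEAR",
    true_strength = vapply(seqs, motif_true_strength, numeric(1), model = model,
                           USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    id = c("Gal4", "SRDX"),
    sequence = c(GAL4_CONTROL_SEQ, SRDX_CONTROL_SEQ),
    library = "control",
    true_strength = c(0, SRDX_TRUE_STRENGTH),
    stringsAsFactors = FALSE
  )
  out <- rbind(lib, controls)
  rownames(out) <- NULL
  class(out) <- c("motif_library", "data.frame")
  out
}

#' Simulate the agroinfiltration reporter assay
#'
#' Generates a long-format plate table: for every motif, `n_bio` plants each
#' contribute `n_tech` leaf-disk fluorescence reads. Reads follow
#' `exp(baseline_log_fluor + log(1 - true_strength) + bio + tech)` with
#' lognormal biological (per plant) and technical (per disk) noise, so zero
#' noise reproduces the expectation exactly. `true_strength` at (or beyond)
#' 1 would send `log(1 - s)` to `-Inf`; such reads are clamped to
#' `floor_fraction` of baseline and flagged in the `clamped` column.
#'
#' @param motifs A `motif_library` (must include `Gal4` and `SRDX` controls).
#' @param model A `ground_truth_model`.
#' @param n_bio Biological replicates (plants) per construct.
#' @param n_tech Technical replicates (leaf disks) per plant.
#' @param floor_fraction Relative fluorescence floor for clamping.
#' @param seed Integer seed.
#' @return Data frame with columns `construct_id`, `plant_id`, `disk_id`,
#'   `fluorescence`, `clamped`.
#' @export
simulate_assay <- function(motifs, model, n_bio = 3L, n_tech = 8L,
                           floor_fraction = 1e-4, seed = 1L) {
  stopifnot(n_bio >= 1, n_tech >= 1)
  if (!all(c("Gal4", "SRDX") %in% motifs$id)) {
    stop("motif library must contain the Gal4 and SRDX controls", call. = FALSE)
  }
  n <- nrow(motifs)
  with_seed(seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      s <- motifs$true_strength[i]
      rel <- 1 - s
      clamped <- rel <= floor_fraction
      log_rel <- log(max(rel, floor_fraction))
      bio <- stats::rnorm(n_bio, 0, model$bio_noise_sd)
      tech <- stats::rnorm(n_bio * n_tech, 0, model$tech_noise_sd)
      fl <- exp(model$baseline_log_fluor + log_rel +
                  rep(bio, each = n_tech) + tech)
      rows[[i]] <- data.frame(
        construct_id = motifs$id[i],
        plant_id = rep(sprintf("plant%d", seq_len(n_bio)), each = n_tech),
        disk_id = rep(sprintf("disk%d", seq_len(n_tech)), times = n_bio),
        fluorescence = fl,
        clamped = clamped,
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate a qPCR Cq table
#'
#' Produces long-format quantification-cycle values for a target and a
#' reference gene across independent lines of each genotype. The target's
#' delta-Cq (target minus reference) for a genotype with true fold change
#' `f` sits `log2(f)` cycles below the wild-type mean, plus Gaussian cycle
#' noise, so the delta-delta-Cq analysis recovers `f` in expectation.
#'
#' @param genotypes Character vector of genotype names.
#' @param n_lines Independent lines (samples) per genotype.
#' @param true_fold_changes Named numeric vector of fold changes (> 0),
#'   one per genotype; the wild type must have fold change 1.
#' @param wildtype Name of the wild-type genotype (must be in `genotypes`).
#' @param cq_noise_sd Per-measurement Cq noise SD (cycles).
#' @param seed Integer seed.
#' @return Data frame with columns `sample_id`, `genotype`, `gene`, `cq`.
#' @export
simulate_qpcr <- function(genotypes, n_lines = 4L, true_fold_changes,
                          wildtype = genotypes[[1]], cq_noise_sd = 0.1,
                          seed = 1L) {
  genotypes <- as.character(genotypes)
  if (!wildtype %in% genotypes) {
    stop("wild-type genotype '", wildtype, "' missing from genotypes",
         call. = FALSE)
  }
  if (!all(genotypes %in% names(true_fold_changes))) {
    stop("true_fold_changes must name every genotype", call. = FALSE)
  }
  if (any(true_fold_changes <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  base_ref <- 20
  base_delta <- 5  # wild-type target sits 5 cycles above reference
  with_seed(seed, {
    rows <- list()
    for (g in genotypes) {
      for (j in seq_len(n_lines)) {
        sid <- sprintf("%s_line%d", g, j)
        cq_ref <- base_ref + stats::rnorm(1, 0, cq_noise_sd)
        dcq <- base_delta - log2(true_fold_changes[[g]]) +
          stats::rnorm(1, 0, cq_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, genotype = g,
          gene = c("target", "reference"),
          cq = c(cq_ref + dcq, cq_ref),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
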