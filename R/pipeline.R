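# One-seed end-to-end pipeline: simulate a natural library and its assay,
# quantify, classify n-grams, generate SynEARs, assay and evaluate them.

#' Run the full repression-toolkit pipeline on synthetic data
#'
#' Reproduces every stage of the analysis from a single master seed:
#' (1) plant a ground-truth model and simulate a natural motif library with
#' its reporter assay; (2) quantify per-construct repression against the
#' Gal4 baseline; (3) partition constructs into strength quartiles and
#' classify amino-acid n-grams; (4) generate a SynEAR library in four
#' predicted strength classes; (5) simulate its assay under the same ground
#' truth, quantify, and evaluate the predictions with the confusion-matrix
#' machinery and both null models. All per-stage seeds are fanned out from
#' `seed`, so the whole run is deterministic.
#'
#' @param seed Master integer seed.
#' @param n_natural Natural-library size (default 84, controls excluded).
#' @param n_strong_grams,n_weak_grams Planted gram-set sizes.
#' @param effect_size Planted latent effect per gram occurrence.
#' @param tech_noise_sd,bio_noise_sd Log-scale assay noise SDs.
#' @param synear_counts Named counts per predicted class (default 20 each,
#'   80 total).
#' @param length_dist Natural motif length support.
#' @param n_perm,n_boot Null-model iterations.
#' @return List with every intermediate artifact: `model`, `natural`
#'   (library), `natural_plate`, `natural_summary`, `partition`,
#'   `ngram_table`, `class_sets`, `synears`, `synear_plate`,
#'   `synear_summary`, `eval`, and the `seeds` used per stage.
#' @export
run_pipeline <- function(seed = 1L,
                         n_natural = 84L,
                         n_strong_grams = 5L, n_weak_grams = 5L,
                         effect_size = 0.3,
                         tech_noise_sd = 0.05, bio_noise_sd = 0.05,
                         synear_counts = c(weak = 20, moderate = 20,
                                           strong = 20, strongest = 20),
                         length_dist = 5:16,
                         n_perm = 1000L, n_boot = 1000L) {
  seeds <- fanout_seeds(seed, 6L)

  model <- generate_ground_truth(
    n_strong = n_strong_grams, n_weak = n_weak_grams,
    effect_size = effect_size,
    tech_noise_sd = tech_noise_sd, bio_noise_sd = bio_noise_sd,
    seed = seeds[1]
  )
  natural <- generate_motif_library(n_natural, model,
                                    length_dist = length_dist,
                                    seed = seeds[2])
  natural_plate <- simulate_assay(natural, model, seed = seeds[3])
  natural_summary <- quantify_assay(natural_plate)

  partition <- quartile_partition(natural_summary)
  ngram_table <- classify_ngrams(build_ngram_table(natural, partition))
  class_sets <- ngram_class_sets(ngram_table)

  natural_lengths <- nchar(natural$sequence[natural$library != "control"])
  spec <- synear_spec(counts = synear_counts,
                      natural_lengths = natural_lengths,
                      seed = seeds[4])
  synears <- generate_synear_library(spec, class_sets)
  synears$true_strength <- vapply(synears$sequence, motif_true_strength,
                                  numeric(1), model = model, USE.NAMES = FALSE)

  controls <- natural[natural$library == "control", , drop = FALSE]
  assay_set <- rbind(synears[, c("id", "sequence", "library", "true_strength")],
                     controls)
  class(assay_set) <- c("motif_library", "data.frame")
  synear_plate <- simulate_assay(assay_set, model, seed = seeds[5])
  synear_summary <- quantify_assay(synear_plate)

  idx <- match(synears$id, synear_summary$construct_id)
  observed <- 1 - synear_summary$relative_gfp[idx]
  eval <- evaluate_predictions(synears$predicted_class, observed,
                               n_perm = n_perm, n_boot = n_boot,
                               seed = seeds[6])

  list(model = model, natural = natural, natural_plate = natural_plate,
       natural_summary = natural_summary, partition = partition,
       ngram_table = ngram_table, class_sets = class_sets,
       synears = synears, synear_plate = synear_plate,
       synear_summary = synear_summary, eval = eval, seeds = seeds)
}

#' Recovery of planted strong grams by the n-gram classifier
#'
#' Among the model's planted strong grams that occur at least `min_count`
#' times in the tallied library, the fraction the classifier labels
#' *strong* (a recall; the quantity checked by the parameter-recovery
#' property).
#'
#' @param ngram_table A classified `ngram_table`.
#' @param model The `ground_truth_model` whose grams were planted.
#' @param min_count Minimum pooled occurrence count for eligibility.
#' @return List with `recovered`, `eligible`, `rate` (`NA` when no gram is
#'   eligible).
#' @export
strong_gram_recovery <- function(ngram_table, model, min_count = 3L) {
  planted <- model$strong_grams
  tab <- ngram_table[ngram_table$gram %in% planted, , drop = FALSE]
  tab <- tab[tab$total_count >= min_count, , drop = FALSE]
  eligible <- nrow(tab)
  recovered <- sum(tab$class == "strong")
  list(recovered = recovered, eligible = eligible,
       rate = if (eligible > 0) recovered / eligible else NA_real_)
}
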