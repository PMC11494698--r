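# Stage 6: characterize the SynEAR library in the simulated assay and
# evaluate the advance strength predictions: optimized observed-class
# thresholds, confusion matrix, permutation and random-guessing nulls.
# Also runs the delta-delta-Cq worked example and a sequence-diversity
# check on the strongest SynEARs.

source("analysis/00_config.R")

model <- ground_truth()
synears <- read_motif_fasta(file.path(RESULTS_DIR, "synear_library.fasta"))
synears$true_strength <- vapply(synears$sequence, motif_true_strength,
                                numeric(1), model = model, USE.NAMES = FALSE)

natural <- read_motif_fasta(file.path(RESULTS_DIR, "natural_library.fasta"))
controls <- natural[natural$library == "control", ]
assay_set <- rbind(synears[, c("id", "sequence", "library", "true_strength")],
                   controls)

plate <- simulate_assay(assay_set, model, seed = STAGE_SEEDS[5])
summ <- quantify_assay(plate)
utils::write.csv(summ, file.path(RESULTS_DIR, "synear_summary.csv"),
                 row.names = FALSE)
syn_core <- summ[summ$construct_id %in% synears$id, ]
cat(sprintf("%d of %d SynEARs pass the repressor threshold\n",
            sum(syn_core$is_repressor), nrow(syn_core)))

observed <- 1 - summ$relative_gfp[match(synears$id, summ$construct_id)]
ev <- evaluate_predictions(synears$predicted_class, observed,
                           n_perm = N_PERM, n_boot = N_BOOT,
                           seed = STAGE_SEEDS[6])
print(ev)
utils::write.csv(as.data.frame(ev$confusion),
                 file.path(RESULTS_DIR, "confusion_matrix.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(accuracy = ev$accuracy, thresholds = ev$thresholds,
       permutation = ev$permutation[c("null_mean", "null_sd",
                                      "percentile_outperformed",
                                      "p_two_tailed_empirical",
                                      "p_two_tailed_normal")],
       bootstrap = ev$bootstrap[c("null_mean", "null_sd",
                                  "percentile_outperformed",
                                  "p_two_tailed_empirical",
                                  "p_two_tailed_normal")],
       n = length(observed), seed = MASTER_SEED),
  file.path(RESULTS_DIR, "eval.json"), auto_unbox = TRUE, digits = NA)

# Sequence diversity among the strongest SynEARs (plus SRDX)
strongest <- synears[synears$predicted_class == "strongest", ]
div <- stats::setNames(c(strongest$sequence, controls$sequence[
  controls$id == "SRDX"]), c(strongest$id, "SRDX"))
m <- identity_matrix(div)
utils::write.csv(m, file.path(RESULTS_DIR, "identity_matrix.csv"))
top <- max_pairwise_identity(div)
cat(sprintf("Max pairwise identity among strongest SynEARs + SRDX: %.1f%% (%s, %s)\n",
            top$value, top$pair[1], top$pair[2]))

# Delta-delta-Cq worked example from the stage-1 fixture
cq <- utils::read.csv(file.path(RESULTS_DIR, "qpcr_cq.csv"))
expr <- delta_delta_cq(cq, wildtype_ids = "WT")
utils::write.csv(expr, file.path(RESULTS_DIR, "qpcr_expression.csv"),
                 row.names = FALSE)
cat(sprintf("qPCR: fusion expression %.2f relative to wild type (true 0.25)\n",
            mean(expr$expression[expr$genotype == "fusion"])))
cat("Wrote synear_summary.csv, confusion_matrix.csv, eval.json,",
    "identity_matrix.csv, qpcr_expression.csv\n")
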