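# Stage 1: simulate the natural EAR-style motif library, its reporter
# assay, and a qPCR fixture. Stands in for the wet-lab data so the rest of
# the analysis runs at desk scale.

source("analysis/00_config.R")

model <- ground_truth()
cat("Planted ground truth:",
    length(model$strong_grams), "strong grams (",
    paste(model$strong_grams, collapse = ", "), "),",
    length(model$weak_grams), "weak grams (",
    paste(model$weak_grams, collapse = ", "), ")\n")

natural <- natural_library(model)
plate <- simulate_assay(natural, model, seed = STAGE_SEEDS[3])
cat(sprintf("Simulated %d constructs (+%d controls): %d fluorescence reads\n",
            sum(natural$library != "control"),
            sum(natural$library == "control"), nrow(plate)))

write_motif_fasta(natural, file.path(RESULTS_DIR, "natural_library.fasta"))
utils::write.csv(plate, file.path(RESULTS_DIR, "natural_plate.csv"),
                 row.names = FALSE)

# qPCR fixture: a transcription-factor target repressed 4-fold by a
# motif fusion, against the wild type.
cq <- simulate_qpcr(c("WT", "fusion"), n_lines = 4,
                    true_fold_changes = c(WT = 1, fusion = 0.25),
                    seed = STAGE_SEEDS[4])
utils::write.csv(cq, file.path(RESULTS_DIR, "qpcr_cq.csv"), row.names = FALSE)
cat("Wrote natural_library.fasta, natural_plate.csv, qpcr_cq.csv\n")
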