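# Stage 5: generate the SynEAR library - synthetic repression motifs
# assembled from classified n-grams in four predicted strength classes.

source("analysis/00_config.R")

natural <- read_motif_fasta(file.path(RESULTS_DIR, "natural_library.fasta"))
sets <- list(
  strong = readLines(file.path(RESULTS_DIR, "grams_strong.txt")),
  moderate = readLines(file.path(RESULTS_DIR, "grams_moderate.txt")),
  weak = readLines(file.path(RESULTS_DIR, "grams_weak.txt"))
)

natural_lengths <- nchar(natural$sequence[natural$library != "control"])
spec <- synear_spec(counts = SYNEAR_COUNTS,
                    natural_lengths = natural_lengths,
                    seed = STAGE_SEEDS[4])
synears <- generate_synear_library(spec, sets)
cat(sprintf("Generated %d SynEARs (%s)\n", nrow(synears),
            paste(sprintf("%s: %d", levels(synears$predicted_class),
                          table(synears$predicted_class)),
                  collapse = ", ")))
cat(sprintf("Lengths %d-%d (natural support %d-%d; strongest class longer)\n",
            min(nchar(synears$sequence)), max(nchar(synears$sequence)),
            min(natural_lengths), max(natural_lengths)))

write_motif_fasta(synears, file.path(RESULTS_DIR, "synear_library.fasta"))
cat("Wrote synear_library.fasta\n")
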