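# Stage 4: partition constructs into strength quartiles, tally 2/3/4-grams
# per quartile, and classify grams as strong, moderate or weak.

source("analysis/00_config.R")

natural <- read_motif_fasta(file.path(RESULTS_DIR, "natural_library.fasta"))
summ <- utils::read.csv(file.path(RESULTS_DIR, "natural_summary.csv"))

partition <- quartile_partition(summ)
cat("Quartile sizes:", lengths(partition), "\n")

tab <- classify_ngrams(build_ngram_table(natural, partition))
utils::write.csv(tab, file.path(RESULTS_DIR, "ngram_table.csv"),
                 row.names = FALSE)

sets <- ngram_class_sets(tab)
cat(sprintf("Classified %d strong, %d moderate, %d weak grams (of %d)\n",
            length(sets$strong), length(sets$moderate), length(sets$weak),
            nrow(tab)))
for (cl in names(sets)) {
  writeLines(sets[[cl]],
             file.path(RESULTS_DIR, sprintf("grams_%s.txt", cl)))
}

# How well were the planted strong grams recovered?
model <- ground_truth()
rec <- strong_gram_recovery(tab, model)
cat(sprintf("Planted strong grams recovered: %d of %d eligible (>=3 occurrences)\n",
            rec$recovered, rec$eligible))
cat("Wrote ngram_table.csv, grams_{strong,moderate,weak}.txt\n")
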