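# Stage 2: quantify the simulated reporter assay into per-construct
# summaries, classify repressors at the 50% GFP-reduction threshold, and
# normalize all constructs onto the shared Gal4 = 0 / SRDX = 1 scale.

source("analysis/00_config.R")

plate <- read_plate_csv(file.path(RESULTS_DIR, "natural_plate.csv"))
summ <- quantify_assay(plate)
utils::write.csv(summ, file.path(RESULTS_DIR, "natural_summary.csv"),
                 row.names = FALSE)

core <- summ[!summ$construct_id %in% c("Gal4", "SRDX"), ]
cat(sprintf("%d of %d constructs pass the 50%% GFP-reduction threshold\n",
            sum(core$is_repressor), nrow(core)))
cat(sprintf("Dynamic range: %.0f%% increase to %.0f%% reduction of GFP\n",
            100 * max(core$relative_gfp - 1),
            100 * max(1 - core$relative_gfp)))
cat(sprintf("%d constructs behave as activators (relative GFP > 1)\n",
            sum(core$is_activator)))

gal4_mean <- summ$mean_fluor[summ$construct_id == "Gal4"]
srdx_mean <- summ$mean_fluor[summ$construct_id == "SRDX"]
scores <- data.frame(
  construct_id = summ$construct_id,
  normalized_score = normalize_cross_library(summ$mean_fluor, gal4_mean,
                                             srdx_mean)
)
utils::write.csv(scores, file.path(RESULTS_DIR, "normalized_scores.csv"),
                 row.names = FALSE)
cat(sprintf("%d constructs score above SRDX on the normalized scale\n",
            sum(scores$normalized_score > 1)))
cat("Wrote natural_summary.csv, normalized_scores.csv\n")
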