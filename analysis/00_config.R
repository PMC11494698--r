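# Shared configuration for the analysis scripts. Every script sources this
# file, takes the master seed from --seed (default 1), and derives its
# stage seed from the same fan-out, so the whole analysis is reproducible
# from one integer. Run the scripts in order from the repository root:
#
#   Rscript analysis/01_simulate_library.R [--seed N]
#   Rscript analysis/02_quantify.R         [--seed N]
#   ...

suppressPackageStartupMessages(library(represskit))

.args <- commandArgs(trailingOnly = TRUE)
.i <- which(.args == "--seed")
MASTER_SEED <- if (length(.i) == 1 && .i < length(.args)) {
  as.integer(.args[.i + 1])
} else 1L

STAGE_SEEDS <- fanout_seeds(MASTER_SEED, 6L)

# Study-scale parameters: 84 natural motifs (plus Gal4/SRDX controls),
# 80 SynEARs in four predicted classes, 3 plants x 8 leaf disks per
# construct, 1000 permutations and 1000 bootstrap runs.
N_NATURAL <- 84L
SYNEAR_COUNTS <- c(weak = 20, moderate = 20, strong = 20, strongest = 20)
N_PERM <- 1000L
N_BOOT <- 1000L
EFFECT_SIZE <- 0.3
TECH_NOISE_SD <- 0.05
BIO_NOISE_SD <- 0.05
LENGTH_DIST <- 5:16

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# The ground-truth model is reconstructed identically in every stage that
# needs it (seeded generation is deterministic).
ground_truth <- function() {
  generate_ground_truth(n_strong = 5, n_weak = 5,
                        effect_size = EFFECT_SIZE,
                        tech_noise_sd = TECH_NOISE_SD,
                        bio_noise_sd = BIO_NOISE_SD,
                        seed = STAGE_SEEDS[1])
}

natural_library <- function(model) {
  generate_motif_library(N_NATURAL, model, length_dist = LENGTH_DIST,
                         seed = STAGE_SEEDS[2])
}
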