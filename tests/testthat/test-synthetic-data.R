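test_that("ground-truth models are deterministic with disjoint planted sets", {
  expect_identical(generate_ground_truth(5, 5, seed = 1),
                   generate_ground_truth(5, 5, seed = 1))
  for (s in 1:100) {
    m <- generate_ground_truth(3, 3, seed = s)
    expect_length(intersect(m$strong_grams, m$weak_grams), 0)
    grams <- c(m$strong_grams, m$weak_grams, m$neutral_grams)
    expect_length(unique(grams), length(grams))
    expect_true(all(nchar(grams) %in% 2:4))
    expect_true(all(strsplit(paste(grams, collapse = ""), "")[[1]] %in%
                      AA_STANDARD))
  }
  m0 <- generate_ground_truth(0, 0, n_neutral = 0, seed = 1)
  expect_length(m0$strong_grams, 0)
  expect_length(m0$weak_grams, 0)
  expect_error(generate_ground_truth(2, 2, effect_size = -0.1), "effect_size")
  expect_error(generate_ground_truth(2, 2, tech_noise_sd = -1), "noise")
})

test_that("true strength is monotone in planted-gram content", {
  model <- make_model(strong = "LDL", weak = "KKR", effect_size = 0.3)
  all_strong <- motif_true_strength(strrep("LDL", 3), model)
  all_weak <- motif_true_strength(strrep("KKR", 3), model)
  neutral_only <- motif_true_strength("AAAAAAAAA", model)
  expect_gt(all_strong, neutral_only)
  expect_gt(neutral_only, all_weak)
  # more strong occurrences, higher strength (zero noise)
  expect_gt(motif_true_strength(strrep("LDL", 4), model), all_strong)
  # overlapping occurrences count once per start position: LDLDL holds
  # LDL at positions 1 and 3
  two_overlap <- motif_true_strength("LDLDL", model)
  one <- motif_true_strength("LDLAA", model)
  expect_gt(two_overlap, one)
})

test_that("a model with no planted grams yields a flat library at baseline", {
  m0 <- generate_ground_truth(0, 0, n_neutral = 0, seed = 4)
  lib <- generate_motif_library(20, m0, seed = 2)
  core <- lib[lib$library != "control", ]
  expect_equal(unique(core$true_strength), 0.2)  # logistic link at zero
})

test_that("motif libraries honor size, length support, ids and controls", {
  model <- generate_ground_truth(3, 3, seed = 7)
  lib <- generate_motif_library(84, model, length_dist = 5:16, seed = 11)
  expect_identical(lib,
                   generate_motif_library(84, model, length_dist = 5:16,
                                          seed = 11))
  core <- lib[lib$library != "control", ]
  expect_equal(nrow(core), 84)
  expect_true(all(nchar(core$sequence) %in% 5:16))
  expect_false(any(duplicated(lib$id)))
  expect_true(all(c("Gal4", "SRDX") %in% lib$id))
  expect_true(all(lib$true_strength >= -0.6 & lib$true_strength <= 1))
  expect_error(generate_motif_library(5, model, length_dist = integer(0)),
               "length_dist")
})

test_that("assay simulation matches the noise-free expectation exactly", {
  model <- make_model(baseline_log_fluor = log(1000))
  motifs <- make_motifs(c("Gal4", "SRDX", "half"),
                        c("MKLLSSIEQA", "LDLDLELRLGFA", "AAAAA"),
                        c(0, 0.9, 0.5),
                        library = c("control", "control", "naturalEAR"))
  plate <- simulate_assay(motifs, model, n_bio = 3, n_tech = 8, seed = 1)
  expect_equal(nrow(plate), 3 * 3 * 8)
  expect_equal(unique(plate$fluorescence[plate$construct_id == "Gal4"]), 1000)
  expect_equal(unique(plate$fluorescence[plate$construct_id == "half"]), 500)
  expect_false(any(plate$clamped))
  # row-count arithmetic at 10 motifs
  ten <- make_motifs(c(sprintf("m%d", 1:8), "Gal4", "SRDX"),
                     rep("AAAAA", 10), rep(0.1, 10))
  expect_equal(nrow(simulate_assay(ten, model, seed = 2)), 240)
  expect_error(simulate_assay(motifs[c(1, 3), ], model), "Gal4 and SRDX")
})

test_that("complete repression is clamped to the floor and flagged", {
  model <- make_model(baseline_log_fluor = log(1000))
  motifs <- make_motifs(c("Gal4", "SRDX", "total"),
                        c("MKLLSSIEQA", "LDLDLELRLGFA", "AAAAA"),
                        c(0, 0.9, 1))
  plate <- simulate_assay(motifs, model, floor_fraction = 1e-4, seed = 1)
  tot <- plate[plate$construct_id == "total", ]
  expect_true(all(tot$clamped))
  expect_equal(unique(tot$fluorescence), 1000 * 1e-4)
  expect_false(any(plate$clamped[plate$construct_id != "total"]))
})

test_that("qPCR simulation plants recoverable fold changes", {
  fc <- c(WT = 1, up = 2, down = 0.25)
  cq <- simulate_qpcr(names(fc), n_lines = 3, true_fold_changes = fc,
                      cq_noise_sd = 0, seed = 5)
  expect_identical(cq, simulate_qpcr(names(fc), n_lines = 3,
                                     true_fold_changes = fc,
                                     cq_noise_sd = 0, seed = 5))
  res <- delta_delta_cq(cq, wildtype_ids = "WT")
  expect_equal(res$expression[res$genotype == "WT"], rep(1, 3))
  expect_equal(res$expression[res$genotype == "up"], rep(2, 3))
  expect_equal(res$expression[res$genotype == "down"], rep(0.25, 3))
  expect_error(simulate_qpcr(c("a"), true_fold_changes = c(a = 1),
                             wildtype = "WT"), "wild-type")
})
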