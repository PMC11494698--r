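test_that("n-gram decomposition enumerates all overlapping substrings", {
  expect_equal(decompose_ngrams("LDLNL", 2), c("LD", "DL", "LN", "NL"))
  expect_equal(decompose_ngrams("LDLNL", 4), c("LDLN", "DLNL"))
  expect_equal(decompose_ngrams("LD", 3), character(0))
  set.seed(2)
  for (i in 1:25) {
    s <- paste(sample(AA_STANDARD, sample(4:15, 1), replace = TRUE),
               collapse = "")
    n <- sample(2:4, 1)
    got <- decompose_ngrams(s, n)
    expect_length(got, max(0, nchar(s) - n + 1))
    # direct substring enumeration
    manual <- vapply(seq_len(max(0, nchar(s) - n + 1)),
                     function(k) substr(s, k, k + n - 1), character(1))
    expect_equal(got, manual)
  }
})

test_that("quartile partition ranks by strength with remainder to the top", {
  summaries <- data.frame(
    construct_id = sprintf("c%02d", 1:8),
    relative_gfp = seq(0.1, 0.8, by = 0.1)  # c01 strongest
  )
  p <- quartile_partition(summaries, controls = character(0))
  expect_equal(lengths(p), c(Q1 = 2L, Q2 = 2L, Q3 = 2L, Q4 = 2L))
  expect_equal(p$Q1, c("c01", "c02"))
  expect_equal(p$Q4, c("c07", "c08"))

  summaries10 <- data.frame(
    construct_id = sprintf("c%02d", 1:10),
    relative_gfp = seq(0.05, 0.95, by = 0.1)
  )
  p10 <- quartile_partition(summaries10, controls = character(0))
  expect_equal(unname(lengths(p10)), c(3L, 3L, 2L, 2L))

  # ties resolved by construct id, controls excluded
  tied <- data.frame(construct_id = c("b", "a", "d", "c", "Gal4", "SRDX"),
                     relative_gfp = c(0.5, 0.5, 0.5, 0.5, 1, 0.1))
  pt <- quartile_partition(tied)
  expect_equal(unlist(pt, use.names = FALSE), c("a", "b", "c", "d"))
  expect_error(quartile_partition(tied[1:3, ]), "at least 4")
})

test_that("n-gram tallies give the expected representation ratios", {
  # equal token totals per quartile; "LD" only in Q1
  motifs <- make_motifs(sprintf("m%d", 1:8),
                        c("LDAAA", "AAAAA",   # Q1
                          "AGAAA", "AAAAA",   # Q2
                          "AGAAA", "AAAAA",   # Q3
                          "AGAAA", "AAAAA"),  # Q4
                        rep(NA_real_, 8))
  part <- structure(list(Q1 = c("m1", "m2"), Q2 = c("m3", "m4"),
                         Q3 = c("m5", "m6"), Q4 = c("m7", "m8")),
                    class = "quartile_partition")
  tab <- build_ngram_table(motifs, part, n_values = 2)
  ld <- tab[tab$gram == "LD", ]
  expect_equal(ld$ratio_q1, 4)
  expect_equal(c(ld$ratio_q2, ld$ratio_q3, ld$ratio_q4), c(0, 0, 0))
  expect_equal(ld$total_count, sum(ld$count_q1, ld$count_q2,
                                   ld$count_q3, ld$count_q4))

  # a gram uniformly frequent across quartiles has all ratios 1
  uni <- make_motifs(sprintf("u%d", 1:8), rep("LDLDA", 8), rep(NA_real_, 8))
  part_u <- structure(list(Q1 = c("u1", "u2"), Q2 = c("u3", "u4"),
                           Q3 = c("u5", "u6"), Q4 = c("u7", "u8")),
                      class = "quartile_partition")
  tab_u <- build_ngram_table(uni, part_u, n_values = 2)
  expect_true(all(abs(as.matrix(tab_u[, paste0("ratio_q", 1:4)]) - 1) < 1e-12))

  # a quartile with no grams of a length leaves those ratios undefined
  short <- make_motifs(sprintf("s%d", 1:8),
                       c(rep("LDLNAP", 6), "LDL", "ALD"),
                       rep(NA_real_, 8))
  part_s <- structure(list(Q1 = c("s1", "s2"), Q2 = c("s3", "s4"),
                           Q3 = c("s5", "s6"), Q4 = c("s7", "s8")),
                      class = "quartile_partition")
  tab_s <- build_ngram_table(short, part_s, n_values = 4)
  expect_true(all(is.na(tab_s$ratio_q4)))
  expect_warning(cls <- classify_ngrams(tab_s), "unclassified")
  expect_true(all(cls$class == "unclassified"))
})

test_that("classification rules assign strong, moderate and weak correctly", {
  tab <- data.frame(
    gram = c("g1", "g2", "g3", "g4", "g5"),
    ratio_q1 = c(2.5, 1.1, 0.9, 2.0, 3.0),
    ratio_q2 = c(1.0, 1.0, 1.0, 1.0, 1.0),
    ratio_q3 = c(0.9, 0.95, 1.1, 1.0, 1.0),
    ratio_q4 = c(0.8, 1.2, 2.2, 1.0, 0.5)
  )
  cls <- classify_ngrams(tab)$class
  expect_equal(as.character(cls),
               c("strong",        # >=2x in Q1, under-represented in Q4
                 "moderate",      # within 25% everywhere
                 "weak",          # >=2x in Q4, under-represented in Q1
                 "unclassified",  # 2x in Q1 but not under-represented in Q4
                 "strong"))
  sets <- ngram_class_sets(classify_ngrams(tab))
  expect_equal(sets$strong, c("g1", "g5"))
  expect_equal(sets$weak, "g3")
})

test_that("n-gram classification is invariant to construct order", {
  model <- generate_ground_truth(4, 4, seed = 21)
  lib <- generate_motif_library(40, model, seed = 22)
  plate <- simulate_assay(lib, model, seed = 23)
  summ <- quantify_assay(plate)
  part <- quartile_partition(summ)
  tab1 <- classify_ngrams(build_ngram_table(lib, part))
  set.seed(1)
  shuffled <- lib[sample(nrow(lib)), ]
  summ_s <- summ[sample(nrow(summ)), ]
  part_s <- quartile_partition(summ_s)
  tab2 <- classify_ngrams(build_ngram_table(shuffled, part_s))
  expect_identical(tab1, tab2)
})
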