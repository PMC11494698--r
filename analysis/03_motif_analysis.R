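# Stage 3: canonical EAR-pattern scan with exact enrichment test,
# length-strength relationship, and a Dunn test of the strongest
# constructs against SRDX.

source("analysis/00_config.R")

natural <- read_motif_fasta(file.path(RESULTS_DIR, "natural_library.fasta"))
summ <- utils::read.csv(file.path(RESULTS_DIR, "natural_summary.csv"))
core_ids <- natural$id[natural$library != "control"]
core <- summ[summ$construct_id %in% core_ids, ]

scan <- scan_canonical(natural$sequence, natural$id)
utils::write.csv(scan, file.path(RESULTS_DIR, "canonical_scan.csv"),
                 row.names = FALSE)
cat(sprintf("Canonical patterns: %d with LxLxL, %d with DLNxxP, %d with both\n",
            sum(scan$has_LxLxL), sum(scan$has_DLNxxP), sum(scan$has_both)))

# Enrichment of dual-canonical-motif constructs in the stronger half
# (top ceiling(n/2) by mean repression, ties by id, controls excluded)
ord <- order(core$relative_gfp, core$construct_id)
stronger <- core$construct_id[ord][seq_len(ceiling(nrow(core) / 2))]
both <- scan$construct_id[scan$has_both & scan$construct_id %in% core_ids]
tab <- matrix(c(
  sum(both %in% stronger), sum(!both %in% stronger),
  sum(!core$construct_id %in% both & core$construct_id %in% stronger),
  sum(!core$construct_id %in% both & !core$construct_id %in% stronger)
), 2, byrow = TRUE)
fisher <- if (sum(tab[1, ]) == 0) {
  cat("No dual-motif constructs in this simulated library;",
      "enrichment test degenerate\n")
  list(p_one_sided = 1, p_two_sided = 1)
} else {
  fisher_exact_2x2(tab)
}
cat(sprintf("Dual-motif enrichment in the stronger half: P = %.4f (two-sided)\n",
            fisher$p_two_sided))

# Length vs strength, with and without the SRDX control
seqs <- stats::setNames(natural$sequence, natural$id)
ls_all <- length_strength(summ, seqs, exclude = "Gal4")
ls_nosrdx <- length_strength(summ, seqs, exclude = c("Gal4", "SRDX"))
cat(sprintf("Length-strength Spearman rho: %.3f (all), %.3f (without SRDX)\n",
            ls_all$spearman_rho, ls_nosrdx$spearman_rho))
utils::write.csv(ls_nosrdx$by_length,
                 file.path(RESULTS_DIR, "length_strength.csv"),
                 row.names = FALSE)

# Are the strongest constructs distinguishable from SRDX? Dunn test with
# Bonferroni correction on per-plant biological values.
bio <- aggregate_replicates(read_plate_csv(file.path(RESULTS_DIR,
                                                     "natural_plate.csv")))
top5 <- core$construct_id[order(core$relative_gfp)][1:5]
groups <- split(bio$bio_value, bio$construct_id)[c(top5, "SRDX")]
dunn <- dunn_test(groups)
vs_srdx <- dunn[dunn$group1 == "SRDX" | dunn$group2 == "SRDX", ]
cat(sprintf("Dunn vs SRDX: %d of %d comparisons significant after Bonferroni\n",
            sum(vs_srdx$p_adj < 0.05), nrow(vs_srdx)))

jsonlite::write_json(
  list(fisher_dual_motif = fisher,
       length_strength_rho = ls_all$spearman_rho,
       length_strength_rho_no_srdx = ls_nosrdx$spearman_rho,
       dunn_vs_srdx = vs_srdx),
  file.path(RESULTS_DIR, "motif_tests.json"),
  auto_unbox = TRUE, digits = NA, dataframe = "rows")
cat("Wrote canonical_scan.csv, length_strength.csv, motif_tests.json\n")
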