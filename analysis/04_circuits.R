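#!/usr/bin/env Rscript
# Hypothesis-driven circuit comparison: fear-conditioning and
# temporal-lobe-epilepsy pathways, ipsilateral and contralateral.
#
# Output: results/circuit_tests.tsv

source(file.path("analysis", "00_config.R"))

cohort <- load_cohort(file.path(results_dir, "cohort", "manifest.tsv"),
                      study_table)

rows <- list()
for (circ in c("fear", "tle")) {
  for (side in c("ipsilateral", "contralateral")) {
    res <- circuit_compare(cohort, circ, side = side, table = study_table)
    rows[[length(rows) + 1L]] <- cbind(circuit = circ, res)
    cat(sprintf("%s circuit, %s:\n", circ, side))
    for (i in seq_len(nrow(res))) {
      cat(sprintf("  %-10s WT %10.1f  KO %10.1f  p_adj = %.4f  %s\n",
                  res$pair[i], res$mean_wt[i], res$mean_ko[i],
                  res$p_adj[i], res$label[i]))
    }
  }
}
out <- do.call(rbind, rows)
write.table(out, file.path(results_dir, "circuit_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")
cat(sprintf("wrote %d circuit pair tests\n", nrow(out)))
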