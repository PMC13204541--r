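#!/usr/bin/env Rscript
# Region-wise diffusivity comparison: FA, MD, AD and RD per region with
# Benjamini-Hochberg-corrected signed p-values.
#
# Output: results/diffusivity_tests.tsv

source(file.path("analysis", "00_config.R"))

records <- read.delim(file.path(results_dir, "cohort", "diffusivity.tsv"))

rows <- lapply(c("FA", "MD", "AD", "RD"), function(scalar) {
  cbind(scalar = scalar, compare_regions(records, scalar))
})
out <- do.call(rbind, rows)
out$abbreviation <- study_table$abbreviation[match(out$region_id,
                                                   study_table$id)]
write.table(out, file.path(results_dir, "diffusivity_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "NA")

flagged <- out[out$flag, ]
cat(sprintf("diffusivity: %d region/scalar combinations flagged at |p_adj| < 0.05\n",
            nrow(flagged)))
for (i in seq_len(nrow(flagged))) {
  cat(sprintf("  %-4s %-6s WT %.3e  KO %.3e  signed p_adj = %+.4f\n",
              flagged$scalar[i], flagged$abbreviation[i],
              flagged$mean_wt[i], flagged$mean_ko[i], flagged$signed_p[i]))
}
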