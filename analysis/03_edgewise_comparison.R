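#!/usr/bin/env Rscript
# Edgewise 630-pair comparison: zero filter, log(x+1), pooled t-tests and
# one Benjamini-Hochberg family per hemisphere view, plus the signed
# adjusted-p matrices and the region-level streamline totals comparison.
#
# Output: results/edgewise_{ipsilateral,contralateral}.tsv,
#         results/signed_p_{ipsilateral,contralateral}.tsv,
#         results/region_totals.tsv

source(file.path("analysis", "00_config.R"))

cohort <- load_cohort(file.path(results_dir, "cohort", "manifest.tsv"),
                      study_table)

for (mode in c("ipsilateral", "contralateral")) {
  ew <- edgewise_compare(cohort, mode = mode, table = study_table)
  write.table(ew$edges, file.path(results_dir,
                                  paste0("edgewise_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  sp <- data.frame(region = rownames(ew$signed_p), ew$signed_p,
                   check.names = FALSE)
  write.table(sp, file.path(results_dir, paste0("signed_p_", mode, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  disc <- ew$edges[ew$edges$discovery, ]
  cat(sprintf("%s: %d of %d pairs included, %d discoveries at FDR 5%%\n",
              mode, sum(ew$edges$included), nrow(ew$edges),
              nrow(disc)))
  if (nrow(disc) > 0) {
    up <- disc$pair[disc$sign == 1]
    dn <- disc$pair[disc$sign == -1]
    if (length(up)) cat("  KO > WT:", paste(head(up, 12), collapse = ", "),
                        "\n")
    if (length(dn)) cat("  WT > KO:", paste(head(dn, 12), collapse = ", "),
                        "\n")
  }
}

regions <- region_streamline_compare(cohort)
write.table(regions, file.path(results_dir, "region_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
hits <- regions[regions$discovery, ]
cat(sprintf("region streamline totals: %d of %d regions differ at FDR 5%%\n",
            nrow(hits), nrow(regions)))
if (nrow(hits) > 0) {
  cat("  regions:", paste(hits$region, collapse = ", "), "\n")
}
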