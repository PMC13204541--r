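# Shared study configuration for the analysis scripts.
#
# One synthetic cohort stands in for the study data throughout: 8 WT and
# 12 KO animals over the packaged 72-region bilateral parcellation, with
# group effects planted where the real study reports its strongest
# alterations — amygdala (COA) and thalamus connectivity within each
# hemisphere, a hippocampus-wide density increase, and a +15% axial
# diffusivity shift in the somatosensory cortex. Effects are multiplicative
# on the KO lognormal edge means; sizes are chosen large enough (x3) to be
# recoverable at n = 8 vs 12 so the downstream scripts have signal to show.

library(hdbn)

study_table <- load_region_table()

.ids <- function(stem, hemi) {
  resolve_composite(study_table, composite_roi(stem, stem), hemi)
}

study_planted_edges <- local({
  edges <- list()
  add <- function(a, b, effect) {
    for (h in c("L", "R")) {
      edges[[length(edges) + 1L]] <<- list(pair = c(.ids(a, h), .ids(b, h)),
                                           effect = effect)
    }
  }
  add("COA", "TH", 3)     # amygdala-thalamus, up in KO
  add("COA", "HY", 3)     # amygdala-hypothalamus, up in KO
  add("SS", "ICtx", 1/3)  # somatosensory-isocortex, down in KO
  hip <- c("CA1", "CA2", "CA3", "DG")
  for (a in hip) add(a, "TH", 3)  # hippocampal-thalamic edges, up in KO
  edges
})

study_config <- sim_config(
  n_wt = 8L, n_ko = 12L, n_regions = 72L,
  baseline_log_mean = 4, baseline_log_sd = 0.5, zero_prob = 0.15,
  planted_edges = study_planted_edges,
  planted_regions = list(
    list(region_id = .ids("SS", "L"), scalar = "AD", effect = 1.15),
    list(region_id = .ids("SS", "R"), scalar = "AD", effect = 1.15)),
  seed = 20260926L %% 2147483647L)

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE)
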