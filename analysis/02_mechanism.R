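#!/usr/bin/env Rscript
# Mechanism analysis on the two synthetic systems: remove unbound-ligand
# frames, map enzyme-ligand contacts, follow the folding state of the
# stimulation-responsive helix, and quantify the coupling between the
# reader-side interactions (d1 salt bridge, d2 cation-pi) and the sulfur
# contact d3. The mutant-like system is built with persistent contacts and
# strong d1-d3 / d2-d3 coupling; the wildtype-like system with intermittent
# contacts and frequent helix unfolding — the analysis should recover that
# contrast from the frames alone.

suppressPackageStartupMessages(library(allostat))

seed <- 1L
n_frames <- 2500L

reports <- list()
for (preset in c("wt_like", "mutant_like")) {
  message("== mechanism: ", preset, " ==")
  reports[[preset]] <- run_mechanism(list(
    outdir = file.path("results/mechanism", preset),
    seed = seed, scenario = preset, n_frames = n_frames
  ))
}

wt <- reports$wt_like$headline
mut <- reports$mutant_like$headline
comparison <- data.frame(
  quantity = c("kept frame fraction", "helix RMSD median (nm)",
               "helix unfolded fraction", "d1 median (nm)",
               "d1 occupancy (<= 0.4 nm)", "r(d1,d3)", "r(d2,d3)"),
  wt_like = unlist(wt[c("kept_frame_fraction", "helix_rmsd_median_nm",
                        "helix_unfolded_fraction", "d1_median_nm",
                        "d1_occupancy", "r_d1_d3", "r_d2_d3")]),
  mutant_like = unlist(mut[c("kept_frame_fraction", "helix_rmsd_median_nm",
                             "helix_unfolded_fraction", "d1_median_nm",
                             "d1_occupancy", "r_d1_d3", "r_d2_d3")])
)
rownames(comparison) <- NULL
write.csv(comparison, "results/mechanism/system_comparison.csv",
          row.names = FALSE)

message("== system comparison ==")
print(comparison, digits = 3)
message(sprintf(paste0(
  "The mutant-like system holds the salt bridge more (occupancy %.2f vs ",
  "%.2f), keeps the helix folded (unfolded in %.0f%% of bound frames vs ",
  "%.0f%%) and shows the stronger induced coupling r(d1,d3) = %.2f vs ",
  "%.2f."),
  mut$d1_occupancy, wt$d1_occupancy, 100 * mut$helix_unfolded_fraction,
  100 * wt$helix_unfolded_fraction, mut$r_d1_d3, wt$r_d1_d3))
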