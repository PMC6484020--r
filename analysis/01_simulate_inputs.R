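#!/usr/bin/env Rscript
# Build every synthetic input the downstream analyses consume: the toy
# reference complex, one wildtype-like and one mutant-like trajectory with
# ground-truth labels, and the plate-reader assay tables. All files land
# under results/inputs/ in plain-text formats (PDB, XYZ dialect, CSV).

suppressPackageStartupMessages(library(allostat))

seed <- 1L
n_frames <- 2500L
outdir <- "results/inputs"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

message("== reference complex ==")
ref <- build_reference_complex()
print(ref)
write_structure(ref, file.path(outdir, "reference_complex.pdb"))

for (preset in c("wt_like", "mutant_like")) {
  message("== trajectory: ", preset, " ==")
  sc <- switch(preset,
               wt_like = wt_like_scenario(n_frames = n_frames, seed = seed),
               mutant_like = mutant_like_scenario(n_frames = n_frames,
                                                  seed = seed))
  ens <- simulate_trajectory(sc, ref)
  print(ens)
  write_ensemble(ens, file.path(outdir, paste0(preset, "_trajectory.xyz")))
  write.csv(ens$truth, file.path(outdir, paste0(preset, "_truth.csv")),
            row.names = FALSE)
  message(sprintf("  bound frames: %.1f%%; folded helix: %.1f%%",
                  100 * mean(ens$truth$bound),
                  100 * mean(ens$truth$helix_folded)))
}

message("== assay tables ==")
panel <- simulate_activity_panel(noise_cv = 0.05, seed = seed)
write.csv(panel, file.path(outdir, "activity_panel.csv"), row.names = FALSE)
message(sprintf("  activity panel: %d wells over %d datasets",
                nrow(panel), length(unique(panel$dataset))))

sc_dr <- assay_scenario(ec50_true = 2.3, noise_cv = 0.03, seed = seed)
write.csv(simulate_assay(sc_dr, "dose_response"),
          file.path(outdir, "dose_response.csv"), row.names = FALSE)
sc_fp <- assay_scenario(kd_true = 156, noise_cv = 0.02, seed = seed)
write.csv(simulate_assay(sc_fp, "fp_titration"),
          file.path(outdir, "fp_titration.csv"), row.names = FALSE)
message("done: inputs under ", outdir)
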