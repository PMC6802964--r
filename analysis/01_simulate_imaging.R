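#!/usr/bin/env Rscript
# Simulate the imaging datasets used throughout the analysis: endocytic
# event trace cohorts for each strain preset, a two-colour Cam1/Cam2 pair
# set, a single-molecule calibration scene, and a small demonstration movie
# written as 16-bit TIFF with its ground truth. Everything downstream
# regenerates what it needs from the same presets and seeds; this script
# materializes one copy on disk for inspection.

library(endotrace)

out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- run_config(preset = "myo1", seed = 20260921)
write_config(cfg, file.path(out, "run_config.yaml"))

message("simulating event cohorts (myo1 n=50, cam1 n=52, S742A n=67, cam2 n=36)")
cohorts <- list(
  myo1 = generate_event_cohort("myo1", 50, seed = cfg$seed + 1),
  cam1 = generate_event_cohort("cam1", 52, seed = cfg$seed + 2),
  myo1_S742A = generate_event_cohort("myo1_S742A", 67, seed = cfg$seed + 3),
  cam2 = generate_event_cohort("cam2", 36, seed = cfg$seed + 4))
truth <- do.call(rbind, lapply(names(cohorts), function(nm) {
  cbind(preset = nm, cohorts[[nm]]$truth)
}))
write.csv(truth, file.path(out, "simulated_event_truth.csv"),
          row.names = FALSE)
write_trace_csv(cohorts$myo1$traces[[1]],
                file.path(out, "example_myo1_trace.csv"))

message("simulating a demonstration endocytosis movie (9 events)")
demo <- generate_event_movie("myo1", n_events = 9, seed = cfg$seed + 5)
write_movie(demo$movie, file.path(out, "demo_myo1_movie.tif"))
write_truth_json(demo$truth$events,
                 file.path(out, "demo_myo1_movie_truth.json"))

message("simulating the single-molecule membrane-binding scene")
sm <- generate_single_molecule_movie(seed = cfg$seed + 6)
write_truth_json(list(n_molecules = nrow(sm$truth$dwells),
                      mean_true_dwell_s = mean(sm$truth$dwells$dwell_s)),
                 file.path(out, "single_molecule_truth_summary.json"))

message("done; outputs under results/")
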