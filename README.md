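# endotrace

Quantitative analysis of myosin-1 dynamics at sites of endocytosis in
fission yeast, and of calmodulin light-chain binding to the myosin-1 IQ
neck region — from single-molecule TIRF movies to equilibrium and
stopped-flow kinetics.

Endocytosis in *S. pombe* recruits the class-I myosin Myo1 and its
calmodulin light chains (Cam1, Cam2) to cortical patches for roughly ten
seconds at a time. The package implements the full measurement chain used
to characterize these events and the underlying calmodulin–IQ chemistry:

* **Event detection** — per-pixel standard-deviation projection of the
  movie; robust (median + k·MAD) local-maximum detection; 5×5 measurement
  cores with 1.5-µm background regions and automated flagging of
  overlapping events.
* **Trace analysis** — background correction; maximum-gradient 60-point
  ramp fits whose zero-intensity intercepts define `T_start`, `T_end` and
  the event duration `T_dur`; mid-event amplitude `A_av`; abrupt-drop
  vesicle-scission detection (`T_scis`); synchronized trace averaging;
  molecule counting via a single-fluorophore calibration measured from
  tracked single molecules.
* **Single-particle tracking** — matched-filter spot detection,
  mutual-nearest-neighbour linking, residency off-rate by truncated
  exponential maximum likelihood (`k = 1/(mean(d) − d_min)`), and lateral
  mobility from the ensemble MSD (`MSD(τ) = 4Dτ +` noise intercept).
* **Binding models** — strictly sequential two-site calmodulin–IQ binding
  (no IQ2-only species) with exact ligand-depletion correction, weighted
  multistart fitting that reports stoichiometrically tight sites as upper
  bounds, Hill (pCa) titration fits, and Förster efficiency↔distance
  conversion (CyPet–YPet R₀ = 5.301 nm).
* **Transient kinetics** — multi-exponential stopped-flow fitting with
  seeded multistart and F-test phase-count selection.
* **Synthetic data** — seeded generators for movies (pixel-integrated
  Gaussian PSFs, Poisson + read noise), traces, two-colour event pairs,
  titrations and transients, all with exported ground truth, so the whole
  pipeline is testable without any raw microscopy data.

## Worked example

Simulate a cohort of wild-type Myo1 endocytic events, measure them, and
convert the plateau amplitude to a copy number using a calibration
estimated from a simulated single-molecule scene:

```r
library(endotrace)

cal_scene <- generate_single_molecule_movie(seed = 20260927)
cal <- estimate_single_fluorophore_intensity(
  track_movie(cal_scene$movie),
  excitation_scale = default_excitation_scale())

coh <- generate_event_cohort("myo1", 50, seed = 20260922)
mm  <- measure_events(coh$traces, calibration = cal)
cat(sprintf("T_dur %.2f +/- %.2f s (n = %d); %.0f molecules at the plateau\n",
            mean(mm$t_dur), sd(mm$t_dur) / sqrt(nrow(mm)), nrow(mm),
            mean(mm$molecules_peak)))
```

```
T_dur 13.62 +/- 0.31 s (n = 50); 45 molecules at the plateau
```

The event lasts ~13.6 s (mean ± SEM over 50 events) and the plateau
corresponds to ~45 myosin molecules. The same pipeline run on the Cam1 and
S742A presets gives ~11.3 s / ~88 molecules and ~11.9 s / ~45 molecules —
the phosphorylation-resistant S742A mutant assembles like the wild type
but leaves earlier, and Cam1 (which occupies both IQ sites) arrives at
twice the myosin copy number and dissociates before the myosin does.

The numbered scripts under `analysis/` run the complete study —
`01_simulate_imaging.R` through `06_transient_kinetics.R` — writing their
tables and JSON summaries under `results/`. For example,
`analysis/05_equilibrium_binding.R` prints:

```
cam1_titration: K1 < 0.1 uM (too tight to determine); K2 = 0.652 uM (95% CI 0.394-1.052); dF2 fraction 0.50
cam2_titration: K1 < 0.1 uM (too tight to determine); K2 = 1.225 uM (95% CI 0.882-2.204); dF2 fraction 0.70
pCa50 = 5.875 (hill n = 1.99)
E = 0.70 corresponds to 4.60 nm (R0 = 5.301 nm)
```

i.e. the first IQ site binds calmodulin too tightly to measure at a 0.5 µM
reporter concentration (reported as a bound, not a point estimate), the
second site binds ~10-fold more weakly, Cam2's dominant phase carries ~70%
of the signal, calcium switches the interaction around pCa ≈ 5.9, and a
FRET efficiency of 0.70 corresponds to a ~4.6-nm calmodulin-bound neck.
`analysis/03_single_molecule.R` reports the transient membrane binding of
single myosin molecules (off-rate ~7–8 s⁻¹, D ≈ 0.03 µm²/s), and
`analysis/06_transient_kinetics.R` resolves the three-phase calcium
release (rates ≈ 137, 13 and 2 s⁻¹ of equal amplitude, with the F-test
selecting three phases).

See `vignettes/endotrace-methods.Rmd` for the models, parameter defaults,
numerical choices and known limitations, and `inst/extdata/presets.json`
for every preset parameter.

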