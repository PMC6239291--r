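# vivorate

Non-invasive assays of radiation-induced lung injury in small animals,
as one tested R toolkit. Preclinical studies of thoracic irradiation —
for example safety studies for MRI-guided radiotherapy, where the
magnetic field perturbs dose deposition at tissue interfaces — monitor
lung damage in mice with three measurements that need neither contact
nor surgery:

1. **Video respirometry.** A mouse sleeping in its cage is filmed; fur
   motion from breathing is tracked with Shi-Tomasi corner detection and
   pyramidal Lucas-Kanade optical flow, and the respiratory rate
   (breaths/min) is read off the spectral peak of the resulting motion
   waveform. The amplitude of that waveform depends on camera distance
   and angle; its frequency does not, which is why the rate is the
   quantity of interest.
2. **CT densitometry.** From a thoracic CT volume, healthy lung is
   segmented by density thresholding (0–0.7 g/cm³), its volume is
   computed, and lung density is measured in seven fixed regions of
   interest (four 1.5 mm squares in the apex, three 2.4 mm squares in
   the base) anchored to the lung bounding box so the same locations are
   measured at every timepoint.
3. **Cohort statistics.** Animals are dichotomized as normal/abnormal
   against control-group cutoffs (mean ± 3 SD), dose–response curves of
   the abnormal fraction are fitted with the Hill equation
   P(D) = 100 / (1 + (ED50/D)^h), ED50s of two treatment arms are
   compared with an extra sum-of-squares F-test, and survival is
   analyzed with Kaplan–Meier/log-rank and Cox proportional-hazards
   models.

Because animal data cannot ship with code, every pipeline has a seeded
synthetic generator with known ground truth: breathing video clips
(quasi-periodic flank motion with jitter, drift, noise, and gasp /
pause / sniff irregularities), two-lung ellipsoid density phantoms with
configurable injury, and irradiation cohorts with a Hill-shaped latent
dose response and administrative censoring at 8 months.

## Worked example

```r
library(vivorate)

# --- respirometry on a synthetic clip with known rate ---------------
sc   <- breathing_scenario(rate_bpm = 191, duration_s = 20,
                           jitter_cv = 0.05, noise_sd = 0.02, seed = 42)
clip <- render_breathing_clip(sc)
est  <- measure_respiration(clip$frames)   # detect -> track -> waveform -> rate
est
#> <rate_estimate> 193.09 bpm (prominence 3281.9, ibi_cv 0.059, qc pass)
clip$truth$true_rate_bpm
#> [1] 191.1821

# --- lung metrics on a digital phantom ------------------------------
ph <- make_phantom(spacing_mm = 0.2,
                   injury = list(fraction = 0.5, lung = 1, density = 0.9))
lm <- lung_metrics(ph$volume)
c(measured = lm$healthy_volume_cm3, analytic = ph$truth$healthy_volume_cm3)
#>  measured  analytic
#> 0.4520640 0.4523893

# --- cohort statistics ----------------------------------------------
sim <- simulate_cohort(cohort_config(seed = 3))
an  <- analyze_cohort(sim$cohort)
an
#> <cohort_analysis>
#>   excluded animals: 15
#>   cutoff rr_bpm       > 207.2
#>   cutoff density_gcc  > 0.662
#>   cutoff volume_cm3   < 0.4241
#>   ED50 rr_bpm       0T 10.836 vs 1.5T 11.385 Gy (p = 0.6876)
#>   ED50 density_gcc  0T 10.791 vs 1.5T 11.924 Gy (p = 0.09272)
#>   ED50 volume_cm3   0T 10.857 vs 1.5T 11.147 Gy (p = 0.442)
```

The rate estimate lands within 2 bpm of the generator's realized rate
and passes both quality checks (a prominent spectral peak, regular
inter-breath intervals). The phantom's measured healthy-lung volume
matches the closed-form ellipsoid volume to 0.1%. In the simulated
cohort the dichotomization cutoffs are re-estimated from the simulated
controls, and with only 10 animals per dose and arm a 3% ED50 shift is
usually not significant in a single cohort — the per-arm ED50 estimates
above scatter around the configured 11 Gy and 10.67 Gy.

A command-line wrapper over the same functions is installed at
`inst/cli/vivorate` with subcommands `simulate-video`, `respirate`,
`lungct`, `simulate-cohort` and `cohort` (exit codes: 0 success, 2 bad
input, 3 quality-control failure).

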