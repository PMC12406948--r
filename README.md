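# mpsquant

Magnetic particle spectroscopy (MPS) measures the nonlinear magnetization
response of iron-oxide nanoparticle tracers to a sinusoidal drive field
(25 kHz, 25 mT) and reads it out as odd harmonics of the drive. Because the
harmonic amplitudes are strictly proportional to the amount of tracer iron,
the third harmonic A₃ quantifies iron down to a blank-derived detection
limit — but ferro-/ferrimagnetic contamination from ordinary rodent diet is
MPS-visible too, and in biodistribution panels it masquerades as tracer in
intestinal tissue, feces and food samples.

`mpsquant` is an R package plus analysis workflow for exactly this
problem, aimed at preclinical imaging and nanomedicine groups:

* **Simulate** time-domain MPS measurements: superparamagnetic tracers
  (size-averaged Langevin equilibrium, m_eq(B) = m_sat·⟨L(ξ)⟩ with
  L(ξ) = coth ξ − 1/ξ, plus Debye relaxation dm/dt = (m_eq(B(t)) − m)/τ),
  spectral-template tracers, hysteretic dietary contaminants, blanks, and
  whole organ-panel studies with ground truth.
* **Analyze** signals into harmonic spectra Aₙ, φₙ with coherent sampling,
  an equilibrium-referenced negative-lag phase convention, and per-order
  noise floors.
* **Quantify** iron via a reference calibration (specific moment
  Â₃ = A₃/m_Fe, units A m² kg⁻¹) and the IUPAC limit of detection
  LOD = μ + 3σ over 20 blank measurements.
* **Classify** each specimen in the concentration-independent
  (A₅/A₃, φ₃) fingerprint plane: below-LOD, tracer (inside a Gaussian
  acceptance ellipse with χ²₂ threshold), or contaminated — and report
  corrected, contamination-excluded biodistribution tables.

## Worked example

```r
library(mpsquant)
rc  <- run_config(seed = 1)            # PBS + tracer groups, 6 organs, n = 8
res <- run_pipeline(rc, out_dir = "results/study")
```

The run prints the detection limit (`LOD = 2e-11 A m^2`), the calibrated
specific moment (`0.2 A m^2/kg Fe`), and classifies all 96 records:

```
               EuVSOP PBS
  below_LOD         0  41
  contaminated      7   7
  target_MNP       41   0
```

Every vehicle-control specimen is either below the detection limit or
excluded as dietary contamination (colon 6/8, caecum 1/8 at this seed), so
no control is ever "quantified"; tracer-group iron recovers ground truth
with median error 0.4% (max 2.5%). The corrected organ means reproduce the
expected biodistribution — liver ≫ spleen ≫ intestinal organs:

```
  LIV    mean A3 = 3.66e-09 A m^2  (n quantified = 8)
  SPL    mean A3 = 7.87e-10 A m^2  (n quantified = 8)
  COL    mean A3 = 2.93e-10 A m^2  (n quantified = 3)
  SIT    mean A3 = 2.62e-10 A m^2  (n quantified = 7)
  CAE    mean A3 = 2.06e-10 A m^2  (n quantified = 7)
  KID    mean A3 = 1.88e-10 A m^2  (n quantified = 8)
```

The numbered scripts under `analysis/` run the same flow as a narrative:
`01_spectral_signatures.R` (tracer fingerprints: A₅/A₃ = 10/20/30%,
φ₃ = −2/−10/−30° for the VSOP-like, Endorem-like and multicore presets),
`02_lod_calibration_linearity.R`, `03_synthetic_study.R`,
`04_corrected_quantification.R`. Outputs land under `results/`.

The methods vignette (`vignettes/mps-quantification.Rmd`) documents the
signal model, analyzer conventions, censoring rules, the fingerprint-region
definition, and what the synthetic generator does and does not emulate.

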