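# stereosim

Design-based stereology estimators, validated end-to-end on synthetic 3D
tissue scenes with known ground truth.

Quantitative neuroanatomy routinely reports three kinds of numbers from
thick, systematically sampled sections: total axon length density
(estimated with virtual spherical probes, "spaceballs"), total neuron
number (the optical fractionator) and mean cell size (the nucleator). In
studies of amyloid pathology these estimators are additionally stratified
by distance from deposit edges — fiber density *near* (≤ 20 μm) versus
*distant* (> 20 μm) from a plaque — to separate local from global
toxicity. All of these are unbiased on paper; whether a concrete
implementation of the whole chain (sectioning, shrinkage, probe placement,
counting rules, classification, statistics) actually recovers known truth
is exactly what a synthetic scene can test.

`stereosim` is for stereologists and methods developers who want that
test harness: it generates fiber fields of prescribed length density
(isotropic or anisotropic), spherical plaques, plaque-local fiber
depletion with known survival fractions, and neuron populations with
known thinning, slices them into sampled sections, and runs the classical
estimators:

* `L_V = 2ΣQ / Σ(surface area)`, `L = L_V · V(ref)` — spherical probes,
  where `Q` counts transversal fiber crossings of each sphere surface;
* `N = ΣQ⁻ · (1/ssf)(1/asf)(1/hsf)` — optical fractionator with a
  100×100 μm frame, 200×200 μm grid, 10 μm dissector, 1 μm guard;
* `V = (4π/3)·mean(l³)`, `A = π·mean(l²)` — vertical nucleator;
* near/distant stratification of probes by center distance from the
  nearest plaque edge, normalization to a non-transgenic reference,
  one/two-way ANOVA with Tukey, Newman–Keuls or Fisher post-hoc tests.

## Worked example

Impose a 60% near-plaque fiber reduction (survival 0.40 within 20 μm of a
deposit edge, 1.0 beyond) and recover it with 500 spherical probes:

```r
library(stereosim)

roi  <- region_box("DG", c(200, 200, 80))           # um, z = cutting axis
fib  <- generate_fiber_field(roi, target_Lv = 0.05, seed = 1)
plq  <- generate_plaques(roi, count = 6, radius = c(7, 11),
                         min_edge_separation = 4, seed = 2)
dep  <- apply_depletion(fib, plq, threshold_d = 20,
                        survival_near = 0.4, survival_distant = 1, seed = 3)
sec  <- slice_sections(dep, sampling_interval = 2, phase_seed = 4)
pr   <- place_probes(sec, roi, n_locations = 500, seed = 5)
pr   <- probe_crossings(pr, sec)
pr   <- classify_probes(pr, plq, proximity_rule(20, "full_3d"), sec)
stratified_density(pr)
#> <stratified_density> near 3.59 (n=44) / distant 7.51 (n=461), 1 within excluded
estimate_length_density(pr)
#> <length_estimate> Lv = 0.04552 um/um^3 (sum Q = 3618 over 506 probes)
```

The near stratum sits at `3.59/7.51 ≈ 0.48` of the distant density — the
imposed 0.40 survival plus the predictable smearing of a 10 μm probe
footprint across a 20 μm zone (see the methods vignette; averaged over
replicate scenes the measured reduction settles around 53–55% for an
imposed 60%). The overall density estimate is below the pre-depletion
0.05 because the depleted field is what is being probed.

Scenario presets encoding the validation conditions (per-region survival
fractions, group sizes, fractionator design) live in
`inst/extdata/presets.yaml`:

```r
near_distant_reduction("DG-12m", seed = 1)$reduction_pct  # 51.6 (imposed 60)
fractionator_loss("NbM-18m", seed = 1)$loss_pct           # 19.2 (imposed 20)
run_pipeline(run_config("DG-12m", seed = 1, out_dir = "out"))  # CSV bundle
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/stereosim.R` (subcommands `simulate`, `probe`, `classify`,
`count`, `stats`, `run`).

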