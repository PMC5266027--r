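# pbpkct

Patient-scalable physiologically based pharmacokinetic (PBPK) simulation
of iodinated contrast medium for cranial CT.

Cerebral CT perfusion and CT angiography depend on the time-density
curve (TDC) — CT attenuation (HU) in an intracranial artery over time
after a contrast bolus. The curve varies strongly with the patient:
blood volume, cardiac output and regional flows scale with sex, height
and weight. `pbpkct` predicts a patient's cerebral arterial TDC *before*
scanning, from those three body parameters and the injection protocol,
and provides the statistical pipeline to compare predicted against
measured curves. Intended users: imaging researchers and physicists
working on scan-delay optimisation and contrast protocol design.

## The model

A whole-body compartment model of the circulation: antecubital vein →
superior vena cava → right heart → pulmonary circulation → left heart →
aorta → parallel systemic branches (cerebral, coronary, extremities,
GI/spleen → portal vein → liver, kidneys, lower body) → venous return
(absorbing sink in the default first-pass mode; closed loop behind a
`recirculation` flag). Organs carry a vascular and an extracellular
state exchanging at a permeability–surface product PS; large-vessel
transit is an Erlang chain of well-mixed sub-compartments. With amounts
`A` (mg iodine), the dynamics are the linear system

    dA/dt = M A + e u(t),      u(t) = rate × C_iodine  for 0 ≤ t < V/rate

integrated with `deSolve::lsoda` (rtol 1e-8). Patient scaling uses
Nadler's sex-specific blood-volume regression `BV = a H³ + b W + c` and
allometric cardiac output `CO = CO_ref (W/70)^0.75`. Concentration maps
linearly to enhancement at the scan's tube voltage, and the clinical
metrics follow:

* **ME** (maximum enhancement) = peak attenuation − baseline, HU
* **TTP** (time to peak) = time of the first curve maximum, s
* **MTT** (mean transit time) = venous TTP − arterial TTP, s

All physiological constants (organ flow/volume fractions, PS values, the
HU-per-concentration coefficient) live in one YAML-serialisable
configuration (`default_config()`), not in code.

## Worked example

```r
library(pbpkct)

profile  <- patient_profile("male", 170, 75)
protocol <- injection_protocol()   # 45 mL, 4 mL/s, 370 mg I/mL, 80 kV
curve    <- simulate_patient_tdc(profile, protocol)
extract_metrics(curve)
#> <tdc_metrics:simulated> ME 424.9 HU (peak 474.9 - baseline 50.0), TTP 19.0 s
```

The reference adult peaks at 424.9 HU enhancement 19.0 s after injection
start: arterial-magnitude enhancement inside the 9–33 s TTP range seen
in healthy adults. Sweeping weight at fixed height shows the expected
dilution effect — ME 540.1 / 424.9 / 352.5 HU at 50 / 75 / 100 kg.

Cohort-level validation against emulated measurements:

```r
spec   <- cohort_spec(19, 25, seed = 7)        # 44 controls
report <- run_validation(generate_cohort(spec))
report$pct_diff
#>       ME      TTP
#> 5.111918 5.912375
```

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "pbpkct", package = "pbpkct"))') \
    simulate --sex male --height 170 --weight 75 --weights 50,75,100
```

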