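# rifvar

Cell-to-cell variability of radiation-induced γH2AX foci (RIF) and the
microdosimetric spread of specific energy.

When thousands of G0/G1 cell nuclei receive the same nominal photon dose,
the per-nucleus RIF count — a proxy for DNA double-strand breaks — varies
widely: for Co-60 irradiated HUVEC populations the relative standard
deviation (SD_rel = SD / mean) is about 0.36 at 0.5 Gy, 0.25 at 1 Gy and
0.18 at 2 Gy, shrinking like 1/√D while the absolute SD grows like √D.
`rifvar` implements the microdosimetric account of that variability and the
full analysis pipeline around it, for radiation biophysicists and
biostatisticians who want to reproduce, probe or extend the calculation
without access to the original per-nucleus tables (which were never
deposited).

## The model

The specific energy z (Gy) absorbed by a target of volume V under
macroscopic dose D is a random sum over a Poisson number ν of particle
tracks (mean n), each depositing energy per the single-track distribution
f₁(z):

    f(z, D) = Σ_ν p(ν) · f_ν(z),    p(ν) = e⁻ⁿ nᵛ / ν!

with f_ν the ν-fold self-convolution of f₁. For n ≫ 1 this converges to
N(n·z̄₁, √(n·(z̄₁² + SD²z₁))), and the relative spread collapses to the
two-constant relation

    SD_rel(V, D) = k1 / √(V^k2 · D),

so every dose doubling multiplies SD_rel by exactly 1/√2 — the same
signature the RIF counts show. The package calibrates (k1, k2) for Co-60
from reference spread values at the whole-nucleus (293.7 μm³) and
DNA-molecule (8.5 μm³) volumes, and inverts the relation in closed form,

    V = (k1 / (SD_rel · √D))^(2/k2),

to find the target volume whose energy spread alone would explain the
observed count spread. Around it sit a synthetic per-nucleus generator
(energy-driven counts, overdispersed sham background, cell-cycle-dependent
DAPI/γH2AX/KI67 intensities, 6% replicate dose jitter), a
flow-cytometry-like G0/G1 gate, and population statistics including Q-Q
comparison of counts against simulated energies.

## Worked example

```r
library(rifvar)

model <- co60_default_model()
model
#> <specific_energy_model Co-60: k1 = 0.3165, k2 = 0.8196 (V in um^3, D in Gy)>
#>   calibrated on 6 points, RMS log-residual 0.00724

# relative energy spread at 1 Gy in the three comparison volumes
sd_rel(model, c(293.7, 8.5, 1.6), 1)
#> [1] 0.03083786 0.13168105 0.26105717

# invert the observed count spreads -> the matching target volume
obs <- rif_reference_counts("Co-60")
invert_target_volume(model, obs$sd_rel, obs$dose_Gy)
#> [1] 1.667408 1.727211 1.656251

# the full synthetic replication: simulate -> gate -> describe -> invert
report <- run_replication(model, seed = 1)
report
#> <replication_report>
#>   model: Co-60, k1 = 0.3165, k2 = 0.8196
#>   doses (Gy): 0, 0.5, 1, 2; gated nuclei per dose: 19847, 6569, 7004, 7081
#>   dose response: 15.73 RIF/Gy (intercept 0.75, R^2 0.9999)
#>   count sd_rel: 2.483, 0.375, 0.266, 0.187
#>   inverted matching volume: 1.54 um^3 (per dose: 1.54, 1.53, 1.55)
```

Reading the output: the calibration reproduces the held-out 1.6 μm³
reference block within ~1%; inverting the three observed spreads (0.363,
0.253, 0.182) gives volumes tightly grouped around 1.7 μm³ — the ~1.6 μm³
matching volume within the ~10% uncertainty the 2-significant-figure
calibration inputs allow, and about the volume of the hydrated
sugar-phosphate backbone of a 6-Gbp genome. On fully synthetic data the
whole pipeline (including gating and replicate dose jitter) recovers the
configured 15.5 foci/Gy yield and an inverted volume within 15% of the
configured 1.6 μm³.

A command-line wrapper with subcommands (`simulate`, `gate`, `stats`,
`energy`, `calibrate`, `invert-volume`, `qq`, `replicate`) is installed at
`inst/cli/rifvar`:

```sh
Rscript inst/cli/rifvar invert-volume --sdrel 0.363 --dose 0.5
#> 1.667
```

The methods vignette (`vignettes/rif-variability.Rmd`) documents the model
assumptions, the generator's scope, all tunable parameters and the
numerical choices.

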