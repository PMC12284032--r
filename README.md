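# cetpflux

Modeling postprandial CETP-mediated triglyceride redistribution among
lipoprotein fractions.

## What this is for

After a fat-rich meal, chylomicrons (CM) and VLDL flood the plasma and
cholesteryl ester transfer protein (CETP) redistributes triglyceride (TG)
from these TG-rich lipoproteins into LDL and HDL, exchanging it equimolarly
against cholesteryl ester (CE). Quantifying that flux from a single blood
draw requires three pieces this package provides for lipid researchers:

1. **Chylomicron quantification** from two-chamber (Airfuge-type)
   ultracentrifugation: CMs float from the plasma-filled outer chamber
   (2.6 ml) into the saline-filled inner chamber (0.9 ml), together with a
   little spilled plasma. Because ApoA1 is not CM-associated, the
   inner/outer ApoA1 ratio `D` measures the spillover, and the
   CM-associated concentration of any component X in plasma is

       g(X) = F * (c_in(X) - D * c_out(X)),    F = 0.9 / 2.6.

2. **Particle geometry**: particle counts from apolipoprotein
   stoichiometry (one ApoB per particle, ApoB-48 in CM and ApoB-100
   elsewhere; 3 ApoA1 per HDL particle), spherical radii from molecular
   volumes, and total surface area per litre.

3. **A surface-driven exchange model**: with `S_i` the fraction surfaces
   and `r_i = TG_i/(TG_i + CE_i)` the core TG ratios, the TG net flux into
   fraction `i` is

       J_i = k * sum_{j != i} S_i S_j (r_j - r_i) / S_tot    [µmol/l/h]

   which conserves mass exactly and vanishes at equal ratios. The rate
   constant `k` is calibrated per subject against the measured 1-hour TG
   redistribution (37 °C vs 4 °C incubation deltas) by least squares
   through the origin. The model runs with CM and VLDL+CMR as separate
   pools ("discriminating") or merged into one TRL pool
   ("nondiscriminating") and quantifies the difference.

Paired cohort statistics (exact Wilcoxon signed-rank, Spearman
correlations, the ApoC3 redistribution analysis) and a ground-truth
synthetic cohort generator round out the pipeline. See the methods
vignette (`vignettes/cetp-flux-model.Rmd`) for the model, its assumptions
and the numerical choices.

## Worked example

Generate a synthetic postprandial subject with known ground truth, recover
its chylomicron profile from simulated two-chamber measurements, calibrate
the exchange rate and compare the two model configurations:

```r
library(cetpflux)

gen <- generate_cohort(generator_params(n_normo = 12, n_htg = 0, n_fcs = 0),
                       seed = 42)
rec <- get_record(gen$dataset, "S01", "postprandial")

# two-chamber measurement at 2% noise, then the spillover correction
m <- simulate_airfuge(gen$truth$S01$cm$postprandial, noncm_plasma(rec),
                      gen$truth$S01$d_true, noise_cv = 0.02)
prof <- cm_profile(m)
prof$correction
#> <cm_correction> D = 0.1475
#>   clipped components: apo_a2
c(recovered = prof$cm$tg, true = gen$truth$S01$cm$postprandial$tg)
#> recovered      true
#>     0.632     0.649      # mmol/l CM TG despite 2% assay noise

# calibrated five-pool fluxes (µmol/l per hour; positive = net TG gain)
fl <- subject_fluxes(rec, config = "discriminating", k = "calibrate")
fl
#> <flux_result> discriminating model, k = 0.27122
#>       CM VLDL_CMR      IDL      LDL      HDL
#> -21.7795 -66.3360  -4.0709  51.5851  40.6013

compare_model_configs(rec, k_policy = "shared", k = fl$k)
#> <model_comparison>
#>   discriminating:         CM VLDL_CMR      IDL      LDL      HDL
#>  -21.780  -66.336   -4.071   51.585   40.601
#>   nondiscriminating:    TRL     IDL     LDL     HDL
#> -89.581  -4.044  51.981  41.645
#>   relative difference (%):
#>  IDL  LDL  HDL
#> 0.65 0.77 2.57
```

Reading the numbers: TG streams out of the TG-rich pools (CM −21.8,
VLDL+CMR −66.3 µmol/l/h) into LDL (+51.6) and HDL (+40.6); the fluxes sum
to zero by construction. The calibrated rate (k = 0.271) recovers this
subject's true value (0.272). Merging CM and VLDL+CMR into one TRL pool
overestimates the TG enrichment of LDL and HDL by under 3% here — the
merged monodisperse pool has a slightly larger surface than the split
pools (power-mean inequality), which is why discriminating CM is
beneficial but not essential.

## Command line

```sh
Rscript inst/cli/cetpflux.R simulate --seed 7 --out-dir out      # synthetic cohort + truth
Rscript inst/cli/cetpflux.R airfuge-correct --airfuge out/airfuge.csv --out-dir out
Rscript inst/cli/cetpflux.R surfaces --cohort out/cohort.csv --out-dir out
Rscript inst/cli/cetpflux.R flux --cohort out/cohort.csv --deltas out/deltas.csv \
        --model both --out-dir out
Rscript inst/cli/cetpflux.R compare-models --cohort out/cohort.csv \
        --deltas out/deltas.csv --out-dir out
Rscript inst/cli/cetpflux.R report --cohort out/cohort.csv --out-dir out
Rscript inst/cli/cetpflux.R config show
Rscript inst/cli/cetpflux.R all --seed 7 --out-dir out           # everything
```

Every run writes a JSON manifest (command, config hash, seed, package
version) next to its outputs; identical config + seed gives byte-identical
files. Exit codes: 0 success, 2 configuration/usage error, 3 data
validation failure.

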