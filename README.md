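# gutpbpk

Mechanistic modeling of regional, transporter-mediated intestinal drug
absorption, built around two questions:

1. **What are the membrane transport kinetics of a compound?** Bidirectional
   Caco-2 transwell assays are simulated and *deconvoluted* with a
   three-compartment (apical / cell / basolateral) ODE model, separating
   passive diffusion of the unionized species from carrier-mediated uptake
   and saturable efflux on each membrane, including their pH dependence.
2. **Can regional transporter interplay explain dual absorption peaks?**
   The fitted kinetics feed a nine-segment gut absorption model coupled to
   a whole-body PBPK model, with per-segment scaling of every transport
   process, peak detection, sensitivity scans, and transporter DDI
   perturbations (induction, competitive and full inhibition).

The motivating system is talinolol, a β1-blocker that is a substrate of
apical P-gp efflux and basolateral (OATP2B1-like) uptake and whose oral
plasma profiles show two absorption peaks near 1 h and 4 h; digoxin serves
as the neutral P-gp probe.

## The model in brief

Monolayer fluxes per cm², with $f_u$ the Henderson–Hasselbalch unionized
fraction and $f_{\mathrm{act}}(\alpha,\mathrm{pH}) = (\mathrm{pH}/6.5)^\alpha$
the pH-power activity law for each active process:

```
J(A→C) = [f_act(α_AC, pH_A)·CL_AC + f_u(pH_A)·CL_diff] · C_A
J(C→A) = f_act(α_CA, pH_A)·Vmax_CA·C_C/(Km_CA + C_C) + f_u(pH_cell)·fu_cell·CL_diff·C_C
J(B→C) = [f_act(α_BC, pH_B)·CL_BC + f_u(pH_B)·CL_diff] · C_B
J(C→B) = f_act(α_CB, pH_B)·Vmax_CB·C_C/(Km_CB + C_C) + f_u(pH_cell)·fu_cell·CL_diff·C_C
```

For talinolol the law reproduces the key translated values: the basolateral
uptake clearance at blood pH, `0.0391·(7.4/6.5)^4.65 = 0.0715` µL/min/cm²;
the apical efflux fold-increase at distal-intestinal pH 7.0,
`(7.0/6.5)^19.3 = 4.18`; and the basolateral efflux capacity at blood pH,
`8.10·(7.4/6.5)^20.1 = 110` pmol/min/cm². In vivo, the same processes act
in each gut segment, with apical efflux additionally scaled by a
duodenum-to-ileum abundance gradient (~9-fold) and by per-segment scaling
factors.

## Worked example

Simulate a bidirectional assay at 10 µM, compute the apparent
permeabilities and the efflux ratio:

```r
library(gutpbpk)
tal <- talinolol_compound()        # monoprotic base, pKa 9.45
kin <- talinolol_kinetics()        # monolayer transport parameters

ab <- simulate_transwell(kin, transwell_design("apical", 10), tal)
ba <- simulate_transwell(kin, transwell_design("basolateral", 10,
                                               pH_A = 7.4), tal)
c(papp_AB = assay_papp(ab), papp_BA = assay_papp(ba),
  ER = efflux_ratio(assay_papp(ba), assay_papp(ab)))
#>      papp_AB      papp_BA           ER
#> 1.670357e-08 2.493565e-06 1.492833e+02
```

The A→B permeability is low (the base is almost fully ionized at pH 6.5,
and apical efflux removes what enters the cell), the B→A permeability is
~150-fold higher — strong directional efflux. Recover the kinetics from a
synthetic noiseless assay and reproduce the dual-peak mechanism:

```r
ds <- generate_transwell_dataset(kin, tal, assay_template(replicates = 1,
                                                          noise_cv = 0))
spec <- fit_spec(free = c("CL_diff", "CL_BC", "Vmax_CA", "Km_CA",
                          "Vmax_CB", "Km_CB", "alpha_CA", "alpha_BC",
                          "alpha_CB"),
                 fixed = list(CL_AC = 0, alpha_AC = 0))
fit <- fit_transport_kinetics_staged(ds, tal, spec)
fit$estimates$Km_CA
#> [1] 0.5711401        # generating value: 0.567 µM

gut <- build_default_gut()
sys <- talinolol_systemic()
base <- simulate_pk(sys, gut, talinolol_invivo_kinetics(), tal,
                    dose_event("oral", 100), t_end = 24)
nrow(detect_peaks(base)$peaks)
#> [1] 1
pert <- simulate_pk(sys, dual_peak_perturbation(gut),
                    talinolol_invivo_kinetics(), tal,
                    dose_event("oral", 100), t_end = 24)
detect_peaks(pert)$peaks$time_h
#> [1] 0.70 3.15
```

Lowering apical uptake and basolateral efflux in the lower jejunum (×0.1)
while raising them in the distal ileum (×10) converts the single-peaked
baseline into a dual-peaked profile; the same factors applied to any other
single segment do not.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

| script | what it does |
| --- | --- |
| `01_simulate_assays.R` | synthetic bidirectional assays + Papp/ER tables |
| `02_fit_kinetics.R` | staged deconvolution, estimates vs generator truth |
| `03_simulate_pk.R` | baseline IV/oral talinolol PK, NCA, mass audit |
| `04_sensitivity.R` | regional scans, the dual-peak demo, segment controls |
| `05_ddi.R` | efflux-transporter induction and inhibition AUC ratios |

The methods vignette (`vignettes/regional-absorption.Rmd`) documents the
model equations, the in-vivo translation and calibration choices, and what
the synthetic-data results do and do not establish.

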