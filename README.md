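# adipoflux

Kinetic modelling of postprandial abdominal subcutaneous adipose tissue
lipid metabolism from arteriovenous meal-challenge data.

## What it does

During a mixed meal challenge, adipose tissue fluxes of triglyceride
(TG), non-esterified fatty acids (NEFA), glycerol and glucose can be
measured as

    flux = ([arterial] - [venous]) x ATBF        (uptake positive)

across the tissue bed, with a meal tracer adding the fractional
spill-over of LPL-derived NEFA. `adipoflux` implements a two-compartment
(plasma + interstitial adipose) ODE model of these five flux series
under delayed insulin control:

- LPL lipolysis of circulating TG:  `k_ad [TG_art] I_LPL`, with the
  insulin signal damped by a three-compartment delay (constant
  `tau_lpl`);
- fractional spill-over:  `f = (d_spill/100) I_B / [I_art]`, clamped to
  [0, 1];
- glucose uptake:  `glut1 [G_art] + glut4 [G_art] I_AT` (second insulin
  delay `tau_at`);
- stored-TG (ATL) lipolysis:  `b_atl + atl_max / (1 + I_AT/k_atl)`,
  releasing 3 NEFA + 1 glycerol per TG;
- gradient exchange of glycerol and NEFA between plasma and adipose
  space (`p_gly`, `p_nefa`), and insulin-stimulated re-esterification
  `3 k_reester I_AT [NEFA_AT] [G3P_AT]` supplied with glycerol-3-
  phosphate from glucose via a delayed two-step cascade.

Around the model the package provides the complete estimation workflow:
weighted nonlinear least squares (`C(p) = sum ((M(p,t_i)-mu_i)/sigma_i)^2`)
with Controlled Random Search + bounded Levenberg-Marquardt and
Jacobian-based 95% confidence intervals; profile-likelihood
identifiability classification; AICc comparison of candidate flux terms;
flux decomposition into constituent reaction rates; HOMA-IR/ADIPO-IR and
AUC summaries; and a synthetic arteriovenous cohort generator (16
subjects, 7 sampling times, tracer included) so the whole pipeline is
testable without any external data.

Intended users: metabolic physiologists and systems biologists analysing
arteriovenous meal-challenge studies, and modellers who need a
reproducible reference implementation of this model family.

## Worked example

```r
library(adipoflux)

# a synthetic 16-subject cohort at the default "true" parameters
coh <- generate_cohort_fluxes(cohort_spec(seed = 42))
head(coh$dataset, 3)
#>    series time      mean        sd
#> 1 glucose  -30 0.5508868 0.2928368
#> 2 glucose    0 0.4828487 0.2307839
#> 3 glucose   60 1.2408633 0.2872468

# fit all 14 parameters to the cohort-mean fluxes
fit <- fit_global(coh$dataset, coh$forcing, seed = 1)
fit
#> Model fit: cost 0.721221 (converged), seed 1
#>   k_ad       0.0099371 (0.0092653, 0.010609)
#>   tau_lpl    165.73 (141.12, 190.34)
#>   tau_at     22.711 (20.519, 24.902)
#>   d_spill    35.514 (33.932, 37.095)
#>   glut1      0.025114 (0.0081272, 0.042101)
#>   glut4      0.0076577 (0.0068111, 0.0085043)
#>   p_gly      0.34207 (-1.2355, 1.9197)
#>   ...

# the cost is the weighted residual sum of squares over the five series;
# the estimates sit close to the generating values (k_ad 0.0096,
# tau_lpl 156.92, tau_at 21.19, d_spill 35) with the truth inside the
# 95% intervals; a weakly identified exchange rate such as p_gly gets a
# wide interval, and intervals may extend below zero because the
# linearisation ignores the non-negativity bounds.

# profile-likelihood identifiability of every parameter
profs <- profile_all_parameters(fit, coh$dataset, coh$forcing)
classify_identifiability(profs)$counts

# decompose the fitted fluxes into constituent reactions
dec <- decompose(simulate_adipose(fit$par, coh$forcing))
fasting_rate(dec$time, dec$atl_rate)   # 0.235 umol/100 ml/min
peak_time(dec$time, dec$lpl_rate)      # 284 min (late TG-driven peak)

# insulin-resistance indices from fasting arterial samples
homa_ir(5.0, 10.0)   # 2.232143
adipo_ir(0.5, 60)    # 30
```

(The numbers above are the output of this exact script at these seeds;
a different seed gives a different cohort and fit.)

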