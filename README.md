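# abxselect

Counterfactual antibiotic selection for sepsis patients with neural
controlled differential equations.

## The problem

Choosing the initial antibiotic (or pair of antibiotics) for a sepsis
patient is a sequential decision under uncertainty: culture results arrive
days late, the first-line drugs differ in efficacy across pathogen classes,
and the two workhorses carry opposing toxicity profiles — Vancomycin is
nephrotoxic (creatinine), Ceftriaxone hepatotoxic (bilirubin total, alanine
transaminase). Electronic health records could inform this choice, but they
are irregularly sampled, heavily missing, and confounded: clinicians assign
treatments *because of* the covariates that also predict outcomes.

`abxselect` implements an online-updateable forecaster of the SOFA score
and the side-effect labs under each candidate treatment, and an iterative,
contraindication-aware selection procedure on top of it:

* **Encoder** — a neural CDE
  `x_t = x_0 + ∫ F_θ(x_s) dX(s)` driven by the *rectilinear* interpolation
  `X` of (time, covariates, cumulative missingness masks, treatment
  indicators), so that the latent disease state at time `t` depends only on
  data observed up to `t` and new measurements are assimilated online.
* **Decoder** — an uncontrolled neural ODE
  `x_{t'} = g_φ(x_{t+ε}, d) + ∫ f_φ(x_s) ds` initialized from the encoder
  state one hour past the decision time; candidate treatments enter only
  through the encoder's treatment channels at the decision hour.
* **Balancing** — the latent state is trained adversarially so it cannot
  predict upcoming treatment (`L = L_y − μ·L_a` for the encoder while the
  treatment head minimizes `L_a`), mitigating time-dependent confounding.
* **Rule layer** — SOFA subscore tables with trailing-24-h worst-value
  aggregation, Sepsis-3 onset labeling (SOFA ≥ 2 within −48/+24 h of a
  suspicion of infection), stage-1 AKI (creatinine +0.3 mg/dl in 48 h,
  1.5× the 7-day baseline, or urine < 0.5 ml/kg/h sustained ≥ 6 h), and the
  contraindication thresholds (creatinine > 2 mg/dl for Vancomycin;
  ALT > 280 U/L, bilirubin > 2.4/2.2 mg/dl for Ceftriaxone).
* **Selector** — enumerates singletons and pairs over the non-resistant
  antibiotics, forecasts each, and recommends the SOFA minimizer at the
  decision horizon (48 h at onset, then every 24 h), skipping warned
  options while a clean candidate exists, with de-escalation and
  fungal/viral-pathogen notifications.
* **Synthetic cohort** — real sepsis EHRs are credentialed-access, so the
  package ships a confounded simulator with shared-noise counterfactual
  ground truth under every option, making every stage testable end to end.

The numerical core (fixed-step RK4 through the CDE/ODE with full analytic
gradients) is compiled C++ (RcppArmadillo), cross-checked in the test suite
against a pure-R reverse-mode tape and dense-grid Euler oracles.

## Worked example

```r
library(abxselect)

# a confounded synthetic cohort with counterfactual ground truth
sim <- simulate_cohort(sim_config(n_patients = 120, seed = 7))
sim
#> <abx_sim> synthetic sepsis cohort
#>   patients:      120
#>   horizon:       96 h
#>   observations:  21126
#>   decisions at:  0, 48, 72 h

# preprocessing fitted on a training split, applied everywhere
sp   <- split_cohort(sim$cohort$statics$patient_id, seed = 1)
coh  <- function(ids) lapply(sim$cohort, \(tb) tb[tb$patient_id %in% ids, ])
prep <- fit_preprocess(coh(sp$train))
tr   <- prepare_tensors(coh(sp$train), prep, horizon_h = 96)
va   <- prepare_tensors(coh(sp$val),   prep, horizon_h = 96)
te   <- prepare_tensors(coh(sp$test),  prep, horizon_h = 96)

# two-stage training: encoder + heads with balancing, then the decoder
fit <- tecde_model(n_vars = tr$K) |>
  train_two_stage(tr, va, train_config(mu = 1, epochs_stage1 = 20,
                                       epochs_stage2 = 20, batch_size = 48))
glance(fit)
#> # A tibble: 1 × 9
#>   latent_dim n_vars n_treatments n_outcomes control_channels n_parameters
#>        <int>  <int>        <int>      <int>            <int>        <int>
#> 1          6      6            3          4               16         7525
#> # i 3 more variables: trained <lgl>, val_outcome_encoder <dbl>,
#> #   val_outcome_decoder <dbl>

# a treatment decision at sepsis onset, 48-h horizon
dec <- select_optimal(fit, te, coh(sp$test), t = 0, horizon = 48,
                      mode = "constrained")
dplyr::filter(dec, patient_id == dec$patient_id[1])[
  , c("option", "sofa_pred_end", "warned", "selected")]
#> # A tibble: 6 × 4
#>   option                                sofa_pred_end warned selected
#>   <chr>                                         <dbl> <lgl>  <lgl>
#> 1 Ceftriaxone                                    4.58 FALSE  FALSE
#> 2 Ceftriaxone + Piperacillin/Tazobactam          4.82 FALSE  FALSE
#> 3 Ceftriaxone + Vancomycin                       4.57 FALSE  FALSE
#> 4 Piperacillin/Tazobactam                        4.79 FALSE  FALSE
#> 5 Piperacillin/Tazobactam + Vancomycin           4.77 FALSE  FALSE
#> 6 Vancomycin                                     4.57 FALSE  TRUE
```

Each row is one candidate option with its forecast SOFA score 48 hours
ahead (lower is better); `warned` flags contraindications detected in the
observed history or the option-specific forecasts, and the selected row is
the warning-free minimizer. `autoplot(dec)` draws the ranking,
`plan_iterations()` runs the full clinical schedule, and `mse_grid()`,
`side_effect_contrast()`, `counterfactual_matching()` and
`average_treatment_improvement()` reproduce the evaluation procedures
(each with an `autoplot()` method).

*(Numbers above are from the code as run at the stated seeds; a fresh
install reproduces them exactly.)*

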