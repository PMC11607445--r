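---
title: "Counterfactual antibiotic selection for sepsis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual antibiotic selection for sepsis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Sepsis treatment success is tracked through the SOFA score (six organ
subscores, 0–4 each), and the first-line antibiotics differ both in their
efficacy against different pathogen classes and in their toxicity profiles:
Vancomycin is nephrotoxic (creatinine), Ceftriaxone is hepatotoxic
(bilirubin total, alanine transaminase). Choosing an antibiotic (or a pair)
for an individual patient is a sequential decision problem under three
obstacles characteristic of electronic health records: irregular sampling,
heavy missingness, and time-dependent confounding — clinicians choose
treatments *because of* the very covariates that predict outcomes, so naive
models attribute illness severity to the drugs given to the sickest
patients.

`abxselect` implements an online-updateable forecaster of the SOFA score
and the three side-effect labs under each candidate treatment, an
adversarially balanced training objective against confounding, a clinical
rule layer (Sepsis-3 labeling, stage-1 AKI, contraindication thresholds),
an iterative treatment selector, and a synthetic EHR simulator that
provides counterfactual ground truth — the quantity that can never be
observed in real data — so every stage of the pipeline is testable.

# Model

## Control paths and the encoder CDE

Each patient record is placed on an hourly grid ($t_0 = 0$ at sepsis
onset). The control path is the rectilinear interpolation of the channels
(time, $K$ selected variables, $K$ cumulative observation-count masks, $M=3$
binary treatment indicators): each hour contributes a *time-advance*
segment at held values followed by a *value-update* segment at constant
time. This ordering makes the path on $[0, t]$ depend only on data with
timestamps $\le t$, which is what makes the model online-updateable; the
reverse ordering breaks that property and is rejected by the causality
tests.

The encoder is a neural controlled differential equation: a latent state
$x_t \in \mathbb{R}^P$ with initial value $g_\eta(z_{t_0}, a_{t_0}, d)$
evolves as $dx = F_\theta(x)\, dX(s)$, where $F_\theta: \mathbb{R}^P \to
\mathbb{R}^{P \times C}$ multiplies the control increments. Because the
rectilinear control has piecewise-constant derivative, every segment is an
autonomous ODE; we integrate each with fixed-step classical Runge–Kutta
(default 2 substeps per segment). Fixed-step integration was chosen over
adaptive solvers deliberately: outputs are bit-reproducible, the
semigroup/restart property holds exactly, and at 2 substeps the solution
already agrees with a dense-grid Euler reference far below the $10^{-3}$
tolerance we test (4 substeps buys ~10× more accuracy for 2× cost and is
available via `substeps`).

At each grid hour the *one-step-lead* state (time advanced to $t$, data
$\le t-1$ assimilated) feeds two heads: the outcome head $h_\alpha$
predicting the four outcomes (SOFA, creatinine, bilirubin total, ALT, in
normalized units) and the treatment head $h_\beta$ predicting the
concurrent treatment administration. All maps are two-hidden-layer tanh
perceptrons (the architecture is a free choice; sizes are configuration).

## Decoder

Long-term forecasts come from an uncontrolled neural ODE initialized by a
transformation $g_\varphi(x_{t+\epsilon}, d)$ of the encoder state one hour
($\epsilon = 1$ h) past the decision time. No future data or treatments
drive the decoder: a candidate treatment enters *only* through the
treatment channels of the control path at the decision hour, and the
decoder then embodies "treatment continues unchanged" over the forecast
horizon (24 or 48 h). This is the only reading consistent with an
uncontrolled decoder that still produces treatment-dependent forecasts.
The decoder has its own outcome-head variant, warm-started from the
encoder head at the beginning of stage 2.

## Training objective and confounding balancing

The outcome loss is the mean squared error over *observed* outcome entries
(unobserved labs cannot contribute error; the normalizer is the count
of observed entries). The treatment loss is a
per-channel binary cross entropy — antibiotic pairs co-occur, so the link
is element-wise logistic rather than a softmax over options; a softmax
link is available behind `treatment_link = "softmax"`.

Balancing: the encoder is trained to *maximize* the treatment BCE so the
latent state carries no information about upcoming treatment assignment,
while the treatment head itself minimizes it (an adversarial pair). Both
shipped mechanisms — gradient reversal between the latent state and the
head, and an explicitly negated term with a head-gradient sign flip —
produce identical encoder updates; the tests verify the equivalence
analytically. $\mu$ controls the trade-off; $\mu = 0$ recovers plain
supervised training exactly.

The hours the balancing term applies to are configurable
(`balance_hours`). The default applies it at every grid hour, as in the
original objective. Because antibiotic treatments persist between
decisions, the all-hours objective also penalizes the latent state for
remembering the *ongoing* treatment — information a counterfactual
forecaster must keep. For the treatment-selection model we therefore
restrict the balancing to the treatment-assignment hours (the decision
times), where the prediction target is the genuinely upcoming, confounded
assignment; the latent's memory of already-administered treatment is left
alone. Both variants are tested against the reverse-mode tape.

Training is two-stage: stage 1 fits encoder + heads on one-hour forecasts
(loss from grid hour 1); stage 2 freezes the encoder, precomputes all
latent states once, and fits the decoder on long-term forecasts from
anchor hours drawn per update from hour 2 to two hours before the grid
end (read as hourly grid indices), predicting up to 48 h past each
anchor. The draw always includes the clinical decision anchors
(`anchors_include`, default the onset anchor) so the decoder trains most
where the selector predicts. For treatment selection the package
optionally fits a small decoder ensemble (extra stage-2 fits from fresh
decoder initializations on the shared encoder; forecasts average over
members), a plain variance-reduction device for the between-option
contrasts that leaves every causality and minimizer invariant intact.
An optional third stage (`epochs_stage3`) jointly refines all parameter
groups: the one-hour encoder loss plus the decoder losses from the
clinical decision anchors, with gradients flowing through the anchors
into the encoder at a reduced learning rate. The frozen-encoder stage 2
can only exploit whatever treatment-by-covariate structure stage 1
happened to leave in the latent state; the joint stage lets the long-term
counterfactual objective carve that structure in directly, which
stabilizes between-option contrasts considerably. The default remains the
plain two-stage protocol. Early stopping watches the validation outcome
loss in every stage. The inner loops (CDE/ODE forward and analytic
reverse sweep) run in compiled code; a pure-R reverse-mode tape
implements the same computation and serves as the gradient oracle in the
test suite.

# Preprocessing

* **Coverage filter**: variables measured in less than half of the
  patients are dropped (a variable at exactly 50% is kept).
* **Spearman screen**: the record is cut into 12-h bins; within each bin
  per-patient means of the candidate and of SOFA are pooled across
  patients and rank-correlated. A variable is selected if any bin exceeds
  $|\rho| > 0.3$. The within-bin aggregation is not pinned down by
  standard practice; per-patient bin means are the default and raw pooling
  is available (`aggregate = "raw"`). SOFA and the outcome labs are always
  retained.
* **Normalization**: per-variable z-scores. The statistics are fitted on
  the *training split only* and re-applied unchanged elsewhere — pooling
  over all patients would leak test-set statistics into the model;
  pooled-fitting is still possible by passing the pooled cohort.
* **Hourly rounding**: timestamps round to the nearest hour; within a
  (patient, variable, hour) collision the latest raw observation wins
  (preserves online causality; averaging is a flag).
* **Initial values**: the encoder cannot start from missing values, so
  admission vectors are completed by K-nearest-neighbour imputation
  (NaN-Euclidean distances on the normalized shared entries).
* **Masks**: one cumulative observation-count channel per variable
  (scaled by 1/10 so its increments are on the order of the normalized
  variables).

# The clinical rule layer

SOFA subscores come from breakpoint tables (data, not code — the
vasopressor tier conventions differ between sites and can be replaced);
the total is the sum over subscores of the trailing-24-h worst level, with
carry-forward of the last known level when a window is empty and 0 before
the first observation (avoiding artificial SOFA collapse under sparse
sampling). The "moving average ... based on the worst measured value" is
implemented as exactly this trailing-window worst — the aggregate itself,
not an additional smoothing pass. Suspicion of infection pairs an
antibiotic administration and a culture sampling (culture within 24 h
after, or antibiotic within 72 h after; boundaries inclusive); Sepsis-3
onset is the earliest SOI with a SOFA $\ge 2$ between 48 h before and 24 h
after it.

Stage-1 AKI follows the guideline disjunction: creatinine +0.3 mg/dl
within 48 h; creatinine at 1.5× the baseline (the *minimum* over the
previous 7 days — the conservative, guideline-typical aggregator, which
the source rule leaves open); or urine output below 0.5 ml/kg/h sustained
for a contiguous span of at least 6 h (spans longer than 12 h also
qualify — the 6–12 h wording bounds the stage, not an exclusion).
Contraindications: Vancomycin at creatinine > 2 mg/dl or any stage-1 AKI;
Ceftriaxone at ALT > 280 U/L or bilirubin total > 2.4 (men) / 2.2 (women)
mg/dl. Thresholds are evaluated on both the observed history and the
option-specific forecasts by default (`threshold_scope`), so warnings can
*anticipate* a contraindicative event.

# The selector

At a decision time the selector enumerates all singletons and pairs over
the non-resistant antibiotics (resistance results count once their report
time has passed), forecasts every option, attaches warnings, and picks the
option minimizing forecast SOFA at the horizon. Constrained mode skips
warned options while a clean candidate exists; when *every* candidate is
warned it still recommends the SOFA minimizer with explicit warnings
rather than refusing (sepsis is life-threatening; hard refusal is a
configuration). Ties break toward fewer antibiotics, then lexicographic —
the de-escalation preference. The schedule is: decision at onset with a
48-h horizon (initial efficacy cannot be judged earlier), then every 24 h
with a 24-h horizon; mid-window re-decisions are triggered by newly
arriving resistance results. A fungal or viral culture result notifies the
physician without changing the antibiotic ranking, and an observed SOFA
that is non-increasing and strictly lower over the trailing 48 h emits a
de-escalation notification.

# The synthetic cohort and what it does (not) show

Latent severity follows an Ornstein–Uhlenbeck-type mean-reverting
diffusion in SOFA units (Euler–Maruyama at 0.25 h), plus an additive drift
per treatment option: the option drift is the sum of its members'
per-pathogen-class efficacies (all zero for fungal/viral classes, which
exercises the notification path). Continuous SOFA is severity clipped to
[0, 24]. Side-effect labs integrate a severity coupling plus toxicity
drifts (Vancomycin → creatinine; Ceftriaxone → bilirubin, ALT), chosen as
pure drift terms so that noise-free toxicity excess has a closed form
(drift × exposure) used in the tests. Treatments are assigned at 0 h, 48 h
and then every 24 h by a softmax policy whose score increases with current
SOFA (sicker patients get combinations) and decreases with creatinine for
Vancomycin-containing options — this induces exactly the time-dependent
confounding the balancing term addresses, and the policy temperature
interpolates to an unconfounded randomized cohort. Observation times are
per-variable Poisson processes thinned by a missingness fraction, plus an
admission lab panel; pathogen classes shift admission labs so the class is
partially observable. All counterfactual paths of a patient share one
Brownian draw, so option contrasts are noise-free and the stored
best-option labels are sharp.

Defaults: 500 patients, 96-h horizon, decisions at 0/48/72 h, severity
noise 0.35 SOFA/√h, gram-positive-predominant pathogen mix
(0.45/0.25/0.15/0.10/0.05 over gram+/gram−/mixed/fungal/viral), efficacies
of order −0.02 to −0.10 SOFA/h, toxicities +0.010 mg/dl/h (creatinine
under Vancomycin) and +0.012 mg/dl/h / +1.2 U/L/h (bilirubin/ALT under
Ceftriaxone) — magnitudes set once so that treatment effects (a few SOFA
units over 48 h) stand in a realistic ratio to diffusion noise and lab
dynamics, and the three single-treatment factual groups stay populated.

What passing tests on this cohort demonstrate: the pipeline recovers known
rule constants exactly; the model's counterfactual ranking recovers the
simulator's true best options far above chance; balancing reduces latent
treatment predictability; toxicity contrasts carry the right signs. What
they do *not* demonstrate: performance on real EHR data — the simulator
has no discrete SOFA jumps, no regime changes, no unmeasured confounding,
far fewer variables, and its policy is a two-covariate softmax rather
than clinical judgment.

# Evaluation procedures

* **Forecast-error grids**: for each (observation time, horizon) cell,
  encode to the observation time, decode to the target hour, and
  accumulate squared error in units of the variable's variance over all
  pooled targets — a predict-the-global-mean baseline therefore pools to
  exactly 1, which is asserted to $10^{-6}$. Sparse labs get a centered
  5-cell moving average along the observation-time axis.
* **Side-effect contrast**: patients on single antibiotics are sampled in
  balanced numbers per factual group without replacement; both contrast
  antibiotics are simulated from the factual treatment start for 72 h and
  per-patient differences are returned (densities are visualization only).
* **Counterfactual matching**: patients whose factual treatment differs
  from the recommended optimum are matched (Euclidean distance on all
  normalized onset covariates, ties by patient id) to patients factually
  given that optimum; the factual-matching arm quantifies how much of the
  discrepancy is plain patient-to-patient variability. Confidence bands
  are normal-approximation over pairs (bootstrap is a flag).
* **Average treatment improvement**: forecast SOFA under the selected
  optimum minus under the factual option, averaged with a 95% band, and
  integrated over the 48-h initial phase by the trapezoid rule; in
  unconstrained mode the value at the selection horizon is non-positive by
  construction of the argmin.

# Study sizes and reproducibility

The shipped synthetic study uses 500 patients (360/40/100
train/validation/test at patient level — the 400 train+validation records
form the training pool), a 96-h grid, and two-stage training with Adam
(learning rate 0.01, minibatches of 100 patients, up to 80 encoder and 60
decoder epochs with early-stopping patience 12). These sizes keep the full
study — two balancing arms plus the treatment-selection model — at a few
minutes of CPU while leaving the acceptance margins wide. Every random
step (simulation, splits, minibatch order, anchor draws) is governed by
explicit seeds, and `scripts/acceptance.R` re-runs the whole study from a
single seed argument. Hyperparameter search is deliberately out of scope;
the defaults are fixed, and a tuning hook can wrap `train_config()` if a
user wants one.

# Known limitations

Binary treatment channels (no dosing); no uncertainty quantification on
forecasts; the decoder cannot anticipate discrete SOFA jumps; balancing
trades outcome accuracy against confounding robustness through a single
scalar $\mu$; the simulator's realism limits are listed above.

Two stability caveats deserve emphasis. First, the adversarial balancing
game does not converge to the same equilibrium from every initialization:
runs can pass through an *anti-predictive* transient in which a freshly
refit probe reads the distorted latents at high AUC before the invariant
regime is reached, so the latent-predictability drop between $\mu = 0$
and $\mu = 1$ varies with the training seed. Second, per-patient
best-option recovery varies across simulated cohorts (roughly 0.4--0.7
against a 1/6 chance level in our runs): the hardest contrasts are
between near-equivalent antibiotic pairs, and patients with fungal or
viral pathogens — for whom all options are truly equivalent — can only be
matched through the de-escalation tie-break. These mirror the method's
own stated boundaries and are the natural next steps.
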