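---
title: "Population PKPD modelling of clonidine and midazolam sedation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PKPD modelling of clonidine and midazolam sedation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedpkpd)
```

# The problem

Mechanically ventilated children in intensive care need continuous sedation,
usually midazolam or clonidine on top of a morphine background, but target
concentrations and doses in this population are poorly established. This
package implements a complete population pharmacokinetic–pharmacodynamic
(PKPD) workflow for that setting: structural PK models for both drugs,
a concentration–effect model for the COMFORT-B sedation score (integer scale
6–31, lower = deeper sedation), a nonlinear mixed-effects estimator with the
standard evaluation tools (bootstrap, prediction-corrected visual predictive
check, likelihood-ratio covariate testing), a pharmacogenetic screen, a
virtual-trial generator emulating a blinded randomized titration trial, and
forward simulation of dose regimens in virtual populations.

Because individual-level trial data of this kind are not publicly
distributable, the package is organized around *simulation-based validation*:
the generator creates trials with exactly the statistical structure the
models assume, and every estimator is judged by its ability to recover the
generating parameters.

# Structural pharmacokinetics

Clonidine follows a one-compartment model with zero-order infusion input,

$$\frac{dA}{dt} = \mathrm{in}(t) - \frac{CL}{V}A, \qquad C = A/V,$$

and midazolam a one-compartment parent with complete conversion to its
1-OH metabolite in a second compartment,

$$\frac{dA_1}{dt} = \mathrm{in}(t) - \frac{CL_m}{V}A_1,\qquad
\frac{dA_2}{dt} = \frac{CL_m}{V}A_1 - \frac{CL_{om}}{V_m}A_2 .$$

Every dose is a zero-order infusion (a bolus is a short infusion; loading
doses run over 15 minutes, the administration time used for both blinded
drugs). Both systems are linear with piecewise-constant input, so the
package evaluates them with exact piecewise-analytic superposition over dose
events (`conc_clonidine()`, `conc_midazolam()`); `conc_ode()` integrates the
same equations with a general-purpose solver (deSolve) as an independent
cross-check, used in the test suite on randomized regimens. The catenary
solution switches to its series limit when the two rate constants are within
`1e-8` of each other.

Size and age enter a priori: allometric weight scaling to a 70-kg reference
(exponent 0.75 on clearances, 1 on volumes) and a sigmoidal postmenstrual-age
(PMA) maturation function on clearances only,

$$MF(PMA) = \frac{PMA^{h}}{PMA_{50}^{h} + PMA^{h}},$$

with constants fixed per drug (clonidine: $PMA_{50}=61.6$ weeks, $h=2.42$;
midazolam: $73.6$ weeks, $h=3$). Whether maturation should also multiply the
metabolite elimination clearance is not settled; the default applies it to
both clearances (`mature_clom = TRUE`), since 1-OH midazolam elimination is
itself a hepatic process maturing on a similar time scale, and the choice is
exposed as an argument. Interindividual variability (IIV) is lognormal and
diagonal: clearance and volume for clonidine, formation clearance and parent
volume for midazolam. Residual error is proportional for clonidine and
combined additive + proportional for each midazolam analyte.

Units are fixed throughout: hours, kg, µg doses, L volumes, ng/mL
concentrations (1 µg into 1 L = 1 ng/mL); any conversion belongs at the I/O
boundary.

# The COMFORT-B score model

The expected score is an additive composition floored at the scale minimum:

* Nonsurgical subjects start from a baseline score $B_0$.
* Subjects arriving from major surgery start at the scale minimum
  ($BASE = 6$, complete anesthesia) and wash out toward an awake ceiling
  $SMAX = BASE + PAE_{max}$ following an Emax function of the time after
  surgery, $PA(t) = BASE + PAE_{max}\, t/(T_{50}+t)$.
* The sedative subtracts an inhibitory sigmoid Emax effect
  $E_{max} C^{\gamma} / (EC_{50}^{\gamma} + C^{\gamma})$ with $E_{max}$
  fixed to 6 (the full depth of the scale) and $\gamma = 1$ by default; no
  estimate of a steeper sigmoid is available, and $\gamma=1$ preserves the
  half-maximum identities the tests rely on. The driver is the individual
  predicted concentration of the assigned drug (supplied per score row in
  the `CONC` column), never the dose — in a titrated trial dose-driven
  effect models are confounded by the feedback between score and dose.
* Co-medication whose concentrations were never measured (bridging
  propofol) acts through a K-PD model: a virtual compartment
  $dA/dt = \mathrm{rate}(t) - k_{de}A$ whose elimination flux
  $IRE = k_{de}A$ drives an Emax term. Its constants are fixed synthetic
  placeholders (`propofol_kpd_params()`), never estimated.

The two arms are mutually exclusive per subject, so the joint model is the
additive union of the per-arm models with a shared $T_{50}$; restricted to
one arm's data it reduces exactly to that arm's model (a property test).
IIV is on $EC_{50}$ only, lognormal; residual error is proportional per arm.
The latent model is continuous; *reported* scores are rounded to integers
and clamped into $[6, 31]$ after residual error. The floor at 6 is a hard
truncation, not a soft bound. For the midazolam arm the nonsurgical
baseline is each subject's observed score at the first assessment (a fixed
per-subject covariate); for clonidine $B_0$ is an estimated parameter.

# Estimation

`pkpd_fit()` maximizes a Laplace approximation to the marginal likelihood —
the implementable equivalent of first-order conditional estimation with
interaction: residual variances depend on the individual predictions, so
the interaction term is inherently included. For every candidate value of
the fixed effects the conditional modes of all subjects' random effects are
found *jointly*: gradients and Hessians of each subject's penalized
individual objective come from finite differences of global objective
evaluations (one evaluation prices the whole population), followed by a
per-subject modified-Newton step with eigenvalue flooring and an
expanding/backtracking line search. Convergence is declared on the Newton
decrement (the expected objective improvement, tolerance `1e-8`), which is
robust to finite-difference gradient error; subjects whose expected
improvement stays above `1e-4` fall back to a per-subject derivative-free
search. The approximation error of the Laplace integral was checked against
direct two-dimensional quadrature on small datasets during development, and
the whole engine is pinned exactly (to `1e-6`) against the closed-form
marginal likelihood of a degenerate linear mixed model and against lme4 on
a repeated-measures variant — both tests ship in the suite.

The outer problem is solved by a damped BFGS on log-transformed parameters
(identity transform for covariate coefficients): central-difference
gradients with step `1e-3`, a trust cap of 0.7 log units per step,
backtracking with a steepest-descent rescue, and restart rounds — long
curved valleys (e.g. the clearance/volume/variance coupling of sparse
designs) defeat a single quasi-Newton trajectory, so whenever a round
stalls after making progress the approximation is rebuilt at the incumbent.
The random-effect reference used to warm-start the inner solver advances
only at accepted outer steps, keeping each line search internally
consistent. Off-the-shelf optimizers (PORT, `optim`'s BFGS) terminated far
from the optimum on these surfaces because their line searches cannot
tolerate the small deterministic noise the inner solver leaves. A
multi-start option (`settings$n_starts`, perturbed starts with a fixed
seed) exists; the default is a single start, which the restart mechanism
made sufficient on every design exercised by the tests.

Standard errors come from the numerical Hessian of the objective at the
optimum, delta-transformed to the natural scale, and are reported only when
that matrix is positive definite. IIV percentages are displayed in both
conventions — $100\sqrt{e^{\omega^2}-1}$ (CV of the lognormal, the primary
convention throughout the package, also used when converting generating
percent-CVs to $\omega$) and the simpler $100\,\omega$ — because published
tables rarely say which one they use.

Any parameter can be held fixed (`fix =` in the model constructors), which
is how the published FIX semantics (maturation constants, $E_{max}$, $BASE$,
clonidine $PAE_{max}$) are expressed. Covariates enter clearances or volumes
exponentially, $\theta\,e^{\beta(x - x_{ref})}$, and are judged by the
likelihood-ratio test (`covariate_test()`; forward inclusion at
$\alpha = 0.05$, i.e. a drop of 3.84 points for one parameter). Records
below the limit of quantification are imputed at LOQ/2 (`blq_impute()`),
never dropped.

# Model evaluation

`bootstrap()` resamples subjects with replacement, refits from the original
estimates and reports medians with 90% percentile intervals; failed
resamples are counted, never silently ignored. `pc_vpc()` implements the
prediction-corrected visual predictive check: observations and simulations
are rescaled by the ratio of the bin-median population prediction to the
record's own population prediction, binned on quantile-spaced time breaks
(empty bins are dropped with a warning), and the observed 5th/50th/95th
percentiles are compared with simulation confidence bands. When all
subjects share covariates and doses the correction is a constant, and the
pcVPC provably equals the uncorrected VPC (a test).

# The pharmacogenetic screen

`screen_snps()` reproduces the two-step screen: SNPs with minor allele
frequency below 5% are excluded; the rest are tested for Hardy–Weinberg
equilibrium with a 1-df chi-square on genotype counts (exclusion below
p = 0.001, a conventional QC threshold — the original procedure tested HWE
without stating a cut); surviving SNPs are regressed (additive 0/1/2
coding, complete-case per SNP) against log individual clearances — the
empirical Bayes estimates from the population fit — and selected at the
Bonferroni-corrected level $0.2/m$. Selected SNPs become two-category
carrier covariates (`group_carriers()`) for testing inside the population
model. The regressions are genotype-only: size and maturation are already
absorbed by the model before the EBEs are formed.

# The virtual-trial generator

`simulate_trial()` emulates the design the analysis assumes: ~28 subjects
(configurable), 1:1 randomization, PMA drawn from a beta shape over 36–372
weeks that concentrates mass at term neonates (matching a PICU census with
median PMA near term and a long right tail), gestational age 36–40 weeks,
weight from a monotone sigmoidal weight-for-PMA curve (asymptote 20 kg,
half-point 150 weeks, shape 1.2, 13% lognormal spread — chosen so a term
neonate weighs about 3 kg and a six-year-old about 15 kg, the corridor of a
critically ill population) — the published virtual populations used a
different growth function whose coefficients are not available, and only
the covariate *structure* matters for testing the models. Surgery and
bridging-propofol status are Bernoulli per arm at the observed trial
frequencies; the end of surgery is set to the start of treatment, so time
after surgery equals study time.

Dosing follows the blinded protocol: clonidine 2 µg/kg loading over 15 min
then 1 µg/kg/h; midazolam 200 µg/kg then 100 µg/kg/h; both halved for
neonates younger than 28 days. Every 3 h the maintenance rate is titrated
against the observed (noisy, rounded) score with a simple two-threshold
band rule — raise one step if the score exceeds 22, lower if below 11,
within protocol bounds — a deliberate simplification of the full bedside
algorithm, which also used a nurse-interpretation score that is not
simulated; titration realism, not fidelity, is what the recovery
experiments need. Assessments are scored every 3 h with additional
assessments 30 min after the start of treatment and after every rate
adjustment, as the protocol prescribed. PK sampling is sparse: one sample
shortly after the loading dose and one just before the end of treatment
(the two mandatory samples) and any further samples uniform, with the
per-subject total drawn from the design (`n_pk_samples`, default 2–4; the
protocol ceiling was six). Concentrations below the analyte's LOQ are
flagged BLQ with the value withheld. An optional exponential covariate
effect on a clearance (`cov_effect`) supports the covariate-test power and
type-I experiments, and `generate_genotypes()` supplies Hardy–Weinberg
genotypes for the screen.

What the generator does *not* emulate: morphine dosing and effect (found
negligible on this score in the source analysis), ketamine, adverse events,
dropout, assay error structure beyond the fitted residual models, and
real-world deviations from protocol. Passing recovery tests therefore shows
the estimator is consistent *under the model's own assumptions*, not that
the model is true of real children.

# Recovery experiments and their design choices

The acceptance experiments (`scripts/acceptance.R`, mirrored at reduced
replicate counts in `tests/testthat/test-acceptance.R`) regenerate and
refit replicate trials of 50 subjects per arm and compare the median
estimate across replicates with the published values:

* **PK recovery** uses the two mandatory samples plus 2–4 further samples
  (4–6 per subject, within the protocol's ceiling of six). Twenty
  replicates per arm in the script, fewer in the tests to keep the default
  run short; replicate counts and sizes are stated where they are used.
* **PD recovery** uses scores every 3 h over 48 h. The EC50 IIV is
  *generated* at 50% CV — at the enormous IIV actually reported (246% and
  525% CV) a 50-subject design cannot recover the typical value, which is
  why those published estimates carry no usable precision — and the fit
  *conditions on that known IIV* (`fix = "omega_ec50"`). With the variance
  free, the marginal likelihood of a titrated, saturating design rises
  along a ridge toward a tiny typical EC50 with huge variance (a
  responder/nonresponder mixture); we verified with exact Gauss–Hermite
  quadrature that this is a property of the likelihood itself, not of the
  Laplace approximation, so the recovery experiment holds the variance at
  its known generating value. For the midazolam arm the finite-sample ML of
  EC50 is additionally skewed by a trade-off with the washout amplitude
  (a lower ceiling compensates a weaker drug effect), and the recovery
  conditions on the known washout ($PAE_{max} = 9.3$, $T_{50} = 0.11$ h) —
  mirroring how the final joint analysis carried all midazolam parameters
  as fixed values — leaving EC50 and the residual error estimated. The
  clonidine arm estimates $B_0$, EC50 and $T_{50}$ with its washout
  amplitude fixed, exactly as in the published model structure.
* **Regimen simulation** generates 1000 virtual children with postnatal
  age above 28 days, individualizes the clonidine PK parameters with full
  IIV, simulates 4 µg/kg over 15 min followed by 3 µg/kg/h for 12 h on a
  0.1-h grid, and reports the first time the median concentration reaches
  the model EC50 (2.73 ng/mL). The published claim is that this happens
  about 3 h after the first dose; the simulated score bands use a baseline
  of 15 and no residual error (the typical-trajectory reading of such
  plots; `residual = TRUE` adds it).

# Numerical choices and degenerate inputs

* Analytic PK solutions are the reference path everywhere; the ODE route
  exists only as a cross-check.
* The inner Newton uses finite-difference steps of `1e-3` on the
  random-effect scale; Hessian eigenvalues are floored at `1e-2` (the
  random-effect prior guarantees curvature of order $2/\omega^2$ anyway).
* Residual SDs are floored at `1e-12` to keep zero predictions from
  producing infinite objectives; a proportional-error observation at a
  structurally zero prediction is a design error the validator reports.
* Monomorphic SNPs get MAF 0 and are excluded, not an error; a screen that
  filters everything returns an empty selection with a warning.
* Bolus doses are short infusions by construction, so a zero-duration dose
  cannot arise; dose rows with nonpositive RATE are rejected.
* `blq_impute()` refuses BLQ records whose analyte has no configured LOQ.
* Subjects observed before any dose have zero predicted concentration —
  valid for score records (the pre-dose baseline), invalid for fitted
  concentration records under proportional error.

# Known limitations

* $\Omega$ is diagonal; correlated random effects are not supported (none
  are reported for these models).
* The Laplace engine supports at most two random effects per subject —
  enough for every model here, by design rather than generality.
* The midazolam EC50 is weakly identified even at 50% CV IIV; its
  replicate-to-replicate spread is large, and only the median across
  replicates is a stable quantity.
* `TPS50` (0.11 h) is much shorter than the 3-h assessment interval; it is
  estimable only through the 30-min extra assessments and remains noisy.
* The estimator is validated against data generated by its own model
  family. Structural misspecification — nonlinear kinetics, tolerance,
  circadian effects on the score — is out of scope.
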