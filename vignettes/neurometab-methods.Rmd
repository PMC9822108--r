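---
title: "Modelling stimulated visual-cortex metabolism and its neurovascular coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stimulated visual-cortex metabolism and its neurovascular coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurometab)
```

## The model

`neurometab` implements a minimal kinetic model of stimulated central
metabolism in the human visual cortex, its coupling to a neurovascular
(hemodynamic) submodel with a BOLD observable, and the statistical
machinery used to estimate and criticise such models against functional
MRS and fMRI percent-change time courses.

### Metabolism

The metabolism model is a mass-action / Michaelis-Menten network around
a condensed TCA cycle, driven by a visual stimulus. A binary step input
$u(t)$ (1 during a stimulation epoch, 0 otherwise) feeds a first-order
stimulus state,

$$\frac{d\,\mathrm{Stimulus}}{dt} = k_{stim1}\,u(t) -
  k_{stim2}\,\mathrm{Stimulus},$$

which accelerates glycolysis. Glucose enters the local circulation at a
constant rate, crosses into tissue by mass action, and is consumed by
glycolysis at rate
$V_{glycolysis} = k_{max,gluct}\,Gluc_t\,(1 + \mathrm{Stimulus})$.
Pyruvate is drained by lactate dehydrogenase (mass action), pyruvate
carboxylase (Michaelis-Menten), and the condensed first half of the TCA
cycle,

$$V_{TCA1} = k_{maxPO}\,
  \frac{Pyr}{K_{M,Pyr} + Pyr}\,\frac{OAA}{K_{M,OAA} + OAA},$$

with a single maximal-rate prefactor multiplying both saturation
factors, used consistently in the pyruvate, OAA and OG equations (an
alternative typesetting that repeats the prefactor inside one factor
is rejected as inconsistent across the three equations). OAA and OG cycle through TCA1/TCA2,
OAA transaminates to aspartate, OG to glutamate, and glutamate
exchanges with glutamine through the synthetase/glutaminase pair. The
glutamate/glutamine exchange terms are implemented with the exchange
arithmetic stated above (glutamate gains
$k_{maxGln}\,Gln$ and loses $k_{maxGlut1}\,Glut$, glutamine mirrors),
irrespective of how the verbal labels attach the enzyme names to the
two directions. Concentrations are in arbitrary units throughout, which
is why every observable carries an unknown scale factor.

Observables are percent changes from the pre-stimulus steady state,

$$\hat y_i(t) = k_{y,i}\left(\frac{X_i(t)}{X_i^{ss}} - 1\right)\cdot
  100\,\%,$$

for $X_i \in \{Lac, Glut, Gluc_t, Asp\}$ (and BOLD in the combined
model). The ratio convention $X/X^{ss}$ follows the verbal definition
of the normalization (divide by the steady-state value, subtract one).

### The neurovascular submodel and the combined model

The combined model replaces the standalone stimulus and glucose
equations with a neurovascular submodel and couples it into the
pyruvate equation:

$$\frac{d\,Pyr}{dt} = V_{baseMet} + V_{stimMet} - V_{TCA1} - V_{LDH}
  - V_{PC},$$

with
$V_{baseMet} = Glucose_A\,k_{basalMet}\,O_{2A}\,k_{prop1}$ and
$V_{stimMet} = Glucose_A\,Delay_M\,O_{2A}\,k_{prop2}$ — products of
the states and rate constants, not powers (of the two readings an
ambiguous typesetting admits, the product form is adopted; a
transcribed neurovascular document can express the power form directly
in its rate expressions if wanted). Tissue glucose
is identified with the neurovascular state $Glucose_A$.

Detailed neurovascular models are published only as supplementary
equation sets, so the package ships a documented *surrogate*
neurovascular submodel: a minimal feed-forward hemodynamic
model exposing exactly the quantities the coupling contract needs
($Glucose_A$, $O_{2A}$, $Delay_M$, $dHb$, $V_{baseMet}$,
$V_{stimMet}$). A fast neural drive feeds (i) the metabolic
intermediate $Delay_M$, (ii) a three-stage low-pass flow cascade
setting blood flow $CBF = 1 + a_F\,Fl$, and (iii) a venous volume
$V_v$ with its own (sub-flow) coupling $a_V$ and time constant
$\tau_v$. Deoxyhaemoglobin is produced in proportion to a fast
stimulus-driven oxygen-extraction term
$k_{dhb}(k_{basalMet} k_{prop1} + k_{dip} Delay_M)$ and washed out at
rate $k_{wash}\,CBF/V_v$; the BOLD signal is $e^{-k_y\,dHb}$, and the
BOLD observable applies the percent-change normalization with its own
scale factor on top of $k_y$ (only the product of the two scale
parameters is identifiable; both are kept for interface fidelity).
Driving deoxyhaemoglobin production from the fast rate term rather
than from the absolute glucose flux is what lets the BOLD response
finish within ~20 s while the metabolite responses are still evolving
over minutes — the separation of timescales the combined model is
meant to expose.

The surrogate's defaults were calibrated once so a 0.5 s stimulus
produces the archetypical BOLD response — an initial dip (oxygen
extraction leads the flow response) with minimum near 2 s, a main peak
near 5–7 s (flow-driven washout), a shallow post-peak undershoot
around 10–16 s (volume outlasting flow), and return to within 0.05% of
baseline by 20 s even for a pair of 0.5 s stimuli 4 s apart. Users can
substitute a transcribed neurovascular model as a JSON model document;
`combine_models()` validates that every contract symbol resolves.

A sign-inverted, reduced-amplitude copy of the BOLD observable
(`BOLDneg`, default relative amplitude 0.4) stands in for the negative
BOLD response of a different cortical region; the mechanism producing
genuinely negative responses lives in the full neurovascular model and
is out of scope for the surrogate.

### Reference parameters

No parameter values are published for this model family in a usable
form, so the package ships a plausible reference set
(`reference_parameters()`, `nvc_reference_parameters()`), calibrated
once so that sustained stimulation reproduces the reported qualitative
pattern (lactate ≈ +15–20%, glutamate ≈ +4%, glucose ≈ −15%, aspartate
≈ −5%), response amplitudes saturate for stimulations of a few hundred
seconds with the reported ordering (lactate/aspartate before glutamate
before glucose), and the BOLD features above hold. These defaults are
the package's study conditions; all synthetic data generation and
recovery experiments run at them.

## Simulation

Models are declarative documents (states, parameters, named rate
expressions, ODEs as signed sums of rates, observables), serializable
as JSON so submodels can be swapped and inspected as text. The two
packaged models additionally carry compiled (C) right-hand sides used
by `deSolve::lsoda`; arbitrary documents run through a generic
interpreter, and a test asserts both paths agree. Integration uses
relative tolerance 1e-8 and absolute tolerance 1e-10 and restarts at
every epoch boundary, because the step input violates the solver's
smoothness assumptions; the input is constant within each segment.
Steady states are obtained by reducing the balance equations to a
two-variable root-finding problem in pyruvate and OAA (damped Newton in
log space) for the packaged models, or by a long pre-simulation plus
damped Newton for arbitrary documents; in both cases the result must
satisfy $\|f\|_\infty < 10^{-9}$ and non-negativity or an error names
the failing state. Degenerate paradigms are tolerated: a zero-length
epoch is a no-op, an epoch starting at $t = 0$ is an immediate onset.

## Likelihood, rejection test, and fitting

The negative log-likelihood under independent Gaussian errors is

$$J(\theta) = \tfrac12 \sum_{e}\sum_{o}\sum_{s}
  \left[\log\!\big(2\pi(\sigma_s^{e,o})^2\big) +
  \left(\frac{y_s^{e,o} - \hat y_s^{e,o}(\theta)}{\sigma_s^{e,o}}
  \right)^2\right],$$

with the per-sample SEM as $\sigma$. Because the normalization term
does not depend on $\theta$, optimization and the rejection test work
with the chi-squared statistic
$\sum \big((y - \hat y)/\sigma\big)^2$, which at the true parameters is
chi-squared distributed with one degree of freedom per residual. That
statistic is what fit summaries print as $J(\theta^*)$, matching how
such fits are conventionally reported. The rejection test compares it
against `chi2_threshold(alpha, dof)` with `dof` equal to the total
residual count; a statistic exactly at the threshold passes (the
boundary convention is documented because the source is silent). The
acceptable-set criterion used for uncertainty instead uses `dof` equal
to the number of sampled parameters — the two degree-of-freedom
conventions serve different purposes and both are exposed.

Fitting (`nmc_fit()`) runs multi-start Levenberg-Marquardt
(`minpack.lm`) on the weighted residual vector in log10 parameter
space within box bounds (default 1e-6..1e6). Two numerical points
matter: the finite-difference step of the residual Jacobian must
exceed the ODE solver tolerance (otherwise the Jacobian is integration
noise; `epsfcn = 1e-6` gives steps of ~1e-3 decades), and random
starts are rejection-sampled for feasibility, because wide draws can
violate the positivity constraints of the steady state where the
objective is flat and a local search cannot recover. Simulation
failures during search return an infinite objective rather than
raising, so the search continues. The enhanced-scatter-search
implementation used in the original study is not mandated; multi-start
LM in log space is the package's choice of global strategy.

## MCMC uncertainty and prediction envelopes

`mcmc_sample()` is an adaptive random-walk Metropolis sampler in log10
space targeting $\exp(-\mathrm{stat}/2)$. The proposal is
preconditioned with a Gauss-Newton covariance approximation at the
optimum (flat directions floored at 1e-6 of the leading curvature),
then shaped adaptively by the running sample covariance, with the
global scale tuned toward an acceptance rate of 0.23 in windows of 200
draws. A temperature argument flattens the target to
$\exp(-\mathrm{stat}/(2T))$; the default for fit posteriors is $T = 2$,
and level-set mapping runs (e.g. the recovery experiments) use $T = 5$,
because the quantity of interest is the *acceptable set*

$$\{\theta : J(\theta) \le J(\theta^*) +
  \Delta_{\alpha}(\chi^2_{\mathrm{DoF}})\},\qquad
  \mathrm{DoF} = \text{number of parameters},$$

whose retained draws (always judged at temperature 1) drive the
pointwise min/max prediction envelopes, not strict posterior
expectations. The default run length is 1e4 draws with 10% burn-in
(1e5 is recommended for final analyses); seeds and acceptance rates
are recorded. Envelopes always include the optimal draw, so they
contain the best-fit trajectory by construction.

## Structural identifiability

Local structural identifiability is assessed through the rank of the
Jacobian of the stacked output derivatives
$(y, \dot y, \ldots, y^{(k)})$ at $t = 0$ with respect to all initial
states and parameters. Derivatives are computed exactly: truncated
power-series (Taylor) arithmetic propagates the state series through
the right-hand side, output expressions are evaluated on the series,
and differentiation uses the complex-step method, which has no
subtractive cancellation. Evaluation points are drawn log-uniform in
[0.1, 10]; singular values below `max(dim) * eps * sv_max` count as
zero; a quantity is unidentifiable at order $k$ when its column
participates in the Jacobian's null space; classification is by
majority vote over 5 random points with discordance flagged. The
stimulus input is treated as a generic differentiable signal (random
Taylor coefficients per trial), the convention of differential-algebra
identifiability analysis; holding it constant instead merges
$(\mathrm{Stimulus}_0, k_{stim1}, k_{max,gluct})$ into a spurious
affine symmetry and the model never becomes fully identifiable.

Two findings are worth recording. First, with the observable scale
factors $k_{y,i}$ treated as unknowns, the model is *never* fully
identifiable: a global concentration rescale (all concentrations and
Michaelis constants scaled together, with compensating rate constants
and scalings) and a glucose-branch rescale are exact symmetries for any
input. The identifiability analysis therefore uses the raw metabolite
states as outputs, the only configuration under which full
identifiability is attainable.
Second, for the 29 unknowns (10 initial states + 19 kinetic
parameters) and 4 outputs, full identifiability first occurs in our
computation at derivative order $k = 7$ (the value plus seven
derivatives, i.e. eight measurement-signal levels; 32 rows is also the
first order at which 29 columns can possibly have full rank). Reference
analyses of this model report that eight derivatives suffice; our
computation confirms sufficiency at order 8 and additionally finds
order 7 sufficient, a one-step discrepancy that most plausibly
reflects a counting convention (number of signal levels versus highest
derivative order) or the treatment of the input, and that no choice of
rank tolerance removes — the boundary singular value at order 7 is
10^-8–10^-6 of the leading one, orders of magnitude above the
numerical noise floor. `minimal_order()` reports the smallest
sufficient highest-derivative order.

## Synthetic data

The generator emulates the visual-stimulation designs the model
targets: single 13.2-min stimulation (with a 13.6-min variant exposed, since
both durations appear in published descriptions of this design),
double 9.9-min blocks, a 0.5-s BOLD stimulus sampled every 0.5 s,
a 5-min block design with 75 samples over 25 min, and a 5.3-min block
design sampled at 2.7-min resolution (9 samples per metabolite).
Epoch arithmetic is exact (stated minutes times 60). Noise is
independent Gaussian with per-observable standard deviations
(defaults: 2 percentage points for lactate and glutamate, 3 for
glucose, 1.5 for aspartate, 0.1 for BOLD) approximating published
error-bar scales; the nominal value is recorded as the per-sample SEM.
Because metabolite sampling resolutions for the long designs are not
stated, those are sampled uniformly (2-min and 2.5-min spacing).
What passing recovery tests show is therefore internal consistency of
the pipeline under the stated designs and noise scales — not that the
model explains real spectroscopy data, which carries subject
variability, drift, and non-Gaussian artifacts the generator
deliberately omits.

## Experiment drivers and problem sizes

`run_estimation()` fits all estimation datasets jointly (232 residuals
under the default designs), `run_validation()` predicts the validation
designs with the optimal parameters unchanged (asserted by a parameter
hash), `amplitude_vs_duration()` sweeps 25 log-spaced stimulation
lengths from 0.5 to 10000 s recording each metabolite's peak absolute
percent change *during the stimulation epoch* (the driven response;
including the post-stimulus rebound makes the amplitude very slightly
non-monotone and is not what a saturation analysis wants), and
`short_stimulus_prediction()` simulates the two-0.5-s-stimulus
paradigm. The plateau onset is defined as the first duration reaching
99% of the asymptotic amplitude — the package's own operationalization
of "roughly maximal". Default test and acceptance runs use the reduced
MCMC budget (1e4 draws) and the sampling grids above; they complete in
minutes on a single core.

## Known limitations

* The neurovascular submodel is a surrogate: it reproduces the
  archetypical BOLD features and honours the coupling contract, but its
  internal states are not those of the published hemodynamic model, its
  parameter count differs (the packaged combined model has 42
  parameters: 35 ODE-level constants, the BOLD exponent, and 6
  observable scale factors), and no quantitative
  BOLD-parameter estimate transfers.
* The negative BOLD observable is a scaled mirror image, not a
  mechanism.
* Metabolite concentrations are in arbitrary units; only scaled
  percent changes are meaningful.
* Compartmentalization (neuron/glia), glycogen metabolism, and
  oxygen-dependent TCA flux are intentionally excluded, following the
  minimal-model design philosophy: complexity beyond what the data can
  constrain degrades identifiability without improving the fit.
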