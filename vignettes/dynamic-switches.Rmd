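---
title: "Dynamic bistable switches: models, detectors and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic bistable switches: models, detectors and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynswitch)
```

## The model

The package is built around a minimal model of a protein that exists in an
active form $X$ and an inactive form, with total $X_T$. The protein
promotes its own activation and inhibits its own inactivation:

$$\frac{dX}{dt} = f(X)\,(X_T - X) - g(X)\,X, \qquad
f(X) = a + \frac{b\,X^n}{K^n + X^n}, \qquad
g(X) = a' + \frac{b'\,K'^m}{K'^m + X^m}.$$

With steep Hill feedback ($n = m = 5$) the steady-state response of $X$ to
$X_T$ is an S-shaped bistable curve whose knees are saddle-node (fold)
points: the upper knee of the low branch is the inactivation-side threshold,
and the $X_T$ value of the right fold is the activation threshold. The
biological reading is mitotic entry: $X$ plays the role of active
Cyclin B--Cdk1, $X_T$ of total Cyclin B, and the basal activation rate $a$
of Cdc25 activity.

The standard parameter set used throughout is $b = 1$, $K = 1$, $n = 5$,
$a' = 0.1$, $b' = 1$, $K' = 1$, $m = 5$, with timescale separation
$\varepsilon = 0.05$: activation/inactivation run a factor
$1/\varepsilon$ faster than production and degradation. These are the
defaults of `feedback_params()`.

Three deterministic variants build on the scalar kinetics
(`simulate_switch()`):

* **transition** — $dX_T/dt = k_X$: constant synthesis pushes the system
  across the activation threshold once;
* **oscillator** — $dX_T/dt = k_X - X_T X$: active protein drives
  degradation of both forms, producing relaxation oscillations for
  intermediate $k_X$. The $-X^2$ self-degradation term is dropped from the
  $X$ equation by default so the bistable response curve is exactly a
  nullcline; the omission amounts to absorbing $\varepsilon X$ into $g$ and
  changes trajectories only at $O(\varepsilon)$ (`full_model = TRUE`
  restores the term, and the test suite checks that the period difference
  between the two forms shrinks with $\varepsilon$);
* **three-equation** — $da/dt = \delta^{-1}(H(X_T) - a)$: the switch shape
  becomes a dynamical variable relaxing towards the modulation law on its
  own timescale $\delta$. For $\delta \to 0$ it collapses onto the
  two-equation model; for large $\delta$ the modulation averages out and
  $a$ is nearly constant.

## The dynamic switch

The switch is made dynamic by coupling $a$ to the total protein
(`switch_modulation()`):

$$a(X_T) = \bar a + \Delta a \tanh\!\big(\kappa\,(X_T - X_c)\big),$$

optionally with a lag, $a(t) = a(X_T(t - \tau))$. Conventions used
everywhere:

* $X_c$ is the midpoint of the two saddle-node $X_T$ coordinates of the
  static switch at $\bar a$ (`midpoint_Xc()`); it is computed once per
  parameter set and an error is raised when the static switch is not
  bistable, because the convention is then undefined.
* Event thresholds come from the same folds (`event_thresholds()`): the up
  threshold is the $X$ coordinate of the left fold, the down threshold
  that of the right fold, and single-transition timing uses their average.

A positive $\Delta a$ moves the activation threshold towards the
approaching system. This has two robustness consequences that the
stochastic machinery quantifies: noisy single transitions are timed more
precisely, and relaxation oscillations exist over a wider band of
production rates and keep a steadier period.

## Continuation

Response curves are traced with a pseudo-arclength continuation
(`trace_response_curve()`): secant predictor, Newton corrector on the
steady-state equation augmented with the arclength constraint, step
adaptation by halving on corrector failure and growth on fast convergence
within $[10^{-5}, 5\times 10^{-2}]$. Two safeguards matter in practice with
$n = m = 5$: a corrector solution that drifts more than twice the step
length from the predictor is rejected (this is how branch jumps across
narrow folds are avoided), and a branch that runs into the $X = 0$ axis is
terminated there rather than continued into negative concentrations.
Stability comes from the sign of $\partial F/\partial X$ — the system is
one-dimensional in $X$, so no eigenvalue machinery is needed. Saddle nodes
are detected as reversals of the continued parameter and refined by a
Newton iteration on $(F = 0, \partial_X F = 0)$ to residuals below
$10^{-8}$.

Every traced curve is verifiable against `steady_states()`, a brute-force
sign-change scan (at least 2000 grid points) plus bisection; the test suite
and the acceptance checks compare the two on random slices to $10^{-6}$.
When a curve is traced against $a$ the package follows the branch connected
to the high-activity state at the right end of the range; at high fixed
$X_T$ the left fold sits at $a < 0$ (an irreversible switch), so ranges
must extend below zero to see it.

The two-parameter bistable region (`bistable_region_2d()`) is assembled by
slice scanning one-parameter continuations rather than by fold-tracking
continuation: simpler, and directly checkable against root counts.

## Event detection

`detect_period()` implements threshold-crossing period detection: collect
up-crossings of the up threshold and down-crossings of the down threshold,
deduplicate repeated same-direction crossings so events alternate, and
report differences of consecutive retained up-crossing times. Requiring
both thresholds means only full two-branch excursions count; small
wiggles around one knee are ignored. A run is classified as *sustained*
oscillation (`sustained_period()`) when at least two retained up-crossings
remain, the last falls in the second half of the run, and the mean period
exceeds 0.01 — the recency requirement is this package's choice, added so
that a damped transient with exactly one full swing is not scored as an
oscillation.

`detect_amplitude()` smooths with a zero-phase second-order Butterworth
low-pass before pairing extrema. The cutoff is set at five times the
dominant frequency (Fourier peak); any zero-phase low-pass that preserves
the envelope would serve, and the filter order/cutoff are deliberately
mild so deterministic waveforms pass through essentially unchanged.

## Stochastic versions

**Langevin** (`simulate_langevin()`): additive noise $\sigma\,dW$ on the
fast variable only; the slow variable stays deterministic. This is the
simplest stochastic extension consistent with transitions happening
through vertical excursions off a branch, and it is the regime in which a
dynamic switch helps most — when slow-variable noise is comparable, the
modulation itself becomes noisy and the benefit shrinks (the discrete
simulation shows exactly that). Integration is Euler--Maruyama with
default $dt = 10^{-3}$; $X$ is clipped at zero (reflection without noise
compensation) to keep concentrations physical. Replicates advance in
lockstep as a vectorised ensemble from one seed. The scheme is first
order, and its error concentrates at the switching jump; the noise-free
limit reproduces the stiff ODE solution to better than $10^{-3}$
sup-norm at $dt = 10^{-5}$.

**Discrete** (`simulate_ssa()`): Gillespie's direct method over
activation, inactivation, production, and (for the oscillator) two
degradation channels, with system size $\Omega$ converting concentrations
to counts. Concentration-scale constants are $\Omega$-scaled
($K \to \Omega K$, $\kappa \to \kappa/\Omega$, $X_c \to \Omega X_c$) so
thresholds correspond to molecule numbers. Two readings of the published
reaction table required a decision: the degradation reactions are
implemented so that only the degraded species is consumed (one inactive
molecule, or one active molecule), the active partner acting
catalytically — this reproduces the deterministic degradation flux
$-X\,X_T$ exactly, whereas consuming both reactants would double it. The
inactivation propensity is a function of the active count (the inactive
count appearing in one rendering of the rate table is treated as a
typographical slip). The modulated basal rate is re-evaluated after every
reaction; no tau-leaping is used. A negative modulated rate (possible at
very small counts when $\Delta a$ is large and negative) is clamped to
zero propensity.

When comparing ensemble means against the ODE, the sup-norm is measured
outside a window of three standard deviations around the mean first
passage: the jump time of a finite-$\Omega$ system jitters, so the
ensemble mean near the jump is smeared regardless of the number of
replicates, and a sup-norm across that instant measures conditioning, not
convergence. Outside the window the relative deviation at $\Omega = 200$
is well under the few-percent level, and it decreases monotonically over
$\Omega \in \{10, 50, 200\}$ (as does the full-window sup-norm).

## Space

`simulate_pde()` integrates the active/inactive pair with diffusion
($D_X = D_Y = 5$ by default), forward Euler in time and centred
differences in space, zero-flux boundaries, on a domain of length 100
with $dx = 0.2$. The time step is taken from the diffusive stability
bound $dt \le dx^2/(2\max(D_X, D_Y))$ with a safety factor 0.4, and a
user-supplied step violating the bound is refused with the admissible
value reported. Initial conditions are step profiles. Front position is
the interpolated crossing of $X$ through the midpoint of the two stable
branch values, velocity the least-squares slope of position against time
after discarding the first 10% of the run (the step relaxing into the
travelling profile); fits with $R^2 < 0.99$ carry a warning. The stall
value of $a$ — where the velocity changes sign, near $0.15$ for
$X_T = 2$ — is obtained by scanning `front_velocity_scan()` and
interpolating with `stall_a()`. In the pinning experiment the $a$ profile
is a smooth hyperbolic tangent between a high plateau (0.27) and a low
one (0.13); the transition width (10 length units) and centre are free
choices, as is the 2-time-unit smooth blend used when the profile is
flipped to release the front.

## Two compartments: mitotic entry

`simulate_mitotic_entry()` couples two copies of a Cdk1--Wee1--Cdc25
switch (nucleus, cytoplasm) through slow transport. Cdc25 level times a
Cdk1-activated Hill activity drives activation; a fixed Wee1 level times
a Cdk1-inhibited activity opposes it; Cyclin is synthesised only in the
cytoplasm. Active cytoplasmic Cdk1 enhances Cdc25 import
($I_{Cdc} = 1 + c_{cdc}\,Cdk1_c$) and active nuclear Cdk1 enhances
Cyclin import ($I_{Cyc} = 0.1 + c_{cyc}\,Cdk1_n$). The import-feedback
coefficients are read as $c_{cyc} = 1/30$ and $c_{cdc} = 1/60$ — the
available rendering of these functions drops the fraction bars, and
coefficients of 130 and 160 would make import explode unphysically; both
remain configurable. The Hill constants reuse the generic switch
parameterisation, and the transport/synthesis rates (not available from
the original supplement) were chosen once so that the mechanism's
qualitative sequence holds robustly: cytoplasmic activation first, then
Cdc25-driven collapse of the nuclear threshold, nuclear activation, and
continued nuclear Cyclin accumulation while cytoplasmic activity
plateaus. Compartment activation times are read off as crossings of each
compartment's transition threshold computed from its instantaneous
($t = 0$) response curve — the same fold conventions as everywhere else,
applied to the compartment's effective parameters. By construction total
Cdc25 is conserved exactly and total Cyclin grows linearly at $k_s$;
both are asserted in the tests at $10^{-8}$.

The per-compartment response curve view
(`mitotic_response_curve()`) treats the compartment as quasi-static: the
curve of steady Cdk1 versus total Cyclin at the current Cdc25/Wee1
levels. This is an interpretive device; transport makes the true dynamics
non-autonomous, which is exactly the point — the compartment rides a
response curve whose shape drifts as proteins relocalise.

## The random survey

`random_survey()` samples feedback parameter sets uniformly from
documented ranges ($a \in [0.05, 0.6]$, $a' \in [0.01, 0.5]$,
$b, b' \in [0.5, 2]$, $K, K' \in [0.5, 2]$, $n, m \in [2, 8]$,
$k_X \in [0.5, 3]$) and $\varepsilon$ log-uniformly on $[0.01, 1]$. The
ranges bracket the standard set and stand in for the original sampling
table, which is not available; they are user-overridable. Each set is
pre-checked for static bistability by continuation (non-bistable sets
count as non-oscillating throughout), then simulated for $T = 200$ under
each modulation condition $\Delta a = i\,a$, $\kappa$, $\tau$, with a run
counted as oscillating when the sustained period exceeds 0.01. Positive
modulation raises the oscillating fraction under every condition tested;
negative modulation lowers it. Small-amplitude oscillations reappearing
at strongly negative $\Delta a$ are an artefact of the $\tanh$ coupling
(the switch then sits entirely left of its centre value) and are only
qualitatively present here.

## Problem sizes and reproducibility

Default experiment sizes are desk-scale by design: 200 Langevin
replicates (the original timing figures use the same number), 2000-sample
discrete histograms reduced to hundreds where only a trend is asserted,
40-point $k_X$ grids for region maps, 500-set surveys, and 20 time units
of front propagation per velocity point. Each stochastic interface takes
a seed and records it in its output; identical configuration plus seed
gives byte-identical outputs. The command-line wrapper writes the
resolved configuration next to every result so any run can be repeated
exactly.

## Known limitations

* The Langevin model has no noise on the slow variable by construction;
  conclusions about timing robustness apply to the fast-noise regime.
* The continuation traces one connected branch per call; disconnected
  solution sets within a parameter window require a second start.
* Delay is supported in the continuous models only, not in the discrete
  (Gillespie) model.
* The spatial model is one-dimensional with reflective ends; no curvature
  or geometry effects.
* The mitotic-entry module stops at the first activation switch: no
  nuclear envelope breakdown, no phosphatase switch, no degradation-driven
  exit from mitosis.
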