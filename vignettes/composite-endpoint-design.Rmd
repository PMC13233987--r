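---
title: "Designing trials with composite endpoints: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing trials with composite endpoints: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cedesign)
```

## The design problem

A two-arm randomized trial uses as primary endpoint the time to the first of
two events, $T_* = \min(T_1, T_2)$, observed over a fixed follow-up $\tau$
with administrative censoring. At the design stage nothing has been
observed; the trialist anticipates, per component $k$:

* the control-arm probability $p_k^{(0)}$ of the event by $\tau$,
* a cause-specific hazard ratio $\mathrm{HR}_k$,
* a Weibull shape $\beta_k$ describing whether the risk falls
  ($\beta_k < 1$), stays constant ($\beta_k = 1$) or rises ($\beta_k > 1$)
  over follow-up,

plus an association between the component times (Spearman's $\rho$ or
Kendall's $\tau$) and which components involve a fatal event (the
competing-risk *case*). From these the package derives the composite law in
both arms and everything downstream: effect summaries, sample size, the
endpoint-selection criterion, and simulated datasets.

## The composite law

Control-arm marginals are Weibull, $S_k(t) = \exp(-(t/b_k)^{\beta_k})$,
with the scale solved from the event probability,
$b_k = \tau / (-\log(1 - p_k^{(0)}))^{1/\beta_k}$. Dependence is introduced
through an Archimedean survival copula,

$$S_*^{(0)}(t) = C_\theta(S_1(t), S_2(t)),$$

so the all-cause density splits into cause-specific subdensities
$f_{Ck}(t) = \partial_k C_\theta \cdot f_k(t)$ and the composite hazard is
$\lambda_*^{(0)} = (f_{C1} + f_{C2})/S_*^{(0)}$. The copula parameter
$\theta$ is calibrated from the requested association and is assumed equal
in both arms.

**Treated arm.** The anticipated hazard ratios are *cause-specific*: they
describe how treatment changes the instantaneous risk of each event type
among participants who have had neither event. We therefore construct the
treated-arm composite hazard directly on that scale,

$$\lambda_*^{(1)}(t) = \mathrm{HR}_1 \,\lambda_{C1}(t)
                     + \mathrm{HR}_2 \,\lambda_{C2}(t),$$

and exponentiate the cumulative hazard for $S_*^{(1)}$. An alternative
construction applies proportional hazards to each *marginal*
($S_k^{(1)} = (S_k^{(0)})^{\mathrm{HR}_k}$) and rebuilds the treated-arm
joint law with the same copula; the two coincide at independence and
whenever $\mathrm{HR}_1 = \mathrm{HR}_2$, and differ by a few percent in the
derived summaries under dependence. We adopt the cause-specific form
because it matches the scale on which component effects are actually
anticipated from prior trials (cause-specific hazard ratios), and because it
makes the time-varying composite hazard ratio a pure mixture,

$$\mathrm{HR}_*(t) = \frac{\mathrm{HR}_1 w_1(t) + \mathrm{HR}_2 w_2(t)}
                          {w_1(t) + w_2(t)},
  \qquad w_k(t) = f_{Ck}(t),$$

with transparent limits: at $t \to 0^+$ the component with the smaller
shape dominates and $\mathrm{HR}_*(0^+)$ equals its hazard ratio. One
consequence worth knowing: the construction is not symmetric in the arms,
so inverting both hazard ratios does not invert the summary measures
*exactly* (it does to within about 2% in the regimes we test, and exactly
when the two hazard ratios are equal).

The `case` argument (which components are fatal) deliberately does **not**
alter the law of $T_*$ — the minimum of the latent pair is what it is — but
it governs the cross-censoring semantics of simulated data and triggers a
note that rank associations cannot be estimated from observed data under
competing risks, so the design value must come from external knowledge.

## Effect summaries

Under non-proportional hazards a single hazard ratio misleads; the package
reports four summaries of $\mathrm{HR}_*(t)$ over $[0, \tau]$:

* the **geometric average hazard ratio**,
  $\mathrm{gAHR}(\tau) = \exp\{\int_0^\tau \log \mathrm{HR}_*(t)
  f_*^{(a)}(t)\,dt / p_*^{(a)}(\tau)\}$, with $f_*^{(a)}$ the average of the
  two arms' densities and $p_*^{(a)}$ the average event probability. This
  is the natural logrank effect measure: the logrank noncentrality is
  $\mu_*(\tau) = \sqrt{n\pi(1-\pi)p_*^{(a)}(\tau)}\,\log\mathrm{gAHR}(\tau)$
  regardless of proportionality;
* the **average hazard ratio**, the ratio of $\int
  (\lambda_*^{(i)}/\lambda_*^{(a)}) f_*^{(a)}$ with
  $\lambda_*^{(a)} = \lambda_*^{(0)} + \lambda_*^{(1)}$ — numerically very
  close to the gAHR in every scenario grid the test suite covers;
* the **median ratio**, root-found on the full parametric law. With rare
  events the medians sit far beyond $\tau$; they are still well defined by
  the Weibull extrapolation but are flagged
  (`median_beyond_tau`) and should be read with caution;
* the **RMST ratio**, areas under the survival curves up to $\tau$.

## Sample size and the significance level

Event counts use Schoenfeld's form
$e_* = 4(z_a + z_\beta)^2/\log^2 \mathrm{gAHR}$ (default — it needs fewer
events) or Freedman's
$e_F = (\mathrm{gAHR}+1)^2 (z_{\alpha/2}+z_\beta)^2/(\mathrm{gAHR}-1)^2$,
then $n = e/p_*^{(a)}(\tau)$, reported raw and rounded up to an even total.
Single-endpoint comparison designs use the same machinery with the
component hazard ratio and the arm-averaged component probability
$p_k^{(a)} = (p_k^{(0)} + 1 - (1-p_k^{(0)})^{\mathrm{HR}_k})/2$.

`alpha` is interpreted as a **two-sided** significance level by default:
$z_a = \Phi^{-1}(1-\alpha/2)$, matching the dominant regulatory convention
and the symmetric rejection rule used by the simulator's logrank validation.
Designs that genuinely intend a one-sided test can set
`alpha_kind = "one.sided"`, which uses $z_\alpha$ in the Schoenfeld form
(Freedman's formula is conventionally stated with $z_{\alpha/2}$ and keeps
it). The two conventions differ by about 15% in $n$ at $\alpha = 0.025$, so
the flag matters and is printed with every design.

## Endpoint selection

The asymptotic relative efficiency compares the logrank test on the
composite against the test on the most relevant component:

$$\mathrm{ARE} = \frac{\left(\int_0^1 \log \mathrm{HR}_*(t)
f_*^{(0)}(t)\,dt\right)^2}{\log^2(\mathrm{HR}_1)\; p_*^{(0)}(1)\;
p_1^{(0)}(1)},$$

evaluated on time normalised to the unit follow-up ($\tau$-scaled designs
are normalised first). ARE > 1 favours the composite; the value roughly
approximates the sample-size ratio of the two designs, and the test suite
checks the directional agreement (never equality) between the two readings.
The binary-endpoint analogue defines ARE as the squared ratio of
standardized effects with unpooled difference-scale variances, which makes
it exactly the pre-rounding sample-size ratio — a definition chosen because
it is fully testable against the sample-size routine.

## Binary composites

For binary components the composite occurrence probability is
$p_* = p_1 + p_2 - [p_1 p_2 + \rho\sqrt{p_1 q_1 p_2 q_2}]$ with $\rho$
Pearson's correlation between the indicators, valid only within the
Fréchet–Hoeffding attainability bounds, which the package exposes and
enforces in both arms. Effects can be anticipated as risk differences,
relative risks or odds ratios and are converted exactly; sample sizes use
the classical two-proportion formulas (pooled or unpooled on the difference
scale; Wald variances on the log scale for relative risk and odds ratio —
score variances would change the last digits and are out of scope).

## Copula engine

Frank (default), Gumbel and Clayton are implemented with closed-form CDFs
and partial derivatives. Independence is a valid limit (Frank and Clayton
$\theta = 0$, Gumbel $\theta = 1$) rather than an error, because zero
association is a legitimate scenario in sensitivity scans. Negative
association between components of a composite is not supported: it is
rarely defensible clinically and would complicate attainability.

Calibration: Kendall's $\tau$ inverts in closed form for Clayton
($\theta = 2\tau/(1-\tau)$) and Gumbel ($\theta = 1/(1-\tau)$) and through
the first Debye function for Frank. Spearman's $\rho$ (the default and
recommended measure) is inverted numerically from
$\rho_s(\theta) = 12\iint C_\theta - 3$, evaluated with a fixed 64-point
Gauss–Legendre product rule on the unit square — the integrand is smooth,
so the fixed order is both accurate (round-trip error well under $10^{-4}$,
typically $10^{-9}$) and bit-reproducible. Sampling uses exact
conditional inversion for Frank and Clayton and the positive-stable frailty
construction for Gumbel; all three samplers are validated against their
target Kendall values and uniform margins in the test suite.

## Numerical choices

* All time integrals use adaptive quadrature with absolute tolerance
  $10^{-10}$; the user-facing `subdivisions` (default 1000) only sets the
  resolution of exported curve tables, deliberately separating numerical
  accuracy from plotting resolution.
* Copula partial derivatives clamp $u, v$ to $[10^{-12}, 1 - 10^{-12}]$
  (with a warning at exact boundaries) to avoid $0\cdot\infty$ in the tails
  while leaving results unchanged to working precision.
* The Frank CDF switches between an `expm1` form (small $\theta$) and a
  rearranged logarithmic form (large $\theta$) at $\theta = 30$; either
  form alone loses all precision at the opposite end. $\theta$ is capped at
  350 (Frank), 100 (Gumbel), 98 (Clayton) — far beyond any association a
  trial design would defend — and associations that would need more are
  reported as unattainable.
* Medians are bracketed by doubling from $\tau$ before root-finding, so
  rare-event designs whose medians lie far beyond follow-up neither fail
  nor evaluate the law where survival underflows.
* Internally time is in units of $\tau$; `followup_time` rescales only
  reported times (medians, RMSTs, curve axes, simulated times), so ratios
  and sample sizes are exactly invariant to the time unit.

## The simulator: what it emulates and what it does not

`simula_tte` draws the latent pair from the copula with arm-specific
Weibull marginals (treated-arm marginals are the proportional-hazards
transforms), censors administratively at $\tau$, and applies the
case-dependent cross-censoring: a fatal component censors the other at its
occurrence time, while the composite always records the first event. With
`keep_latent = TRUE` the uncensored times are returned, which is what makes
dependence-recovery checks possible at all — under competing risks the
observed data cannot identify the rank association.

Two honest caveats. First, the simulator's treated arm uses the
marginal-proportional-hazards joint law, while the design calculations use
the cause-specific construction; the two agree at independence and at equal
hazard ratios, and differ by under two percent in event counts at the
moderate associations where both are defensible. The power
self-consistency check in the test suite (1000 simulated trials at the
computed sample size, two-sided logrank at the design level) passes under
this mismatch, which bounds its practical impact. Second, the simulator
emulates an idealised trial: simultaneous entry, no dropout or
loss-to-follow-up, perfectly non-informative administrative censoring.
Passing tests therefore demonstrate internal consistency of law, formulas
and data generation — not robustness to accrual patterns or informative
censoring, which real trials must still assess separately.

## Problem sizes used by the test suite

Deterministic checks run on 50-point grids and desk-scale designs in
seconds. Stochastic checks use sizes chosen to make three Monte Carlo
standard errors decisive while keeping the suite fast: $10^5$ pairs for
sampler margins, $10^6$ pairs for the Monte Carlo Spearman round trip,
50,000 subjects for marginal shape recovery, 4,000-pair subsamples for the
$O(n^2)$ Kendall estimator, and 1000 replicate trials at the computed
sample size for the logrank power check.

## Known limitations

Two components only; balanced allocation ($\pi = 1/2$ — the Freedman form
is stated as printed and not generalised to unequal allocation);
nonnegative association; Weibull marginals (no piecewise or cure models);
anticipated hazard ratios constant in time per component; no group
sequential or adaptive features. The median ratio for rare-event designs
relies on parametric extrapolation beyond the observed horizon and is
flagged accordingly.
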