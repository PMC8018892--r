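---
title: "Axiomatic analysis of risky choice with riskaxioms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axiomatic analysis of risky choice with riskaxioms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskaxioms)
```

## The problem

Expected Utility Theory (EUT) describes risky choice as the maximization
of a numerical subjective value: each gamble — a known probability
distribution over reward magnitudes — gets a utility, and the option with
the higher utility is chosen. Whether such a number *exists at all* for a
given decision maker is not a modeling convenience but an empirical claim,
pinned down by the EUT axioms. The continuity axiom is the crux: for any
ranked triple of gambles A ≻ B ≻ C there must be a unique mixture
probability α such that the decision maker is indifferent between B and
the compound gamble αA + (1−α)C. If continuity fails (for instance under a
lexicographic heuristic that always takes the option with the larger
maximum payoff), no numerical utility can represent the preferences, and
fitted "utility functions" lose their meaning.

`riskaxioms` implements this program end to end for two-alternative
trial data: stochastic axiom tests, indifference-point (IP) and
indifference-curve (IC) estimation, maximum-likelihood fitting of six
value-model families, model comparison, and reconstruction of full
indifference maps, together with a synthetic-agent generator that
produces data with the statistical structure the analyses assume.

## Stochastic reading of deterministic axioms

Axioms are deterministic rules; behavior is stochastic. Every test in the
package therefore works on choice *proportions*: option 1 is preferred to
option 2 when its choice proportion exceeds 0.5 by an exact two-sided
binomial test (`binomial_preference()`, with Clopper–Pearson intervals;
we choose the exact test because per-condition trial counts in this kind
of experiment are routinely 10–30). Direction is assigned from the point
estimate only when the test is significant. Families of tests are
corrected by the Benjamini–Hochberg step-up procedure (`bh_fdr()`).

The continuity test (`test_continuity()`) takes choices between the
middle gamble B and mixtures AC(p_A) on a probability grid and requires:

* **Archimedean criterion** — at least one interior grid level
  significantly dispreferred and one significantly preferred (binomial
  tests, FDR-corrected across the levels of the test). The criterion is
  evaluated on *interior* levels only (0 < p_A < 1) because the
  Archimedean property quantifies over mixture probabilities strictly
  inside (0, 1); the endpoint levels p_A = 0 and p_A = 1 reduce to the
  ranking premise (AC = C and AC = A) and serve as its precheck. This
  distinction has teeth: a lexicographic agent rejects AC at p_A = 0
  (where AC *is* C) yet accepts it at every p_A > 0, and only the
  interior-level rule classifies that pattern as the violation it is.
* **Monotonicity criterion** — a significant positive Spearman rank
  correlation between p_A and the trial-level choice. We correlate at the
  trial level rather than on level means because it is well defined for
  any level design and uses all the data; with only ~9 interior levels a
  level-wise correlation would be underpowered.
* The FDR family is the set of levels within one continuity test, not
  all tests of a session: correcting across tests would make one test's
  verdict depend on unrelated tests and change the compliance semantics.

If the precheck fails, the premise A ≻ B ≻ C does not hold and the
function raises an error rather than reporting a meaningless verdict;
when the grid has no endpoint levels and no precheck data are available,
it proceeds with a warning. Ranking prechecks pool trials across sessions
by default; per-session prechecks can be had by subsetting the table.

## Indifference points and curves

Given per-level counts, the IP is the α of the softmax
P(p_A) = 1/(1 + exp(−(p_A − α)/τ)), fitted by least squares weighted by
per-level trial counts (so unequal repeats do not distort the fit). The
curve passes through 0.5 at α exactly, so α inherits the IP
interpretation by construction. Numerical choices: α starts at the
interpolated 0.5-crossing of the observed proportions (always computable;
falls back to the count-weighted grid mean), τ starts at 0.1 and is
optimized on the log scale within [1e−4, 10] to keep the slope positive
and finite; data that never cross 0.5 still return a fit but are flagged
`extrapolated`. Confidence intervals come from a seeded nonparametric
bootstrap that resamples choices within each level (1000 resamples by
default).

ICs are fitted to sets of (magnitude, probability) IPs by least squares
in the probability domain with linear, power `a(x−c)^b` and hyperbolic
`a + b/(x−c)` forms (`fit_indifference_curve()`), using bounded
Levenberg–Marquardt; the shift `c` is constrained to `[0, min(x))` so the
power base stays positive. A bounded quasi-Newton least-squares fallback
covers the corner case where the start is already a perfect fit and the
gradient is singular. `loo_coverage()` quantifies smoothness the way one
checks for discontinuities in an IC: each IP is left out, the curve is
refitted, and the IP is compared with a pairs-bootstrap band at its
magnitude.

Two session-level analyses target IP stability: `ip_session_series()`
(5-session centered moving average, edge windows shortened) and
`within_session_ip_change()`, which splits each session at the trial
midpoint (middle trial to the first half), fits an IP per half, and runs
a one-sample t test on the per-session differences.

## Value models and estimation

All six families score choices through
P(A|{A,B}) = 1/(1 + exp(−(V_A − V_B)/τ)). Utilities are normalized by
`m0` (default 0.5 ml, the maximum reward of the emulated task) so that
U(m0) = 1:

| kind | value | free parameters |
|---|---|---|
| `EV` | Σ (m_i/m0) p_i | τ |
| `EU_power` | Σ (m_i/m0)^a p_i | a, τ |
| `EU_sshape` | Σ exp(−b(−log(m_i/m0))^a) p_i | a, b, τ |
| `PW` | U(m)·w(p), Prelec w | a, a_w, b_w, τ |
| `additive` | ω_m U(m) + ω_p p | a, ω_m, ω_p, τ |
| `mean_variance` | EV + β·Risk | β, τ |

The PW and additive values are defined, as in prospect theory, only for
gambles with at most one non-zero outcome; gambles outside that class
raise an explicit error rather than being silently extended. This also
means tasks whose "risky" option carries a small non-zero floor reward
(two non-zero outcomes) are scored only by the EU-type and mean-variance
families. β is unconstrained in sign (positive = risk seeking). Each
family carries its own τ in comparisons — the alternative of sharing one
τ across families would couple the fits without a principled scale to
share.

`fit_model_mle()` minimizes the negative log-likelihood (per-trial
Bernoulli terms, probabilities clipped at 1e−12 so the objective is
finite even under near-deterministic fits) with Nelder–Mead from five
seeded starts — the S-shaped and PW likelihoods are multimodal — with
positive parameters on the log scale; one-parameter families use Brent.
Standard errors come from the numerical Hessian at the optimum, with
Wald intervals mapped back to the natural scale. BIC and AIC use n =
number of trials in the fitted set.

Model-implied indifference maps are built exactly as an experimenter
would read them off: for a reference gamble B, sweep probe magnitudes in
0.001 ml steps, and for each probe find the probability (0.001-step grid,
ties to the smaller probability) whose two-outcome gamble value is
closest to V_B. For power utility this reproduces the closed form
p = (m_B/m)^a to within one grid step, which the tests assert for
a ∈ {0.5, 1, 2}. `compare_models()` reports four lower-is-better
metrics: BIC, AIC, the RMSE between model-implied and measured IPs
(probability units), and `var_pref`, the variance across
(test, level) conditions of predicted-minus-observed AC-choice
proportions — our operational reading of "variance of the differences
between modeled and measured preferences".

`ip_cross_correlation()` asks whether the map moves as a whole: Pearson
correlations between all pairs of per-session IP series
(pairwise-complete, at least three shared sessions), grouped into
within-IC and across-IC pairs, each group tested against zero with a
one-sample t test. A common drifting utility function predicts positive
correlations in both groups; independent per-IP noise predicts neither.

## The synthetic-agent generator

`simulate_experiment()` produces trial tables from parameterized agents.
Value agents draw choices from the logistic rule at the agent's (possibly
drifting) parameters; a `side_bias` adds a constant logit offset toward
one screen side; a lexicographic agent implements the
maximum-magnitude-first heuristic softened by a lapse rate (default 0.02,
so that observed proportions stay estimable rather than degenerate 0/1).
Layouts are balanced — each pair appears on each side equally often,
exactly so for even repeat counts — and rewards are realized by sampling
the chosen gamble, which feeds the previous-trial regressor of the choice
regression. A single seed drives per-session substreams, so tables are
reproducible and sessions are independently regenerable.

Two drift mechanisms emulate the nonstationarity seen in long
experiments. Across sessions, one named model parameter follows a
Gaussian random walk. Within a session, a linear ramp of the *implied
indifference point* is imposed: the target IP path spans twice the
configured `within_session_decline` so that the second-half-minus-
first-half difference equals the configured value; the underlying
parameter is recovered from the target IP by monotone interpolation of
the parameter→IP mapping computed for a reference continuity test. We
calibrate in IP units (not parameter units) because the decline is
defined and measured behaviorally. The default decline magnitude used in
the package's benchmarks, −0.10, matches the upper end of what such
experiments report; session counts (50–60) and 10–30 trials per level
match ordinary data-collection scales and keep every benchmark inside a
few minutes on one CPU.

What the generator does *not* emulate: reaction times, error/abort
trials, learning of cue–reward associations, satiety effects beyond the
linear IP ramp, and any trial-to-trial dependence other than the
reward-history regressor. Passing tests on these agents therefore shows
that the *analyses* behave as designed under their own assumptions — not
that real animals satisfy those assumptions.

## The choice regression

`fit_choice_logistic()` fits
logit P(right) = β0 + β1 m_L + β2 p_L + β3 m_R + β4 p_R + β5·preCh·preRew
per session, with preCh ∈ {−1, +1} (0 on a session's first trial) and
preRew the delivered reward in ml. Gambles enter through a scalar (m, p)
encoding: degenerate → (m, 1); two-outcome with a zero outcome → the
non-zero outcome's magnitude and probability; anything more complex →
(EV, 1), with the result flagged — the regression is written for scalar
cues and has no canonical multi-outcome encoding. Coefficients are
standardized by SD(x)/SD(y) so they are comparable across sessions;
`population_beta_tests()` then runs one-sample t tests across sessions
with FDR over the six coefficients. Complete separation triggers a
ridge-penalized refit rather than divergent estimates. A session-level
random-effects variant is deliberately out of scope: per-session fits
plus population tests carry the across-session question here.

## Degenerate inputs and tie-breaks

Gambles are canonicalized on construction: outcomes sorted ascending,
magnitudes equal within 1e−9 ml merged, probabilities validated to sum
to 1 within 1e−9 and renormalized (text round-trip safety),
zero-probability outcomes dropped. Mixtures therefore land automatically
in the Marschak–Machina triangle when their supports overlap. Grid
searches break ties toward the smaller probability. The S-shaped utility
is capped at 1 above m0 (its log form is undefined there) with a
warning. `predict_indifference_point()` returns `NA` with a warning when
even the sure probe cannot reach the reference value.

## A compact worked run

```{r example, eval = FALSE}
A <- degenerate(0.5); B <- degenerate(0.25); C <- degenerate(0)
agent  <- agent_spec(model_spec("EU_power", a = 0.8, tau = 0.05))
trials <- simulate_experiment(
  agent, continuity_design(A, B, C, repeats = 30), seed = 42)
ct <- test_continuity(trials, A, B, C)
ct$compliant          # TRUE for this agent
ct$ip$alpha           # near (0.25/0.5)^0.8 = 0.574
fits <- lapply(c("EV", "EU_power"), fit_model_mle, trials = trials)
compare_models(fits, continuity_tests = list(ct))
```

The same flow, driven by a configuration list or YAML file, is available
as `run_pipeline()`, which writes trial tables, per-test continuity
verdicts, model-comparison tables and a seed-stamped JSON summary.

## Known limitations

* The analytic scope is gains-only: no losses, no reference-point
  adaptation, no cumulative weighting over multiple non-zero outcomes.
* The additive family's τ is redundant with the weight scale (the
  likelihood has a ridge); estimates of ω_m, ω_p are interpretable only
  up to that scale, though fitted probabilities and information criteria
  are unaffected.
* Bootstrap ICs for α resample within levels, conditioning on the
  realized design; they do not propagate uncertainty in the ranking
  precheck.
* The regression's scalar encoding discards structure for three-outcome
  gambles; such sessions are better interrogated through the value
  models, which score arbitrary gambles (EU-type and mean-variance).
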