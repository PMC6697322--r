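---
title: "Searching combinatorial model spaces with adaptive forward, backward and swap moves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching combinatorial model spaces with adaptive forward, backward and swap moves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepswap)
```

## The problem

Dynamic models of biological systems — compartment models of cell
populations, signalling cascades, infection dynamics — are assembled from
candidate processes, each carried by one rate parameter. A *global* model
that admits every candidate process has $n$ parameters and therefore
$2^n - 1$ non-empty sub-models, each obtained by switching parameters on
(fitted to data) or off (held at a default value). Already for a
4-compartment population model with 4 multiplication and 12 transition
rates this is 65,535 candidate structures; for the 43-parameter cell
proliferation problem bundled here it is more than $10^{12}$. Exhaustive
evaluation is impossible, and classical one-directional stepwise selection
is easily trapped when structurally similar processes can compensate for
each other.

`stepswap` implements a stepwise search whose *move schedule adapts to the
search progress*, together with everything needed to run it end to end:
a declarative description of the model space, a restart-capped multistart
fitting scheme, information-criterion scoring, Akaike-weight diagnostics,
profile-likelihood identifiability, a most-distant-restart campaign driver,
and two synthetic benchmark systems on which every feature is exercisable
offline.

## Encoding the model space

A sub-model is a binary inclusion vector $\alpha = (\alpha_1, \dots,
\alpha_n)$ over the global parameter list; its canonical form is the 0/1
string in parameter order. Three kinds of prior structure restrict and
guide the search:

* **Critical sets** — a model is admissible only if it includes at least
  one member of every critical set (and at least one parameter overall;
  the empty model is never evaluated). They encode structural necessities,
  e.g. "the initial population must do *something*".
* **Swap sets** — groups of structurally similar, mutually compensating
  parameters. The swap move exchanges an included member for an excluded
  member of the same set. All critical sets are automatically treated as
  swap sets.
* **Default rules** — what an *excluded* parameter is worth. A rule is an
  ordered fallback list of literals and references to other parameters,
  optionally guarded by "only if the model includes one of ...". This is
  how inheritance chains ("an unfitted generation rate equals the previous
  generation's rate") are expressed; absent any rule, an excluded
  parameter is 0, i.e. the process is switched off.

```{r space-example}
sp <- parameter_space(
  c("mu_AB", "mu_CB", "rho_B"),
  critical_sets = list(c("mu_AB", "mu_CB")),
  swap_sets     = list(c("mu_AB", "rho_B")),
  bounds        = c(0, 10)
)
is_valid_model("001", sp)   # violates the critical set
sapply(swap_neighbors(model_id("100", sp), sp), model_string)
```

## The search

Starting from an admissible model (the global model, a random admissible
model, a user model, or — across campaign runs — the model most distant
from everything tested before), each iteration

1. generates the neighbourhood of the current best model under the current
   move: *forward* (add one parameter), *backward* (remove one), or *swap*
   (exchange within a set);
2. fits every previously unseen candidate to the data and scores it with
   the chosen information criterion (AICc by default); previously fitted
   models are looked up in the history, not refitted, but still compete;
3. accepts the best candidate only on a *strict* criterion decrease.

The move schedule is an automaton: successful forward/backward moves keep
their method, a successful swap switches to forward, a failed forward
switches to backward and vice versa — until both directions have failed
consecutively, at which point the swap move is tried if any swap or
critical set exists, and the search terminates when the swap move fails
too (or none is available). Strict improvement plus finite history
guarantees termination. Ties between candidates are resolved first by
parameter count (prefer the smaller model), then by canonical string
order; the same convention breaks ties in the most-distant-model search.
These completions of the schedule — what exactly follows a failed move,
and all tie-breaks — are this package's own conventions; published
descriptions of such searches typically leave them open.

Every candidate fit draws from a random-number stream derived from the
master seed *and the model string*, so results are independent of the
order in which candidates are evaluated — a prerequisite for parallel
candidate evaluation and for reproducible traces.

## Fitting one sub-model

Each candidate is fitted by minimizing a user cost function on the
$-2\log L$ scale over its *included* parameters; excluded parameters are
resolved through the default rules, so the cost function always receives a
complete parameter vector. The minimizer is Nelder–Mead (`stats::optim`),
wrapped in the following scheme:

* a chain is a sequence of *legs*, each capped at `iteration_cap` (default
  1000) iterations; restarting a leg re-inflates the simplex, which covers
  a broader region than one long run. The chain stops when the between-leg
  decrease falls below `convergence_tol` (default $10^{-3}$; the tolerance
  value is this package's choice) or after `max_legs` legs;
* `optim_runs` independent chains are run per model. During a search,
  chain 1 starts from the estimates inherited from the current best model
  (newly added parameters are sampled); the remaining chains start from
  random values, drawn uniformly or log-uniformly within the bounds.
  Log-uniform sampling is the right choice for rate parameters whose
  plausible values span orders of magnitude, and is used for all bundled
  benchmarks;
* box bounds are enforced by evaluating the cost at the clamped vector
  plus a quadratic penalty on the excursion, and clamping the returned
  estimates. Single-parameter models use bounded Brent search directly.

A model whose cost is non-finite at every attempted start is recorded as a
failed fit with an infinite criterion value: it can never win, but it
remains in the history.

Identifiability of a fitted parameter is assessed by its profile
likelihood: the parameter is walked away from its estimate with adaptive
steps, all other parameters re-optimized at each point (warm-started from
the neighbouring point), and the 95% confidence bound is placed where the
profiled $-2\log L$ rises by $\chi^2_1(0.95) = 3.841$, refined by
bisection. A profile that stays below the threshold all the way to a box
bound reports the bound itself and flags that side non-identifiable.

## Benchmark 1: the four-compartment population model

Compartments $A, B, C, D$ multiply at rates $\rho_X$ and transfer at rates
$\mu_{XY}$; the generating sub-model is $\mu_{AB} = 0.1$, $\rho_B = 0.1$,
$\mu_{BC} = 0.05$, $\mu_{BD} = 0.2$, $\rho_C = 0.1$, starting from 100
members of $A$. Data are per-time-point means (and SDs) of 10 independent
stochastic simulations at 30 equidistant time points over 10 time units,
generated by adaptive tau-leaping with an exact-SSA fallback; for a linear
birth/transfer process the mean dynamics solve the corresponding ODE
system, which is how the simulator is validated. Deterministic
trajectories are propagated by the matrix exponential of the rate matrix
over each grid step — exact for these constant-coefficient linear systems
(so well beyond any integrator-tolerance requirement), and a single
`expm` call per evaluation on an equidistant grid. The hot propagator and
the benchmark cost run in compiled code; slower pure-R implementations of
both are kept and tested for equality, and an adaptive-integrator oracle
(`deSolve::lsoda`) independently confirms the trajectories.

The benchmark cost is a Gaussian $-2\log L$ of the per-point *means*.
Because each data point is a mean of `reps` independent simulations, the
residual weight is the standard error of that mean,
$(\sigma + 1)/\sqrt{\mathrm{reps}}$, with a floor of one count on the
individual-measurement scale so that noiseless data remain usable. The
floor is fixed, not fitted, so the benchmark space keeps exactly its 16
rate parameters and 65,535 candidate models.

On this benchmark the package reproduces the qualitative selection
behaviour the search was designed for, checked by the acceptance tests:
forward/backward-only searches from random starting models split between
the generating model and a small set of local minima, evaluating on the
order of 90 distinct models per run (about 0.1% of the space); searches
started *in* such a local minimum stay there under forward/backward moves,
escape to the generating model when "influx" swap sets
$\{\rho_X, \mu_{YX}\}$ (everything that increases compartment $X$) are
enabled, and are *not* rescued by the structurally mismatched "efflux"
grouping $\{\rho_X, \mu_{XY}\}$. The published study reports a 79%/21%
split over all 65,535 possible starts; the scaled-down re-run here (10–20
random starts, one noise realization, and this package's cost weighting)
reproduces the mean search effort well but shows a larger share of local
minima — with a handful of starts and a different noise realization the
split fraction is the quantity most sensitive to the unpublished details
of the original setup (simulation horizon, exact cost weighting, data
realization).

## Benchmark 2: dye-dilution T-cell proliferation

Generation-structured proliferation after dye labelling: $T_i$ counts
cells that have divided $i$ times ($i = 0..9$, generation 9 collecting all
later divisions),

$$\frac{dT_0}{dt} = -(\rho_0 + \delta_0) T_0, \qquad
  \frac{dT_i}{dt} = 2\rho_{i-1} T_{i-1} - (\rho_i + \delta_i) T_i,$$

with division rates $\rho_i$, death rates $\delta_i$ (per hour), and an
environment-specific adaptation time $\tau_E$ during which no division
occurs ($\rho_i = 0$ for $t \le \tau_E$): freshly transferred cells first
adapt to their culture environment (2D suspension vs 3D collagen). The
system is integrated piecewise-exactly, split at $\tau_E$. As printed,
cells dividing in the top generation leave the tracked system; an
accumulating-top-generation variant (divisions return to $T_9$) is
available behind a flag because verbal descriptions and printed equations
of such models commonly disagree on this point. Model predictions are
frequencies $m_i(t) = T_i / \sum_j T_j$ over living modelled cells.

The selectable space has 42 parameters — $\rho_i$ and $\delta_i$ per
generation for the collagen reference environment and suspension, plus
$\tau_C$ and $\tau_S$ — and the cost's SD-inflation $\tilde\sigma$ as a
43rd parameter held in a singleton critical set so every model contains
it. Inheritance makes excluded parameters meaningful: an unfitted collagen
rate inherits the previous generation's value; an unfitted suspension rate
inherits down the suspension chain once the model selects any suspension
difference at that or an earlier generation, and otherwise equals the
collagen rate of its generation (this guarded form is the only reading
consistent with "environments share parameters until a difference is
selected" while keeping the two environments' generation groupings
independent); an unfitted $\tau_S$ equals $\tau_C$.

The cost is the weighted least-squares $-2\log L$ over replicate means
$\bar y_i(t)$ with weights $\sigma_i(t) + \tilde\sigma$, summed over both
environments, where $\sigma_i(t)$ is the replicate SD and $\tilde\sigma$
compensates the tiny replicate number (here the raw SD, not the SEM, is
deliberately kept: with three replicates the empirical SD is itself so
unreliable that $\tilde\sigma$ is estimated to absorb the difference). The
AICc sample size is the number of mean data cells (time points ×
generations × environments = 80), and every fitted parameter — including
$\tilde\sigma$ — counts towards $k$.

The synthetic data generator mirrors the shape of the experimental data:
frequencies for generations 0–9 at days 0, 2, 4, 7 (0/48/96/168 h), three
replicates, both environments, with truncated-Gaussian noise renormalized
per replicate. Its default truth uses a low early division rate (0.04/h,
generations 0–2) rising to 0.10/h from generation 3, a uniform death rate
of 0.005/h, and the published adaptation-time estimates (46.1 h collagen,
40.6 h suspension) so that the only environmental difference is the
adaptation time. What the generator does *not* emulate: flow-cytometry
peak deconvolution, gating noise, absolute cell counts, or
between-replicate correlation — so passing recovery tests demonstrate
correctness of the machinery on well-specified data, not robustness to
those real-data complications. A uniform death rate is deliberately part
of the truth: death acting equally on all generations cancels from
frequencies, so its base level is structurally non-identifiable from
frequency data alone, and the recovery tests document that the profile
machinery flags exactly this direction while recovering the adaptation
times and division rates.

```{r recovery, eval = FALSE}
sp <- proliferation_space()
dat <- simulate_dye_dilution(proliferation_params(), seed = 101)
cost <- dye_dilution_cost_fn(dat)
alpha <- model_id(c("rho_C0", "rho_C3", "delta_C0",
                    "tau_C", "tau_S", "sigma_tilde"), sp)
fit <- fit_submodel(alpha, cost, sp,
                    fit_options(optim_runs = 3, sampling = "log-uniform",
                                convergence_tol = 1e-4, seed = 1),
                    ic_type = "AICc", n_data = attr(cost, "n_data"))
profile_likelihood_ci(fit, "tau_S", cost, sp)
```

## Numerical and design choices

* **Criterion tie-breaks**: strict improvement is required for acceptance
  (prevents cycling among ties); candidate ties prefer fewer parameters,
  then the smaller canonical string.
* **Most-distant restart**: maximizes the minimum Hamming distance to all
  tested models over the selectable parameters; exhaustive up to 20
  selectable parameters, a seeded multi-restart bit-flip hill climb above
  (the published option names the idea but not an algorithm). Ties by
  canonical string order.
* **History semantics**: candidates compete against the current best and
  this iteration's records; stored records re-enter the comparison only
  when re-proposed. A `refit` flag forces refitting with inheritance,
  keeping the better record.
* **Invalid user starts** are rejected, or repaired on request by adding
  the lowest-index member of each violated critical set.
* **Bounds**: benchmark rates live in [0, 10] (4-compartment) and [0, 1]
  h⁻¹ (proliferation; published estimates are capped at 100 × 10⁻² h⁻¹),
  adaptation times in [0, 48] h, $\tilde\sigma$ in (0, 1].
* **Degenerate inputs**: the empty model is invalid; fits with no finite
  cost are flagged, kept in the history, and excluded from best-model
  updates; population underflow in the proliferation model yields
  undefined frequencies, which surface as failed fits.
* **Experiment sizes** used by the acceptance checks (documented here as
  the package's own scaling choices): the stochastic split experiment uses
  10 random starts and the acceptance script 20, versus all 65,535 starts
  in the original study; tau-leaping validation uses 600 replicates at a
  single time point; dye-dilution recovery uses 3 seeds. The fitting
  protocol for the stochastic benchmark searches is 2 chains,
  500-iteration legs, at most 4 legs, between-leg tolerance 0.01,
  log-uniform starts; noiseless searches use 1000-iteration legs (up to
  6) at tolerance $10^{-3}$, because the criterion differences to resolve
  there are of order unity on a near-zero cost scale.

## Known limitations

* The search is a local hill climb in model space; even with swap moves it
  can terminate in local minima, which is precisely why the most-distant
  campaign driver exists.
* Criterion comparisons inherit the quality of the underlying fits: an
  under-fitted candidate can misdirect a whole search. The restart-capped
  multistart scheme mitigates but cannot eliminate this.
* Parallel candidate evaluation is by design deterministic and
  order-independent (per-model seed streams), but the package itself runs
  candidates sequentially; a parallel map can be dropped in by the user
  without changing any result.
* The profile-likelihood walker assumes a locally smooth, unimodal
  profile; disconnected confidence regions are not detected.
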