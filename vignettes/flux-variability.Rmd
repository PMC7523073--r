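---
title: "Flux variability analysis with scheduled LP sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux variability analysis with scheduled LP sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxvar)
```

## The model

A constraint-based metabolic model couples $n$ reaction fluxes
$v \in \mathbb{R}^n$ through the stoichiometric matrix
$S \in \mathbb{R}^{m \times n}$. At steady state every metabolite is
produced as fast as it is consumed, $S v = b$ with $b = 0$, and each flux
is confined to $lb_i \le v_i \le ub_i$ (by convention in
mmol·gDW⁻¹·h⁻¹, treated here as plain reals). Flux balance analysis
(FBA) picks out one phenotype by maximizing a cellular objective
$Z = c^\top v$ — typically the biomass reaction — over that polytope.

Because $m < n$ the system is under-determined and the optimum is rarely
unique: a whole face of the polytope attains $Z$. Flux variability
analysis (FVA) delineates that space of alternate optimal solutions by
solving, for every reaction $i$, the pair of LPs

$$\min_v \; / \; \max_v \quad v_i
\quad \text{s.t.} \quad S v = b,\quad
c^\top v \ge \tfrac{\mathrm{optPerc}}{100}\, Z,\quad lb \le v \le ub,$$

$2n$ LPs in total. `optPerc` (a percentage of the FBA optimum, default
100) controls how far below optimality solutions may stray; a reaction
whose range is $[0, 0]$ at the chosen `optPerc` is *blocked*.

### The optimality constraint

The textbook formulation fixes the objective by equality,
$c^\top v = Z$. We standardize on the inequality form with a relative
slack of $10^{-9}|Z|$ at `optPerc = 100`: it recovers the equality to
numerical tolerance, degrades gracefully to the near-optimal sweep for
`optPerc < 100`, and avoids the brittleness of an exact equality row
sitting on the boundary of feasibility. The slack is visible in results
as range endpoints within $\sim 10^{-8} Z$ of their analytic values —
the toy network below shows a blocked reaction with range
$[0, 10^{-8}]$ rather than exactly $[0,0]$.

A corner the definition leaves open is a *negative* optimum under
maximization: the literal fraction $(\mathrm{optPerc}/100)\,Z$ is then a
*tighter* bound than $Z$ itself. `apply_optimality_constraint()` applies
the literal fraction and warns, since no standard convention exists;
analyses of such models should use `optPerc = 100`.

## The LP engine

No LP backend is assumed. The package carries its own bounded-variable
two-phase revised simplex (`lp_solve()`): row senses are encoded through
slack-variable bounds (equality rows get a slack fixed at zero), the
basis inverse is maintained explicitly with product-form rank-one
updates and refactorized every 40 pivots, Dantzig pricing switches to
Bland's rule after an iteration threshold to rule out cycling, and an
iteration cap of $200(m{+}N){+}2000$ surfaces pathological instances as
`numeric_failure` rather than hanging. Default feasibility and
optimality tolerances are $10^{-9}$; they are configurable through
`solver_options()` but there is rarely a reason to touch them at desk
scale.

The property that matters for a $2n$-LP sweep is *warm starting*:
successive subproblems differ only in their objective, so the optimal
basis of one LP is primal-feasible for the next and phase 1 can be
skipped entirely. `lp_solve()` returns an opaque basis token;
supplying it to the next solve may change which vertex of a degenerate
face is reported, but never the optimal value beyond the optimality
tolerance — the invariant the test suite checks against both a
rebuild-from-scratch cold sweep and an independent LP implementation
(scipy's HiGHS interface). A token whose shape no longer matches the
problem (e.g. after adding a constraint) is silently ignored and the
solve cold-starts, so correctness never depends on basis reuse.

`scaling = "off"` in `solver_options()` exists for parity with solver
configurations that disable equilibration scaling on coupled models;
the built-in backend performs no scaling, so the flag is recorded in
run metadata and otherwise ignored with a warning.

## Scheduling the sweep

LP solve times vary widely — ill-conditioned columns, coupling
constraints, or awkward objectives can make one subproblem orders of
magnitude slower than its neighbours — so distributing $2n$ iterations
evenly across workers does not distribute *time* evenly. The scheduler
implements the classic loop-scheduling triad over a two-level worker
hierarchy of `nproc` groups × `nthreads` slots:

* **static** — contiguous blocks, sizes differing by at most one
  (`partition_static()`); no dispatch overhead, worst balance;
* **guided** — idle workers pull chunks of
  $\lceil \text{remaining}/\text{workers} \rceil$ items, large at first
  and decaying to 1 (`next_chunk_guided()`);
* **dynamic** — idle workers pull fixed chunks of `chunk` items from a
  shared FIFO queue.

The two levels encode a memory contract rather than a deployment: each
*group* owns a private copy of the LP problem (what a process would
hold), while slots within a group share it (what threads would do).
`run_schedule()` realizes the contract as a deterministic virtual-clock
simulation: chunks are dispatched FIFO to the earliest-idle worker
(ties broken by worker id), per-item costs are either measured wall
time or caller-supplied virtual delays, and execution is sequential in
virtual-time order. This was a deliberate design choice over OS-level
parallelism: the scientifically checkable claims — results independent
of the schedule, conservation of iterations, the balance advantage of
small dynamic chunks on skewed workloads, the chunk-size trade-off
against basis reuse — are all properties of the *dispatch discipline*,
and a simulator makes them exactly reproducible and testable, where a
real thread pool would bury them in timing noise. The telemetry
(`WorkerReport`: iterations, busy seconds, chunks per worker) is the
observable on which those properties are asserted.

Warm-start state chains only across the consecutive items of one chunk:
a worker that picks up a distant chunk has lost the geometric locality
that made its previous basis useful, which is also why very small
chunks trade balance against cold-start overhead. The default schedule
is dynamic with `chunk = 50` — small enough to keep loads even, large
enough to amortize the per-chunk cold solve; with a per-chunk setup
cost injected, the suite demonstrates total busy time at `chunk = 1`
exceeding that at `chunk = 50`. A chunk whose worker function throws is
re-queued once (covering transient failures); on a second failure the
surviving items are recorded individually and the failed ones carry
`schedule_failure` markers, so a sweep never aborts wholesale.

## Warmup points

Uniform samplers of the flux polytope start from feasible points.
`warmup_points()` generates $p$ of them: the first $2n$ are the FVA
witness vectors (for each reaction: argmin, then argmax), the rest are
optima of random objectives with coordinates i.i.d. uniform on
$[-1, 1]$, alternating maximize/minimize between consecutive draws.
Full solution vectors are stored, with per-column provenance. Two
choices deserve justification:

* **No optimality constraint by default.** Sampling aims to cover the
  whole polytope, not the optimal face; passing `opt_perc` restricts
  the points when the near-optimal space is the target.
* **Every point is solved cold.** The deliverable here is the full
  vector, and on degenerate faces the vertex reached *does* depend on
  the starting basis. Chaining warm starts would make the point set a
  function of the chunking; cold solves keep it a pure function of
  (model, $p$, seed), which is what reproducibility of a sampling
  pipeline requires. The draw stream is likewise pre-materialized, so
  the matrix is identical under any schedule, and a failed random
  subproblem is replaced from the continuation of the same stream.

Requesting $p < 2n$ truncates the FVA sweep with a warning; an
infeasible model errors before any point is produced.

## The synthetic generator

Verification needs models whose ground truth is computable, not
downloads. `generate_model()` builds metabolic-like fixtures that are
feasible by construction rather than by rejection: with irreversible
default bounds the zero flux vector always satisfies $S v = 0$, and an
embedded source → chain → sink path of capacity `bound_mag` guarantees
the designated objective (the chain's sink) a strictly positive,
bounded optimum for every seed. Around that skeleton, exchange
reactions attach to random metabolites and internal conversions draw
stoichiometric coefficients from $\{-2,-1,1,2\}$, keeping matrices
well-conditioned by default; an `ill_fraction` knob multiplies a random
column subset by $10^6$ to emulate the condition numbers of multi-scale
models, and `reversible_frac` opens internal lower bounds.
`heterogeneous_workload()` complements it with per-item virtual delays
whose max/min ratio equals a requested skew exactly (log-uniform in
between), the fixture for all load-balance experiments.

What the generator does **not** emulate: biologically realistic network
topology (scale-free degree distributions, compartments), coupling
constraints of metabolism-and-expression models, gene–protein–reaction
structure, or realistic objective composition. Passing tests therefore
demonstrate correctness of the sweep machinery on well-posed LPs of
this family, not performance or numerical behaviour on genome-scale
reconstructions.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated
fixtures at sizes chosen to keep a full verification cycle around two
minutes on one core: oracle-equivalence sweeps use twenty models with
up to ~50 reactions; schedule-invariance and warmup checks use one
100-reaction model (200-LP sweeps, 500–1000 warmup points); partition
and chunk rules are exercised up to the 27 452-item scale at which the
static split yields blocks of 1715 and 1716 over 16 workers. Tolerances
in tests reflect their sources: $10^{-6}$ absolute against independent
solvers (double-precision agreement through different pivot paths),
$10^{-8}$ for schedule invariance (same backend, different warm-start
chains), exact equality for seeded reproducibility and MPS round-trips
(`%.17g` formatting round-trips IEEE doubles).

## Known limitations

* The simplex is dense and maintains an explicit basis inverse —
  appropriate for verification-scale models (hundreds of reactions),
  not for genome-scale matrices, where a sparse-LU backend would slot
  in behind the same `lp_solve()` contract.
* Worker groups are logical; wall-clock speedups from multi-core
  execution are out of scope, only the scheduling discipline and its
  telemetry are modelled.
* `RANGES` sections, integer markers and multiple objective rows in
  MPS input are rejected rather than interpreted.
* Degenerate optima make witness vectors (not their objective values)
  implementation-defined; downstream code should treat warmup columns
  as *some* optimal vertex, not a canonical one.
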