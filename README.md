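# fluxvar

Parallel flux variability analysis (FVA) of constraint-based metabolic
models, with dynamic load balancing and basis warm starts.

## The problem

A genome-scale metabolic model confines the reaction fluxes
*v* ∈ ℝⁿ to a polytope: steady-state mass balance *S v* = 0 over the
stoichiometric matrix *S* (m metabolites × n reactions) and bounds
*lb* ≤ *v* ≤ *ub*. Flux balance analysis (FBA) maximizes a cellular
objective *Z* = *c*ᵀ*v* (typically biomass) over that polytope; because
the system is under-determined, many flux vectors attain the same
optimum. FVA maps that space of alternate optima by solving, for every
reaction *i*,

    min / max   v_i
    subject to  S v = 0
                cᵀv ≥ (optPerc/100) · Z
                lb ≤ v ≤ ub

— 2n linear programs. The per-reaction ranges identify blocked
reactions ([0, 0]), flexible pathways, and the metabolic envelope at
any fraction `optPerc` of optimality.

Two engineering facts dominate at scale, and this package is built
around both:

* **LP costs are heterogeneous.** Splitting the 2n iterations into
  equal blocks (static balancing) leaves fast workers idling behind
  slow ones. Work is instead pulled in chunks from a shared queue
  (dynamic or guided scheduling) by whichever worker is idle.
* **Consecutive LPs differ only in the objective.** The optimal simplex
  basis of one subproblem warm-starts the next, skipping phase 1
  entirely — provided the scheduler keeps consecutive items on one
  worker, which is why chunk size trades load balance against basis
  reuse.

The package is solver-agnostic by contract and ships its own
bounded-variable two-phase revised simplex with an opaque warm-start
basis token. It reads and writes free-format MPS, converts COBRA-style
structured containers (JSON), generates warmup points for flux-space
sampling (the 2n FVA witnesses followed by optima of random objectives
drawn uniform on [−1, 1]), and includes a synthetic model generator so
every property is verifiable without external data. Everything is
driven either from R or from a command-line front end.

## Worked example

The canonical toy network has one metabolite A and three reactions:
uptake R1 (∅→A, [0, 10]), export R2 (A→∅, [0, 10], the objective) and a
second export R3 (A→∅, [0, 5]).

```r
library(fluxvar)
model <- toy_model()
fba(model)
#> LP solution: status=optimal, Z=10 (3 simplex iterations)

res <- fva(model, opt_perc = 50)
res
#> Flux variability analysis: 3 reactions, optPerc=50, Z=10
#>   6 LPs over 1 worker(s), schedule=dynamic(chunk=50), 1x1 workers
#>  reaction_id min_flux max_flux status_min status_max
#>           R1        5       10    optimal    optimal
#>           R2        5       10    optimal    optimal
#>           R3        0        5    optimal    optimal
```

Mass balance forces v₁ = v₂ + v₃, so at full optimality (Z = 10) the
sweep pins R1 and R2 to 10 and blocks R3; retaining only 50 % of the
optimum (cᵀv ≥ 5) frees R3 up to 5, as printed above. `summary()` adds
the blocked-reaction count and the per-worker telemetry (iterations,
busy time, chunks received) that the load-balancing properties are
stated in terms of:

```r
summary(res)
#> FVA of 3 reactions at optPerc=50 (Z=10, 6 LPs)
#>   blocked reactions (range [0,0]): 0
#>   unbounded directions: 0, failed subproblems: 0
#>   median flux range: 5
#> Per-worker telemetry:
#>  group slot worker iterations busy_seconds chunks
#>      1    1      1          6        0.004      1
```

Warmup points for sampling, reproducible under a seed:

```r
w <- warmup_points(model, p = 8, seed = 7)
w
#> Warmup point set: 8 points in 3 dimensions (seed 7)
#>   FVA witness columns: 6, random-objective columns: 2
```

Larger, feasible-by-construction test models come from the generator:

```r
m <- generate_model(synthetic_spec(seed = 1))   # 50 metabolites, 100 reactions
f <- fva(m, opt_perc = 90,
         schedule = schedule_spec("dynamic", chunk = 10, nproc = 2, nthreads = 2))
```

The same operations are available from a shell via the launcher in
`inst/cli/`:

```sh
fluxvar fva --model model.mps --opt-perc 90 --schedule dynamic --chunk 50 \
        --nproc 4 --nthreads 2
fluxvar warmup --model model.mps --points 1000 --seed 7
fluxvar convert --model model.json --out model.mps
```

`fva` writes `<prefix>.fva.csv`, run metadata as JSON, worker telemetry
as CSV and a log; exit codes distinguish usage errors (2), model errors
(3), infeasible/unbounded FBA (4) and partial sub-LP failures (5).

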