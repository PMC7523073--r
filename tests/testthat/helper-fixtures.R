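# Shared fixtures: small seeded synthetic models, built fresh per run.

small_spec <- function(seed, reversible = 0.3) {
  synthetic_spec(n_metabolites = 8L + (seed %% 6L),
                 n_internal = 12L + 2L * (seed %% 5L),
                 n_exchange = 4L + 2L * (seed %% 2L),
                 reversible_frac = reversible,
                 bound_mag = 50, seed = seed)
}

small_model <- function(seed, reversible = 0.3) generate_model(small_spec(seed, reversible))

# a model whose FBA objective has a strictly negative optimum: the
# objective reaction is an export forced to run in reverse
negative_optimum_model <- function() {
  metabolic_model(S = matrix(c(1, -1), 1, 2),
                  lb = c(-10, 2), ub = c(10, 10),
                  obj = c(-1, 0),
                  reaction_ids = c("R1", "R2"), metabolite_ids = "A")
}

# two antiparallel reactions around one metabolite with an open bound:
# any flux level is feasible, so maximizing either flux is unbounded
cycle_model <- function() {
  metabolic_model(S = matrix(c(1, -1), 1, 2),
                  lb = c(0, 0), ub = c(Inf, Inf),
                  obj = c(1, 0),
                  reaction_ids = c("F", "B"), metabolite_ids = "A")
}

# bounded objective chain plus an independent unbounded two-reaction cycle:
# FBA is finite but the cycle reactions have infinite FVA maxima
cycle_fva_model <- function() {
  S <- matrix(0, 2, 4)
  S[1, 1] <- 1; S[1, 2] <- -1        # A: R1 in, R2 out (objective)
  S[2, 3] <- 1; S[2, 4] <- -1        # B: unbounded cycle C1/C2
  metabolic_model(S = S, lb = c(0, 0, 0, 0), ub = c(10, 10, Inf, Inf),
                  obj = c(0, 1, 0, 0),
                  reaction_ids = c("R1", "R2", "C1", "C2"),
                  metabolite_ids = c("A", "B"))
}

write_toy_mps_2rxn <- function(path) {
  writeLines(c(
    "NAME TOY2",
    "ROWS",
    " N  COST",
    " E  A",
    "COLUMNS",
    "    R1  COST  1  A  1",
    "    R2  A  -1",
    "RHS",
    "BOUNDS",
    " UP  BND  R1  10",
    " UP  BND  R2  10",
    "ENDATA"), path)
  path
}
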