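# Independent oracles.
#
# oracle_batch(): solves a list of LPs with scipy.optimize.linprog (HiGHS)
#   through one python subprocess — a completely independent, production
#   grade LP implementation. Infinities are ferried as +-1e30.
#
# cold_sweep_fva(): the rebuild-from-scratch reference sweep — for every
#   subproblem a fresh lp_problem is constructed and solved cold, no warm
#   starts, no scheduler. Shares only the backend with fva(), so it checks
#   the sweep/plumbing independently of scheduling and basis reuse.

scipy_script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog

INF = 1e30

def aslist(x):
    if x is None:
        return []
    return x if isinstance(x, list) else [x]

lps = json.load(open(sys.argv[1]))
out = []
for lp in lps:
    c = np.asarray(aslist(lp["c"]), float)
    sign = -1.0 if lp["maximize"] else 1.0
    b_eq = np.asarray(aslist(lp["b_eq"]), float)
    b_ub = np.asarray(aslist(lp["b_ub"]), float)
    A_eq = np.asarray(aslist(lp["A_eq"]), float).reshape(len(b_eq), len(c)) if len(b_eq) else None
    A_ub = np.asarray(aslist(lp["A_ub"]), float).reshape(len(b_ub), len(c)) if len(b_ub) else None
    if not len(b_eq):
        b_eq = None
    if not len(b_ub):
        b_ub = None
    bounds = [(None if l <= -INF else l, None if u >= INF else u)
              for l, u in zip(aslist(lp["lb"]), aslist(lp["ub"]))]
    res = linprog(sign * c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                  bounds=bounds, method="highs")
    status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(res.status, "failed")
    out.append({"status": status,
                "z": sign * res.fun if res.status == 0 else None,
                "v": list(res.x) if res.x is not None else None})
json.dump(out, open(sys.argv[2], "w"))
'

# lps: list of lists with fields c, maximize, lb, ub, A_eq (matrix or NULL),
# b_eq, A_ub, b_ub. Returns list of (status, z, v).
oracle_batch <- function(lps) {
  enc <- lapply(lps, function(lp) {
    lb <- pmax(lp$lb, -1e30); ub <- pmin(lp$ub, 1e30)
    list(c = as.numeric(lp$c), maximize = isTRUE(lp$maximize),
         lb = as.numeric(lb), ub = as.numeric(ub),
         A_eq = if (is.null(lp$A_eq)) numeric(0) else as.numeric(t(as.matrix(lp$A_eq))),
         b_eq = if (is.null(lp$b_eq)) numeric(0) else as.numeric(lp$b_eq),
         A_ub = if (is.null(lp$A_ub)) numeric(0) else as.numeric(t(as.matrix(lp$A_ub))),
         b_ub = if (is.null(lp$b_ub)) numeric(0) else as.numeric(lp$b_ub))
  })
  dir <- tempfile("oracle"); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  fin <- file.path(dir, "in.json"); fout <- file.path(dir, "out.json")
  fpy <- file.path(dir, "solve.py")
  jsonlite::write_json(enc, fin, auto_unbox = TRUE, digits = NA)
  writeLines(scipy_script, fpy)
  st <- system2("python", c(fpy, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("scipy oracle failed: ", paste(st, collapse = "\n"))
  jsonlite::read_json(fout, simplifyVector = FALSE)
}

# single-LP convenience over a metabolic-model-shaped polytope
oracle_lp <- function(S, b, lb, ub, obj, maximize = TRUE, extra = NULL) {
  A_ub <- NULL; b_ub <- NULL
  if (!is.null(extra)) {
    for (e in extra) {
      co <- e$coef; rhs <- e$rhs
      if (e$sense == "G") { co <- -co; rhs <- -rhs }
      A_ub <- rbind(A_ub, co); b_ub <- c(b_ub, rhs)
    }
  }
  r <- oracle_batch(list(list(c = obj, maximize = maximize, lb = lb, ub = ub,
                              A_eq = as.matrix(S), b_eq = b,
                              A_ub = A_ub, b_ub = b_ub)))[[1]]
  list(status = r$status,
       z = if (is.null(r$z)) NA_real_ else r$z,
       v = if (is.null(r$v)) NULL else unlist(r$v))
}

oracle_fba <- function(model) {
  oracle_lp(model$S, model$b, model$lb, model$ub, model$obj,
            maximize = identical(model$objective_sense, "maximize"))
}

# full FVA reference in one python call: FBA + 2n constrained subproblems
oracle_fva <- function(model, opt_perc = 100) {
  fb <- oracle_fba(model)
  stopifnot(fb$status == "optimal")
  Z <- fb$z
  maxim <- identical(model$objective_sense, "maximize")
  rhs <- if (opt_perc == 100) {
    if (maxim) Z - abs(Z) * 1e-9 else Z + abs(Z) * 1e-9
  } else opt_perc / 100 * Z
  co <- if (maxim) -model$obj else model$obj
  bu <- if (maxim) -rhs else rhs
  n <- ncol(model$S)
  A_eq <- as.matrix(model$S)
  lps <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- 1
    common <- list(lb = model$lb, ub = model$ub, A_eq = A_eq, b_eq = model$b,
                   A_ub = matrix(co, 1), b_ub = bu)
    lps[[2L * i - 1L]] <- c(list(c = ei, maximize = FALSE), common)
    lps[[2L * i]] <- c(list(c = ei, maximize = TRUE), common)
  }
  res <- oracle_batch(lps)
  zs <- vapply(res, function(r) if (is.null(r$z)) NA_real_ else r$z, 0)
  list(Z = Z, min_flux = zs[seq(1L, 2L * n, by = 2L)],
       max_flux = zs[seq(2L, 2L * n, by = 2L)])
}

# rebuild-and-cold-solve reference sweep (no warm starts, no scheduler)
cold_sweep_fva <- function(model, opt_perc = 100, rxns = NULL,
                           options = solver_options()) {
  sol0 <- fba(model, options)
  stopifnot(sol0$status == "optimal")
  Z <- sol0$objective
  idx <- if (is.null(rxns)) seq_len(ncol(model$S)) else match(rxns, model$reaction_ids)
  mn <- mx <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    for (dir in c("min", "max")) {
      prob <- lp_problem(model, options)                 # from scratch
      prob <- apply_optimality_constraint(prob, Z, opt_perc)
      ei <- numeric(ncol(model$S)); ei[i] <- 1
      prob <- set_objective(prob, ei, if (dir == "max") "maximize" else "minimize")
      sol <- lp_solve(prob)                              # cold
      val <- switch(sol$status, optimal = sol$objective,
                    unbounded = if (dir == "max") Inf else -Inf, NaN)
      if (dir == "min") mn[k] <- val else mx[k] <- val
    }
  }
  list(Z = Z, min_flux = mn, max_flux = mx)
}

feasible_point <- function(model, v, tol = 1e-8) {
  resid <- max(abs(drop(as.matrix(model$S %*% v)) - model$b))
  inb <- all(v >= model$lb - tol) && all(v <= model$ub + tol)
  resid <= tol && inb
}
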