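#' Flux balance analysis
#'
#' Maximizes (or minimizes, per the model's objective sense) the objective
#' `Z = c'v` subject to steady-state mass balance `S v = b` and the flux
#' bounds — the initial LP whose optimum anchors the FVA sweep.
#'
#' @param model a `metabolic_model` with a nonzero objective vector.
#' @param options a [solver_options()] object.
#' @return An `lp_solution`: the optimum `Z` and a witness flux vector `v`.
#'   An infeasible or unbounded model is reported through `status`, not an
#'   error.
#' @examples
#' fba(toy_model())
#' @export
fba <- function(model, options = solver_options()) {
  validate_model(model)
  if (all(model$obj == 0))
    stop("model has a zero objective vector; flux balance analysis is undefined",
         call. = FALSE)
  lp_solve(lp_problem(model, options))
}

#' Append the optimality-percentage constraint
#'
#' After the FBA optimum `Z` is known, the FVA sweep restricts the polytope
#' to near-optimal solutions: `c'v >= (optPerc/100) * Z` for a maximization
#' objective (`<=` for minimization). At `optPerc = 100` the right-hand side
#' is relaxed by a relative slack of `1e-9 * |Z|`, recovering the equality
#' `c'v = Z` up to numerical tolerance without the brittleness of an exact
#' equality row.
#'
#' For a negative optimum under maximization the literal fraction
#' `(optPerc/100) * Z` is *tighter* than `Z` for `optPerc < 100`; the
#' constraint is still applied as stated, with a warning, since no standard
#' convention exists for that corner.
#'
#' @param problem an `lp_problem` built from the model (its original
#'   objective is remembered as the biomass row of the constraint).
#' @param Z finite FBA optimum.
#' @param opt_perc percentage of the optimum to retain, in `[0, 100]`.
#' @return The modified `lp_problem`.
#' @export
apply_optimality_constraint <- function(problem, Z, opt_perc = 100) {
  stopifnot(inherits(problem, "lp_problem"))
  if (!is.finite(Z)) stop("Z must be finite", call. = FALSE)
  if (!is.numeric(opt_perc) || opt_perc < 0 || opt_perc > 100)
    stop("opt_perc must be in [0, 100]", call. = FALSE)
  frac <- opt_perc / 100
  rhs <- frac * Z
  if (opt_perc == 100) {
    rhs <- if (problem$maximize0) Z - abs(Z) * 1e-9 else Z + abs(Z) * 1e-9
  } else if ((problem$maximize0 && Z < 0) || (!problem$maximize0 && Z > 0)) {
    warning(sprintf(
      "optimum Z=%g and optPerc=%g give a bound (%g) tighter than Z itself; applying the literal fraction",
      Z, opt_perc, rhs), call. = FALSE)
  }
  add_constraint(problem, problem$obj0,
                 sense = if (problem$maximize0) "G" else "L",
                 rhs = rhs)
}

#' Minimize or maximize one reaction over the constrained polytope
#'
#' One FVA subproblem: the objective becomes the indicator of reaction `i`
#' and is optimized in the requested direction, optionally warm-started
#' from a previous basis.
#'
#' @param problem an `lp_problem`, typically with the optimality constraint
#'   already applied.
#' @param i reaction index (1-based).
#' @param direction `"min"` or `"max"`.
#' @param warm_start optional basis token.
#' @return list with `value` (the optimum of `v_i`; `+-Inf` when unbounded,
#'   `NaN` when the subproblem failed), `status`, and `basis` for chaining.
#' @export
fva_single <- function(problem, i, direction = c("min", "max"),
                       warm_start = NULL) {
  direction <- match.arg(direction)
  n <- problem$n
  if (!is.numeric(i) || i < 1 || i > n) stop("reaction index out of range", call. = FALSE)
  ei <- numeric(n); ei[i] <- 1
  problem <- set_objective(problem, ei,
                           sense = if (direction == "max") "maximize" else "minimize")
  sol <- lp_solve(problem, warm_start = warm_start)
  value <- switch(sol$status,
                  optimal = sol$objective,
                  unbounded = if (direction == "max") Inf else -Inf,
                  NaN)
  list(value = value, status = sol$status, basis = sol$basis, v = sol$v,
       iterations = sol$iterations)
}

fva_work_items <- function(idx) {
  # reaction-major, min then max adjacent: the sweep order of the 2n LPs
  items <- vector("list", 2L * length(idx))
  k <- 0L
  for (i in idx) {
    items[[k + 1L]] <- list(i = i, direction = "min")
    items[[k + 2L]] <- list(i = i, direction = "max")
    k <- k + 2L
  }
  items
}

#' Flux variability analysis
#'
#' Computes, for each reaction (or a subset), the minimum and maximum flux
#' attainable while retaining at least `opt_perc` percent of the FBA
#' optimum: first one FBA solve fixes `Z`, then the optimality constraint
#' is appended, and the `2n` subproblems (for each reaction: minimize, then
#' maximize) are distributed over the worker hierarchy described by
#' `schedule` with warm-start chaining inside each chunk. Results are
#' independent of the schedule; the schedule only shapes the per-worker
#' telemetry.
#'
#' @param model a `metabolic_model` with a nonzero objective.
#' @param opt_perc percentage of the FBA optimum solutions must retain
#'   (default 100).
#' @param rxns optional character vector of reaction ids to analyze
#'   (default: all reactions). Exactly `2 * length(rxns)` LPs are solved.
#' @param schedule a [schedule_spec()].
#' @param options a [solver_options()].
#' @return An object of class `fva`: a list with `table` (data frame of
#'   `reaction_id`, `min_flux`, `max_flux`, `status_min`, `status_max`),
#'   `Z` (the FBA optimum), `opt_perc`, `n_lps`, `schedule`, and `workers`
#'   (per-worker telemetry). Failed subproblems appear as `NaN` with their
#'   status; unbounded directions as `+-Inf`.
#' @examples
#' fva(toy_model(), opt_perc = 50)
#' @seealso [fba()], [warmup_points()], [schedule_spec()]
#' @export
fva <- function(model, opt_perc = 100, rxns = NULL,
                schedule = schedule_spec(), options = solver_options()) {
  validate_model(model)
  sol0 <- fba(model, options)
  if (sol0$status != "optimal")
    stop("flux balance analysis did not reach an optimum (status: ",
         sol0$status, "); the optimality constraint is undefined", call. = FALSE)
  Z <- sol0$objective

  idx <- resolve_rxns(model, rxns)
  base <- lp_problem(model, options)
  base <- apply_optimality_constraint(base, Z, opt_perc)
  items <- fva_work_items(idx)

  run <- run_schedule(
    items,
    worker_fn = function(item, state, ctx) {
      r <- fva_single(ctx, item$i, item$direction, warm_start = state)
      list(result = r, state = r$basis)
    },
    spec = schedule,
    init_group = function(g) base)   # one private problem instance per group

  n_sub <- length(idx)
  min_flux <- max_flux <- rep(NaN, n_sub)
  status_min <- status_max <- rep("failed", n_sub)
  for (k in seq_along(items)) {
    res <- run$results[[k]]
    pos <- (k + 1L) %/% 2L
    ok <- !inherits(res, "schedule_failure")
    val <- if (ok) res$value else NaN
    stat <- if (ok) res$status else "failed"
    if (items[[k]]$direction == "min") {
      min_flux[pos] <- val; status_min[pos] <- stat
    } else {
      max_flux[pos] <- val; status_max[pos] <- stat
    }
  }
  structure(list(
    table = data.frame(reaction_id = model$reaction_ids[idx],
                       min_flux = min_flux, max_flux = max_flux,
                       status_min = status_min, status_max = status_max,
                       stringsAsFactors = FALSE),
    Z = Z, opt_perc = opt_perc, n_lps = length(items),
    schedule = schedule, workers = run$reports,
    options = options),
    class = "fva")
}

resolve_rxns <- function(model, rxns) {
  if (is.null(rxns)) return(seq_along(model$reaction_ids))
  idx <- match(rxns, model$reaction_ids)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(rxns[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}

#' @export
print.fva <- function(x, ...) {
  cat(sprintf("Flux variability analysis: %d reactions, optPerc=%g, Z=%.10g\n",
              nrow(x$table), x$opt_perc, x$Z))
  cat(sprintf("  %d LPs over %d worker(s), schedule=%s\n",
              x$n_lps, nrow(x$workers), format(x$schedule)))
  print(utils::head(x$table, 10L), row.names = FALSE)
  if (nrow(x$table) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x$table) - 10L))
  invisible(x)
}

#' @export
summary.fva <- function(object, blocked_tol = 1e-9, ...) {
  tab <- object$table
  rng <- tab$max_flux - tab$min_flux
  blocked <- abs(tab$min_flux) <= blocked_tol & abs(tab$max_flux) <= blocked_tol
  failed <- tab$status_min == "failed" | tab$status_max == "failed" |
    is.nan(tab$min_flux) | is.nan(tab$max_flux)
  out <- list(n = nrow(tab), Z = object$Z, opt_perc = object$opt_perc,
              n_blocked = sum(blocked & !failed),
              n_failed = sum(failed),
              n_unbounded = sum(is.infinite(tab$min_flux) | is.infinite(tab$max_flux)),
              median_range = stats::median(rng[is.finite(rng)]),
              n_lps = object$n_lps,
              workers = object$workers)
  class(out) <- "summary.fva"
  out
}

#' @export
print.summary.fva <- function(x, ...) {
  cat(sprintf("FVA of %d reactions at optPerc=%g (Z=%.10g, %d LPs)\n",
              x$n, x$opt_perc, x$Z, x$n_lps))
  cat(sprintf("  blocked reactions (range [0,0]): %d\n", x$n_blocked))
  cat(sprintf("  unbounded directions: %d, failed subproblems: %d\n",
              x$n_unbounded, x$n_failed))
  cat(sprintf("  median flux range: %.6g\n", x$median_range))
  cat("Per-worker telemetry:\n")
  print(x$workers, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.fva <- function(x, ...) x$table

#' @export
plot.fva <- function(x, ...) {
  tab <- x$table
  n <- nrow(tab)
  fin_lo <- ifelse(is.finite(tab$min_flux), tab$min_flux, NA)
  fin_hi <- ifelse(is.finite(tab$max_flux), tab$max_flux, NA)
  ord <- order(fin_hi - fin_lo, decreasing = TRUE)
  graphics::plot(NULL, xlim = range(c(fin_lo, fin_hi), na.rm = TRUE),
                 ylim = c(0.5, n + 0.5), xlab = "flux", ylab = "",
                 yaxt = "n", main = sprintf("FVA ranges (optPerc=%g)", x$opt_perc),
                 ...)
  graphics::segments(fin_lo[ord], seq_len(n), fin_hi[ord], seq_len(n))
  graphics::points(fin_lo[ord], seq_len(n), pch = "|")
  graphics::points(fin_hi[ord], seq_len(n), pch = "|")
  graphics::axis(2, at = seq_len(n), labels = tab$reaction_id[ord],
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write FVA results to CSV / JSON
#'
#' `write_fva()` writes the per-reaction table as CSV
#' (`reaction_id,min_flux,max_flux,status_min,status_max`) and, when
#' `json_path` is given, a JSON run-metadata record (optimum, optPerc,
#' schedule, worker telemetry, solver options).
#'
#' @param x an `fva` object.
#' @param path CSV output path.
#' @param json_path optional JSON metadata path.
#' @return `path`, invisibly.
#' @export
write_fva <- function(x, path, json_path = NULL) {
  stopifnot(inherits(x, "fva"))
  utils::write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    meta <- list(Z = x$Z, opt_perc = x$opt_perc, n_lps = x$n_lps,
                 schedule = list(policy = x$schedule$policy,
                                 chunk = x$schedule$chunk,
                                 nproc = x$schedule$nproc,
                                 nthreads = x$schedule$nthreads),
                 solver = list(backend = x$options$backend,
                               feas_tol = x$options$feas_tol,
                               opt_tol = x$options$opt_tol,
                               scaling = x$options$scaling),
                 workers = x$workers)
    jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
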