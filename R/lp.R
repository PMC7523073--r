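#' Solver options for the LP layer
#'
#' @param feas_tol primal feasibility tolerance (> 0), default `1e-9`.
#' @param opt_tol reduced-cost optimality tolerance (> 0), default `1e-9`.
#' @param scaling `"default"` or `"off"`. The built-in simplex backend does
#'   not scale the constraint matrix; the flag is recorded in run metadata
#'   (and a warning is emitted for `"off"`) so that runs remain
#'   reproducible from their logs when a scaling-capable backend is added.
#' @param backend LP backend name; `"simplex"` (the built-in
#'   bounded-variable revised simplex) is currently the only backend.
#' @param time_limit per-LP time limit in seconds (advisory; the built-in
#'   backend enforces an iteration cap instead).
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(feas_tol = 1e-9, opt_tol = 1e-9,
                           scaling = c("default", "off"),
                           backend = "simplex", time_limit = Inf) {
  scaling <- match.arg(scaling)
  if (!is.numeric(feas_tol) || feas_tol <= 0) stop("feas_tol must be > 0", call. = FALSE)
  if (!is.numeric(opt_tol) || opt_tol <= 0) stop("opt_tol must be > 0", call. = FALSE)
  if (!identical(backend, "simplex"))
    stop("unknown LP backend '", backend, "' (available: simplex)", call. = FALSE)
  if (scaling == "off")
    warning("backend 'simplex' has no scaling switch; scaling='off' recorded and ignored",
            call. = FALSE)
  structure(list(feas_tol = feas_tol, opt_tol = opt_tol, scaling = scaling,
                 backend = backend, time_limit = time_limit),
            class = "solver_options")
}

#' Build an LP problem from a metabolic model
#'
#' Encodes the FBA polytope `S v = b`, `lb <= v <= ub` with objective `obj`,
#' plus any auxiliary inequality constraints the model carries. Additional
#' constraints (notably the optimality-percentage constraint of the FVA
#' sweep) can be appended with [add_constraint()]; the objective is swapped
#' with [set_objective()] without disturbing the constraint rows, so a
#' retained simplex basis remains valid.
#'
#' @param model a validated `metabolic_model`.
#' @param options a [solver_options()] object.
#' @return An object of class `lp_problem`.
#' @export
lp_problem <- function(model, options = solver_options()) {
  validate_model(model)
  stopifnot(inherits(options, "solver_options"))
  A <- as.matrix(model$S)
  sense <- rep("E", nrow(A))
  rhs <- model$b
  if (!is.null(model$aux)) {
    A <- rbind(A, model$aux$C)
    sense <- c(sense, model$aux$sense)
    rhs <- c(rhs, model$aux$rhs)
  }
  structure(list(A = A, sense = sense, rhs = rhs,
                 lb = model$lb, ub = model$ub,
                 obj = model$obj,
                 maximize = identical(model$objective_sense, "maximize"),
                 obj0 = model$obj,              # the model's own objective (biomass)
                 maximize0 = identical(model$objective_sense, "maximize"),
                 n = ncol(A), reaction_ids = model$reaction_ids,
                 n_extra = 0L, options = options),
            class = "lp_problem")
}

#' Swap the objective of an LP problem
#'
#' Only the objective vector and sense change; constraint rows, bounds and
#' any retained warm-start basis are untouched. This is the Eq.-style FVA
#' step of setting a single reaction as the new objective.
#'
#' @param problem an `lp_problem`.
#' @param obj numeric objective vector of length n.
#' @param sense `"maximize"` or `"minimize"`.
#' @return The modified `lp_problem`.
#' @export
set_objective <- function(problem, obj, sense = c("maximize", "minimize")) {
  stopifnot(inherits(problem, "lp_problem"))
  sense <- match.arg(sense)
  if (length(obj) != problem$n)
    stop(sprintf("objective has length %d, expected %d", length(obj), problem$n),
         call. = FALSE)
  problem$obj <- as.numeric(obj)
  problem$maximize <- identical(sense, "maximize")
  problem
}

#' Append a linear constraint to an LP problem
#'
#' @param problem an `lp_problem`.
#' @param coef numeric coefficient vector of length n.
#' @param sense one of `"L"` (<=), `"G"` (>=), `"E"` (=).
#' @param rhs scalar right-hand side.
#' @return The modified `lp_problem`. Note that adding a row invalidates
#'   warm-start tokens taken from the previous problem shape; [lp_solve()]
#'   detects the mismatch and cold-starts.
#' @export
add_constraint <- function(problem, coef, sense, rhs) {
  stopifnot(inherits(problem, "lp_problem"))
  if (length(coef) != problem$n)
    stop(sprintf("constraint has length %d, expected %d", length(coef), problem$n),
         call. = FALSE)
  if (!sense %in% c("L", "G", "E")) stop("sense must be 'L', 'G' or 'E'", call. = FALSE)
  problem$A <- rbind(problem$A, as.numeric(coef))
  problem$sense <- c(problem$sense, sense)
  problem$rhs <- c(problem$rhs, as.numeric(rhs))
  problem$n_extra <- problem$n_extra + 1L
  problem
}

#' Solve an LP problem
#'
#' Dispatches to the configured backend (the built-in bounded-variable
#' revised simplex). Row senses are encoded through slack-variable bounds
#' (equality rows get a fixed zero slack), which gives every problem an
#' immediate slack starting basis; a `warm_start` basis token from a
#' previous solve of the same problem shape is used instead when supplied,
#' so that successive solves after an objective swap skip phase 1 and start
#' next to the previous optimum.
#'
#' @param problem an `lp_problem`.
#' @param warm_start optional basis token from a previous [lp_solve()] on a
#'   problem of identical shape; tokens of mismatched shape are silently
#'   ignored (cold start).
#' @return An object of class `lp_solution` with fields `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`, `"numeric_failure"`),
#'   `objective` (the optimum `Z`; `+-Inf` when unbounded), `v` (flux vector,
#'   present iff optimal), `basis` (warm-start token) and `iterations`.
#' @examples
#' p <- lp_problem(toy_model())
#' lp_solve(p)
#' @export
lp_solve <- function(problem, warm_start = NULL) {
  stopifnot(inherits(problem, "lp_problem"))
  n <- problem$n
  m <- nrow(problem$A)
  Afull <- cbind(problem$A, diag(1, m))
  slack_lb <- ifelse(problem$sense == "G", -Inf, 0)
  slack_ub <- ifelse(problem$sense == "L", Inf, 0)
  lb <- c(problem$lb, slack_lb)
  ub <- c(problem$ub, slack_ub)
  obj <- c(problem$obj, numeric(m))
  if (!is.null(warm_start) && !inherits(warm_start, "lp_basis")) warm_start <- NULL
  res <- solve_bounded_lp(Afull, problem$rhs, lb, ub, obj,
                          maximize = problem$maximize,
                          basis = warm_start,
                          tol = problem$options$opt_tol)
  v <- if (res$status == "optimal") res$x[seq_len(n)] else NULL
  structure(list(status = res$status,
                 objective = res$z,
                 v = v,
                 basis = res$basis,
                 iterations = res$iterations,
                 n = n),
            class = "lp_solution")
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("LP solution: status=%s", x$status))
  if (!is.na(x$objective)) cat(sprintf(", Z=%.10g", x$objective))
  cat(sprintf(" (%d simplex iterations)\n", x$iterations))
  invisible(x)
}
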