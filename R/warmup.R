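#' Generate warmup points for flux-space sampling
#'
#' Uniform samplers of the flux polytope (hit-and-run family) start from a
#' set of feasible flux vectors. The first `2n` warmup points are the
#' witness solutions of the FVA sweep (for each reaction: the argmin, then
#' the argmax of its flux); points beyond `2n` are optima of randomly
#' generated objectives, each coordinate drawn i.i.d. uniform on
#' `[-1, 1]`, with the optimization direction alternating
#' maximize/minimize between consecutive draws. Full solution vectors `v`
#' are stored (not just objective values), one column per point.
#'
#' No optimality-percentage constraint is applied unless `opt_perc` is
#' given, so the points cover the whole flux polytope rather than the
#' near-optimal slice. A random-objective subproblem that fails (e.g. an
#' unbounded direction when some bounds are open) is dropped and replaced
#' with the next draw, preserving the requested count. Requesting
#' `p < 2n` truncates the FVA sweep with a warning.
#'
#' @param model a `metabolic_model`. Must be feasible; infeasibility is an
#'   error before any point is produced.
#' @param p number of points to generate (default `2n`).
#' @param schedule a [schedule_spec()]; work distribution never changes
#'   the point set, only the telemetry.
#' @param options a [solver_options()].
#' @param seed RNG seed governing the random objectives; the same seed
#'   reproduces the point matrix exactly.
#' @param opt_perc optional optimality percentage; when given, the
#'   FBA optimum is computed first and all points are confined to the
#'   near-optimal polytope, as in the FVA sweep.
#' @return An object of class `warmup_points`: list with `points`
#'   (n x p matrix, columns are flux vectors), `provenance` (data frame
#'   with per-column `kind` (`"fva"`/`"random"`), `reaction_id`,
#'   `direction`, `draw`), `seed`, `opt_perc`, and `workers` (telemetry).
#' @examples
#' w <- warmup_points(toy_model(), p = 6, seed = 7)
#' dim(w$points)
#' @export
warmup_points <- function(model, p = NULL,
                          schedule = schedule_spec(),
                          options = solver_options(),
                          seed = 1L, opt_perc = NULL) {
  validate_model(model)
  n <- ncol(model$S)
  if (is.null(p)) p <- 2L * n
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1", call. = FALSE)

  base <- lp_problem(model, options)
  feas <- lp_solve(set_objective(base, numeric(n), "maximize"))
  if (feas$status == "infeasible")
    stop("model is infeasible; no warmup points can be generated", call. = FALSE)
  if (!is.null(opt_perc)) {
    sol0 <- fba(model, options)
    if (sol0$status != "optimal")
      stop("flux balance analysis did not reach an optimum; cannot apply opt_perc",
           call. = FALSE)
    base <- apply_optimality_constraint(base, sol0$objective, opt_perc)
  }

  if (p < 2L * n)
    warning(sprintf("p=%d is smaller than 2n=%d; the FVA sweep is truncated", p, 2L * n),
            call. = FALSE)

  fva_items <- fva_work_items(seq_len(n))
  n_fva <- min(p, 2L * n)
  n_random <- p - n_fva

  # pre-draw random objectives so the point set is schedule-independent;
  # draws consumed by failed subproblems are replaced from the same stream
  draw_pool <- list()
  draw_cursor <- 0L
  rng <- with_seed(seed, .Random.seed)  # materialize a private RNG stream
  next_draw <- function() {
    draw_cursor <<- draw_cursor + 1L
    if (length(draw_pool) < draw_cursor) {
      had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
      if (had) old <- get(".Random.seed", envir = globalenv())
      assign(".Random.seed", rng, envir = globalenv())
      cvec <- stats::runif(n, -1, 1)
      rng <<- get(".Random.seed", envir = globalenv())
      if (had) assign(".Random.seed", old, envir = globalenv())
      draw_pool[[draw_cursor]] <<- cvec
    }
    list(c = draw_pool[[draw_cursor]], draw = draw_cursor)
  }

  items <- fva_items[seq_len(n_fva)]
  if (n_random > 0L) {
    for (k in seq_len(n_random)) {
      d <- next_draw()
      items[[n_fva + k]] <- list(random = TRUE, c = d$c, draw = d$draw,
                                 direction = if (d$draw %% 2L == 1L) "max" else "min")
    }
  }

  # Each point is solved from a cold start: the stored deliverable is the
  # full solution vector, and alternate optima reached from different warm
  # bases would make the point set depend on the chunking. Cold solves
  # keep the matrix a pure function of (model, p, seed).
  solve_item <- function(item, state, ctx) {
    if (is.null(item$random)) {
      r <- fva_single(ctx, item$i, item$direction)
      list(result = r, state = NULL)
    } else {
      prob <- set_objective(ctx, item$c,
                            sense = if (item$direction == "max") "maximize" else "minimize")
      sol <- lp_solve(prob)
      list(result = list(v = sol$v, status = sol$status, basis = sol$basis),
           state = NULL)
    }
  }

  run <- run_schedule(items, solve_item, spec = schedule,
                      init_group = function(g) base)
  results <- run$results

  # serial repair pass: regenerate failed random columns with fresh draws
  for (k in seq_along(results)) {
    res <- results[[k]]
    bad <- inherits(res, "schedule_failure") || is.null(res$v)
    if (!bad) next
    item <- items[[k]]
    if (is.null(item$random)) {
      stop(sprintf("FVA warmup subproblem failed for reaction %s (%s): status %s",
                   model$reaction_ids[item$i], item$direction,
                   if (inherits(res, "schedule_failure")) res$message else res$status),
           call. = FALSE)
    }
    for (attempt in seq_len(50L)) {
      d <- next_draw()
      dir <- if (d$draw %% 2L == 1L) "max" else "min"
      sol <- lp_solve(set_objective(base, d$c,
                                    sense = if (dir == "max") "maximize" else "minimize"))
      if (!is.null(sol$v)) {
        results[[k]] <- list(v = sol$v, status = sol$status, basis = sol$basis)
        items[[k]] <- list(random = TRUE, c = d$c, draw = d$draw, direction = dir)
        break
      }
    }
    if (is.null(results[[k]]$v))
      stop("could not generate a replacement warmup point after 50 random draws",
           call. = FALSE)
  }

  points <- matrix(NA_real_, n, p)
  kind <- character(p); rxn <- rep(NA_character_, p)
  dirn <- character(p); draw <- rep(NA_integer_, p)
  for (k in seq_len(p)) {
    points[, k] <- results[[k]]$v
    it <- items[[k]]
    if (is.null(it$random)) {
      kind[k] <- "fva"; rxn[k] <- model$reaction_ids[it$i]
      dirn[k] <- it$direction
    } else {
      kind[k] <- "random"; dirn[k] <- it$direction; draw[k] <- it$draw
    }
  }
  structure(list(points = points,
                 provenance = data.frame(column = seq_len(p), kind = kind,
                                         reaction_id = rxn, direction = dirn,
                                         draw = draw, stringsAsFactors = FALSE),
                 seed = seed, opt_perc = opt_perc,
                 workers = run$reports),
            class = "warmup_points")
}

#' @export
print.warmup_points <- function(x, ...) {
  cat(sprintf("Warmup point set: %d points in %d dimensions (seed %d)\n",
              ncol(x$points), nrow(x$points), x$seed))
  cat(sprintf("  FVA witness columns: %d, random-objective columns: %d\n",
              sum(x$provenance$kind == "fva"), sum(x$provenance$kind == "random")))
  if (!is.null(x$opt_perc))
    cat(sprintf("  restricted to %g%% of the FBA optimum\n", x$opt_perc))
  invisible(x)
}

#' Write a warmup point set
#'
#' The dense point matrix goes to CSV (one row per reaction, one column
#' per point, reaction ids in the first column); the provenance table and
#' seed go to JSON when `json_path` is given.
#'
#' @param x a `warmup_points` object.
#' @param path CSV output path.
#' @param json_path optional provenance JSON path.
#' @param reaction_ids optional reaction identifiers for the row labels.
#' @return `path`, invisibly.
#' @export
write_warmup <- function(x, path, json_path = NULL, reaction_ids = NULL) {
  stopifnot(inherits(x, "warmup_points"))
  df <- as.data.frame(x$points)
  names(df) <- paste0("pt", seq_len(ncol(x$points)))
  if (is.null(reaction_ids)) reaction_ids <- paste0("R", seq_len(nrow(x$points)))
  df <- cbind(data.frame(reaction_id = reaction_ids, stringsAsFactors = FALSE), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(seed = x$seed,
                              opt_perc = x$opt_perc,
                              provenance = x$provenance,
                              workers = x$workers),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}
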