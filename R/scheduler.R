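#' Specify the work-distribution schedule
#'
#' The 2n FVA subproblems are distributed over a two-level worker
#' hierarchy: `nproc` worker groups, each holding its own private problem
#' instance (the memory contract of process-level parallelism), times
#' `nthreads` slots per group sharing that instance. Three policies are
#' supported, mirroring the classic loop-scheduling triad:
#'
#' * `static` — each worker receives one contiguous block, block sizes
#'   differing by at most one;
#' * `guided` — idle workers pull chunks of decaying size
#'   `ceiling(remaining / n_workers)`;
#' * `dynamic` — idle workers pull fixed-size chunks of `chunk` items from
#'   a shared FIFO queue.
#'
#' The default is `dynamic` with `chunk = 50`: a chunk small enough to keep
#' worker loads balanced yet large enough that warm-start chaining inside
#' the chunk amortizes cold solves.
#'
#' @param policy `"dynamic"`, `"static"` or `"guided"`.
#' @param chunk positive chunk size (dynamic policy only; ignored
#'   otherwise).
#' @param nproc number of worker groups (>= 1).
#' @param nthreads slots per group (>= 1).
#' @return An object of class `schedule_spec`.
#' @export
schedule_spec <- function(policy = c("dynamic", "static", "guided"),
                          chunk = 50L, nproc = 1L, nthreads = 1L) {
  policy <- match.arg(policy)
  chunk <- as.integer(chunk); nproc <- as.integer(nproc); nthreads <- as.integer(nthreads)
  if (nproc < 1L || nthreads < 1L) stop("nproc and nthreads must be >= 1", call. = FALSE)
  if (policy == "dynamic" && chunk < 1L)
    stop("chunk must be >= 1 for the dynamic schedule", call. = FALSE)
  structure(list(policy = policy, chunk = chunk,
                 nproc = nproc, nthreads = nthreads),
            class = "schedule_spec")
}

#' @export
format.schedule_spec <- function(x, ...) {
  base <- if (x$policy == "dynamic") sprintf("dynamic(chunk=%d)", x$chunk) else x$policy
  sprintf("%s, %dx%d workers", base, x$nproc, x$nthreads)
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat("Schedule:", format(x), "\n"); invisible(x)
}

#' Static partition of a work range
#'
#' Splits `n_items` work items into `n_workers` contiguous, disjoint blocks
#' covering the whole range, with block sizes differing by at most one (the
#' first `n_items %% n_workers` workers receive the larger size).
#'
#' @param n_items number of work items.
#' @param n_workers number of workers (>= 1).
#' @return A list of `n_workers` integer index vectors (possibly empty).
#' @examples
#' lengths(partition_static(27452, 16))  # only sizes 1715 and 1716 occur
#' @export
partition_static <- function(n_items, n_workers) {
  n_items <- as.integer(n_items); n_workers <- as.integer(n_workers)
  if (n_workers < 1L) stop("n_workers must be >= 1", call. = FALSE)
  base <- n_items %/% n_workers
  extra <- n_items %% n_workers
  sizes <- rep(base, n_workers)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(n_workers), function(w)
    if (sizes[w] == 0L) integer(0) else starts[w]:ends[w])
}

#' Next chunk size under the guided schedule
#'
#' The guided policy hands an idle worker `ceiling(remaining / n_workers)`
#' items — `2n / workers` on the first dispatch of an FVA sweep, then a
#' decaying fraction of what remains, floored at one item.
#'
#' @param remaining items not yet dispatched (>= 0).
#' @param n_workers number of workers.
#' @return The chunk size; `0` when nothing remains (termination signal).
#' @export
next_chunk_guided <- function(remaining, n_workers) {
  if (remaining <= 0) return(0L)
  max(1L, as.integer(ceiling(remaining / n_workers)))
}

#' Run work items through the scheduled worker hierarchy
#'
#' Deterministic virtual-clock execution of the two-level worker contract:
#' chunks are dispatched FIFO from a single shared queue to the idle worker
#' with the smallest busy time (ties broken by worker id), each group owns
#' one private context created by `init_group`, and warm-start state chains
#' only across the consecutive items of one chunk (a new chunk starts with
#' empty state, as a worker picking up a distant chunk has lost the basis
#' of its previous subproblem). Execution is sequential in virtual-time
#' order; the schedule therefore shapes telemetry and state chaining, never
#' the results, which are returned in input order.
#'
#' Per-item costs default to measured wall time; supplying `costs` (e.g.
#' from [heterogeneous_workload()]) makes busy times fully deterministic
#' for load-balance experiments. `chunk_setup` adds a fixed virtual cost at
#' every chunk start, modelling the cold solve a worker pays when it
#' abandons its warm basis.
#'
#' A chunk whose worker function throws is re-queued once; on the second
#' failure the surviving items are recorded individually and failed items
#' yield `schedule_failure` results.
#'
#' @param items list of work items.
#' @param worker_fn `function(item, state, ctx)` returning
#'   `list(result, state)`; `state` is the warm-start chain, `ctx` the
#'   group's private context.
#' @param spec a [schedule_spec()].
#' @param init_group `function(group_id)` building one private context per
#'   worker group (the memory contract); defaults to `NULL` contexts.
#' @param costs optional numeric vector of per-item virtual costs
#'   (seconds).
#' @param chunk_setup fixed virtual cost added per chunk received.
#' @return list with `results` (same order as `items`) and `reports`, a
#'   data frame with one row per worker: `group`, `slot`, `worker`,
#'   `iterations`, `busy_seconds`, `chunks`.
#' @export
run_schedule <- function(items, worker_fn, spec = schedule_spec(),
                         init_group = NULL, costs = NULL, chunk_setup = 0) {
  stopifnot(inherits(spec, "schedule_spec"))
  n <- length(items)
  if (!is.null(costs) && length(costs) != n)
    stop("costs must have one entry per work item", call. = FALSE)
  n_workers <- spec$nproc * spec$nthreads
  groups <- rep(seq_len(spec$nproc), each = spec$nthreads)
  slots <- rep(seq_len(spec$nthreads), times = spec$nproc)
  ctx <- vector("list", spec$nproc)
  for (g in seq_len(spec$nproc))
    ctx[[g]] <- if (is.null(init_group)) NULL else init_group(g)

  clock <- numeric(n_workers)
  iters <- integer(n_workers)
  nchunks <- integer(n_workers)
  results <- vector("list", n)

  # chunk queue: list of integer index vectors, FIFO; attempt count each
  pending <- list()
  if (n > 0L) {
    if (spec$policy == "static") {
      blocks <- partition_static(n, n_workers)
      # pre-assigned: worker w gets exactly its block (dispatch respects it)
      pending <- lapply(seq_len(n_workers), function(w)
        list(idx = blocks[[w]], attempt = 1L, owner = w))
      pending <- Filter(function(ch) length(ch$idx) > 0L, pending)
    } else if (spec$policy == "dynamic") {
      starts <- seq(1L, n, by = spec$chunk)
      pending <- lapply(starts, function(s)
        list(idx = s:min(s + spec$chunk - 1L, n), attempt = 1L, owner = NA))
    } else {
      # guided: sizes are decided at dispatch time; materialize the
      # dispatch sequence now (it depends only on n and n_workers)
      pos <- 1L
      while (pos <= n) {
        sz <- next_chunk_guided(n - pos + 1L, n_workers)
        pending[[length(pending) + 1L]] <-
          list(idx = pos:(pos + sz - 1L), attempt = 1L, owner = NA)
        pos <- pos + sz
      }
    }
  }

  process_chunk <- function(chunk) {
    w <- if (!is.na(chunk$owner)) chunk$owner else {
      cand <- which(clock == min(clock))
      cand[1L]                                  # ties: lowest worker id
    }
    g <- groups[w]
    state <- NULL
    busy <- chunk_setup
    done <- 0L
    failed_at <- 0L
    per_item <- if (chunk$attempt >= 2L) TRUE else FALSE
    for (k in seq_along(chunk$idx)) {
      it <- chunk$idx[k]
      t0 <- proc.time()[["elapsed"]]
      out <- tryCatch(worker_fn(items[[it]], state, ctx[[g]]),
                      error = function(e) e)
      cost <- if (!is.null(costs)) costs[it]
              else proc.time()[["elapsed"]] - t0
      busy <- busy + cost
      if (inherits(out, "error")) {
        if (!per_item) { failed_at <- k; break }
        results[[it]] <<- structure(list(message = conditionMessage(out)),
                                    class = "schedule_failure")
        iters[w] <<- iters[w] + 1L
        state <- NULL
      } else {
        results[[it]] <<- out$result
        state <- out$state
        iters[w] <<- iters[w] + 1L
        done <- done + 1L
      }
    }
    clock[w] <<- clock[w] + busy
    nchunks[w] <<- nchunks[w] + 1L
    if (failed_at > 0L) {
      # first failure: discard this pass, re-queue the whole chunk once
      iters[w] <<- iters[w] - done
      results[chunk$idx[seq_len(failed_at - 1L)]] <<- list(NULL)
      pending[[length(pending) + 1L]] <<-
        list(idx = chunk$idx, attempt = 2L, owner = chunk$owner)
    }
    invisible(NULL)
  }

  while (length(pending) > 0L) {
    chunk <- pending[[1L]]
    pending <- pending[-1L]
    process_chunk(chunk)
  }

  reports <- data.frame(group = groups, slot = slots,
                        worker = seq_len(n_workers),
                        iterations = iters,
                        busy_seconds = clock,
                        chunks = nchunks)
  list(results = results, reports = reports)
}
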