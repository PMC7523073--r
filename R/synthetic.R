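#' The canonical hand-checkable toy network
#'
#' One metabolite A and three reactions: an uptake `R1` (bounds `[0, 10]`),
#' an export `R2` (bounds `[0, 10]`, the objective), and a second export
#' `R3` (bounds `[0, 5]`). Mass balance forces `v1 = v2 + v3`, so the FBA
#' optimum is `Z = 10` and at full optimality `R3` is blocked.
#'
#' @return A validated `metabolic_model` with `m = 1`, `n = 3`.
#' @examples
#' fba(toy_model())$objective  # 10
#' @export
toy_model <- function() {
  metabolic_model(S = matrix(c(1, -1, -1), 1, 3),
                  lb = c(0, 0, 0), ub = c(10, 10, 5),
                  obj = c(0, 1, 0),
                  reaction_ids = c("R1", "R2", "R3"),
                  metabolite_ids = "A")
}

#' Specification for the synthetic model generator
#'
#' Describes a feasible metabolic-like network: `n_exchange` boundary
#' reactions (half sources, half sinks), `n_internal` random conversion
#' reactions with stoichiometric coefficients drawn from `{-2,-1,1,2}`, a
#' fraction of reversible internal reactions, and an embedded
#' source-to-sink throughput chain guaranteeing that the designated
#' objective (the chain's sink) has a strictly positive, bounded optimum
#' for every seed. `ill_fraction > 0` multiplies that fraction of random
#' columns by `1e6`, emulating the large stoichiometric condition numbers
#' of multi-scale (ME) models.
#'
#' @param n_metabolites number of metabolites (>= 2).
#' @param n_internal number of internal reactions (>= 1).
#' @param n_exchange number of exchange reactions (>= 2).
#' @param reversible_frac fraction of internal reactions with negative
#'   lower bounds, in `[0, 1]`.
#' @param bound_mag magnitude of the default flux bounds.
#' @param seed RNG seed; the same spec generates byte-identical models.
#' @param ill_fraction fraction of internal columns scaled by `1e6`.
#' @param cost_skew max/min ratio for the per-item artificial solve delays
#'   paired with this spec in scheduler experiments (see
#'   [heterogeneous_workload()]).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_metabolites = 50L, n_internal = 80L,
                           n_exchange = 20L, reversible_frac = 0.3,
                           bound_mag = 100, seed = 1L,
                           ill_fraction = 0, cost_skew = 1) {
  if (n_metabolites < 2L) stop("need at least 2 metabolites", call. = FALSE)
  if (n_internal < 1L) stop("need at least 1 internal reaction", call. = FALSE)
  if (n_exchange < 2L)
    stop("need at least 2 exchange reactions (one source, one sink) for a feasible throughput chain",
         call. = FALSE)
  if (reversible_frac < 0 || reversible_frac > 1)
    stop("reversible_frac must be in [0, 1]", call. = FALSE)
  if (cost_skew < 1) stop("cost_skew must be >= 1", call. = FALSE)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_internal = as.integer(n_internal),
                 n_exchange = as.integer(n_exchange),
                 reversible_frac = reversible_frac,
                 bound_mag = bound_mag, seed = as.integer(seed),
                 ill_fraction = ill_fraction, cost_skew = cost_skew),
            class = "synthetic_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a feasible synthetic metabolic model
#'
#' Feasibility and a positive bounded optimum are guaranteed by
#' construction rather than rejection sampling: `v = 0` always satisfies
#' `S v = 0` with the irreversible default bounds, and an embedded chain
#' source -> M1 -> M2 -> ... -> sink (each link with capacity `bound_mag`)
#' carries positive flux to the objective (sink) reaction regardless of the
#' random internal wiring. All bounds are finite, so every FVA subproblem
#' is bounded.
#'
#' @param spec a [synthetic_spec()].
#' @return A validated `metabolic_model` with
#'   `n = n_internal + n_exchange` reactions.
#' @examples
#' m <- generate_model(synthetic_spec(n_metabolites = 10, n_internal = 15,
#'                                    n_exchange = 4, seed = 7))
#' fba(m)$objective > 0
#' @export
generate_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    m <- spec$n_metabolites
    n <- spec$n_internal + spec$n_exchange
    B <- spec$bound_mag
    chain_len <- min(m, 4L)
    chain_mets <- seq_len(chain_len)

    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    lb <- numeric(n); ub <- rep(B, n)
    rxn_ids <- character(n)
    add_entry <- function(i, j, x) {
      ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
    }

    # exchange reactions: first half sources (import), second half sinks
    n_src <- ceiling(spec$n_exchange / 2)
    for (k in seq_len(spec$n_exchange)) {
      j <- k
      if (k <= n_src) {
        met <- if (k == 1L) chain_mets[1L] else sample.int(m, 1L)
        add_entry(met, j, 1)                  # source: creates the metabolite
        rxn_ids[j] <- paste0("EX_in_", k)
      } else {
        met <- if (k == n_src + 1L) chain_mets[chain_len] else sample.int(m, 1L)
        add_entry(met, j, -1)                 # sink: consumes the metabolite
        rxn_ids[j] <- paste0("EX_out_", k - n_src)
      }
    }
    obj_rxn <- n_src + 1L                     # sink of the chain end

    # internal reactions: the chain links first, then random conversions
    n_links <- chain_len - 1L
    if (spec$n_internal < n_links)
      stop("n_internal too small for the embedded throughput chain", call. = FALSE)
    for (k in seq_len(spec$n_internal)) {
      j <- spec$n_exchange + k
      rxn_ids[j] <- paste0("RXN_", k)
      if (k <= n_links) {
        add_entry(chain_mets[k], j, -1)
        add_entry(chain_mets[k + 1L], j, 1)
      } else {
        n_sub <- sample(1:2, 1L)
        n_prod <- sample(1:2, 1L)
        mets <- sample.int(m, n_sub + n_prod)
        co <- sample(c(1, 2), n_sub + n_prod, replace = TRUE)
        for (q in seq_len(n_sub)) add_entry(mets[q], j, -co[q])
        for (q in seq_len(n_prod)) add_entry(mets[n_sub + q], j, co[n_sub + q])
      }
    }

    # reversibility of internal reactions: opening lower bounds never
    # removes the positive-flux chain, so the optimum stays positive
    if (spec$reversible_frac > 0) {
      internal <- spec$n_exchange + seq_len(spec$n_internal)
      n_rev <- round(spec$reversible_frac * length(internal))
      if (spec$reversible_frac >= 1) n_rev <- length(internal)
      rev <- if (n_rev > 0L) internal[sample.int(length(internal), n_rev)] else integer(0)
      lb[rev] <- -B
    }

    S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, n))

    if (spec$ill_fraction > 0 && spec$n_internal > n_links) {
      cand <- spec$n_exchange + (n_links + 1L):spec$n_internal
      n_ill <- max(1L, round(spec$ill_fraction * length(cand)))
      ill <- cand[sample.int(length(cand), min(n_ill, length(cand)))]
      S[, ill] <- S[, ill] * 1e6
    }

    obj <- numeric(n); obj[obj_rxn] <- 1
    metabolic_model(S = S, lb = lb, ub = ub, obj = obj,
                    reaction_ids = rxn_ids,
                    metabolite_ids = paste0("M", seq_len(m)))
  })
}

#' Heterogeneous per-item workload for scheduler experiments
#'
#' Emulates the wide spread of LP solve times seen with ill-conditioned
#' subproblems: positive virtual delays whose max/min ratio equals `skew`
#' exactly, log-uniformly distributed in between, deterministic under
#' `seed`. Feed the result to [run_schedule()]'s `costs` argument.
#'
#' @param n_items number of work items (>= 2 unless `skew == 1`).
#' @param skew ratio of slowest to fastest item (>= 1).
#' @param seed RNG seed.
#' @param base fastest item's delay in virtual seconds.
#' @return Numeric vector of length `n_items`.
#' @export
heterogeneous_workload <- function(n_items, skew, seed = 1L, base = 0.001) {
  if (skew < 1) stop("skew must be >= 1", call. = FALSE)
  n_items <- as.integer(n_items)
  if (skew == 1) return(rep(base, n_items))
  if (n_items < 2L) stop("need at least 2 items for skew > 1", call. = FALSE)
  with_seed(seed, {
    u <- stats::runif(n_items)
    u <- (u - min(u)) / (max(u) - min(u))    # exact endpoints 0 and 1
    base * skew^u
  })
}
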