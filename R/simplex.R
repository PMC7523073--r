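# Bounded-variable two-phase revised simplex.
#
# Solves   min / max  c'x   s.t.  A x = rhs,  lb <= x <= ub
# where A already contains one slack column per row (the caller encodes row
# senses through the slack bounds: E -> [0,0], L -> [0,Inf), G -> (-Inf,0]).
# The basis inverse is maintained explicitly and updated by a product-form
# (eta) rank-one update, with periodic refactorization for stability; this is
# what makes warm-started resolves cheap after an objective swap, because a
# primal-feasible basis skips phase 1 entirely.
#
# Nonbasic status codes: 0 basic, 1 at lower bound, 2 at upper bound,
# 3 free at zero (both bounds infinite).

.simplex_refactor_every <- 40L

solve_bounded_lp <- function(A, rhs, lb, ub, obj, maximize = TRUE,
                             basis = NULL, tol = 1e-9,
                             max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); N <- ncol(A)
  stopifnot(length(rhs) == m, length(lb) == N, length(ub) == N,
            length(obj) == N)
  if (is.null(max_iter)) max_iter <- 200L * (m + N) + 2000L
  cmin <- if (maximize) -obj else obj     # internal sense: minimize
  ftol <- max(tol, 1e-11)                  # bound feasibility tolerance
  otol <- max(tol, 1e-11)                  # reduced-cost tolerance
  ztol <- 1e-11                            # pivot magnitude floor

  # --- starting basis -------------------------------------------------
  stat <- integer(N)
  use_warm <- FALSE
  if (!is.null(basis) && length(basis$basis) == m &&
      length(basis$stat) == N && !anyDuplicated(basis$basis) &&
      all(basis$basis >= 1L & basis$basis <= N)) {
    Binv <- tryCatch(solve(A[, basis$basis, drop = FALSE]),
                     error = function(e) NULL)
    if (!is.null(Binv) && all(is.finite(Binv))) {
      bas <- as.integer(basis$basis)
      stat <- as.integer(basis$stat)
      stat[bas] <- 0L
      use_warm <- TRUE
    }
  }
  if (!use_warm) {
    bas <- (N - m + 1L):N                  # slack columns form the identity
    Binv <- diag(1, m)
    stat[] <- ifelse(is.finite(lb), 1L, ifelse(is.finite(ub), 2L, 3L))
    stat[bas] <- 0L
  }

  nonbasic_value <- function(j) {
    s <- stat[j]
    if (s == 1L) lb[j] else if (s == 2L) ub[j] else 0
  }
  xN_values <- function(nb) {
    v <- numeric(length(nb))
    sN <- stat[nb]
    v[sN == 1L] <- lb[nb[sN == 1L]]
    v[sN == 2L] <- ub[nb[sN == 2L]]
    v
  }

  iter <- 0L
  pivots_since_factor <- 0L
  bland_after <- 20L * (m + N) + 200L
  status <- "numeric_failure"

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) { status <- "numeric_failure"; break }
    if (pivots_since_factor >= .simplex_refactor_every) {
      Binv <- tryCatch(solve(A[, bas, drop = FALSE]), error = function(e) NULL)
      if (is.null(Binv)) { status <- "numeric_failure"; break }
      pivots_since_factor <- 0L
    }
    nb <- which(stat != 0L)
    xN <- xN_values(nb)
    resid <- rhs - if (length(nb)) A[, nb, drop = FALSE] %*% xN else numeric(m)
    xB <- drop(Binv %*% resid)
    lbB <- lb[bas]; ubB <- ub[bas]
    low <- xB < lbB - ftol
    high <- xB > ubB + ftol
    phase1 <- any(low) || any(high)

    if (phase1) {
      c1 <- numeric(m); c1[low] <- -1; c1[high] <- 1
      pi1 <- drop(crossprod(Binv, c1))
      r <- -drop(pi1 %*% A[, nb, drop = FALSE])
    } else {
      cB <- cmin[bas]
      piv <- drop(crossprod(Binv, cB))
      r <- cmin[nb] - drop(piv %*% A[, nb, drop = FALSE])
    }

    sN <- stat[nb]
    elig_up <- (sN == 1L & r < -otol) | (sN == 3L & r < -otol)   # enter increasing
    elig_dn <- (sN == 2L & r > otol) | (sN == 3L & r > otol)     # enter decreasing
    elig <- elig_up | elig_dn
    if (!any(elig)) {
      if (phase1) {
        # phase-1 optimum still infeasible
        worst <- max(c(lbB[low] - xB[low], xB[high] - ubB[high], 0))
        status <- if (worst <= 1e-7) "optimal_tolerance" else "infeasible"
        if (status == "infeasible") break
        # accept mild residual infeasibility and fall through to phase 2
        phase1 <- FALSE
        cB <- cmin[bas]
        piv <- drop(crossprod(Binv, cB))
        r <- cmin[nb] - drop(piv %*% A[, nb, drop = FALSE])
        elig_up <- (sN == 1L & r < -otol) | (sN == 3L & r < -otol)
        elig_dn <- (sN == 2L & r > otol) | (sN == 3L & r > otol)
        elig <- elig_up | elig_dn
        if (!any(elig)) { status <- "optimal"; break }
      } else {
        status <- "optimal"; break
      }
    }

    cand <- which(elig)
    if (iter > bland_after) {
      k <- cand[which.min(nb[cand])]           # Bland's rule
    } else {
      k <- cand[which.max(abs(r[cand]))]       # Dantzig pricing
    }
    j <- nb[k]
    dir <- if (elig_up[k]) 1 else -1

    y <- drop(Binv %*% A[, j])
    delta <- -dir * y                          # d(xB)/dt, t >= 0

    # ratio test ------------------------------------------------------
    t_best <- Inf; leave <- 0L; leave_bound <- 0L; best_piv <- 0
    for (i in seq_len(m)) {
      di <- delta[i]
      if (abs(di) <= ztol) next
      xi <- xB[i]
      if (phase1 && low[i]) {
        if (di > 0) ti <- (lbB[i] - xi) / di else next
        tb <- 1L
      } else if (phase1 && high[i]) {
        if (di < 0) ti <- (ubB[i] - xi) / di else next
        tb <- 2L
      } else if (di > 0) {
        if (!is.finite(ubB[i])) next
        ti <- (ubB[i] - xi) / di
        tb <- 2L
      } else {
        if (!is.finite(lbB[i])) next
        ti <- (lbB[i] - xi) / di
        tb <- 1L
      }
      if (ti < -ftol) ti <- 0
      if (ti < t_best - 1e-10 ||
          (ti < t_best + 1e-10 && abs(di) > abs(best_piv))) {
        t_best <- ti; leave <- i; leave_bound <- tb; best_piv <- di
      }
    }
    # entering variable's own opposite bound (bound flip)
    t_self <- if (stat[j] == 1L) ub[j] - lb[j]
              else if (stat[j] == 2L) ub[j] - lb[j]
              else Inf
    if (is.finite(t_self) && t_self < t_best) {
      t_best <- t_self; leave <- 0L
    }

    if (!is.finite(t_best)) {
      if (phase1) { status <- "numeric_failure"; break }
      status <- "unbounded"; break
    }
    if (leave == 0L) {
      # bound flip, basis unchanged
      stat[j] <- if (stat[j] == 1L) 2L else 1L
      next
    }
    # pivot: j enters, bas[leave] leaves at leave_bound
    out <- bas[leave]
    stat[out] <- leave_bound
    stat[j] <- 0L
    bas[leave] <- j
    yr <- y[leave]
    if (abs(yr) <= ztol) { status <- "numeric_failure"; break }
    # eta update of Binv
    Br <- Binv[leave, ] / yr
    Binv <- Binv - outer(y, Br)
    Binv[leave, ] <- Br
    pivots_since_factor <- pivots_since_factor + 1L
  }

  if (status == "optimal_tolerance") status <- "optimal"
  x <- numeric(N)
  z <- NA_real_
  if (status %in% c("optimal", "unbounded")) {
    nb <- which(stat != 0L)
    x[nb] <- xN_values(nb)
    resid <- rhs - if (length(nb)) A[, nb, drop = FALSE] %*% x[nb] else numeric(m)
    x[bas] <- drop(Binv %*% resid)
    z <- sum(obj * x)
    if (status == "unbounded") z <- if (maximize) Inf else -Inf
  }
  list(status = status, x = x, z = z,
       basis = structure(list(basis = bas, stat = stat), class = "lp_basis"),
       iterations = iter)
}
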