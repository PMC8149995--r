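# Bounded-variable two-phase primal simplex.
#
# Solves   max / min  c'x   s.t.  A x = b,  lb <= x <= ub
# with a dense basis-inverse update, Dantzig pricing and a Bland fallback
# against cycling. Sized for constraint-based metabolic models at desk scale
# (hundreds to a few thousand variables); all FBA problems in this package
# have finite bounds, but free variables are supported.

LP_STATE_LB <- 1L
LP_STATE_UB <- 2L
LP_STATE_FREE <- 3L
LP_STATE_BASIC <- 0L

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `obj %*% x` subject to `A %*% x == b` and
#' `lb <= x <= ub`, using a two-phase primal simplex with implicit handling
#' of variable bounds. This is the workhorse behind [solve_fba()],
#' [pfba()] and [fva()].
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (m x n), dense or a `Matrix` sparse matrix.
#' @param b right-hand side vector (length m).
#' @param lb,ub lower/upper bound vectors (length n); `-Inf`/`Inf` allowed.
#' @param sense `"max"` or `"min"`.
#' @param tol pivot / feasibility tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"` or
#'   `"maxiter"`), `objective` (numeric, `NA` unless optimal) and `x`
#'   (primal solution, `NULL` unless optimal).
#' @export
lp_solve <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                     tol = 1e-9, max_iter = 100000L) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  cvec <- if (sense == "min") -as.numeric(obj) else as.numeric(obj)

  if (m == 0L) {
    # pure box problem: optimum at the bound matching the objective sign
    x <- ifelse(cvec > 0, ub, ifelse(cvec < 0, lb, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x) & cvec != 0)) {
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }
    x[!is.finite(x)] <- 0
    objv <- sum(cvec * x)
    return(list(status = "optimal",
                objective = if (sense == "min") -objv else objv, x = x))
  }

  res <- .simplex_bounded(cvec, A, as.numeric(b), as.numeric(lb),
                          as.numeric(ub), tol, as.integer(max_iter))
  if (res$status == "optimal" && sense == "min") res$objective <- -res$objective
  res
}

# core routine: maximize c'x, A x = b, lb <= x <= ub
.simplex_bounded <- function(cvec, A, b, lb, ub, tol, max_iter) {
  n <- ncol(A)
  m <- nrow(A)

  # augment with one artificial per row; sign chosen so its start value >= 0
  state <- integer(n + m)
  xval <- numeric(n + m) # current value of every variable
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      state[j] <- LP_STATE_LB; xval[j] <- lb[j]
    } else if (is.finite(ub[j])) {
      state[j] <- LP_STATE_UB; xval[j] <- ub[j]
    } else {
      state[j] <- LP_STATE_FREE; xval[j] <- 0
    }
  }
  resid <- b - as.vector(A %*% xval[seq_len(n)])
  art_sign <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(art_sign, nrow = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  basis <- n + seq_len(m)
  state[basis] <- LP_STATE_BASIC
  xval[basis] <- abs(resid)
  Binv <- diag(1 / art_sign, nrow = m) # inverse of diag(art_sign)

  phase <- 1L
  cwork <- c(rep(0, n), rep(-1, m)) # phase 1: maximize -sum(artificials)
  iter <- 0L
  bland <- FALSE
  stall <- 0L
  last_obj <- -Inf
  refactor_every <- 100L

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(status = "maxiter", objective = NA_real_, x = NULL))
    }
    if (iter %% refactor_every == 0L) {
      Binv <- tryCatch(solve(Afull[, basis, drop = FALSE]),
                       error = function(e) Binv)
      xval[basis] <- as.vector(Binv %*%
        (b - Afull[, -basis, drop = FALSE] %*% xval[-basis]))
    }

    y <- as.vector(crossprod(cwork[basis], Binv)) # simplex multipliers
    dall <- cwork - as.vector(y %*% Afull)
    nonbasic <- which(state != LP_STATE_BASIC)
    if (phase == 2L) nonbasic <- nonbasic[nonbasic <= n] # never re-enter artificials
    d <- dall[nonbasic]
    st <- state[nonbasic]
    improving <- (st == LP_STATE_LB & d > tol * 10) |
      (st == LP_STATE_UB & d < -tol * 10) |
      (st == LP_STATE_FREE & abs(d) > tol * 10)
    if (!any(improving)) {
      # optimal for current phase
      if (phase == 1L) {
        p1 <- sum(xval[n + seq_len(m)][state[n + seq_len(m)] == LP_STATE_BASIC]) +
          sum(xval[n + seq_len(m)][state[n + seq_len(m)] != LP_STATE_BASIC])
        art_total <- sum(abs(xval[(n + 1L):(n + m)]))
        if (art_total > 1e-7 * max(1, max(abs(b)))) {
          return(list(status = "infeasible", objective = NA_real_, x = NULL))
        }
        # pin artificials to zero and switch to the real objective
        ubf[(n + 1L):(n + m)] <- 0
        cwork <- c(cvec, rep(0, m))
        phase <- 2L
        bland <- FALSE
        stall <- 0L
        last_obj <- -Inf
        next
      }
      xopt <- xval[seq_len(n)]
      return(list(status = "optimal", objective = sum(cvec * xopt), x = xopt))
    }

    cand <- nonbasic[improving]
    dc <- d[improving]
    jidx <- if (bland) which.min(cand) else which.max(abs(dc))
    j <- cand[jidx]
    dir <- if (state[j] == LP_STATE_UB) -1 else if (state[j] == LP_STATE_FREE)
      sign(dall[j]) else 1

    w <- as.vector(Binv %*% Afull[, j])
    delta <- dir * w # basic values move by -t * delta
    xb <- xval[basis]
    lob <- lbf[basis]
    upb <- ubf[basis]

    tvals <- rep(Inf, m)
    pos <- delta > tol
    neg <- delta < -tol
    tvals[pos] <- (xb[pos] - lob[pos]) / delta[pos]
    tvals[neg] <- (xb[neg] - upb[neg]) / delta[neg]
    tvals[!is.finite(tvals)] <- Inf
    tvals[tvals < 0] <- 0 # numerical guard on slightly infeasible basics

    t_own <- if (is.finite(lbf[j]) && is.finite(ubf[j])) ubf[j] - lbf[j] else Inf
    tmin <- min(tvals, t_own)
    if (!is.finite(tmin)) {
      if (phase == 1L) { # phase 1 objective is bounded; treat as numerical failure
        return(list(status = "infeasible", objective = NA_real_, x = NULL))
      }
      return(list(status = "unbounded", objective = NA_real_, x = NULL))
    }

    if (t_own <= tmin + tol && t_own <= min(tvals)) {
      # bound flip: entering variable moves to its opposite bound
      xval[basis] <- xb - t_own * delta
      xval[j] <- xval[j] + dir * t_own
      state[j] <- if (dir > 0) LP_STATE_UB else LP_STATE_LB
    } else {
      ties <- which(abs(tvals - tmin) <= tol)
      r <- if (bland) ties[which.min(basis[ties])] else
        ties[which.max(abs(delta[ties]))]
      leave <- basis[r]
      xval[basis] <- xb - tmin * delta
      xval[j] <- xval[j] + dir * tmin
      xval[leave] <- if (delta[r] > 0) lob[r] else upb[r]
      state[leave] <- if (delta[r] > 0) LP_STATE_LB else LP_STATE_UB
      state[j] <- LP_STATE_BASIC
      basis[r] <- j
      # eta update of the basis inverse
      piv <- w[r]
      Binv[r, ] <- Binv[r, ] / piv
      other <- setdiff(seq_len(m), r)
      if (length(other)) {
        Binv[other, ] <- Binv[other, , drop = FALSE] -
          outer(w[other], Binv[r, ])
      }
    }

    # cycling guard: switch to Bland's rule when the objective stalls
    cur <- sum(cwork[basis] * xval[basis])
    if (cur <= last_obj + tol) stall <- stall + 1L else stall <- 0L
    last_obj <- cur
    if (stall > 2L * (n + m)) bland <- TRUE
  }
}
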