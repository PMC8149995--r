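# Independent oracles used to cross-check the package's algorithms. These
# deliberately re-derive results through unrelated routes (exhaustive
# enumeration, union-find, a second solver) and must stay independent of
# the implementation under test.

# Brute-force LP oracle: enumerate all basic solutions (basic subsets of
# size rank(A), nonbasic variables pinned at each bound combination) and
# keep the best feasible one. Only viable for a handful of variables.
lp_enum_oracle <- function(obj, A, b, lb, ub, sense = "max", tol = 1e-7) {
  n <- ncol(A)
  r <- qr(A)$rank
  best <- NULL
  for (B in utils::combn(n, r, simplify = FALSE)) {
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    combos <- if (length(N)) {
      expand.grid(rep(list(c(1, 2)), length(N)))
    } else data.frame(row.names = 1)
    for (k in seq_len(nrow(combos))) {
      xN <- numeric(length(N))
      if (length(N)) {
        pick <- as.numeric(combos[k, ])
        xN <- ifelse(pick == 1, lb[N], ub[N])
        if (any(!is.finite(xN))) next
      }
      rhs <- b - if (length(N)) A[, N, drop = FALSE] %*% xN else 0
      xB <- tryCatch(qr.solve(AB, rhs, tol = 1e-10), error = function(e) NULL)
      if (is.null(xB)) next
      x <- numeric(n); x[B] <- xB; x[N] <- xN
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      v <- sum(obj * x)
      if (is.null(best) ||
          (sense == "max" && v > best) ||
          (sense == "min" && v < best)) best <- v
    }
  }
  best
}

# Second-solver oracle: boot::simplex on the shifted problem x = v - lb >= 0
lp_boot_oracle <- function(obj, A, b, lb, ub, sense = "max") {
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  n <- ncol(A)
  # maximize obj'(x + lb) s.t. A x = b - A lb, x <= ub - lb, x >= 0;
  # boot::simplex requires non-negative right-hand sides, so equality rows
  # with negative rhs are sign-flipped
  A3 <- A
  b3 <- as.vector(b - A %*% lb)
  flip <- b3 < 0
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3[flip] <- -b3[flip]
  res <- tryCatch(
    boot::simplex(a = obj,
                  A1 = diag(n), b1 = ub - lb,
                  A3 = A3, b3 = b3,
                  maxi = (sense == "max")),
    error = function(e) NULL) # boot's tableau can fail on degenerate cases
  if (is.null(res) || res$solved != 1) return(NULL)
  sum(obj * (res$soln + lb))
}

# Union-find oracle for weakly connected components of the bipartite
# reaction-metabolite graph
wcc_union_find_oracle <- function(stoichs, currency = character(0)) {
  nodes <- c(paste0("r:", names(stoichs)),
             paste0("m:", setdiff(unique(unlist(lapply(stoichs, names))),
                                  currency)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (rid in names(stoichs)) {
    for (cid in setdiff(names(stoichs[[rid]]), currency)) {
      union(match(paste0("r:", rid), nodes),
            match(paste0("m:", cid), nodes))
    }
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  # count components that contain at least one reaction
  length(unique(roots[startsWith(nodes, "r:")]))
}
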