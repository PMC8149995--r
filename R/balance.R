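# Element and charge conservation checks, and automatic balancing with a
# small set of filler species (water, protons, electrons, methane, ethylene
# by default — the species that close the overwhelming majority of
# bookkeeping imbalances in KEGG-derived equations).

#' Check element and charge balance of a reaction
#'
#' The deficit convention is products minus substrates: a positive deficit
#' for an element means the right-hand side carries more of it. A reaction
#' is balanced iff every element deficit and the charge deficit are zero.
#' Compounds missing from `compounds` (or with an unknown formula) make the
#' reaction uncomputable; it is flagged, not errored.
#'
#' @param reaction a reaction record (list with `stoichiometry`).
#' @param compounds named list of compounds (with `formula`, `charge`).
#' @return object of class `imbalance_report`: list with `element_deficit`
#'   (named numeric), `charge_deficit`, `balanced`, `computable`.
#' @export
check_balance <- function(reaction, compounds) {
  stoich <- reaction$stoichiometry
  deficit <- numeric(0)
  charge <- 0
  computable <- TRUE
  for (cid in names(stoich)) {
    cpd <- compounds[[cid]]
    if (is.null(cpd) || is.null(cpd$formula)) {
      computable <- FALSE
      next
    }
    coef <- stoich[[cid]]
    f <- cpd$formula
    for (el in names(f)) {
      deficit[el] <- (if (el %in% names(deficit)) deficit[[el]] else 0) +
        coef * f[[el]]
    }
    charge <- charge + coef * (if (is.null(cpd$charge)) 0 else cpd$charge)
  }
  deficit <- deficit[abs(deficit) > 1e-9]
  structure(list(element_deficit = deficit,
                 charge_deficit = charge,
                 balanced = computable && length(deficit) == 0L &&
                   abs(charge) < 1e-9,
                 computable = computable),
            class = "imbalance_report")
}

#' @export
print.imbalance_report <- function(x, ...) {
  if (!x$computable) {
    cat("imbalance not computable (species with unknown formula)\n")
  } else if (x$balanced) {
    cat("balanced (all element and charge deficits zero)\n")
  } else {
    cat("unbalanced; deficits (products - substrates):\n")
    for (el in names(x$element_deficit)) {
      cat("  ", el, ": ", x$element_deficit[[el]], "\n", sep = "")
    }
    if (abs(x$charge_deficit) > 1e-9) {
      cat("  charge:", x$charge_deficit, "\n")
    }
  }
  invisible(x)
}

#' Default filler species for equation balancing
#'
#' Water, proton, electron, methane and ethylene, in that priority order,
#' using their KEGG compound accessions.
#' @return character vector of compound ids.
#' @export
default_fillers <- function() {
  c(H2O = "C00001", `H+` = "C00080", `e-` = "C05359",
    CH4 = "C01438", ethylene = "C06547")
}

# depth-first search for integer filler multiples in [-max_coef, max_coef]
# that zero every deficit; minimizes sum(|coef|), first-found wins among ties
# (fillers explored in list order, coefficients in order 0, 1, -1, 2, -2, ...)
.filler_search <- function(deficit, charge, filler_info, max_coef = 10L) {
  k <- length(filler_info)
  best <- NULL
  best_total <- Inf
  # track every element the deficit or any filler touches, so a filler can
  # never fix one element while silently unbalancing another
  elements <- sort(unique(c(names(deficit),
                            unlist(lapply(filler_info,
                                          function(f) names(f$formula))))))
  contrib <- matrix(0, nrow = k, ncol = length(elements) + 1L,
                    dimnames = list(NULL, c(elements, ".charge")))
  for (i in seq_len(k)) {
    f <- filler_info[[i]]
    for (el in names(f$formula)) {
      contrib[i, el] <- f$formula[[el]]
    }
    contrib[i, ".charge"] <- f$charge
  }
  target <- stats::setNames(numeric(length(elements) + 1L),
                            c(elements, ".charge"))
  target[names(deficit)] <- -unlist(deficit)
  target[".charge"] <- -charge
  coef_order <- c(0L, as.vector(rbind(seq_len(max_coef), -seq_len(max_coef))))

  rec <- function(i, acc, total) {
    if (total >= best_total) return()
    if (i > k) {
      if (all(abs(acc - target) < 1e-9)) {
        best <<- integer(0)
        best_total <<- total
        best <<- acc_path
      }
      return()
    }
    # prune: remaining fillers must be able to close every residual
    rem <- target - acc
    if (i <= k) {
      reach <- colSums(abs(contrib[i:k, , drop = FALSE])) * max_coef
      if (any(abs(rem) > reach + 1e-9)) return()
    }
    for (a in coef_order) {
      acc_path[i] <<- a
      rec(i + 1L, acc + a * contrib[i, ], total + abs(a))
    }
    acc_path[i] <<- 0L
  }
  acc_path <- integer(k)
  rec(1L, stats::setNames(numeric(length(target)), names(target)), 0L)
  best
}

#' Balance a reaction by adding filler species
#'
#' Searches integer multiples (|coefficient| <= `max_coef`) of the filler
#' species, added to either side, that zero all element and charge deficits.
#' Among solutions it minimizes the total filler count (sum of absolute
#' coefficients); ties resolve deterministically in filler list order. The
#' original non-filler stoichiometry is never modified.
#'
#' @param reaction a reaction record.
#' @param compounds named list of compounds covering the reaction species
#'   and the fillers.
#' @param fillers ordered character vector of filler compound ids; defaults
#'   to [default_fillers()].
#' @param max_coef bound on each filler coefficient magnitude.
#' @return list with `reaction` (balanced or untouched), `status` one of
#'   `"already_balanced"`, `"balanced"`, `"unbalanceable"`,
#'   `"uncomputable"`, and `added` (named numeric of filler coefficients).
#' @export
balance_reaction <- function(reaction, compounds, fillers = default_fillers(),
                             max_coef = 10L) {
  rep0 <- check_balance(reaction, compounds)
  if (!rep0$computable) {
    return(list(reaction = reaction, status = "uncomputable",
                added = numeric(0)))
  }
  if (rep0$balanced) {
    return(list(reaction = reaction, status = "already_balanced",
                added = numeric(0)))
  }
  fillers <- Filter(function(cid) {
    !is.null(compounds[[cid]]) && !is.null(compounds[[cid]]$formula)
  }, fillers)
  filler_info <- lapply(fillers, function(cid) compounds[[cid]])
  sol <- .filler_search(rep0$element_deficit, rep0$charge_deficit,
                        filler_info, max_coef)
  if (is.null(sol)) {
    return(list(reaction = reaction, status = "unbalanceable",
                added = numeric(0)))
  }
  added <- stats::setNames(as.numeric(sol), fillers)[sol != 0]
  stoich <- reaction$stoichiometry
  for (cid in names(added)) {
    stoich[cid] <- (if (cid %in% names(stoich)) stoich[[cid]] else 0) +
      added[[cid]]
  }
  reaction$stoichiometry <- stoich[stoich != 0]
  list(reaction = reaction, status = "balanced", added = added)
}
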