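# Flux balance analysis: stoichiometric matrix assembly, LP solution,
# synthesis capability tests, growth maximization, parsimonious flux
# distributions and flux variability.

#' Build the stoichiometric system of a model
#'
#' Rows are metabolites, columns reactions, both in sorted id order so the
#' mapping is deterministic; entries are the stoichiometric coefficients.
#'
#' @param model a `metabolic_model`.
#' @return object of class `stoichiometric_system`: sparse `S`, bound
#'   vectors `lb`/`ub`, `objective` coefficient vector, and the id
#'   orderings `metabolite_ids` / `reaction_ids`.
#' @export
build_matrix <- function(model) {
  validate_model(model)
  met_ids <- sort(names(model$metabolites))
  rxn_ids <- sort(names(model$reactions))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions[[rxn_ids[j]]]$stoichiometry
    ii <- c(ii, met_index[names(st)])
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, as.numeric(st))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  lb <- vapply(model$reactions[rxn_ids], `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions[rxn_ids], `[[`, numeric(1), "upper_bound")
  obj <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  if (!is.na(model$objective)) obj[model$objective] <- 1
  structure(list(S = S, lb = lb, ub = ub, objective = obj,
                 metabolite_ids = met_ids, reaction_ids = rxn_ids),
            class = "stoichiometric_system")
}

#' @export
print.stoichiometric_system <- function(x, ...) {
  nz <- Matrix::nnzero(x$S)
  cat("Stoichiometric system: ", nrow(x$S), " metabolites x ",
      ncol(x$S), " reactions, ", nz, " nonzeros (density ",
      signif(nz / (nrow(x$S) * ncol(x$S)), 3), ")\n", sep = "")
  invisible(x)
}

#' Solve the FBA linear program
#'
#' Optimizes `objective . v` subject to the steady-state constraint
#' `S v = 0` and the flux bounds, via the package's bounded-variable
#' simplex ([lp_solve()]).
#'
#' @param system a `stoichiometric_system`.
#' @param sense `"max"` or `"min"`.
#' @return object of class `flux_solution`: `status`, `objective_value`,
#'   `fluxes` (named), and `residual` (max |S v|).
#' @export
solve_fba <- function(system, sense = c("max", "min")) {
  sense <- match.arg(sense)
  res <- lp_solve(system$objective, system$S, rep(0, nrow(system$S)),
                  system$lb, system$ub, sense = sense)
  fluxes <- NULL
  residual <- NA_real_
  if (res$status == "optimal") {
    fluxes <- stats::setNames(res$x, system$reaction_ids)
    residual <- if (nrow(system$S)) max(abs(system$S %*% res$x)) else 0
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal")
                   res$objective else NA_real_,
                 fluxes = fluxes, residual = residual),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution: status ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", objective ", signif(x$objective_value, 6),
        ", residual ", format(x$residual, digits = 3), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Maximum synthesis flux of a compound
#'
#' Sets the compound's exchange reaction as the objective and maximizes it.
#' If the model has no exchange for the compound, a temporary secretion-only
#' (0, 1000) demand on the cytosolic species is used. A maximum of 0 means
#' the compound cannot be synthesized under the current medium.
#'
#' @param model a `metabolic_model`.
#' @param compound_id plain compound accession (no compartment suffix).
#' @return the maximal flux (numeric scalar).
#' @export
max_synthesis_flux <- function(model, compound_id) {
  ex <- paste0("EX_", compound_id)
  if (is.null(model$reactions[[ex]])) {
    mc <- met_id(compound_id, "c")
    if (is.null(model$metabolites[[mc]])) {
      stop("compound ", compound_id, " is not in the model")
    }
    dm <- paste0("DM_", compound_id)
    model$reactions[[dm]] <- list(
      id = dm, stoichiometry = stats::setNames(-1, mc),
      lower_bound = 0, upper_bound = 1000, direction = "forward",
      kind = "metabolic", gpr = NULL, pathways = character(0),
      subsystem = NA_character_, tags = "demand")
    model$objective <- dm
  } else {
    model$objective <- ex
  }
  sol <- solve_fba(build_matrix(model), "max")
  if (sol$status != "optimal") {
    stop("synthesis LP for ", compound_id, " ended with status ", sol$status)
  }
  sol$objective_value
}

#' Maximum growth rate of a model
#'
#' Maximizes the flux of the (single) biomass reaction; the optimum is the
#' growth rate in 1/h.
#'
#' @param model a `metabolic_model` carrying exactly one biomass reaction.
#' @return growth rate (numeric scalar).
#' @export
max_growth <- function(model) {
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  bio <- names(kinds)[kinds == "biomass"]
  if (length(bio) != 1L) {
    stop("model must have exactly one biomass reaction (found ",
         length(bio), ")")
  }
  model$objective <- bio
  sol <- solve_fba(build_matrix(model), "max")
  if (sol$status != "optimal") {
    stop("growth LP ended with status ", sol$status)
  }
  sol$objective_value
}

# parsimonious FBA: minimize sum |v| with the objective reaction pinned.
# Implemented by splitting v = p - q, p,q >= 0.
.pfba_fluxes <- function(system, pinned_id, pinned_value) {
  j <- match(pinned_id, system$reaction_ids)
  lb <- system$lb; ub <- system$ub
  lb[j] <- pinned_value; ub[j] <- pinned_value
  n <- length(lb)
  S2 <- cbind(system$S, -system$S)
  lb2 <- c(pmax(lb, 0), pmax(-ub, 0))
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  obj <- rep(1, 2L * n)
  res <- lp_solve(obj, S2, rep(0, nrow(S2)), lb2, ub2, sense = "min")
  if (res$status != "optimal") {
    stop("parsimonious FBA ended with status ", res$status)
  }
  stats::setNames(res$x[seq_len(n)] - res$x[n + seq_len(n)],
                  system$reaction_ids)
}

#' Flux variability at a fixed objective flux
#'
#' For each requested reaction, minimizes and maximizes its flux with the
#' pinned reaction held at `pinned_value`, exposing alternate optima.
#'
#' @param model a `metabolic_model`.
#' @param reaction_ids reactions to scan.
#' @param pinned_id reaction held fixed (default: the biomass reaction).
#' @param pinned_value the value it is held at.
#' @return data.frame with `reaction_id`, `min`, `max`.
#' @export
fva <- function(model, reaction_ids, pinned_id, pinned_value) {
  system <- build_matrix(model)
  j <- match(pinned_id, system$reaction_ids)
  if (is.na(j)) stop("unknown pinned reaction ", pinned_id)
  system$lb[j] <- pinned_value
  system$ub[j] <- pinned_value
  out <- data.frame(reaction_id = reaction_ids, min = NA_real_,
                    max = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(reaction_ids)) {
    system$objective[] <- 0
    system$objective[reaction_ids[k]] <- 1
    lo <- solve_fba(system, "min")
    hi <- solve_fba(system, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA LP for ", reaction_ids[k], " did not reach optimality")
    }
    out$min[k] <- lo$objective_value
    out$max[k] <- hi$objective_value
  }
  out
}

#' Nutrient requirement profile at fixed growth
#'
#' Pins the biomass flux (default 1/h), computes a parsimonious flux
#' distribution (minimizing total absolute flux, which tames the alternate
#' optima that plague single FBA vertices), and attaches the flux
#' variability range of every exchange reaction at that growth rate.
#' Negative exchange flux is uptake from the feed, positive is secretion.
#'
#' @param model a `metabolic_model` with one biomass reaction.
#' @param biomass_flux growth rate to fix, 1/h.
#' @return object of class `requirement_profile`: list with `variety`,
#'   `biomass_flux` and `profile`, a data.frame (nutrient, reaction_id,
#'   flux, fva_min, fva_max, class, lower_bound, upper_bound).
#' @export
nutrient_requirements <- function(model, biomass_flux = 1) {
  g <- max_growth(model)
  if (g < biomass_flux - 1e-9) {
    stop("infeasible at requested growth: maximum growth rate is ",
         signif(g, 6), " < ", biomass_flux)
  }
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  bio <- names(kinds)[kinds == "biomass"]
  system <- build_matrix(model)
  fluxes <- .pfba_fluxes(system, bio, biomass_flux)
  ex_ids <- sort(names(kinds)[kinds == "exchange"])
  ranges <- fva(model, ex_ids, bio, biomass_flux)
  cids <- vapply(ex_ids, function(rid) {
    .met_compound(names(model$reactions[[rid]]$stoichiometry)[1])
  }, character(1))
  cls <- vapply(cids, function(cid) {
    hits <- names(model$nutrient_classes)[vapply(
      model$nutrient_classes, function(v) cid %in% v, logical(1))]
    if (length(hits)) hits[1] else NA_character_
  }, character(1))
  profile <- data.frame(
    nutrient = cids,
    reaction_id = ex_ids,
    flux = unname(fluxes[ex_ids]),
    fva_min = ranges$min,
    fva_max = ranges$max,
    class = cls,
    lower_bound = vapply(model$reactions[ex_ids], `[[`, numeric(1),
                         "lower_bound"),
    upper_bound = vapply(model$reactions[ex_ids], `[[`, numeric(1),
                         "upper_bound"),
    stringsAsFactors = FALSE)
  rownames(profile) <- NULL
  tags <- model$reactions[[bio]]$tags
  variety <- sub("^variety:", "", grep("^variety:", tags, value = TRUE)[1])
  structure(list(variety = if (is.na(variety)) NULL else variety,
                 biomass_flux = biomass_flux, profile = profile),
            class = "requirement_profile")
}

#' @export
print.requirement_profile <- function(x, ...) {
  cat("Nutrient requirement profile",
      if (!is.null(x$variety)) paste0("(variety '", x$variety, "')"),
      "at biomass flux", x$biomass_flux, "/h\n")
  df <- x$profile
  df$flux <- round_half_up(df$flux, 2)
  df$fva_min <- round_half_up(df$fva_min, 2)
  df$fva_max <- round_half_up(df$fva_max, 2)
  print(utils::head(df[order(df$flux), ], 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ...", nrow(df) - 20, "more exchanges\n")
  invisible(x)
}
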