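# The compartmentalized constraint-based model. Metabolites are
# (compound, compartment) pairs written "C00031[c]"; reactions carry
# stoichiometry over metabolites, flux bounds in mmol/gDW/h, a kind tag
# (metabolic / transport / exchange / biomass), and optionally a GPR.

met_id <- function(compound_id, compartment) {
  paste0(compound_id, "[", compartment, "]")
}

.met_compound <- function(met) sub("\\[[ce]\\]$", "", met)
.met_compartment <- function(met) sub("^.*\\[([ce])\\]$", "\\1", met)

#' Convert a refined draft network into a compartmentalized model
#'
#' Every metabolic reaction is placed in the cytosol `(c)`; reversible
#' reactions get bounds (-1000, 1000) mmol/gDW/h and irreversible ones
#' (0, 1000). Transport, exchange and biomass reactions are added later by
#' [add_boundary_reactions()] and [add_biomass_reaction()].
#'
#' @param network a `draft_network`.
#' @param id model identifier string.
#' @return an object of class `metabolic_model`.
#' @export
network_to_model <- function(network, id = "model") {
  metabolites <- list()
  reactions <- list()
  for (rid in sort(names(network$reactions))) {
    entry <- network$reactions[[rid]]
    rec <- entry$record
    stoich <- rec$stoichiometry
    mids <- met_id(names(stoich), "c")
    for (k in seq_along(mids)) {
      if (is.null(metabolites[[mids[k]]])) {
        metabolites[[mids[k]]] <- list(id = mids[k],
                                       compound_id = names(stoich)[k],
                                       compartment = "c")
      }
    }
    rev <- identical(rec$direction, "reversible")
    reactions[[rid]] <- list(
      id = rid,
      stoichiometry = stats::setNames(as.numeric(stoich), mids),
      lower_bound = if (rev) -1000 else 0,
      upper_bound = 1000,
      direction = rec$direction,
      kind = "metabolic",
      gpr = entry$gpr,
      pathways = rec$pathways,
      subsystem = rec$subsystem,
      tags = if (is.null(rec$tags)) character(0) else rec$tags)
  }
  structure(list(id = id,
                 metabolites = metabolites[order(names(metabolites))],
                 reactions = reactions,
                 objective = NA_character_,
                 compartments = c(c = "cytosol", e = "extracellular"),
                 nutrient_classes = list()),
            class = "metabolic_model")
}

#' Default flux bounds policy
#'
#' Bounds in mmol/gDW/h: reversible and transport reactions (-1000, 1000);
#' irreversible (0, 1000); exchanges (0, 1000) for nutrients the model can
#' synthesize, (-5, 1000) for nutrients absorbed from feed, and (-1, 1000)
#' for trace elements. Negative exchange flux is uptake.
#'
#' @return object of class `bounds_policy` (a named list of length-2
#'   numeric vectors).
#' @export
bounds_policy <- function() {
  structure(list(reversible = c(-1000, 1000),
                 irreversible = c(0, 1000),
                 transport = c(-1000, 1000),
                 exchange_synthesizable = c(0, 1000),
                 exchange_feed_nutrient = c(-5, 1000),
                 exchange_trace_element = c(-1, 1000)),
            class = "bounds_policy")
}

#' Add transport and exchange reactions for nutrient classes
#'
#' For each nutrient compound: one transport reaction `TR_<cid>`
#' (X(e) <-> X(c)) and one exchange reaction `EX_<cid>` (X(e) <-> nothing),
#' creating the extracellular (and if needed cytosolic) metabolites.
#' Re-adding a boundary pair for a compound is an error, not silent
#' duplication.
#'
#' @param model a `metabolic_model`.
#' @param nutrient_classes named list: class name (e.g. `"amino_acid"`,
#'   `"trace_element"`) -> character vector of compound ids. Stored on the
#'   model for later bounds classification.
#' @return the augmented model.
#' @export
add_boundary_reactions <- function(model, nutrient_classes) {
  stopifnot(inherits(model, "metabolic_model"))
  all_cids <- sort(unique(unlist(nutrient_classes)))
  for (cid in all_cids) {
    tr <- paste0("TR_", cid)
    ex <- paste0("EX_", cid)
    if (!is.null(model$reactions[[tr]]) || !is.null(model$reactions[[ex]])) {
      stop("boundary reactions already exist for compound ", cid)
    }
    me <- met_id(cid, "e")
    mc <- met_id(cid, "c")
    if (is.null(model$metabolites[[me]])) {
      model$metabolites[[me]] <- list(id = me, compound_id = cid,
                                      compartment = "e")
    }
    if (is.null(model$metabolites[[mc]])) {
      model$metabolites[[mc]] <- list(id = mc, compound_id = cid,
                                      compartment = "c")
    }
    model$reactions[[tr]] <- list(
      id = tr, stoichiometry = stats::setNames(c(-1, 1), c(me, mc)),
      lower_bound = -1000, upper_bound = 1000, direction = "reversible",
      kind = "transport", gpr = NULL, pathways = character(0),
      subsystem = NA_character_, tags = character(0))
    model$reactions[[ex]] <- list(
      id = ex, stoichiometry = stats::setNames(-1, me),
      lower_bound = 0, upper_bound = 1000, direction = "reversible",
      kind = "exchange", gpr = NULL, pathways = character(0),
      subsystem = NA_character_, tags = character(0))
  }
  model$metabolites <- model$metabolites[order(names(model$metabolites))]
  for (cls in names(nutrient_classes)) {
    model$nutrient_classes[[cls]] <-
      sort(unique(c(model$nutrient_classes[[cls]], nutrient_classes[[cls]])))
  }
  model
}

#' Apply the flux bounds policy to every reaction
#'
#' Metabolic reactions get reversible/irreversible bounds from their
#' direction; transport reactions the transport bounds; exchange reactions
#' are classified with precedence trace element > synthesizable > feed
#' nutrient. An exchange whose compound is in no class defaults to feed
#' nutrient with a warning.
#'
#' @param model a `metabolic_model` with boundary reactions.
#' @param policy a [bounds_policy()].
#' @param synthesizable compound ids the organism can make itself.
#' @param trace_elements compound ids treated as trace elements.
#' @return the model with bounds set.
#' @export
apply_bounds_policy <- function(model, policy = bounds_policy(),
                                synthesizable = character(0),
                                trace_elements = character(0)) {
  unclassified <- character(0)
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    bounds <- switch(r$kind,
      metabolic = if (identical(r$direction, "forward"))
        policy$irreversible else policy$reversible,
      transport = policy$transport,
      biomass = c(0, 1000),
      exchange = {
        cid <- .met_compound(names(r$stoichiometry)[1])
        if (cid %in% trace_elements) {
          policy$exchange_trace_element
        } else if (cid %in% synthesizable) {
          policy$exchange_synthesizable
        } else {
          if (!cid %in% unlist(model$nutrient_classes)) {
            unclassified <- c(unclassified, cid)
          }
          policy$exchange_feed_nutrient
        }
      },
      stop("unknown reaction kind: ", r$kind))
    model$reactions[[rid]]$lower_bound <- bounds[1]
    model$reactions[[rid]]$upper_bound <- bounds[2]
  }
  if (length(unclassified)) {
    warning("exchange compound(s) in no nutrient class, treated as feed ",
            "nutrients: ", paste(unclassified, collapse = ", "))
  }
  model
}

#' Validate the structural invariants of a model
#'
#' Checks: bounds ordered; every reaction references existing metabolites;
#' exchanges touch exactly one extracellular species; transports span both
#' compartments; metabolic reactions are purely cytosolic.
#'
#' @param model a `metabolic_model`.
#' @return invisibly `TRUE`; errors with all violations otherwise.
#' @export
validate_model <- function(model) {
  problems <- character(0)
  mids <- names(model$metabolites)
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound) {
      problems <- c(problems, paste0(r$id, ": lower bound above upper"))
    }
    unknown <- setdiff(names(r$stoichiometry), mids)
    if (length(unknown)) {
      problems <- c(problems, paste0(r$id, ": unknown metabolite(s) ",
                                     paste(unknown, collapse = ", ")))
    }
    comps <- .met_compartment(names(r$stoichiometry))
    if (r$kind == "exchange" &&
        !(length(comps) == 1L && comps == "e")) {
      problems <- c(problems, paste0(r$id, ": exchange must have exactly ",
                                     "one extracellular species"))
    }
    if (r$kind == "transport" && !setequal(unique(comps), c("c", "e"))) {
      problems <- c(problems, paste0(r$id, ": transport must span both ",
                                     "compartments"))
    }
    if (r$kind == "metabolic" && any(comps != "c")) {
      problems <- c(problems, paste0(r$id, ": metabolic reaction must be ",
                                     "cytosolic"))
    }
  }
  if (length(problems)) {
    stop("model validation failed:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(TRUE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  kinds <- vapply(x$reactions, `[[`, character(1), "kind")
  comps <- vapply(x$metabolites, `[[`, character(1), "compartment")
  cat("Constraint-based metabolic model '", x$id, "'\n", sep = "")
  cat("  reactions: ", length(x$reactions),
      " (metabolic ", sum(kinds == "metabolic"),
      ", transport ", sum(kinds == "transport"),
      ", exchange ", sum(kinds == "exchange"),
      ", biomass ", sum(kinds == "biomass"), ")\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      " (cytosol ", sum(comps == "c"),
      ", extracellular ", sum(comps == "e"), ")\n", sep = "")
  if (!is.na(x$objective)) cat("  objective:", x$objective, "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  kinds <- vapply(object$reactions, `[[`, character(1), "kind")
  comps <- vapply(object$metabolites, `[[`, character(1), "compartment")
  genes <- sort(unique(unlist(lapply(object$reactions,
                                     function(r) gpr_genes(r$gpr)))))
  paths <- sort(unique(unlist(lapply(object$reactions, `[[`, "pathways"))))
  subs <- sort(unique(stats::na.omit(vapply(object$reactions, `[[`,
                                            character(1), "subsystem"))))
  out <- list(genes = length(genes),
              reactions = length(object$reactions),
              metabolic_reactions = sum(kinds == "metabolic"),
              transport_reactions = sum(kinds == "transport"),
              exchange_reactions = sum(kinds == "exchange"),
              biomass_reactions = sum(kinds == "biomass"),
              metabolites = length(object$metabolites),
              cytosol_metabolites = sum(comps == "c"),
              extracellular_metabolites = sum(comps == "e"),
              pathways = length(paths),
              subsystems = length(subs))
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat("Model characteristics\n")
  for (k in names(x)) cat(sprintf("  %-26s %d\n", gsub("_", " ", k), x[[k]]))
  invisible(x)
}
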