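# Blocked-precursor diagnosis and repair. A biomass precursor whose maximal
# synthesis flux is zero marks a flaw in the synthetic route; repair
# searches small sets of universe reactions (and direction reversals of
# existing irreversible reactions) that unblock it.

# universe reactions within `depth` reaction-layers of the target compound,
# walking the bipartite compound/reaction graph with currency excluded
.reactions_near <- function(universe, target, depth,
                            currency = default_currency_metabolites()) {
  frontier <- target
  seen_cpd <- character(0)
  found <- character(0)
  for (d in seq_len(depth)) {
    seen_cpd <- union(seen_cpd, frontier)
    layer <- Filter(function(rid) {
      any(names(universe$reactions[[rid]]$stoichiometry) %in% frontier)
    }, names(universe$reactions))
    found <- union(found, layer)
    frontier <- setdiff(
      unique(unlist(lapply(universe$reactions[layer],
                           function(r) names(r$stoichiometry)))),
      union(seen_cpd, currency))
    if (length(frontier) == 0L) break
  }
  sort(found)
}

.apply_edit <- function(model, edit, universe) {
  if (edit$type == "add") {
    rec <- universe$reactions[[edit$id]]
    stoich <- rec$stoichiometry
    mids <- met_id(names(stoich), "c")
    for (m in mids) {
      if (is.null(model$metabolites[[m]])) {
        model$metabolites[[m]] <- list(id = m, compound_id = .met_compound(m),
                                       compartment = "c")
      }
    }
    rev <- identical(rec$direction, "reversible")
    model$reactions[[edit$id]] <- list(
      id = edit$id, stoichiometry = stats::setNames(as.numeric(stoich), mids),
      lower_bound = if (rev) -1000 else 0, upper_bound = 1000,
      direction = rec$direction, kind = "metabolic", gpr = NULL,
      pathways = rec$pathways, subsystem = rec$subsystem, tags = "repair")
  } else { # reverse: swap reactants and products of an irreversible reaction
    r <- model$reactions[[edit$id]]
    r$stoichiometry <- -r$stoichiometry
    r$tags <- union(r$tags, "reversed")
    model$reactions[[edit$id]] <- r
  }
  model
}

#' Diagnose and repair blocked biomass precursors
#'
#' For every target compound whose [max_synthesis_flux()] is zero, searches
#' candidate edits — universe reactions near the target in the
#' compound-reaction graph, plus direction reversals of irreversible model
#' reactions adjacent to those candidates — in order of increasing edit-set
#' size (1, 2, ... up to `max_additions`). The first edit set making the
#' synthesis flux positive is applied; within a size, sets are tried in
#' lexicographic candidate order, so the result is deterministic and the
#' found set is minimal.
#'
#' @param model a `metabolic_model` whose targets have exchange reactions.
#' @param targets character vector of compound ids to check.
#' @param universe a `kegg_universe` supplying candidate reactions.
#' @param max_additions largest edit-set size to try (default 3).
#' @param search_depth how many reaction layers around the target to draw
#'   candidates from.
#' @return list with `model` (repaired) and `report`, a `repair_report`:
#'   per-target status (`"ok"`, `"repaired"`, `"unrepaired"`) and the edits
#'   applied.
#' @export
diagnose_and_repair <- function(model, targets, universe,
                                max_additions = 3L, search_depth = 4L) {
  report <- list()
  for (target in targets) {
    f0 <- max_synthesis_flux(model, target)
    if (f0 > 1e-9) {
      report[[target]] <- list(status = "ok", flux = f0, edits = list())
      next
    }
    near <- .reactions_near(universe, target, search_depth)
    add_ids <- setdiff(near, names(model$reactions))
    edits <- lapply(add_ids, function(id) list(type = "add", id = id))
    # reversal candidates: irreversible model reactions touching the same
    # compound neighbourhood (a wrong-direction reaction on the route)
    near_cpds <- unique(unlist(lapply(universe$reactions[near],
                                      function(r) names(r$stoichiometry))))
    rev_ids <- Filter(function(rid) {
      r <- model$reactions[[rid]]
      r$kind == "metabolic" && identical(r$direction, "forward") &&
        any(.met_compound(names(r$stoichiometry)) %in% near_cpds)
    }, sort(names(model$reactions)))
    edits <- c(edits, lapply(rev_ids, function(id)
      list(type = "reverse", id = id)))
    found <- NULL
    for (size in seq_len(min(max_additions, length(edits)))) {
      combos <- utils::combn(seq_along(edits), size, simplify = FALSE)
      for (combo in combos) {
        trial <- model
        for (k in combo) trial <- .apply_edit(trial, edits[[k]], universe)
        f <- max_synthesis_flux(trial, target)
        if (f > 1e-9) {
          found <- list(edits = edits[combo], flux = f, model = trial)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) {
      report[[target]] <- list(status = "unrepaired", flux = 0,
                               edits = list())
    } else {
      model <- found$model
      report[[target]] <- list(status = "repaired", flux = found$flux,
                               edits = found$edits)
    }
  }
  class(report) <- "repair_report"
  list(model = model, report = report)
}

#' @export
print.repair_report <- function(x, ...) {
  cat("Precursor repair report\n")
  for (target in names(x)) {
    e <- x[[target]]
    cat("  ", target, ": ", e$status, sep = "")
    if (length(e$edits)) {
      cat(" via ", paste(vapply(e$edits, function(ed)
        paste0(ed$type, ":", ed$id), character(1)), collapse = ", "),
        sep = "")
    }
    cat(" (flux ", signif(e$flux, 4), ")\n", sep = "")
  }
  invisible(x)
}
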