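# Connectivity-based gap filling. The network is viewed as an undirected
# bipartite graph (reactions <-> their metabolites, currency metabolites
# excluded) and decomposed into weakly connected components (WCCs); gaps are
# filled greedily with universe reactions that merge components, first
# within shared pathways, then globally.

.network_stoichs <- function(network) {
  if (inherits(network, "draft_network")) {
    lapply(network$reactions, function(r) r$record$stoichiometry)
  } else if (is.list(network) && !is.null(network$reactions)) {
    lapply(network$reactions, function(r) {
      if (!is.null(r$record)) r$record$stoichiometry else r$stoichiometry
    })
  } else {
    stop("cannot extract stoichiometries from this network object")
  }
}

#' Default currency metabolites excluded from connectivity analysis
#'
#' Ubiquitous cofactors (water, protons, ATP/ADP, NAD(P)(H), phosphate,
#' CO2, O2, electrons) would connect essentially every reaction and
#' collapse the component structure to a single blob, so they carry no
#' connectivity edges by default. The list ships as a TSV (columns
#' `compound_id`, `name`) and is configurable.
#'
#' @param path optional path to a currency TSV.
#' @return character vector of compound ids.
#' @export
default_currency_metabolites <- function(path = system.file(
    "extdata", "currency_metabolites.tsv", package = "fluxforge")) {
  utils::read.delim(path, colClasses = "character")$compound_id
}

#' Decompose a network into weakly connected components
#'
#' @param network a `draft_network` (or any list with per-reaction
#'   stoichiometries).
#' @param currency_excluded compound ids excluded from connectivity edges.
#' @return object of class `wcc_partition`: list with `components` (list of
#'   reaction-id vectors, ordered by smallest contained reaction id),
#'   `metabolite_assignment` (named integer: metabolite -> component index)
#'   and `n` (component count).
#' @export
compute_wccs <- function(network,
                         currency_excluded = default_currency_metabolites()) {
  stoichs <- .network_stoichs(network)
  if (length(stoichs) == 0L) {
    return(structure(list(components = list(),
                          metabolite_assignment = integer(0), n = 0L),
                     class = "wcc_partition"))
  }
  rids <- names(stoichs)
  edges <- character(0)
  mets <- character(0)
  for (rid in rids) {
    cids <- setdiff(names(stoichs[[rid]]), currency_excluded)
    mets <- c(mets, cids)
    if (length(cids)) {
      edges <- c(edges, rbind(paste0("r:", rid), paste0("m:", cids)))
    }
  }
  mets <- sort(unique(mets))
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(paste0("r:", rids), paste0("m:", mets)))
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  memb <- comp$membership
  vnames <- names(memb)
  rmask <- startsWith(vnames, "r:")
  rx_comp <- split(substring(vnames[rmask], 3L), memb[rmask])
  rx_comp <- lapply(rx_comp, sort)
  # deterministic ordering: by smallest contained reaction id
  ord <- order(vapply(rx_comp, `[`, character(1), 1L))
  rx_comp <- unname(rx_comp[ord])
  # remap membership ids to the new ordering
  old_ids <- as.integer(names(split(seq_along(memb[rmask]), memb[rmask])))[ord]
  remap <- stats::setNames(seq_along(old_ids), old_ids)
  mmask <- startsWith(vnames, "m:")
  met_assign <- remap[as.character(memb[mmask])]
  names(met_assign) <- substring(vnames[mmask], 3L)
  met_assign <- met_assign[!is.na(met_assign)] # metabolite-only components
  structure(list(components = rx_comp,
                 metabolite_assignment = met_assign,
                 n = length(rx_comp)),
            class = "wcc_partition")
}

#' @export
print.wcc_partition <- function(x, ...) {
  cat("WCC partition:", x$n, "component(s); sizes:",
      paste(utils::head(lengths(x$components), 20L), collapse = ", "),
      if (x$n > 20L) "..." else "", "\n")
  invisible(x)
}

.component_pathways <- function(network, partition) {
  lapply(partition$components, function(rids) {
    sort(unique(unlist(lapply(network$reactions[rids],
                              function(r) r$record$pathways))))
  })
}

#' Find universe reactions able to merge network components
#'
#' A candidate is a universe reaction absent from the network whose
#' (non-currency) metabolites touch at least two distinct components. At
#' pathway scale, the candidate must additionally share a pathway with
#' every component it touches. Candidates are ranked by number of
#' components merged (descending), ties by reaction id.
#'
#' @param network a `draft_network`.
#' @param universe a `kegg_universe`.
#' @param scale `"pathway"` or `"global"`.
#' @param currency_excluded compound ids without connectivity edges.
#' @param partition optionally a precomputed [compute_wccs()] partition.
#' @return character vector of reaction ids, best candidate first.
#' @export
find_gap_candidates <- function(network, universe,
                                scale = c("pathway", "global"),
                                currency_excluded = default_currency_metabolites(),
                                partition = NULL) {
  scale <- match.arg(scale)
  if (is.null(partition)) {
    partition <- compute_wccs(network, currency_excluded)
  }
  if (partition$n < 2L) return(character(0))
  comp_paths <- if (scale == "pathway") {
    .component_pathways(network, partition)
  }
  absent <- setdiff(names(universe$reactions), names(network$reactions))
  ids <- character(0)
  merged <- integer(0)
  for (rid in absent) {
    rec <- universe$reactions[[rid]]
    if (isTRUE(rec$flags$generic) || isTRUE(rec$flags$incomplete) ||
        isTRUE(rec$flags$symbolic_coefficient)) next
    cids <- setdiff(names(rec$stoichiometry), currency_excluded)
    comps <- unique(partition$metabolite_assignment[
      intersect(cids, names(partition$metabolite_assignment))])
    if (length(comps) < 2L) next
    if (scale == "pathway") {
      if (length(rec$pathways) == 0L) next
      share <- vapply(comps, function(k) {
        length(intersect(rec$pathways, comp_paths[[k]])) > 0L
      }, logical(1))
      if (!all(share)) next
    }
    ids <- c(ids, rid)
    merged <- c(merged, length(comps))
  }
  ids[order(-merged, ids)]
}

#' Fill network gaps with universe reactions
#'
#' Greedy two-phase loop: repeatedly add the top-ranked candidate and
#' recompute the component structure, first at pathway scale until no
#' pathway-scale candidate remains, then at global scale. Added reactions
#' carry no gene association and are tagged `"gapfilled"`.
#'
#' @inheritParams find_gap_candidates
#' @return list with `network` and `report`, a `gap_report` with
#'   `wcc_before`, `wcc_after` and `added` (data.frame of reaction id and
#'   scale, in addition order).
#' @export
fill_gaps <- function(network, universe,
                      currency_excluded = default_currency_metabolites()) {
  partition <- compute_wccs(network, currency_excluded)
  wcc_before <- partition$n
  added_id <- character(0)
  added_scale <- character(0)
  for (scale in c("pathway", "global")) {
    repeat {
      cand <- find_gap_candidates(network, universe, scale,
                                  currency_excluded, partition)
      if (length(cand) == 0L) break
      rid <- cand[1]
      rec <- universe$reactions[[rid]]
      rec$tags <- union(rec$tags, "gapfilled")
      network$reactions[[rid]] <- list(record = rec, gpr = NULL,
                                       genes = character(0),
                                       ecs = rec$ec_numbers)
      added_id <- c(added_id, rid)
      added_scale <- c(added_scale, scale)
      partition <- compute_wccs(network, currency_excluded)
    }
  }
  report <- structure(list(
    wcc_before = wcc_before,
    wcc_after = partition$n,
    added = data.frame(reaction_id = added_id, scale = added_scale,
                       stringsAsFactors = FALSE)),
    class = "gap_report")
  list(network = network, report = report)
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Gap filling: WCCs", x$wcc_before, "->", x$wcc_after, "\n")
  cat("  added at pathway scale:", sum(x$added$scale == "pathway"), "\n")
  cat("  added at global scale: ", sum(x$added$scale == "global"), "\n")
  invisible(x)
}
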