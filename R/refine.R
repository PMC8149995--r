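# Network refinement: chiral standardization, redundancy removal, metadata
# supplementation, and the orchestrating refine_network() step.

#' Replace chiral alias compounds by their canonical forms
#'
#' KEGG assigns distinct accessions to chiral variants of one molecule
#' (e.g. D-glucose C00031 vs alpha-D-glucose C00267). The alias policy maps
#' each ambiguous id to its canonical id; every occurrence in the network is
#' substituted. Reactions whose equation collapses to nothing under the
#' substitution (substrates become identical to products) are flagged as
#' chiral self-duplicates for later removal.
#'
#' @param network a `draft_network`.
#' @param alias_policy named character vector: alias id -> canonical id.
#' @return list with `network` (substituted), `modified` (reaction ids whose
#'   equations changed) and `self_identical` (ids collapsing to an empty
#'   equation).
#' @export
standardize_chirality <- function(network, alias_policy) {
  if (length(alias_policy) == 0L) {
    return(list(network = network, modified = character(0),
                self_identical = character(0)))
  }
  if (any(names(alias_policy) %in% alias_policy)) {
    bad <- intersect(names(alias_policy), alias_policy)
    stop("alias policy is not idempotent (chain or cycle) via: ",
         paste(bad, collapse = ", "))
  }
  modified <- character(0)
  self_identical <- character(0)
  for (rid in names(network$reactions)) {
    stoich <- network$reactions[[rid]]$record$stoichiometry
    ids <- names(stoich)
    hit <- ids %in% names(alias_policy)
    if (!any(hit)) next
    ids[hit] <- alias_policy[ids[hit]]
    # merge coefficients that now land on the same compound
    merged <- tapply(stoich, ids, sum)
    merged <- stats::setNames(as.numeric(merged), names(merged))
    merged <- merged[abs(merged) > 1e-12]
    network$reactions[[rid]]$record$stoichiometry <-
      merged[order(names(merged))]
    modified <- c(modified, rid)
    if (length(merged) == 0L) self_identical <- c(self_identical, rid)
  }
  list(network = network, modified = modified,
       self_identical = self_identical)
}

.stoich_key <- function(stoich) {
  o <- order(names(stoich))
  paste(names(stoich)[o], format(stoich[o], digits = 12), collapse = "|")
}

#' Remove redundant reactions from a draft network
#'
#' Four categories are removed, in order, with every removal attributed to
#' exactly one category:
#' 1. `step`: a two-step chain whose net stoichiometry equals an existing
#'    total reaction, where the intermediate participates in no other
#'    reaction ("no branch") — the total reaction is kept, the steps go;
#' 2. `generic`: reactions over compound classes rather than specific
#'    metabolites (the `generic` parse flag);
#' 3. `incomplete_or_symbolic`: reactions with a missing side or `m`/`n`
#'    coefficients;
#' 4. `chiral_duplicate`: reactions made identical to another reaction (or
#'    to nothing) by chiral standardization.
#'
#' @param network a `draft_network`.
#' @param self_identical reaction ids flagged by [standardize_chirality()].
#' @return list with `network` and `removed` (named list of id vectors per
#'   category).
#' @export
remove_redundant <- function(network, self_identical = character(0)) {
  removed <- list(step = character(0), generic = character(0),
                  incomplete_or_symbolic = character(0),
                  chiral_duplicate = character(0))
  rids <- names(network$reactions)
  stoichs <- lapply(network$reactions, function(r) r$record$stoichiometry)

  # --- step reactions -------------------------------------------------
  # compound participation index ("branch" test)
  participation <- list()
  for (rid in rids) {
    for (cid in names(stoichs[[rid]])) {
      participation[[cid]] <- c(participation[[cid]], rid)
    }
  }
  key_to_rid <- stats::setNames(rids, vapply(stoichs, .stoich_key, character(1)))
  gone <- character(0)
  for (cid in names(participation)) {
    involved <- setdiff(participation[[cid]], gone)
    if (length(involved) != 2L) next # intermediate must have no branch
    s1 <- stoichs[[involved[1]]]
    s2 <- stoichs[[involved[2]]]
    # one must produce cid, the other consume it, in equal measure
    if (abs(s1[[cid]] + s2[[cid]]) > 1e-9) next
    all_ids <- union(names(s1), names(s2))
    net <- stats::setNames(numeric(length(all_ids)), all_ids)
    net[names(s1)] <- net[names(s1)] + s1
    net[names(s2)] <- net[names(s2)] + s2
    net <- net[abs(net) > 1e-9]
    if (length(net) == 0L) next
    total <- key_to_rid[.stoich_key(net)]
    if (!is.na(total) && !(total %in% involved) && !(total %in% gone)) {
      gone <- c(gone, involved)
    }
  }
  removed$step <- sort(gone)

  still <- function() setdiff(rids, unlist(removed))

  # --- generic --------------------------------------------------------
  removed$generic <- sort(Filter(function(rid) {
    isTRUE(network$reactions[[rid]]$record$flags$generic)
  }, still()))

  # --- incomplete / symbolic -----------------------------------------
  removed$incomplete_or_symbolic <- sort(Filter(function(rid) {
    fl <- network$reactions[[rid]]$record$flags
    isTRUE(fl$incomplete) || isTRUE(fl$symbolic_coefficient)
  }, still()))

  # --- chiral duplicates ---------------------------------------------
  dup <- intersect(self_identical, still())
  seen <- character(0)
  for (rid in sort(still())) {
    if (rid %in% dup) next
    key <- .stoich_key(stoichs[[rid]])
    if (key %in% names(seen)) {
      dup <- c(dup, rid) # a lexicographically earlier twin is kept
    } else {
      seen[key] <- rid
    }
  }
  removed$chiral_duplicate <- sort(unique(dup))

  network$reactions <- network$reactions[still()]
  network$genes <- sort(unique(unlist(lapply(network$reactions, `[[`, "genes"))))
  list(network = network, removed = removed)
}

#' Supplement missing reaction metadata from the universe
#'
#' Reactions lacking a main-reaction link, pathway set or subsystem inherit
#' them from the universe record. A reaction still without a pathway gets
#' the intersection of its metabolites' pathway sets (a metabolite's
#' pathways being the union over universe reactions it participates in)
#' when that intersection is non-empty. Subsystems resolve through the
#' pathway-to-subsystem mapping.
#'
#' @param network a `draft_network`.
#' @param universe a `kegg_universe`.
#' @return list with `network` and `supplemented` (named counts:
#'   `main_reaction`, `pathway`, `subsystem`, plus `reactions`, the number
#'   of distinct reactions touched).
#' @export
supplement_metadata <- function(network, universe) {
  counts <- c(main_reaction = 0L, pathway = 0L, subsystem = 0L)
  touched <- character(0)

  cpd_pathways <- NULL # built lazily
  build_cpd_pathways <- function() {
    out <- list()
    for (r in universe$reactions) {
      if (length(r$pathways) == 0L) next
      for (cid in names(r$stoichiometry)) {
        out[[cid]] <- union(out[[cid]], r$pathways)
      }
    }
    out
  }

  for (rid in names(network$reactions)) {
    rec <- network$reactions[[rid]]$record
    urec <- universe$reactions[[rid]]
    changed <- FALSE
    if (is.na(rec$main_reaction_id) && !is.null(urec) &&
        !is.na(urec$main_reaction_id)) {
      rec$main_reaction_id <- urec$main_reaction_id
      counts["main_reaction"] <- counts["main_reaction"] + 1L
      changed <- TRUE
    }
    if (length(rec$pathways) == 0L) {
      if (!is.null(urec) && length(urec$pathways)) {
        rec$pathways <- urec$pathways
      } else {
        if (is.null(cpd_pathways)) cpd_pathways <- build_cpd_pathways()
        sets <- cpd_pathways[names(rec$stoichiometry)]
        sets <- Filter(Negate(is.null), sets)
        if (length(sets)) {
          inferred <- Reduce(intersect, sets)
          if (length(inferred)) rec$pathways <- sort(inferred)
        }
      }
      if (length(rec$pathways)) {
        counts["pathway"] <- counts["pathway"] + 1L
        changed <- TRUE
      }
    }
    if (is.na(rec$subsystem) && length(rec$pathways)) {
      hit <- intersect(rec$pathways, names(universe$pathway_to_subsystem))
      if (length(hit)) {
        rec$subsystem <- unname(universe$pathway_to_subsystem[sort(hit)[1]])
        counts["subsystem"] <- counts["subsystem"] + 1L
        changed <- TRUE
      }
    }
    if (changed) {
      network$reactions[[rid]]$record <- rec
      touched <- c(touched, rid)
    }
  }
  network$pathways <- sort(unique(unlist(lapply(
    network$reactions, function(r) r$record$pathways))))
  network$subsystems <- sort(unique(stats::na.omit(vapply(
    network$reactions, function(r) r$record$subsystem, character(1)))))
  list(network = network,
       supplemented = c(counts, reactions = length(unique(touched))))
}

#' Refine a draft network
#'
#' Runs the refinement sequence: balance every reaction by element and
#' charge conservation, standardize chiral metabolites, remove redundant
#' reactions (step / generic / incomplete-or-symbolic / chiral duplicates)
#' and supplement missing metadata from the universe.
#'
#' @param network a `draft_network`.
#' @param universe the `kegg_universe` it was drafted from.
#' @param alias_policy named character vector (alias -> canonical id);
#'   defaults to the glucose-family policy shipped with the package.
#' @param fillers filler species for balancing, see [balance_reaction()].
#' @return list with `network` and `report`, a `refinement_report` holding
#'   `balanced_count`, `unbalanceable` ids, `modified_chirality_count`,
#'   `removed` (per-category id lists) and `metadata_supplemented_count`.
#' @export
refine_network <- function(network, universe,
                           alias_policy = default_alias_policy(),
                           fillers = default_fillers()) {
  balanced <- 0L
  unbalanceable <- character(0)
  for (rid in names(network$reactions)) {
    rec <- network$reactions[[rid]]$record
    if (isTRUE(rec$flags$incomplete) ||
        isTRUE(rec$flags$symbolic_coefficient) ||
        isTRUE(rec$flags$generic)) {
      next # these are slated for removal, not balancing
    }
    res <- balance_reaction(rec, universe$compounds, fillers)
    if (res$status == "balanced") {
      network$reactions[[rid]]$record <- res$reaction
      balanced <- balanced + 1L
    } else if (res$status == "unbalanceable") {
      unbalanceable <- c(unbalanceable, rid)
      network$reactions[[rid]]$record$flags$unbalanceable <- TRUE
    }
  }
  chir <- standardize_chirality(network, alias_policy)
  network <- chir$network
  rem <- remove_redundant(network, self_identical = chir$self_identical)
  network <- rem$network
  sup <- supplement_metadata(network, universe)
  network <- sup$network
  report <- structure(list(
    balanced_count = balanced,
    unbalanceable = unbalanceable,
    modified_chirality_count = length(chir$modified),
    removed = rem$removed,
    metadata_supplemented_count = unname(sup$supplemented[["reactions"]]),
    supplemented = sup$supplemented),
    class = "refinement_report")
  list(network = network, report = report)
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("Refinement report\n")
  cat("  reactions balanced:", x$balanced_count, "\n")
  if (length(x$unbalanceable)) {
    cat("  unbalanceable (flagged):", length(x$unbalanceable), "\n")
  }
  cat("  equations modified by chiral standardization:",
      x$modified_chirality_count, "\n")
  cat("  removed:",
      paste(sprintf("%s=%d", names(x$removed), lengths(x$removed)),
            collapse = ", "), "\n")
  cat("  reactions with supplemented metadata:",
      x$metadata_supplemented_count, "\n")
  invisible(x)
}

#' Default chiral alias policy
#'
#' Maps chirally ambiguous compound ids to a canonical form. The shipped
#' policy covers the glucose family (D-glucose and beta-D-glucose to
#' alpha-D-glucose, the form favoured in animal cells); extend it via the
#' TSV format (columns `alias_id`, `canonical_id`).
#'
#' @param path optional path to a policy TSV; default uses the packaged one.
#' @return named character vector alias -> canonical.
#' @export
default_alias_policy <- function(path = system.file("extdata",
                                                    "alias_policy.tsv",
                                                    package = "fluxforge")) {
  df <- utils::read.delim(path, colClasses = "character")
  stats::setNames(df$canonical_id, df$alias_id)
}
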