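# Draft gene-enzyme-reaction network assembly. EC numbers are the bridge:
# a reaction enters the draft iff at least one of its ECs is carried by an
# annotated gene.

#' Map annotated genes onto universe reactions via EC numbers
#'
#' @param universe a `kegg_universe`.
#' @param annotations a `gene_annotations` object.
#' @return named list: reaction id -> data.frame(gene, ec), one row per
#'   (gene, EC) pair that justifies the reaction. Reactions with no annotated
#'   EC are absent.
#' @export
map_genes_to_reactions <- function(universe, annotations) {
  stopifnot(inherits(universe, "kegg_universe"))
  ec_to_genes <- list()
  for (g in names(annotations)) {
    for (ec in annotations[[g]]) {
      ec_to_genes[[ec]] <- c(ec_to_genes[[ec]], g)
    }
  }
  out <- list()
  for (ec in sort(intersect(names(ec_to_genes), names(universe$ec_to_reactions)))) {
    genes <- sort(unique(ec_to_genes[[ec]]))
    for (rid in universe$ec_to_reactions[[ec]]) {
      out[[rid]] <- rbind(out[[rid]],
                          data.frame(gene = genes, ec = ec,
                                     stringsAsFactors = FALSE))
    }
  }
  if (length(out) == 0L) return(list())
  for (rid in names(out)) {
    df <- out[[rid]]
    out[[rid]] <- df[order(df$ec, df$gene), , drop = FALSE]
    rownames(out[[rid]]) <- NULL
  }
  out[order(names(out))]
}

#' Build a gene-protein-reaction (GPR) rule from (gene, EC) pairs
#'
#' Genes annotated to the same enzyme (same EC) are treated as subunits of a
#' complex and combine with AND; genes reaching the reaction through
#' different enzymes are alternatives and combine with OR. A single gene
#' yields a bare leaf.
#'
#' @param pairs data.frame with columns `gene` and `ec`.
#' @return a GPR: either a character scalar (leaf) or a list
#'   `list(op = "and"|"or", args = list(...))` with no single-child nodes.
#' @export
build_gpr <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) {
    stop("cannot build a GPR from an empty set of (gene, EC) pairs")
  }
  groups <- lapply(split(pairs$gene, pairs$ec), function(g) sort(unique(g)))
  groups <- groups[order(names(groups))]
  terms <- lapply(groups, function(genes) {
    if (length(genes) == 1L) genes else
      list(op = "and", args = as.list(genes))
  })
  # identical complexes reached through different ECs collapse
  terms <- unique(unname(terms))
  if (length(terms) == 1L) terms[[1]] else list(op = "or", args = terms)
}

#' Render a GPR rule as a string
#'
#' @param gpr a GPR as produced by [build_gpr()], or `NULL`.
#' @return character scalar, `""` for `NULL`.
#' @export
gpr_to_string <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  inner <- vapply(gpr$args, function(a) {
    s <- gpr_to_string(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(inner, collapse = paste0(" ", gpr$op, " "))
}

#' Genes referenced by a GPR
#' @param gpr a GPR or `NULL`.
#' @return character vector of gene ids (sorted, unique).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (is.character(gpr)) return(gpr)
  sort(unique(unlist(lapply(gpr$args, gpr_genes))))
}

#' Assemble the draft metabolic network
#'
#' Joins the reference universe with the genome annotation. The draft
#' contains exactly the reactions justified by at least one annotated EC,
#' each with its GPR rule, gene set and enzyme (EC) set; pathway and
#' subsystem metadata propagate from the universe.
#'
#' @param universe a `kegg_universe`.
#' @param annotations a `gene_annotations` object.
#' @return an object of class `draft_network`: list with `reactions` (named
#'   list of `record`, `gpr`, `genes`, `ecs`), `genes`, `pathways`,
#'   `subsystems`.
#' @export
assemble_draft <- function(universe, annotations) {
  mapping <- map_genes_to_reactions(universe, annotations)
  if (length(mapping) == 0L) {
    warning("no annotated EC matches any universe reaction; draft is empty")
  }
  reactions <- list()
  for (rid in names(mapping)) {
    pairs <- mapping[[rid]]
    reactions[[rid]] <- list(
      record = universe$reactions[[rid]],
      gpr = build_gpr(pairs),
      genes = sort(unique(pairs$gene)),
      ecs = sort(unique(pairs$ec)))
  }
  net <- structure(list(
    reactions = reactions,
    genes = sort(unique(unlist(lapply(reactions, `[[`, "genes")))),
    pathways = sort(unique(unlist(lapply(reactions,
                                         function(r) r$record$pathways)))),
    subsystems = sort(unique(stats::na.omit(vapply(
      reactions, function(r) r$record$subsystem, character(1)))))),
    class = "draft_network")
  net
}

#' Summary counts for a draft network
#'
#' Mirrors the usual reconstruction bookkeeping: genes, distinct enzymes
#' (EC numbers), reactions, pathways and subsystems.
#'
#' @param object a `draft_network`.
#' @param ... unused.
#' @export
summary.draft_network <- function(object, ...) {
  ecs <- sort(unique(unlist(lapply(object$reactions, `[[`, "ecs"))))
  out <- list(genes = length(object$genes),
              enzymes = length(ecs),
              reactions = length(object$reactions),
              pathways = length(object$pathways),
              subsystems = length(object$subsystems))
  class(out) <- "summary.draft_network"
  out
}

#' @export
print.summary.draft_network <- function(x, ...) {
  cat("Draft network summary\n")
  for (k in names(x)) cat(sprintf("  %-10s %d\n", k, x[[k]]))
  invisible(x)
}

#' @export
print.draft_network <- function(x, ...) {
  s <- summary(x)
  cat("Draft metabolic network:", s$reactions, "reactions,",
      s$genes, "genes,", s$enzymes, "enzymes,",
      s$pathways, "pathways,", s$subsystems, "subsystems\n")
  invisible(x)
}
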