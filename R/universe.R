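# Reference knowledge base ("universe") parsed from KEGG-style flat files.
#
# Flat-file dialect: plain tab-separated tables with a header row, one record
# per line. KEGG's native multi-line format is assumed converted upstream.
#   compounds.tsv : compound_id, name, formula, charge, aliases
#   reactions.tsv : reaction_id, equation, direction, ec_numbers,
#                   main_reaction_id, pathways, subsystem, flags
#   pathways.tsv  : pathway_id, subsystem
#   enzymes.tsv   : ec_number, reaction_id
#   genes.tsv     : gene_id, ec_number
# Multi-valued cells (aliases, ec_numbers, pathways, flags) use ";" as the
# separator; empty cells mean absent.

#' Parse a chemical formula string into element counts
#'
#' Formulas are Hill-style strings such as `"C6H12O6"`. The empty string is a
#' valid formula (e.g. the electron, which carries charge but no atoms).
#'
#' @param x formula string.
#' @return named integer vector of element counts (possibly empty).
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(stats::setNames(integer(0), character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  toks <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(toks)) != nchar(x)) {
    stop("unparsable formula: '", x, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnt, el, sum)
  stats::setNames(as.integer(out), names(out))
}

.split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else
    trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

.parse_coef <- function(tok) {
  # numeric, fraction "p/q", or symbolic "m"/"n" (returned as NA + flag)
  if (grepl("^[mn]$", tok)) return(list(value = NA_real_, symbolic = TRUE))
  if (grepl("^[0-9]+/[0-9]+$", tok)) {
    pq <- as.numeric(strsplit(tok, "/", fixed = TRUE)[[1]])
    return(list(value = pq[1] / pq[2], symbolic = FALSE))
  }
  v <- suppressWarnings(as.numeric(tok))
  if (is.na(v)) return(NULL)
  list(value = v, symbolic = FALSE)
}

#' Parse a reaction equation string
#'
#' Equations look like `"2 C00001 + C00007 <=> 2 C00080"`. `<=>` marks a
#' reversible reaction, `=>` an irreversible (forward) one. Coefficient
#' tokens `m`/`n` are accepted and set the `symbolic_coefficient` flag; the
#' species keeps a placeholder coefficient of +/-1 so the record remains
#' inspectable. An empty side marks the reaction `incomplete`.
#'
#' @param eq equation string.
#' @return list with `stoichiometry` (named numeric, negative = substrate),
#'   `direction`, and logical flags `symbolic_coefficient`, `incomplete`.
#' @export
parse_equation <- function(eq) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("=>", eq, fixed = TRUE)) "=>" else
      stop("equation has no '<=>' or '=>' arrow: '", eq, "'")
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  direction <- if (arrow == "<=>") "reversible" else "forward"
  symbolic <- FALSE
  stoich <- numeric(0)
  for (k in 1:2) {
    sgn <- if (k == 1L) -1 else 1
    side <- trimws(sides[k])
    if (!nzchar(side)) next
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    for (term in terms[nzchar(terms)]) {
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1; cid <- parts[1]
      } else if (length(parts) == 2L) {
        pc <- .parse_coef(parts[1])
        if (is.null(pc)) stop("bad coefficient '", parts[1], "' in '", eq, "'")
        if (pc$symbolic) { symbolic <- TRUE; coef <- 1 } else coef <- pc$value
        cid <- parts[2]
      } else {
        stop("unparsable term '", term, "' in '", eq, "'")
      }
      stoich[cid] <- if (cid %in% names(stoich)) stoich[[cid]] + sgn * coef else
        sgn * coef
    }
  }
  stoich <- stoich[stoich != 0]
  incomplete <- !nzchar(trimws(sides[1])) || !nzchar(trimws(sides[2]))
  list(stoichiometry = stoich, direction = direction,
       symbolic_coefficient = symbolic, incomplete = incomplete)
}

.read_tsv <- function(path, required_cols) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          quote = "", comment.char = "", check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Parse KEGG-style flat files into a reference universe
#'
#' Builds the reference knowledge base used for draft reconstruction, gap
#' filling and repair: all known compounds, reactions (with equations, EC
#' links, pathway and subsystem metadata) and the EC-to-reaction index.
#' Unparsable lines are reported (with line numbers) and skipped, never
#' silently dropped.
#'
#' @param compound_file,reaction_file,pathway_links,enzyme_links paths to the
#'   TSV tables (see the package vignette for the dialect).
#' @param generic_compounds compound ids denoting classes of substances
#'   rather than specific molecules ("a protein", "an acceptor"); any
#'   reaction touching one is flagged generic, in addition to reactions
#'   flagged generic in the file itself. Defaults to the curated list
#'   shipped with the package ([default_generic_compounds()]).
#' @return an object of class `kegg_universe` with elements `compounds`,
#'   `reactions`, `ec_to_reactions` and `pathway_to_subsystem`.
#' @export
parse_universe <- function(compound_file, reaction_file, pathway_links,
                           enzyme_links,
                           generic_compounds = default_generic_compounds()) {
  cdf <- .read_tsv(compound_file, c("compound_id", "name"))
  compounds <- list()
  for (i in seq_len(nrow(cdf))) {
    rec <- tryCatch({
      id <- cdf$compound_id[i]
      if (!nzchar(id)) stop("empty compound id")
      aliases <- .split_multi(.col(cdf, "aliases", i))
      if (id %in% aliases) stop("compound lists itself as alias")
      # formula cell: "" = unknown (reaction uncomputable), "." = known
      # to have no atoms (e.g. the electron), otherwise a Hill string
      fcell <- .col(cdf, "formula", i)
      formula <- if (is.na(fcell) || !nzchar(fcell)) NULL
        else if (fcell == ".") parse_formula("")
        else parse_formula(fcell)
      list(id = id, name = cdf$name[i],
           formula = formula,
           charge = .parse_int(.col(cdf, "charge", i), 0L),
           aliases = aliases)
    }, error = function(e) {
      message("skipping ", compound_file, " line ", i + 1L, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) {
      if (rec$id %in% names(compounds)) {
        message("skipping ", compound_file, " line ", i + 1L,
                ": duplicate compound id ", rec$id)
      } else compounds[[rec$id]] <- rec
    }
  }

  rdf <- .read_tsv(reaction_file, c("reaction_id", "equation"))
  reactions <- list()
  for (i in seq_len(nrow(rdf))) {
    rec <- tryCatch({
      id <- rdf$reaction_id[i]
      if (!nzchar(id)) stop("empty reaction id")
      eqp <- parse_equation(rdf$equation[i])
      dircol <- .col(rdf, "direction", i)
      direction <- if (!is.na(dircol) && nzchar(dircol)) {
        if (dircol %in% c("forward", "fwd", "=>")) "forward" else
          if (dircol %in% c("reversible", "rev", "<=>")) "reversible" else
            stop("unknown direction '", dircol, "'")
      } else eqp$direction
      flags_in <- .split_multi(.col(rdf, "flags", i))
      main_id <- .col(rdf, "main_reaction_id", i)
      subsys <- .col(rdf, "subsystem", i)
      list(id = id, stoichiometry = eqp$stoichiometry, direction = direction,
           ec_numbers = .split_multi(.col(rdf, "ec_numbers", i)),
           main_reaction_id = if (!is.na(main_id) && nzchar(main_id)) main_id
             else NA_character_,
           pathways = .split_multi(.col(rdf, "pathways", i)),
           subsystem = if (!is.na(subsys) && nzchar(subsys)) subsys
             else NA_character_,
           flags = list(
             generic = "generic" %in% flags_in ||
               any(names(eqp$stoichiometry) %in% generic_compounds),
             incomplete = eqp$incomplete || "incomplete" %in% flags_in,
             symbolic_coefficient = eqp$symbolic_coefficient))
    }, error = function(e) {
      message("skipping ", reaction_file, " line ", i + 1L, ": ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) reactions[[rec$id]] <- rec
  }

  # reactions must only reference known compounds
  offenders <- character(0)
  for (r in reactions) {
    unknown <- setdiff(names(r$stoichiometry), names(compounds))
    if (length(unknown)) {
      offenders <- c(offenders, paste0(r$id, ": ",
                                       paste(unknown, collapse = ", ")))
    }
  }
  if (length(offenders)) {
    stop("reactions reference unknown compounds:\n  ",
         paste(offenders, collapse = "\n  "))
  }

  pdf <- .read_tsv(pathway_links, c("pathway_id", "subsystem"))
  pathway_to_subsystem <- stats::setNames(pdf$subsystem, pdf$pathway_id)
  pathway_to_subsystem <- pathway_to_subsystem[nzchar(names(pathway_to_subsystem))]

  edf <- .read_tsv(enzyme_links, c("ec_number", "reaction_id"))
  keep <- edf$reaction_id %in% names(reactions)
  if (any(!keep)) {
    message("enzyme links reference ", sum(!keep),
            " unknown reaction(s); dropped")
  }
  edf <- edf[keep, , drop = FALSE]
  ec_to_reactions <- lapply(split(edf$reaction_id, edf$ec_number),
                            function(x) sort(unique(x)))
  # ECs stated inline on reactions are part of the index too
  for (r in reactions) {
    for (ec in r$ec_numbers) {
      ec_to_reactions[[ec]] <- sort(unique(c(ec_to_reactions[[ec]], r$id)))
    }
  }
  # and conversely the link table enriches the reaction records
  for (ec in names(ec_to_reactions)) {
    for (rid in ec_to_reactions[[ec]]) {
      reactions[[rid]]$ec_numbers <- sort(unique(c(reactions[[rid]]$ec_numbers, ec)))
    }
  }

  structure(list(compounds = compounds,
                 reactions = reactions,
                 ec_to_reactions = ec_to_reactions[order(names(ec_to_reactions))],
                 pathway_to_subsystem = pathway_to_subsystem),
            class = "kegg_universe")
}

.col <- function(df, col, i) if (col %in% names(df)) df[[col]][i] else NA_character_

.parse_int <- function(x, default) {
  if (is.na(x) || !nzchar(x)) return(default)
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) stop("not an integer: '", x, "'")
  v
}

#' Parse a gene-to-EC annotation table
#'
#' The table has columns `gene_id` and `ec_number`; a gene may appear on
#' several lines with different ECs. Duplicate (gene, EC) pairs collapse.
#' EC strings must look like EC numbers (four dot-separated fields, trailing
#' fields possibly `-`); malformed ones are skipped with a warning.
#'
#' @param annotation_file path to genes.tsv.
#' @return named list of class `gene_annotations`: gene id -> sorted
#'   character vector of EC numbers.
#' @export
parse_annotations <- function(annotation_file) {
  df <- .read_tsv(annotation_file, c("gene_id", "ec_number"))
  ok <- grepl("^[0-9]+\\.[0-9-]+\\.[0-9-]+\\.[0-9-]+$", df$ec_number) &
    nzchar(df$gene_id)
  if (any(!ok)) {
    warning(sum(!ok), " malformed annotation line(s) skipped (lines ",
            paste(utils::head(which(!ok) + 1L, 10L), collapse = ", "), ")")
  }
  df <- df[ok, , drop = FALSE]
  ann <- lapply(split(df$ec_number, df$gene_id), function(x) sort(unique(x)))
  structure(ann[order(names(ann))], class = "gene_annotations")
}

#' Curated list of generic (class) compounds
#'
#' @param path optional alternative TSV (columns `compound_id`, `name`).
#' @return character vector of compound ids.
#' @export
default_generic_compounds <- function(path = system.file(
    "extdata", "generic_compounds.tsv", package = "fluxforge")) {
  utils::read.delim(path, colClasses = "character")$compound_id
}

#' @export
print.kegg_universe <- function(x, ...) {
  cat("KEGG-style reference universe\n")
  cat("  compounds:", length(x$compounds), "\n")
  cat("  reactions:", length(x$reactions), "\n")
  cat("  EC numbers indexed:", length(x$ec_to_reactions), "\n")
  cat("  pathway-subsystem links:", length(x$pathway_to_subsystem), "\n")
  invisible(x)
}
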