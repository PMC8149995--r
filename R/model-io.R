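# Model serialization. JSON is the lossless native format (documented
# schema, versioned); SBML Level 3 + fbc is the interchange export, readable
# by standard constraint-based tooling.

MODEL_SCHEMA_VERSION <- "1.0"

.gpr_to_json <- function(gpr) {
  if (is.null(gpr)) return(NULL)
  if (is.character(gpr)) return(list(gene = gpr))
  list(op = gpr$op, args = lapply(gpr$args, .gpr_to_json))
}

.gpr_from_json <- function(x) {
  if (is.null(x)) return(NULL)
  if (!is.null(x$gene)) return(x$gene)
  list(op = x$op, args = lapply(x$args, .gpr_from_json))
}

#' Write a model to disk
#'
#' @param model a `metabolic_model` (validated before writing).
#' @param path output file path.
#' @param format `"json"` (lossless, see the schema in the vignette) or
#'   `"sbml"` (Level 3 Version 1 with the fbc version 2 extension).
#' @return invisibly `path`.
#' @export
write_model <- function(model, path, format = c("json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "json") .write_model_json(model, path)
  else .write_model_sbml(model, path)
  invisible(path)
}

.write_model_json <- function(model, path) {
  mets <- lapply(unname(model$metabolites), function(m) {
    list(id = m$id, compound_id = m$compound_id, compartment = m$compartment)
  })
  rxns <- lapply(unname(model$reactions), function(r) {
    list(id = r$id,
         stoichiometry = as.list(r$stoichiometry),
         lower_bound = r$lower_bound,
         upper_bound = r$upper_bound,
         direction = r$direction,
         kind = r$kind,
         gpr = .gpr_to_json(r$gpr),
         pathways = as.list(r$pathways),
         subsystem = if (is.na(r$subsystem)) NULL else r$subsystem,
         tags = as.list(r$tags))
  })
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              id = model$id,
              compartments = as.list(model$compartments),
              objective = if (is.na(model$objective)) NULL else model$objective,
              nutrient_classes = lapply(model$nutrient_classes, as.list),
              metabolites = mets,
              reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

#' Read a model written by [write_model()]
#'
#' Only the JSON format is readable; the SBML export is a one-way
#' interchange artifact.
#'
#' @param path path to a model JSON file.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path) {
  if (!grepl("\\.json$", path, ignore.case = TRUE)) {
    stop("read_model() reads the JSON format; got: ", path)
  }
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema_version)) {
    stop("not a model file (no schema_version): ", path)
  }
  metabolites <- list()
  for (m in doc$metabolites) {
    metabolites[[m$id]] <- list(id = m$id, compound_id = m$compound_id,
                                compartment = m$compartment)
  }
  reactions <- list()
  for (r in doc$reactions) {
    reactions[[r$id]] <- list(
      id = r$id,
      stoichiometry = stats::setNames(as.numeric(unlist(r$stoichiometry)),
                                      names(r$stoichiometry)),
      lower_bound = r$lower_bound,
      upper_bound = r$upper_bound,
      direction = r$direction,
      kind = r$kind,
      gpr = .gpr_from_json(r$gpr),
      pathways = as.character(unlist(r$pathways)),
      subsystem = if (is.null(r$subsystem)) NA_character_ else r$subsystem,
      tags = as.character(unlist(r$tags)))
  }
  structure(list(
    id = doc$id,
    metabolites = metabolites,
    reactions = reactions,
    objective = if (is.null(doc$objective)) NA_character_ else doc$objective,
    compartments = stats::setNames(as.character(unlist(doc$compartments)),
                                   names(doc$compartments)),
    nutrient_classes = lapply(doc$nutrient_classes,
                              function(v) as.character(unlist(v)))),
    class = "metabolic_model")
}

.sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

.write_model_sbml <- function(model, path) {
  sbml_ns <- "http://www.sbml.org/sbml/level3/version1/core"
  fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
  doc <- xml2::xml_new_root("sbml",
    xmlns = sbml_ns, "xmlns:fbc" = fbc_ns,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = .sbml_sid(model$id),
                             "fbc:strict" = "true")
  cl <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (k in names(model$compartments)) {
    xml2::xml_add_child(cl, "compartment", id = k,
                        name = model$compartments[[k]], constant = "true")
  }
  sl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites) {
    xml2::xml_add_child(sl, "species",
      id = paste0("M_", .sbml_sid(m$id)),
      name = m$compound_id,
      compartment = m$compartment,
      hasOnlySubstanceUnits = "false",
      boundaryCondition = "false",
      constant = "false")
  }
  # distinct bounds become shared parameters
  bvals <- sort(unique(c(
    vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
    vapply(model$reactions, `[[`, numeric(1), "upper_bound"))))
  bid <- function(v) paste0("fb_", .sbml_sid(gsub("-", "m", format(v))))
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bvals) {
    xml2::xml_add_child(pl, "parameter", id = bid(v),
                        value = format(v, scientific = FALSE),
                        constant = "true")
  }
  # gene products referenced by GPRs
  genes <- sort(unique(unlist(lapply(model$reactions,
                                     function(r) gpr_genes(r$gpr)))))
  if (length(genes)) {
    gl <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(gl, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", .sbml_sid(g)),
                          "fbc:label" = g)
    }
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  add_gpr <- function(parent, gpr) {
    if (is.character(gpr)) {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
                          "fbc:geneProduct" = paste0("G_", .sbml_sid(gpr)))
    } else {
      node <- xml2::xml_add_child(parent,
        if (gpr$op == "and") "fbc:and" else "fbc:or")
      for (a in gpr$args) add_gpr(node, a)
    }
  }
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(rl, "reaction",
      id = paste0("R_", .sbml_sid(r$id)),
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = bid(r$lower_bound),
      "fbc:upperFluxBound" = bid(r$upper_bound))
    sub <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(sub)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (m in names(sub)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", .sbml_sid(m)),
                            stoichiometry = format(-sub[[m]], digits = 15),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (m in names(prod)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", .sbml_sid(m)),
                            stoichiometry = format(prod[[m]], digits = 15),
                            constant = "true")
      }
    }
    if (!is.null(r$gpr)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_gpr(ga, r$gpr)
    }
  }
  if (!is.na(model$objective)) {
    ol <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(fl, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", .sbml_sid(model$objective)),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
}
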