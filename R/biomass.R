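# Biomass objective construction from measured nutritional composition.
# Measured contents (g/100 g, mg/kg or %) convert to mmol per gram dry
# weight and become the stoichiometric coefficients of the biomass
# pseudo-reaction; energy maintenance enters as an ATP hydrolysis term.

#' Round half away from zero
#'
#' Plain `round()` rounds half to even; composition tables in the
#' literature are formatted with conventional half-up rounding, so report
#' display uses this helper. Internal values keep full precision.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert a measured nutrient content to mmol per gram (dry) weight
#'
#' Conversions: `g/100g` (and `percent`, its synonym) give
#' `content * 10 / molar_mass` mmol per gram of sample; `mg/kg` gives
#' `content / (1000 * molar_mass)`. With `dry_basis = TRUE` the result is
#' expressed per gram dry weight by dividing by `1 - moisture_fraction`
#' (dry weight = total mass minus water).
#'
#' @param content measured content (non-negative).
#' @param unit one of `"g/100g"`, `"mg/kg"`, `"percent"`.
#' @param molar_mass molar mass in g/mol (> 0).
#' @param moisture_fraction water mass fraction in `[0, 1)`.
#' @param dry_basis express per gram dry weight?
#' @return mmol per gram (dry weight when `dry_basis`).
#' @examples
#' content_to_mmol_per_gdw(2.43, "g/100g", 174.20) # arginine, ~0.14
#' @export
content_to_mmol_per_gdw <- function(content, unit, molar_mass,
                                    moisture_fraction = 0,
                                    dry_basis = FALSE) {
  if (any(content < 0)) stop("content must be non-negative")
  stopifnot(molar_mass > 0, moisture_fraction >= 0, moisture_fraction < 1)
  per_g <- switch(unit,
    "g/100g" = ,
    "g/100 g" = ,
    "percent" = content * 10 / molar_mass,
    "mg/kg" = content / (1000 * molar_mass),
    stop("unknown content unit: '", unit, "'"))
  if (dry_basis) per_g <- per_g / (1 - moisture_fraction)
  per_g
}

#' Read a per-variety nutritional composition table
#'
#' TSV columns: `variety`, `compound_id`, `content`, `unit`. The moisture
#' fraction rides in a sidecar row with `compound_id == "MOISTURE"` and
#' unit `"fraction"`. A file may hold several varieties.
#'
#' @param path TSV path.
#' @param variety which variety to extract; default: the single one present.
#' @return object of class `composition_table`: list with `variety`,
#'   `entries` (data.frame compound_id/content/unit) and
#'   `moisture_fraction`.
#' @export
read_composition_table <- function(path, variety = NULL) {
  df <- .read_tsv(path, c("variety", "compound_id", "content", "unit"))
  df$content <- as.numeric(df$content)
  if (is.null(variety)) {
    vs <- unique(df$variety)
    if (length(vs) != 1L) {
      stop("file holds varieties ", paste(vs, collapse = ", "),
           "; pick one via the 'variety' argument")
    }
    variety <- vs
  }
  df <- df[df$variety == variety, , drop = FALSE]
  if (nrow(df) == 0L) stop("variety '", variety, "' not found in ", path)
  moist <- df$compound_id == "MOISTURE"
  moisture_fraction <- if (any(moist)) df$content[moist][1] else 0
  entries <- df[!moist, c("compound_id", "content", "unit"), drop = FALSE]
  rownames(entries) <- NULL
  if (any(entries$content < 0)) stop("negative content in ", path)
  structure(list(variety = variety, entries = entries,
                 moisture_fraction = moisture_fraction),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Composition table for variety '", x$variety, "': ",
      nrow(x$entries), " nutrients, moisture fraction ",
      x$moisture_fraction, "\n", sep = "")
  invisible(x)
}

# atomic masses (g/mol) for molar-mass computation from formulas
.atomic_masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                    P = 30.974, S = 32.06, Na = 22.99, K = 39.098,
                    Mg = 24.305, Ca = 40.078, Fe = 55.845, Zn = 65.38,
                    Cu = 63.546, Mn = 54.938, Cl = 35.45, Se = 78.971)

#' Molar mass of a parsed formula
#' @param formula named integer vector of element counts.
#' @return g/mol.
#' @export
formula_weight <- function(formula) {
  if (length(formula) == 0L) return(0)
  unknown <- setdiff(names(formula), names(.atomic_masses))
  if (length(unknown)) {
    stop("no atomic mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.atomic_masses[names(formula)] * formula)
}

#' Standard molar masses shipped with the package
#'
#' Covers the common feed nutrients (amino acids, saccharides, essential
#' fatty acids, nucleotides, mineral elements), keyed by lowercase name.
#'
#' @param path optional alternative TSV (columns `name`, `molar_mass`).
#' @return named numeric vector, g/mol.
#' @export
standard_molar_masses <- function(path = system.file(
    "extdata", "molar_masses.tsv", package = "fluxforge")) {
  df <- utils::read.delim(path)
  stats::setNames(as.numeric(df$molar_mass), tolower(df$name))
}

#' Build a biomass equation from a composition table
#'
#' Each measured nutrient converts to mmol/gDW on a dry basis (moisture
#' subtracted) and becomes a consumed precursor of the biomass
#' pseudo-reaction. Energy maintenance adds ATP + H2O consumed and
#' ADP + phosphate + H+ produced, all at `maintenance_coefficient`
#' (29.8303 by default, adopted from a curated mammalian-cell biomass
#' equation, the closest available organism with measured maintenance).
#' NADPH can optionally join the maintenance set at the same coefficient.
#'
#' @param composition a `composition_table`.
#' @param molar_masses named numeric vector (g/mol) keyed by compound id.
#' @param maintenance_coefficient mmol/gDW for the maintenance cofactors.
#' @param include_nadph also add NADPH consumed / NADP+ produced?
#' @return object of class `biomass_equation`: list with `variety`,
#'   `precursor_coefficients` (named numeric, mmol/gDW, all > 0),
#'   `maintenance_coefficient`, `maintenance` (consumed/produced compound
#'   ids) and `moisture_fraction`.
#' @export
build_biomass_equation <- function(composition, molar_masses,
                                   maintenance_coefficient = 29.8303,
                                   include_nadph = FALSE) {
  stopifnot(inherits(composition, "composition_table"))
  if (nrow(composition$entries) == 0L) {
    stop("composition table is empty; cannot build a biomass equation")
  }
  cids <- composition$entries$compound_id
  missing <- setdiff(cids, names(molar_masses))
  if (length(missing)) {
    stop("no molar mass for compound(s): ", paste(missing, collapse = ", "))
  }
  coefs <- mapply(function(content, unit, cid) {
    content_to_mmol_per_gdw(content, unit, molar_masses[[cid]],
                            composition$moisture_fraction, dry_basis = TRUE)
  }, composition$entries$content, composition$entries$unit, cids)
  names(coefs) <- cids
  coefs <- tapply(coefs, names(coefs), sum) # merge duplicate nutrients
  coefs <- stats::setNames(as.numeric(coefs), names(coefs))
  coefs <- coefs[coefs > 0]
  if (length(coefs) == 0L) {
    stop("all converted precursor coefficients are zero")
  }
  consumed <- c(ATP = "C00002", H2O = "C00001")
  produced <- c(ADP = "C00008", phosphate = "C00009", `H+` = "C00080")
  if (include_nadph) {
    consumed <- c(consumed, NADPH = "C00005")
    produced <- c(produced, `NADP+` = "C00006")
  }
  structure(list(variety = composition$variety,
                 precursor_coefficients = coefs[order(names(coefs))],
                 maintenance_coefficient = maintenance_coefficient,
                 maintenance = list(consumed = consumed, produced = produced),
                 moisture_fraction = composition$moisture_fraction),
            class = "biomass_equation")
}

#' @export
print.biomass_equation <- function(x, ...) {
  cat("Biomass equation (variety '", x$variety, "'): ",
      length(x$precursor_coefficients), " precursors, maintenance ",
      x$maintenance_coefficient, " mmol/gDW\n", sep = "")
  df <- data.frame(compound = names(x$precursor_coefficients),
                   mmol_per_gDW = round_half_up(
                     unname(x$precursor_coefficients), 4))
  print(utils::head(df, 15), row.names = FALSE)
  if (nrow(df) > 15) cat("  ...", nrow(df) - 15, "more\n")
  invisible(x)
}

#' Attach a biomass equation to a model
#'
#' Adds a `kind = "biomass"` reaction consuming each precursor (cytosolic)
#' at its coefficient, carrying the maintenance terms on both sides, and
#' producing one unit of a biomass pseudo-metabolite, which a dedicated
#' sink exchange drains. The biomass reaction becomes the model objective.
#'
#' @param model a `metabolic_model`.
#' @param equation a `biomass_equation`.
#' @param reaction_id id for the biomass reaction.
#' @return the model with biomass reaction, drain and objective set.
#' @export
add_biomass_reaction <- function(model, equation,
                                 reaction_id = "BIOMASS") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(equation, "biomass_equation"))
  if (!is.null(model$reactions[[reaction_id]])) {
    stop("model already has a reaction '", reaction_id, "'")
  }
  stoich <- -equation$precursor_coefficients
  names(stoich) <- met_id(names(equation$precursor_coefficients), "c")
  mc <- equation$maintenance_coefficient
  for (cid in equation$maintenance$consumed) {
    m <- met_id(cid, "c")
    stoich[m] <- (if (m %in% names(stoich)) stoich[[m]] else 0) - mc
  }
  for (cid in equation$maintenance$produced) {
    m <- met_id(cid, "c")
    stoich[m] <- (if (m %in% names(stoich)) stoich[[m]] else 0) + mc
  }
  bm <- met_id("BIOMASS", "c")
  stoich[bm] <- 1
  for (m in names(stoich)) {
    if (is.null(model$metabolites[[m]])) {
      model$metabolites[[m]] <- list(id = m, compound_id = .met_compound(m),
                                     compartment = "c")
    }
  }
  model$reactions[[reaction_id]] <- list(
    id = reaction_id, stoichiometry = stoich[order(names(stoich))],
    lower_bound = 0, upper_bound = 1000, direction = "forward",
    kind = "biomass", gpr = NULL, pathways = character(0),
    subsystem = NA_character_,
    tags = paste0("variety:", equation$variety))
  drain <- paste0("SK_", reaction_id)
  model$reactions[[drain]] <- list(
    id = drain, stoichiometry = stats::setNames(-1, bm),
    lower_bound = 0, upper_bound = 1000, direction = "forward",
    kind = "metabolic", gpr = NULL, pathways = character(0),
    subsystem = NA_character_, tags = "sink")
  model$metabolites <- model$metabolites[order(names(model$metabolites))]
  model$objective <- reaction_id
  model
}
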