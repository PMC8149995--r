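empty_model <- function() {
  structure(list(id = "m", metabolites = list(), reactions = list(),
                 objective = NA_character_,
                 compartments = c(c = "cytosol", e = "extracellular"),
                 nutrient_classes = list()),
            class = "metabolic_model")
}

test_that("one nutrient gains exactly a transport, an exchange and an (e) species", {
  m <- add_boundary_reactions(empty_model(), list(feed_nutrient = "CX"))
  expect_setequal(names(m$reactions), c("TR_CX", "EX_CX"))
  comps <- vapply(m$metabolites, `[[`, character(1), "compartment")
  expect_equal(sum(comps == "e"), 1L)
  expect_equal(m$reactions$TR_CX$stoichiometry,
               c(`CX[e]` = -1, `CX[c]` = 1))
  expect_equal(m$reactions$EX_CX$stoichiometry, c(`CX[e]` = -1))
  expect_equal(m$reactions$TR_CX$kind, "transport")
  expect_equal(m$reactions$EX_CX$kind, "exchange")
  # re-adding is an error naming the compound, never silent duplication
  expect_error(add_boundary_reactions(m, list(feed_nutrient = "CX")), "CX")
})

test_that("the six nutrient classes reproduce the 91/91 boundary shape", {
  classes <- list(
    amino_acid = sprintf("AA%02d", 1:20),
    fatty_acid = sprintf("FA%02d", 1:28),
    saccharide = sprintf("SA%02d", 1:5),
    vitamin = sprintf("VI%02d", 1:15),
    mineral_element = sprintf("MI%02d", 1:10),
    cofactor = sprintf("CO%02d", 1:12),
    extra = "XX01") # one configured extra on top of the 90 class nutrients
  m <- add_boundary_reactions(empty_model(), classes)
  kinds <- vapply(m$reactions, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "transport"), 91L)
  expect_equal(sum(kinds == "exchange"), 91L)
  comps <- vapply(m$metabolites, `[[`, character(1), "compartment")
  expect_equal(sum(comps == "e"), 91L)
})

test_that("the bounds policy assigns fluxes by kind and class with the right precedence", {
  m <- empty_model()
  m$metabolites[["A[c]"]] <- list(id = "A[c]", compound_id = "A",
                                  compartment = "c")
  m$metabolites[["B[c]"]] <- list(id = "B[c]", compound_id = "B",
                                  compartment = "c")
  m$reactions$RREV <- list(id = "RREV",
                           stoichiometry = c(`A[c]` = -1, `B[c]` = 1),
                           lower_bound = 0, upper_bound = 0,
                           direction = "reversible", kind = "metabolic",
                           gpr = NULL, pathways = character(0),
                           subsystem = NA_character_, tags = character(0))
  m$reactions$RFWD <- list(id = "RFWD",
                           stoichiometry = c(`A[c]` = -1, `B[c]` = 1),
                           lower_bound = 0, upper_bound = 0,
                           direction = "forward", kind = "metabolic",
                           gpr = NULL, pathways = character(0),
                           subsystem = NA_character_, tags = character(0))
  m <- add_boundary_reactions(m, list(
    feed_nutrient = c("FN", "BOTH"),
    trace_element = c("TE", "BOTH"),
    synthesizable = "SY"))
  m <- apply_bounds_policy(m, bounds_policy(),
                           synthesizable = c("SY", "BOTH"),
                           trace_elements = c("TE", "BOTH"))
  b <- function(rid) c(m$reactions[[rid]]$lower_bound,
                       m$reactions[[rid]]$upper_bound)
  expect_equal(b("RREV"), c(-1000, 1000))
  expect_equal(b("RFWD"), c(0, 1000))
  expect_equal(b("TR_FN"), c(-1000, 1000))
  expect_equal(b("EX_FN"), c(-5, 1000))
  expect_equal(b("EX_TE"), c(-1, 1000))
  expect_equal(b("EX_SY"), c(0, 1000))
  # precedence: trace element beats synthesizable beats feed nutrient
  expect_equal(b("EX_BOTH"), c(-1, 1000))

  # unclassified exchange: feed-nutrient default with a warning
  m$nutrient_classes <- list()
  expect_warning(m2 <- apply_bounds_policy(m, bounds_policy()),
                 "no nutrient class")
  expect_equal(c(m2$reactions$EX_FN$lower_bound,
                 m2$reactions$EX_FN$upper_bound), c(-5, 1000))
})

test_that("every exchange and transport in the pipeline model obeys the policy", {
  run <- default_run()
  m <- run$report$model
  for (r in m$reactions) {
    bounds <- c(r$lower_bound, r$upper_bound)
    if (r$kind == "exchange") {
      expect_true(identical(bounds, c(0, 1000)) ||
                    identical(bounds, c(-5, 1000)) ||
                    identical(bounds, c(-1, 1000)),
                  label = paste("exchange bounds of", r$id))
    } else if (r$kind == "transport") {
      expect_identical(bounds, c(-1000, 1000))
    }
  }
  validate_model(m)
})

test_that("content conversion reproduces the printed requirement table cells", {
  mm <- standard_molar_masses()
  cells <- data.frame(
    name = c("arginine", "lysine", "leucine", "histidine",
             "phenylalanine", "threonine", "tryptophan", "valine",
             "mg", "epa"),
    content = c(2.43, 0.63, 2.18, 0.73, 1.28, 1.15, 0.28, 1.35,
                0.12, 0.20),
    printed = c(0.14, 0.04, 0.17, 0.05, 0.08, 0.10, 0.01, 0.12,
                0.05, 0.01))
  got <- round_half_up(content_to_mmol_per_gdw(
    cells$content, "g/100g", mm[cells$name]), 2)
  expect_equal(unname(got), cells$printed)
})

test_that("content conversion algebra: units, zero, linearity, moisture scaling", {
  expect_equal(content_to_mmol_per_gdw(1, "g/100g", 100), 0.1)
  expect_equal(content_to_mmol_per_gdw(1, "percent", 100), 0.1)
  expect_equal(content_to_mmol_per_gdw(500, "mg/kg", 100), 0.005)
  expect_equal(content_to_mmol_per_gdw(0, "g/100g", 123), 0)
  expect_error(content_to_mmol_per_gdw(-1, "g/100g", 100), "non-negative")
  expect_error(content_to_mmol_per_gdw(1, "stones", 100), "unknown")

  set.seed(3)
  for (k in 1:20) {
    content <- runif(1, 0, 10); mwt <- runif(1, 20, 500)
    a <- runif(1, 0.1, 5)
    # linear in content, inverse in molar mass
    expect_equal(content_to_mmol_per_gdw(a * content, "g/100g", mwt),
                 a * content_to_mmol_per_gdw(content, "g/100g", mwt))
    expect_equal(content_to_mmol_per_gdw(content, "g/100g", a * mwt),
                 content_to_mmol_per_gdw(content, "g/100g", mwt) / a)
    # dry-basis rescales by 1/(1 - moisture), uniformly
    moist <- runif(1, 0, 0.9)
    expect_equal(
      content_to_mmol_per_gdw(content, "g/100g", mwt, moist, TRUE),
      content_to_mmol_per_gdw(content, "g/100g", mwt) / (1 - moist))
  }
})

test_that("biomass equations convert on a dry basis with maintenance at 29.8303", {
  comp <- structure(list(
    variety = "test",
    entries = data.frame(compound_id = c("AA", "BB"),
                         content = c(2.0, 0.5),
                         unit = c("g/100g", "g/100g"),
                         stringsAsFactors = FALSE),
    moisture_fraction = 0.75), class = "composition_table")
  eq <- build_biomass_equation(comp, c(AA = 100, BB = 50))
  # hand arithmetic: (g/100g * 10 / MW) / (1 - 0.75)
  expect_equal(unname(eq$precursor_coefficients["AA"]),
               (2.0 * 10 / 100) / 0.25)
  expect_equal(unname(eq$precursor_coefficients["BB"]),
               (0.5 * 10 / 50) / 0.25)
  expect_equal(eq$maintenance_coefficient, 29.8303)
  expect_setequal(unname(eq$maintenance$consumed), c("C00002", "C00001"))
  expect_setequal(unname(eq$maintenance$produced),
                  c("C00008", "C00009", "C00080"))

  # NADPH joins only on request, at the same coefficient
  eq2 <- build_biomass_equation(comp, c(AA = 100, BB = 50),
                                include_nadph = TRUE)
  expect_true("C00005" %in% eq2$maintenance$consumed)

  empty <- comp
  empty$entries <- empty$entries[0, ]
  expect_error(build_biomass_equation(empty, c(AA = 100)), "empty")
  expect_error(build_biomass_equation(comp, c(AA = 100)), "BB")
})

test_that("changing moisture rescales all biomass coefficients by one factor", {
  comp <- structure(list(
    variety = "t",
    entries = data.frame(compound_id = c("AA", "BB"),
                         content = c(1.2, 3.4), unit = "g/100g",
                         stringsAsFactors = FALSE),
    moisture_fraction = 0.5), class = "composition_table")
  e1 <- build_biomass_equation(comp, c(AA = 10, BB = 20))
  comp$moisture_fraction <- 0.8
  e2 <- build_biomass_equation(comp, c(AA = 10, BB = 20))
  ratio <- e2$precursor_coefficients / e1$precursor_coefficients
  expect_equal(unname(ratio), rep(0.5 / 0.2, length(ratio)))
  expect_true(all(e1$precursor_coefficients > 0))
})

test_that("the attached biomass reaction produces one biomass unit through a drain", {
  comp <- structure(list(
    variety = "t",
    entries = data.frame(compound_id = "AA", content = 1, unit = "g/100g",
                         stringsAsFactors = FALSE),
    moisture_fraction = 0), class = "composition_table")
  eq <- build_biomass_equation(comp, c(AA = 100))
  m <- add_biomass_reaction(empty_model(), eq)
  expect_equal(m$objective, "BIOMASS")
  st <- m$reactions$BIOMASS$stoichiometry
  expect_equal(unname(st["BIOMASS[c]"]), 1)
  expect_equal(unname(st["AA[c]"]), -0.1)
  expect_equal(unname(st["C00002[c]"]), -29.8303)
  expect_equal(unname(st["C00008[c]"]), 29.8303)
  expect_equal(m$reactions$SK_BIOMASS$stoichiometry, c(`BIOMASS[c]` = -1))
  expect_error(add_biomass_reaction(m, eq), "already")
})

test_that("composition tables read variety-wise with the moisture sidecar row", {
  run <- default_run()
  path <- run$dataset$files["compositions"]
  expect_error(read_composition_table(path), "pick one")
  ct <- read_composition_table(path, "variety_1")
  expect_s3_class(ct, "composition_table")
  expect_equal(ct$moisture_fraction,
               run$ground_truth$varieties$moisture[1])
  expect_false("MOISTURE" %in% ct$entries$compound_id)
  expect_error(read_composition_table(path, "nope"), "not found")
})
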