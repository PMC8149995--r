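test_that("formula parsing handles multi-letter elements, counts and the empty formula", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("Mg"), c(Mg = 1L))
  expect_equal(parse_formula("C10H16N5O13P3"),
               c(C = 10L, H = 16L, N = 5L, O = 13L, P = 3L))
  expect_length(parse_formula(""), 0)
  expect_error(parse_formula("c6h12"), "unparsable")
})

test_that("equation parsing recovers hand-parsed stoichiometry, direction and flags", {
  eq <- parse_equation("2 C00001 + C00007 <=> 4 C00080")
  expect_equal(eq$stoichiometry,
               c(C00001 = -2, C00007 = -1, C00080 = 4))
  expect_equal(eq$direction, "reversible")
  expect_false(eq$symbolic_coefficient)
  expect_false(eq$incomplete)

  fwd <- parse_equation("C00031 => C00267")
  expect_equal(fwd$direction, "forward")

  sym <- parse_equation("n C00031 <=> n C00267")
  expect_true(sym$symbolic_coefficient)

  inc <- parse_equation("C00031 <=>")
  expect_true(inc$incomplete)

  frac <- parse_equation("1/2 C00007 + C00282 <=> C00001")
  expect_equal(frac$stoichiometry[["C00007"]], -0.5)

  expect_error(parse_equation("C00031 C00267"), "arrow")
})

test_that("a toy universe parses with hand-checked records", {
  dir <- write_toy_universe()
  u <- parse_universe(file.path(dir, "compounds.tsv"),
                      file.path(dir, "reactions.tsv"),
                      file.path(dir, "pathways.tsv"),
                      file.path(dir, "enzymes.tsv"))
  expect_s3_class(u, "kegg_universe")
  expect_equal(u$compounds$C00031$name, "D-glucose")
  expect_setequal(u$compounds$C00031$aliases, c("C00267", "C00221"))
  expect_equal(u$compounds$C05359$charge, -1)
  expect_length(u$compounds$C05359$formula, 0)
  # hand-parsed coefficients of the kinase reaction
  expect_equal(u$reactions$R00001$stoichiometry,
               c(C00031 = -1, C00002 = -1, C00092 = 1, C00008 = 1))
  expect_equal(u$reactions$R00002$direction, "forward")
  expect_true(u$reactions$R00004$flags$symbolic_coefficient)
  # EC index merges inline ECs and the link table
  expect_setequal(u$ec_to_reactions[["5.1.3.3"]], c("R00002", "R00004"))
  expect_setequal(u$ec_to_reactions[["2.7.1.2"]], "R00001")
  expect_equal(unname(u$pathway_to_subsystem["pwy2"]), "Carbohydrate")
})

test_that("parsing is idempotent and rejects unknown compounds", {
  dir <- write_toy_universe()
  paths <- file.path(dir, c("compounds.tsv", "reactions.tsv",
                            "pathways.tsv", "enzymes.tsv"))
  u1 <- parse_universe(paths[1], paths[2], paths[3], paths[4])
  u2 <- parse_universe(paths[1], paths[2], paths[3], paths[4])
  expect_identical(u1, u2)

  # referencing a compound missing from the table is a validation error
  cat("R99999\tC00031 <=> C99999\t\t\t\t\t\t\n",
      file = paths[2], append = TRUE)
  expect_error(parse_universe(paths[1], paths[2], paths[3], paths[4]),
               "C99999")
  expect_error(parse_universe(tempfile(), paths[2], paths[3], paths[4]),
               "does not exist")
})

test_that("header-only files give an empty universe", {
  dir <- tempfile("empty")
  dir.create(dir)
  writeLines("compound_id\tname\tformula\tcharge\taliases",
             file.path(dir, "compounds.tsv"))
  writeLines("reaction_id\tequation", file.path(dir, "reactions.tsv"))
  writeLines("pathway_id\tsubsystem", file.path(dir, "pathways.tsv"))
  writeLines("ec_number\treaction_id", file.path(dir, "enzymes.tsv"))
  u <- parse_universe(file.path(dir, "compounds.tsv"),
                      file.path(dir, "reactions.tsv"),
                      file.path(dir, "pathways.tsv"),
                      file.path(dir, "enzymes.tsv"))
  expect_length(u$compounds, 0)
  expect_length(u$reactions, 0)
})

test_that("unparsable lines are logged and skipped, not silently dropped", {
  dir <- write_toy_universe()
  paths <- file.path(dir, c("compounds.tsv", "reactions.tsv",
                            "pathways.tsv", "enzymes.tsv"))
  cat("RBAD01\tC00031 + + bogus\t\t\t\t\t\t\n",
      file = paths[2], append = TRUE)
  expect_message(
    u <- parse_universe(paths[1], paths[2], paths[3], paths[4]),
    "skipping.*line")
  expect_false("RBAD01" %in% names(u$reactions))
  expect_true("R00001" %in% names(u$reactions))
})

test_that("annotations group per gene, collapse duplicates and keep KEGG-style ids", {
  path <- write_toy_annotations(rows = c(
    "pvm:113803399\t2.7.1.1",
    "pvm:113803399\t2.7.1.1",   # duplicate pair collapses
    "pvm:113803399\t1.1.1.1",
    "g2\t5.1.3.3",
    "g3\tnot-an-ec"))
  expect_warning(ann <- parse_annotations(path), "malformed")
  expect_s3_class(ann, "gene_annotations")
  expect_equal(ann[["pvm:113803399"]], c("1.1.1.1", "2.7.1.1"))
  expect_length(ann, 2) # g3 dropped entirely
})

test_that("the EC index reaches every annotated gene sharing that EC", {
  rows <- c(sprintf("g%d\t1.1.1.%d", 1:7, c(1, 2, 3, 9, 9, 9, 4)),
            sprintf("g%d\t2.2.2.2", 8:10))
  ann <- parse_annotations(write_toy_annotations(rows = rows))
  sharing <- names(Filter(function(ecs) "1.1.1.9" %in% ecs, ann))
  expect_setequal(sharing, c("g4", "g5", "g6"))
  expect_length(ann, 10)
})

test_that("model JSON round-trip is lossless", {
  # empty model
  empty <- structure(list(id = "empty", metabolites = list(),
                          reactions = list(), objective = NA_character_,
                          compartments = c(c = "cytosol",
                                           e = "extracellular"),
                          nutrient_classes = list()),
                     class = "metabolic_model")
  p <- tempfile(fileext = ".json")
  write_model(empty, p, "json")
  expect_equal(read_model(p), empty)

  # a full synthetic model with GPRs, kinds, bounds, classes and objective
  run <- default_run()
  model <- run$report$model
  write_model(model, p, "json")
  back <- read_model(p)
  expect_equal(back, model)
  expect_error(read_model(tempfile(fileext = ".sbml")), "JSON")
})

test_that("random perturbed models survive the JSON round-trip field by field", {
  run <- default_run()
  base <- run$report$model
  set.seed(99)
  for (k in 1:5) {
    m <- base
    keep <- sort(sample(names(m$reactions),
                        max(2L, length(m$reactions) %/% 2L)))
    m$reactions <- m$reactions[keep]
    mids <- sort(unique(unlist(lapply(m$reactions,
                                      function(r) names(r$stoichiometry)))))
    m$metabolites <- m$metabolites[mids]
    m$objective <- NA_character_
    p <- tempfile(fileext = ".json")
    write_model(m, p, "json")
    expect_equal(read_model(p), m)
  }
})

test_that("the SBML export is readable by an independent SBML implementation", {
  run <- default_run()
  sbml <- file.path(run$dir, "out", "model.sbml")
  expect_true(file.exists(sbml))
  # structural sanity through a fresh XML parse
  doc <- xml2::read_xml(sbml)
  ns <- xml2::xml_ns(doc)
  n_rxn <- length(xml2::xml_find_all(doc, "//d1:reaction", ns))
  expect_equal(n_rxn, length(run$report$model$reactions))
  # independent reader: the COBRA reference implementation via python
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import cobra,sys;",
    "m=cobra.io.read_sbml_model(sys.argv[1]);",
    "print(len(m.reactions),len(m.metabolites),",
    "round(m.optimize().objective_value,6))")), sbml),
    stdout = TRUE, stderr = FALSE))
  expect_equal(length(out), 1L)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  expect_equal(vals[1], length(run$report$model$reactions))
  expect_equal(vals[2], length(run$report$model$metabolites))
  expect_equal(vals[3], unname(run$report$growth[1]), tolerance = 1e-5)
})
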