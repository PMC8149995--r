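# Fixtures are built in code at test time. Expensive shared artifacts
# (the default synthetic dataset and its full pipeline run) are computed
# once per session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

# default synthetic dataset + complete pipeline run (shared across tests)
default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    dir <- file.path(tempdir(), "fluxforge-default-run")
    cfg <- generator_config() # the study conditions; seed 1
    d <- generate_dataset(cfg, dir)
    pc <- pipeline_config(dir, out_dir = file.path(dir, "out"), seed = 1L)
    .fixture_cache$run <- list(dir = dir, config = cfg, dataset = d,
                               ground_truth = d$ground_truth,
                               report = run_pipeline(pc))
  }
  .fixture_cache$run
}

# hand-written 5-reaction universe exercising the parser corner cases
write_toy_universe <- function(dir = tempfile("universe")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(
    "compound_id\tname\tformula\tcharge\taliases",
    "C00001\tH2O\tH2O\t0\t",
    "C00031\tD-glucose\tC6H12O6\t0\tC00267;C00221",
    "C00267\talpha-D-glucose\tC6H12O6\t0\tC00031",
    "C00221\tbeta-D-glucose\tC6H12O6\t0\tC00031",
    "C00092\tglucose 6-phosphate\tC6H13O9P\t0\t",
    "C00002\tATP\tC10H16N5O13P3\t0\t",
    "C00008\tADP\tC10H15N5O10P2\t0\t",
    "C05359\te-\t\t-1\t",
    "X00001\tsplitA\tC3H6O3\t0\t",
    "X00002\tsplitB\tC3H6O3\t0\t"),
    file.path(dir, "compounds.tsv"))
  writeLines(c(
    "reaction_id\tequation\tdirection\tec_numbers\tmain_reaction_id\tpathways\tsubsystem\tflags",
    "R00001\tC00031 + C00002 <=> C00092 + C00008\t\t2.7.1.1;2.7.1.2\tR00001\tpwy1\tCarbohydrate\t",
    "R00002\tC00267 => C00221\tforward\t5.1.3.3\t\tpwy1\tCarbohydrate\t",
    "R00003\tC00031 <=> X00001 + X00002\t\t4.1.2.13\t\tpwy2\t\t",
    "R00004\tn C00031 <=> n C00267\t\t5.1.3.3\t\tpwy1\tCarbohydrate\t",
    "R00005\t2 X00001 <=> 2 X00002\t\t5.3.1.1\t\tpwy2\t\t"),
    file.path(dir, "reactions.tsv"))
  writeLines(c("pathway_id\tsubsystem",
               "pwy1\tCarbohydrate",
               "pwy2\tCarbohydrate"),
             file.path(dir, "pathways.tsv"))
  writeLines(c("ec_number\treaction_id",
               "2.7.1.1\tR00001",
               "5.1.3.3\tR00002"),
             file.path(dir, "enzymes.tsv"))
  dir
}

write_toy_annotations <- function(dir = tempfile("genes"), rows = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(rows)) {
    rows <- c("g1\t2.7.1.1", "g1\t2.7.1.2", "g2\t5.1.3.3", "g3\t2.7.1.1")
  }
  path <- file.path(dir, "genes.tsv")
  writeLines(c("gene_id\tec_number", rows), path)
  path
}

# minimal in-code metabolic model: EX_A -> TR_A -> A(c) -v-> B(c) -> TR_B -> EX_B
chain_model <- function(uptake_lb = -5) {
  m <- structure(list(id = "chain", metabolites = list(),
                      reactions = list(), objective = NA_character_,
                      compartments = c(c = "cytosol", e = "extracellular"),
                      nutrient_classes = list()),
                 class = "metabolic_model")
  for (mid in c("A[c]", "A[e]", "B[c]", "B[e]")) {
    m$metabolites[[mid]] <- list(id = mid,
                                 compound_id = sub("\\[.\\]", "", mid),
                                 compartment = sub("^.*\\[(.)\\]$", "\\1", mid))
  }
  rxn <- function(id, stoich, lb, ub, kind, direction = "reversible") {
    list(id = id, stoichiometry = stoich, lower_bound = lb, upper_bound = ub,
         direction = direction, kind = kind, gpr = NULL,
         pathways = character(0), subsystem = NA_character_,
         tags = character(0))
  }
  m$reactions$EX_A <- rxn("EX_A", c(`A[e]` = -1), uptake_lb, 1000, "exchange")
  m$reactions$TR_A <- rxn("TR_A", c(`A[e]` = -1, `A[c]` = 1), -1000, 1000,
                          "transport")
  m$reactions$CONV <- rxn("CONV", c(`A[c]` = -1, `B[c]` = 1), -1000, 1000,
                          "metabolic")
  m$reactions$TR_B <- rxn("TR_B", c(`B[c]` = -1, `B[e]` = 1), -1000, 1000,
                          "transport")
  m$reactions$EX_B <- rxn("EX_B", c(`B[e]` = -1), 0, 1000, "exchange")
  m$objective <- "EX_B"
  m
}

# random small stoichiometric systems for the LP equivalence checks
random_lp_case <- function(max_rxns = 6L) {
  n <- sample(2:max_rxns, 1)
  m <- sample(1:(n - 1), 1)
  A <- matrix(sample(-2:2, m * n, replace = TRUE), m, n)
  lb <- round(runif(n, -10, 0), 1)
  ub <- lb + round(runif(n, 0, 10), 1)
  x0 <- lb + runif(n) * (ub - lb) # guarantees feasibility
  b <- as.vector(A %*% x0)
  obj <- round(runif(n, -3, 3), 2)
  list(obj = obj, A = A, b = b, lb = lb, ub = ub,
       sense = sample(c("max", "min"), 1))
}
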