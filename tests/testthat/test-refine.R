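mini_compounds <- function() {
  list(
    A = list(id = "A", formula = c(C = 6L, H = 12L, O = 6L), charge = 0),
    B = list(id = "B", formula = c(C = 6L, H = 12L, O = 6L), charge = 0),
    Bdehyd = list(id = "Bdehyd", formula = c(C = 6L, H = 10L, O = 5L),
                  charge = 0),
    Bdeprot = list(id = "Bdeprot", formula = c(C = 6L, H = 11L, O = 6L),
                   charge = -1),
    C00001 = list(id = "C00001", formula = c(H = 2L, O = 1L), charge = 0),
    C00080 = list(id = "C00080", formula = c(H = 1L), charge = 1),
    C05359 = list(id = "C05359", formula = integer(0), charge = -1),
    C01438 = list(id = "C01438", formula = c(C = 1L, H = 4L), charge = 0),
    C06547 = list(id = "C06547", formula = c(C = 2L, H = 4L), charge = 0))
}

test_that("balance checking computes signed element and charge deficits", {
  cpds <- mini_compounds()
  # an isomerization over identical formulas is balanced
  rep0 <- check_balance(list(stoichiometry = c(A = -1, B = 1)), cpds)
  expect_true(rep0$balanced)

  # right side short one water: deficit H -2, O -1
  rep1 <- check_balance(list(stoichiometry = c(A = -1, Bdehyd = 1)), cpds)
  expect_false(rep1$balanced)
  expect_equal(rep1$element_deficit[["H"]], -2)
  expect_equal(rep1$element_deficit[["O"]], -1)

  # the electron is a legitimate species: empty formula, charge -1
  rep2 <- check_balance(list(stoichiometry = c(C00080 = -1, C05359 = -1)),
                        cpds)
  expect_true(rep2$computable)
  expect_equal(rep2$charge_deficit, 0)
  expect_equal(rep2$element_deficit[["H"]], -1)

  # unknown species make the reaction uncomputable, never an error
  rep3 <- check_balance(list(stoichiometry = c(A = -1, UNKNOWN = 1)), cpds)
  expect_false(rep3$computable)
})

test_that("filler balancing finds the minimal fix and flags the hopeless", {
  cpds <- mini_compounds()
  ok <- balance_reaction(list(stoichiometry = c(A = -1, B = 1)), cpds)
  expect_equal(ok$status, "already_balanced")

  # one water short on the right: unique minimal fix +1 H2O
  fix <- balance_reaction(list(stoichiometry = c(A = -1, Bdehyd = 1)), cpds)
  expect_equal(fix$status, "balanced")
  expect_equal(fix$added, c(C00001 = 1))
  expect_true(check_balance(fix$reaction, cpds)$balanced)

  # deprotonated product: +1 H+ restores both hydrogen and charge
  fix2 <- balance_reaction(list(stoichiometry = c(A = -1, Bdeprot = 1)), cpds)
  expect_equal(fix2$added, c(C00080 = 1))
  expect_true(check_balance(fix2$reaction, cpds)$balanced)

  # charge-only deficit resolves through the electron
  fix3 <- balance_reaction(
    list(stoichiometry = c(C05359 = -2, C00080 = 1)), cpds)
  expect_equal(fix3$status, "balanced")
  expect_true(check_balance(fix3$reaction, cpds)$balanced)

  # nitrogen cannot be made from the filler set
  cpds$N1 <- list(id = "N1", formula = c(N = 1L), charge = 0)
  bad <- balance_reaction(list(stoichiometry = c(A = -1, N1 = 1)), cpds)
  expect_equal(bad$status, "unbalanceable")
  expect_equal(bad$reaction$stoichiometry, c(A = -1, N1 = 1))
})

test_that("balanced fixes from the search always re-check as balanced", {
  cpds <- mini_compounds()
  set.seed(5)
  fillers <- default_fillers()
  for (k in 1:50) {
    # random achievable imbalance: start balanced, remove random fillers
    extra <- sample(fillers, sample(1:3, 1))
    stoich <- c(A = -1, B = 1)
    for (f in extra) {
      stoich[f] <- (if (f %in% names(stoich)) stoich[[f]] else 0) +
        sample(c(-3:-1, 1:3), 1)
    }
    stoich <- stoich[stoich != 0]
    res <- balance_reaction(list(stoichiometry = stoich), cpds)
    expect_true(res$status %in% c("balanced", "already_balanced"))
    expect_true(check_balance(res$reaction, cpds)$balanced)
    # minimality: undoing the perturbation is one solution, so the found
    # fix can never use more filler molecules than the perturbation itself
    if (res$status == "balanced") {
      planted <- sum(abs(stoich[names(stoich) %in% fillers]))
      expect_lte(sum(abs(res$added)), planted)
    }
  }
})

mini_network <- function(reactions) {
  structure(list(
    reactions = lapply(reactions, function(r) {
      list(record = c(r, list(
        direction = "reversible",
        ec_numbers = character(0), main_reaction_id = NA_character_,
        pathways = character(0), subsystem = NA_character_,
        flags = modifyList(list(generic = FALSE, incomplete = FALSE,
                                symbolic_coefficient = FALSE),
                           if (is.null(r$flags)) list() else r$flags))[
                             c("stoichiometry", "direction", "ec_numbers",
                               "main_reaction_id", "pathways", "subsystem",
                               "flags")]),
           gpr = "g1", genes = "g1", ecs = "1.1.1.1")
    }),
    genes = "g1", pathways = character(0), subsystems = character(0)),
    class = "draft_network")
}

test_that("chiral standardization substitutes aliases and is idempotent", {
  net <- mini_network(list(
    R1 = list(stoichiometry = c(C00031 = -1, X = 1)),
    R2 = list(stoichiometry = c(Y = -1, Z = 1))))
  pol <- c(C00031 = "C00267")
  out <- standardize_chirality(net, pol)
  expect_equal(out$modified, "R1")
  expect_equal(names(out$network$reactions$R1$record$stoichiometry),
               c("C00267", "X"))
  again <- standardize_chirality(out$network, pol)
  expect_length(again$modified, 0)
  expect_identical(again$network, out$network)

  # empty policy is a no-op
  none <- standardize_chirality(net, character(0))
  expect_identical(none$network, net)

  # a policy chain/cycle is fatal
  expect_error(standardize_chirality(net, c(A = "B", B = "C")),
               "idempotent")

  # substitution collapsing both sides flags a self-duplicate
  self <- mini_network(list(R3 = list(
    stoichiometry = c(C00031 = -1, C00267 = 1))))
  res <- standardize_chirality(self, pol)
  expect_equal(res$self_identical, "R3")
})

test_that("step chains collapse onto the total reaction only when unbranched", {
  # A -> B, B -> C with total A -> C and unbranched B: steps removed
  net <- mini_network(list(
    RSTEP1 = list(stoichiometry = c(A = -1, B = 1)),
    RSTEP2 = list(stoichiometry = c(B = -1, C = 1)),
    RTOTAL = list(stoichiometry = c(A = -1, C = 1))))
  out <- remove_redundant(net)
  expect_setequal(out$removed$step, c("RSTEP1", "RSTEP2"))
  expect_true("RTOTAL" %in% names(out$network$reactions))

  # branched intermediate: nothing removed
  net2 <- mini_network(list(
    RSTEP1 = list(stoichiometry = c(A = -1, B = 1)),
    RSTEP2 = list(stoichiometry = c(B = -1, C = 1)),
    RBRANCH = list(stoichiometry = c(B = -1, D = 1)),
    RTOTAL = list(stoichiometry = c(A = -1, C = 1))))
  out2 <- remove_redundant(net2)
  expect_length(out2$removed$step, 0)
  expect_length(out2$network$reactions, 4)
})

test_that("generic, symbolic and duplicate reactions are removed into disjoint categories", {
  net <- mini_network(list(
    RGEN = list(stoichiometry = c(A = -1, B = 1),
                flags = list(generic = TRUE)),
    RSYM = list(stoichiometry = c(A = -1, C = 1),
                flags = list(symbolic_coefficient = TRUE)),
    RINC = list(stoichiometry = c(A = -1), flags = list(incomplete = TRUE)),
    RAKEEP = list(stoichiometry = c(A = -1, D = 1)),
    RDUP = list(stoichiometry = c(A = -1, D = 1))))
  out <- remove_redundant(net)
  expect_equal(out$removed$generic, "RGEN")
  expect_setequal(out$removed$incomplete_or_symbolic, c("RINC", "RSYM"))
  # of two identical equations the lexicographically first id is kept
  expect_equal(out$removed$chiral_duplicate, "RDUP")
  expect_setequal(names(out$network$reactions), "RAKEEP")
  all_removed <- unlist(out$removed)
  expect_equal(anyDuplicated(all_removed), 0)
})

test_that("metadata supplementation inherits from the universe and infers pathways", {
  dir <- write_toy_universe()
  u <- parse_universe(file.path(dir, "compounds.tsv"),
                      file.path(dir, "reactions.tsv"),
                      file.path(dir, "pathways.tsv"),
                      file.path(dir, "enzymes.tsv"))
  net <- mini_network(list(
    # has pathway, lacks subsystem: filled via pathway->subsystem map
    R00003 = list(stoichiometry = u$reactions$R00003$stoichiometry)))
  net$reactions$R00003$record$pathways <- "pwy2"
  out <- supplement_metadata(net, u)
  expect_equal(out$network$reactions$R00003$record$subsystem, "Carbohydrate")
  expect_equal(unname(out$supplemented["subsystem"]), 1L)

  # no pathway: inferred from the metabolites' shared pathway
  net2 <- mini_network(list(
    RNEW = list(stoichiometry = c(X00001 = -1, X00002 = 1))))
  out2 <- supplement_metadata(net2, u)
  expect_equal(out2$network$reactions$RNEW$record$pathways, "pwy2")
})

test_that("the full refinement pass reproduces the planted bookkeeping", {
  run <- default_run()
  gt <- run$ground_truth
  ref <- run$report$refinement_report
  expect_equal(ref$balanced_count, length(gt$unbalanced))
  expect_gte(ref$modified_chirality_count, length(gt$chiral_aliases))
  for (cat in names(gt$removable)) {
    expect_identical(ref$removed[[cat]], gt$removable[[cat]])
  }
  expect_equal(ref$metadata_supplemented_count, length(gt$metadata_missing))
  expect_length(ref$unbalanceable, 0)
})
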