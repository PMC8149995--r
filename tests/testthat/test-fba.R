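test_that("the stoichiometric matrix maps the model exactly, both ways", {
  m <- chain_model()
  sys <- build_matrix(m)
  expect_s3_class(sys, "stoichiometric_system")
  expect_equal(dim(sys$S), c(4, 5))
  expect_equal(sys$metabolite_ids, sort(names(m$metabolites)))
  # hand-written column for the conversion reaction
  expect_equal(as.numeric(sys$S[, "CONV"]),
               as.numeric(c(`A[c]` = -1, `A[e]` = 0, `B[c]` = 1,
                            `B[e]` = 0)))
  # reconstruction: every nonzero traces back to a stoichiometry entry
  for (rid in sys$reaction_ids) {
    col <- sys$S[, rid]
    expect_equal(col[col != 0],
                 m$reactions[[rid]]$stoichiometry[names(col[col != 0])])
  }
  # a reaction naming an unknown metabolite is a validation error
  bad <- m
  bad$reactions$CONV$stoichiometry <- c(`A[c]` = -1, `GHOST[c]` = 1)
  expect_error(build_matrix(bad), "GHOST")
})

test_that("a bound-limited uptake chain attains exactly its uptake capacity", {
  sol <- solve_fba(build_matrix(chain_model(uptake_lb = -5)), "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 5, tolerance = 1e-9)
  expect_lte(sol$residual, 1e-8)
  expect_equal(unname(sol$fluxes["EX_A"]), -5, tolerance = 1e-9)

  # degenerate: all bounds zero is optimal at zero, not an error
  m0 <- chain_model()
  for (rid in names(m0$reactions)) {
    m0$reactions[[rid]]$lower_bound <- 0
    m0$reactions[[rid]]$upper_bound <- 0
  }
  sol0 <- solve_fba(build_matrix(m0), "max")
  expect_equal(sol0$status, "optimal")
  expect_equal(sol0$objective_value, 0)
})

test_that("the simplex agrees with enumeration and second-solver oracles on random systems", {
  set.seed(17)
  n_checked <- 0
  for (k in 1:120) {
    case <- random_lp_case()
    mine <- lp_solve(case$obj, case$A, case$b, case$lb, case$ub,
                     sense = case$sense)
    expect_equal(mine$status, "optimal")
    enum <- lp_enum_oracle(case$obj, case$A, case$b, case$lb, case$ub,
                           sense = case$sense)
    expect_lt(abs(mine$objective - enum), 1e-6)
    expect_lte(max(abs(case$A %*% mine$x - case$b)), 1e-8)
    if (k <= 40) { # a slower third route on a subset
      bo <- lp_boot_oracle(case$obj, case$A, case$b, case$lb, case$ub,
                           sense = case$sense)
      if (!is.null(bo)) expect_lt(abs(mine$objective - bo), 1e-6)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 100)
})

test_that("infeasible and unbounded programs are reported, never silent zeros", {
  inf <- lp_solve(c(1, 0), matrix(c(1, 1), 1, 2), 10, c(0, 0), c(1, 1))
  expect_equal(inf$status, "infeasible")
  unb <- lp_solve(c(1, 1), matrix(c(1, -1), 1, 2), 0, c(0, 0), c(Inf, Inf))
  expect_equal(unb$status, "unbounded")
})

test_that("synthesis flux is zero without a route and positive after repair", {
  m <- chain_model()
  # B is producible from A's uptake
  expect_gt(max_synthesis_flux(m, "B"), 0)
  # hand-computed capacity: limited by A uptake of 5
  expect_equal(max_synthesis_flux(m, "B"), 5, tolerance = 1e-9)

  # cut the conversion: B no longer synthesizable
  cut <- m
  cut$reactions$CONV <- NULL
  expect_equal(max_synthesis_flux(cut, "B"), 0, tolerance = 1e-9)
  expect_error(max_synthesis_flux(m, "NOPE"), "not in the model")

  # a compound with no exchange gets a temporary demand
  noex <- m
  noex$reactions$TR_B <- NULL
  noex$reactions$EX_B <- NULL
  noex$metabolites[["B[e]"]] <- NULL
  expect_equal(max_synthesis_flux(noex, "B"), 5, tolerance = 1e-9)
})

biomass_toy <- function(coef = 2) {
  m <- chain_model()
  m$metabolites[["BIOMASS[c]"]] <- list(id = "BIOMASS[c]",
                                        compound_id = "BIOMASS",
                                        compartment = "c")
  m$reactions$BIOMASS <- list(
    id = "BIOMASS", stoichiometry = c(`B[c]` = -coef, `BIOMASS[c]` = 1),
    lower_bound = 0, upper_bound = 1000, direction = "forward",
    kind = "biomass", gpr = NULL, pathways = character(0),
    subsystem = NA_character_, tags = "variety:toy")
  m$reactions$SK_BIOMASS <- list(
    id = "SK_BIOMASS", stoichiometry = c(`BIOMASS[c]` = -1),
    lower_bound = 0, upper_bound = 1000, direction = "forward",
    kind = "metabolic", gpr = NULL, pathways = character(0),
    subsystem = NA_character_, tags = "sink")
  m$objective <- "BIOMASS"
  m
}

test_that("growth equals the hand-solved bottleneck flux over the biomass coefficient", {
  # uptake cap 5, biomass consumes 2 B per unit: growth = 5 / 2
  expect_equal(max_growth(biomass_toy(coef = 2)), 2.5, tolerance = 1e-9)
  # scaling the precursor coefficient by k divides growth by exactly k
  g1 <- max_growth(biomass_toy(coef = 1))
  for (k in c(2, 5, 10)) {
    expect_equal(max_growth(biomass_toy(coef = k)), g1 / k,
                 tolerance = 1e-9)
  }
  # an unproducible precursor forces zero growth
  cut <- biomass_toy()
  cut$reactions$CONV <- NULL
  expect_equal(max_growth(cut), 0, tolerance = 1e-9)
  # exactly one biomass reaction is required
  expect_error(max_growth(chain_model()), "exactly one biomass")
})

test_that("relaxing an uptake bound never decreases growth", {
  bounds <- c(-1, -2, -5, -10, -50)
  g <- vapply(bounds, function(b) {
    m <- biomass_toy()
    m$reactions$EX_A$lower_bound <- b
    max_growth(m)
  }, numeric(1))
  expect_true(all(diff(g) >= -1e-9))
})

test_that("requirement profiles are parsimonious, within bounds, and refuse infeasible growth", {
  m <- biomass_toy(coef = 2)
  m$nutrient_classes <- list(feed_nutrient = "A", synthesizable = "B")
  prof <- nutrient_requirements(m, biomass_flux = 1)
  df <- prof$profile
  # single-route model: uptake equals coefficient x biomass flux
  expect_equal(df$flux[df$nutrient == "A"], -2, tolerance = 1e-8)
  # B is not secreted in the parsimonious solution
  expect_equal(df$flux[df$nutrient == "B"], 0, tolerance = 1e-8)
  expect_true(all(df$flux >= df$lower_bound - 1e-9))
  expect_true(all(df$flux <= df$upper_bound + 1e-9))
  expect_true(all(df$fva_min <= df$flux + 1e-9))
  expect_true(all(df$fva_max >= df$flux - 1e-9))
  expect_equal(df$class[df$nutrient == "A"], "feed_nutrient")

  expect_error(nutrient_requirements(m, biomass_flux = 10), "infeasible")
})

test_that("planted growth rates are recovered through the full model", {
  run <- default_run()
  gt <- run$ground_truth
  expect_equal(unname(run$report$growth[gt$varieties$name]),
               gt$varieties$growth, tolerance = 1e-6)
})
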