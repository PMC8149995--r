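# Synthetic KEGG-like data with planted ground truth. The chemistry is
# token-level: pathway modules are chains of isomerase-style reactions over
# same-formula compounds (balanced by construction), so the balancing,
# connectivity and LP logic is what the planted defects exercise, not real
# biochemistry.
#
# Planted structures, each recorded in the returned ground truth:
#   * gap reactions linking module pairs, present in the universe but never
#     annotated (so absent from the draft);
#   * unbalanced reactions missing one H2O or one H+;
#   * chiral alias pairs whose substitution creates a duplicate reaction;
#   * two-step chains shadowing an existing total reaction;
#   * generic / symbolic-coefficient / incomplete reactions;
#   * reactions stripped of pathway+subsystem metadata;
#   * blocked synthesizable precursors: a single missing reaction, a
#     missing three-reaction stretch, and a wrong-direction reaction;
#   * a feed-limited biomass bottleneck giving each variety a closed-form
#     achievable growth rate.

#' Generator configuration
#'
#' Defaults define the study conditions used throughout the test-suite:
#' 20 pathway modules of 6 reactions, 5 withheld gap reactions, a handful
#' of each defect category, full annotation coverage, and five commercial
#' varieties whose compositions are small perturbations of a common base.
#'
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical output files.
#' @param n_pathways number of chain modules.
#' @param reactions_per_pathway chain length per module (>= 5 when defects
#'   are planted).
#' @param n_compounds extra unused decoy compounds.
#' @param planted_gaps withheld gap reactions (<= floor(n_pathways/2)).
#' @param planted_unbalanced,planted_chiral_pairs,planted_generic,planted_step_chains,planted_symbolic,planted_incomplete,planted_missing_metadata
#'   counts of each planted defect.
#' @param planted_blocked_single,planted_blocked_triple,planted_blocked_reversed
#'   0 or 1: plant the corresponding blocked-precursor lesion.
#' @param annotation_coverage fraction of plain chain reactions annotated
#'   with genes (planted structures are always annotated; gap and lesion
#'   reactions never are).
#' @param energy_yield ATP made per unit of energy substrate.
#' @param maintenance_coefficient mmol ATP (etc.) per gDW of biomass.
#' @param varieties data.frame with columns `name`, `perturbation`
#'   (relative scale of composition noise), `moisture` (water mass
#'   fraction).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_pathways = 20L,
                             reactions_per_pathway = 6L,
                             n_compounds = 0L,
                             planted_gaps = 5L,
                             planted_unbalanced = 4L,
                             planted_chiral_pairs = 3L,
                             planted_generic = 3L,
                             planted_step_chains = 3L,
                             planted_symbolic = 2L,
                             planted_incomplete = 2L,
                             planted_missing_metadata = 5L,
                             planted_blocked_single = 1L,
                             planted_blocked_triple = 1L,
                             planted_blocked_reversed = 1L,
                             annotation_coverage = 1.0,
                             energy_yield = 40L,
                             maintenance_coefficient = 29.8303,
                             varieties = NULL) {
  if (is.null(varieties)) {
    varieties <- data.frame(
      name = paste0("variety_", 1:5),
      perturbation = c(0, 0.05, 0.1, 0.15, 0.2),
      moisture = c(0.75, 0.76, 0.74, 0.77, 0.75))
  }
  cfg <- list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
              reactions_per_pathway = as.integer(reactions_per_pathway),
              n_compounds = as.integer(n_compounds),
              planted_gaps = as.integer(planted_gaps),
              planted_unbalanced = as.integer(planted_unbalanced),
              planted_chiral_pairs = as.integer(planted_chiral_pairs),
              planted_generic = as.integer(planted_generic),
              planted_step_chains = as.integer(planted_step_chains),
              planted_symbolic = as.integer(planted_symbolic),
              planted_incomplete = as.integer(planted_incomplete),
              planted_missing_metadata = as.integer(planted_missing_metadata),
              planted_blocked_single = as.integer(planted_blocked_single),
              planted_blocked_triple = as.integer(planted_blocked_triple),
              planted_blocked_reversed = as.integer(planted_blocked_reversed),
              annotation_coverage = annotation_coverage,
              energy_yield = as.integer(energy_yield),
              maintenance_coefficient = maintenance_coefficient,
              varieties = varieties)
  counts <- cfg[grep("^(n_|planted_)", names(cfg))]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (annotation_coverage <= 0 || annotation_coverage > 1) {
    stop("annotation_coverage must be in (0, 1]")
  }
  if (cfg$planted_gaps > cfg$n_pathways %/% 2L) {
    stop("more planted gaps (", cfg$planted_gaps,
         ") than disjoint pathway pairs (", cfg$n_pathways %/% 2L, ")")
  }
  has_defects <- any(unlist(cfg[grep("^planted_", names(cfg))]) > 0)
  if (has_defects && cfg$reactions_per_pathway < 5L) {
    stop("reactions_per_pathway must be >= 5 to host planted defects")
  }
  if (any(cfg$varieties$moisture < 0 | cfg$varieties$moisture >= 1)) {
    stop("moisture fractions must be in [0, 1)")
  }
  structure(cfg, class = "generator_config")
}

# currency / cofactor compounds shared with the packaged currency list
.currency_compound_rows <- function() {
  data.frame(
    compound_id = c("C00001", "C00002", "C00008", "C00009", "C00080",
                    "C05359", "C01438", "C06547", "C00011", "C00007",
                    "C00003", "C00004", "C00005", "C00006"),
    name = c("H2O", "ATP", "ADP", "Orthophosphate", "H+",
             "e-", "CH4", "Ethylene", "CO2", "O2",
             "NAD+", "NADH", "NADPH", "NADP+"),
    formula = c("H2O", "C10H16N5O13P3", "C10H15N5O10P2", "H3O4P", "H",
                ".", "CH4", "C2H4", "CO2", "O2",
                "C21H27N7O14P2", "C21H28N7O14P2", "C21H30N7O17P3",
                "C21H29N7O17P3"),
    charge = c(0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 0, 0, 0, 0),
    aliases = "",
    stringsAsFactors = FALSE)
}

# the full deterministic build; every public generator entry point calls
# this so the emitted pieces are mutually consistent for a given config
.generate_all <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  P <- config$n_pathways
  L <- config$reactions_per_pathway

  cpd <- .currency_compound_rows()
  add_cpd <- function(id, name, formula, charge = 0, aliases = "") {
    cpd <<- rbind(cpd, data.frame(compound_id = id, name = name,
                                  formula = formula, charge = charge,
                                  aliases = aliases, stringsAsFactors = FALSE))
  }
  rxn <- data.frame(reaction_id = character(0), equation = character(0),
                    direction = character(0), ec_numbers = character(0),
                    main_reaction_id = character(0), pathways = character(0),
                    subsystem = character(0), flags = character(0),
                    stringsAsFactors = FALSE)
  add_rxn <- function(id, equation, ec = "", pathways = "", subsystem = "",
                      direction = "", main = "", flags = "") {
    rxn <<- rbind(rxn, data.frame(reaction_id = id, equation = equation,
                                  direction = direction, ec_numbers = ec,
                                  main_reaction_id = main,
                                  pathways = pathways, subsystem = subsystem,
                                  flags = flags, stringsAsFactors = FALSE))
  }
  annotated <- character(0) # reaction ids that receive gene annotation

  # ---- pathway modules ----------------------------------------------
  pwy <- sprintf("pwy%02d", seq_len(P))
  subsystems <- sprintf("subsystem_%d", (seq_len(P) - 1L) %% 3L + 1L)
  xid <- function(p, i) sprintf("CM%02d%02d", p, i)
  rid_chain <- function(p, i) sprintf("RM%02d%02d", p, i)
  for (p in seq_len(P)) {
    for (i in 0:L) add_cpd(xid(p, i), sprintf("module %d metabolite %d", p, i),
                           "C6H12O6")
    for (i in seq_len(L)) {
      add_rxn(rid_chain(p, i),
              paste(xid(p, i - 1L), "<=>", xid(p, i)),
              ec = sprintf("1.1.%d.%d", p, i),
              pathways = pwy[p], subsystem = subsystems[p],
              main = rid_chain(p, i))
      annotated <- c(annotated, rid_chain(p, i))
    }
  }

  # ---- withheld gap reactions ---------------------------------------
  gap_ids <- character(0); gap_scale <- character(0)
  if (config$planted_gaps > 0) {
    for (k in seq_len(config$planted_gaps)) {
      a <- 2L * k - 1L; b <- 2L * k
      id <- sprintf("RGAP%02d", k)
      on_pathway <- k %% 2L == 1L
      add_rxn(id, paste(xid(a, L), "<=>", xid(b, 0L)),
              pathways = if (on_pathway) paste(pwy[a], pwy[b], sep = ";")
                else "",
              subsystem = if (on_pathway) subsystems[a] else "")
      gap_ids <- c(gap_ids, id)
      gap_scale <- c(gap_scale, if (on_pathway) "pathway" else "global")
    }
  }

  slot_module <- function(j) (j - 1L) %% P + 1L

  # ---- unbalanced reactions (missing H2O or H+) ---------------------
  unbalanced <- list()
  for (j in seq_len(config$planted_unbalanced)) {
    p <- slot_module(j)
    id <- sprintf("RUNB%02d", j)
    cidp <- sprintf("CUNB%02d", j)
    if (j %% 2L == 1L) { # dehydrated product: right side short one water
      add_cpd(cidp, sprintf("dehydrated product %d", j), "C6H10O5")
      fix <- c(C00001 = 1)
    } else {             # deprotonated product: short one proton
      add_cpd(cidp, sprintf("deprotonated product %d", j), "C6H11O6",
              charge = -1)
      fix <- c(C00080 = 1)
    }
    add_rxn(id, paste(xid(p, 2L), "<=>", cidp),
            ec = sprintf("2.1.%d.1", j), pathways = pwy[p],
            subsystem = subsystems[p])
    annotated <- c(annotated, id)
    unbalanced[[id]] <- fix
  }

  # ---- chiral alias pairs -> duplicate reactions --------------------
  chiral_aliases <- character(0)
  chiral_dup_ids <- character(0)
  for (j in seq_len(config$planted_chiral_pairs)) {
    p <- slot_module(j + 1L)
    canon <- sprintf("CCHA%02d", j)
    alias <- sprintf("CCHD%02d", j)
    add_cpd(canon, sprintf("alpha form %d", j), "C6H12O6", aliases = alias)
    add_cpd(alias, sprintf("open form %d", j), "C6H12O6", aliases = canon)
    ida <- sprintf("RCHA%02d", j)
    idd <- sprintf("RCHD%02d", j)
    add_rxn(ida, paste(xid(p, 1L), "<=>", canon),
            ec = sprintf("2.2.%d.1", j), pathways = pwy[p],
            subsystem = subsystems[p])
    add_rxn(idd, paste(xid(p, 1L), "<=>", alias),
            ec = sprintf("2.2.%d.2", j), pathways = pwy[p],
            subsystem = subsystems[p])
    annotated <- c(annotated, ida, idd)
    chiral_aliases[alias] <- canon
    chiral_dup_ids <- c(chiral_dup_ids, idd)
  }

  # ---- step chains shadowing a total reaction -----------------------
  step_ids <- character(0)
  for (j in seq_len(config$planted_step_chains)) {
    p <- slot_module(j + 2L)
    b <- sprintf("CSTP%02d", j)
    add_cpd(b, sprintf("step intermediate %d", j), "C6H12O6")
    ids <- c(sprintf("RSTA%02d", j), sprintf("RSTB%02d", j))
    add_rxn(ids[1], paste(xid(p, 4L), "<=>", b),
            ec = sprintf("2.3.%d.1", j), pathways = pwy[p],
            subsystem = subsystems[p])
    add_rxn(ids[2], paste(b, "<=>", xid(p, 5L)),
            ec = sprintf("2.3.%d.2", j), pathways = pwy[p],
            subsystem = subsystems[p])
    annotated <- c(annotated, ids)
    step_ids <- c(step_ids, ids)
  }

  # ---- generic / symbolic / incomplete ------------------------------
  generic_ids <- character(0)
  for (j in seq_len(config$planted_generic)) {
    p <- slot_module(j + 3L)
    g <- sprintf("CGEN%02d", j)
    add_cpd(g, sprintf("a sugar (class) %d", j), "") # class compound, no formula
    id <- sprintf("RGEN%02d", j)
    add_rxn(id, paste(g, "<=>", xid(p, 3L)),
            ec = sprintf("2.4.%d.1", j), pathways = pwy[p],
            subsystem = subsystems[p], flags = "generic")
    annotated <- c(annotated, id)
    generic_ids <- c(generic_ids, id)
  }
  symbolic_ids <- character(0)
  for (j in seq_len(config$planted_symbolic)) {
    p <- slot_module(j + 4L)
    id <- sprintf("RSYM%02d", j)
    add_rxn(id, paste("n", xid(p, 1L), "<=>", "n", xid(p, 2L)),
            ec = sprintf("2.5.%d.1", j), pathways = pwy[p],
            subsystem = subsystems[p])
    annotated <- c(annotated, id)
    symbolic_ids <- c(symbolic_ids, id)
  }
  incomplete_ids <- character(0)
  for (j in seq_len(config$planted_incomplete)) {
    p <- slot_module(j + 5L)
    id <- sprintf("RINC%02d", j)
    add_rxn(id, paste(xid(p, 5L), "<=>"),
            ec = sprintf("2.6.%d.1", j), pathways = pwy[p],
            subsystem = subsystems[p])
    annotated <- c(annotated, id)
    incomplete_ids <- c(incomplete_ids, id)
  }

  # ---- reactions with withheld metadata -----------------------------
  meta_ids <- character(0)
  for (j in seq_len(config$planted_missing_metadata)) {
    p <- slot_module(j)
    id <- rid_chain(p, 3L)
    k <- rxn$reaction_id == id
    rxn$pathways[k] <- ""
    rxn$subsystem[k] <- ""
    rxn$main_reaction_id[k] <- ""
    meta_ids <- c(meta_ids, id)
  }

  # ---- core scaffold: precursors, energy, blocked routes ------------
  amino_formula <- "C3H7NO2"   # alanine-like
  glut_formula <- "C5H9NO4"    # glutamate-like
  n_pre <- 6L
  pre_ids <- sprintf("CPRE%02d", seq_len(n_pre))
  for (i in seq_len(n_pre)) {
    add_cpd(pre_ids[i], sprintf("feed precursor %d", i), amino_formula)
  }
  add_cpd("CMIN01", "mineral (magnesium-like)", "Mg")
  add_cpd("CNRG00", "energy substrate", "C6H12O6")
  add_cpd("CFUEL0", "spent energy carrier", "C6H12O6")
  ey <- config$energy_yield
  add_rxn("RNRG01",
          paste0("CNRG00 + ", ey, " C00008 + ", ey, " C00009 => ",
                 ey, " C00002 + ", ey, " C00001 + CFUEL0"),
          ec = "3.2.1.1")
  annotated <- c(annotated, "RNRG01")

  blocked <- list()
  synth_targets <- character(0)
  if (config$planted_blocked_single > 0) {
    add_cpd("CSUBS1", "substrate of route 1", glut_formula)
    add_cpd("CINTR1", "intermediate of route 1", glut_formula)
    add_cpd("CGLUT1", "synthesizable precursor 1", glut_formula)
    add_rxn("RCOR1A", "CSUBS1 <=> CINTR1", ec = "3.1.1.1")
    add_rxn("RCOR1B", "CINTR1 <=> CGLUT1") # withheld: the planted lesion
    annotated <- c(annotated, "RCOR1A")
    blocked[["CGLUT1"]] <- list(kind = "single",
                                repair = list(list(type = "add",
                                                   id = "RCOR1B")))
    synth_targets <- c(synth_targets, "CGLUT1")
  }
  if (config$planted_blocked_triple > 0) {
    add_cpd("CSUBS2", "substrate of route 2", glut_formula)
    for (s in c("CINT2A", "CINT2B", "CINT2C")) {
      add_cpd(s, paste("intermediate", s), glut_formula)
    }
    add_cpd("CGLUT2", "synthesizable precursor 2", glut_formula)
    add_rxn("RCOR2A", "CSUBS2 <=> CINT2A", ec = "3.3.1.1")
    add_rxn("RCOR2B", "CINT2A <=> CINT2B") # withheld
    add_rxn("RCOR2C", "CINT2B <=> CINT2C") # withheld
    add_rxn("RCOR2D", "CINT2C <=> CGLUT2") # withheld
    annotated <- c(annotated, "RCOR2A")
    blocked[["CGLUT2"]] <- list(kind = "triple",
                                repair = list(
                                  list(type = "add", id = "RCOR2B"),
                                  list(type = "add", id = "RCOR2C"),
                                  list(type = "add", id = "RCOR2D")))
    synth_targets <- c(synth_targets, "CGLUT2")
  }
  if (config$planted_blocked_reversed > 0) {
    add_cpd("CSUBS3", "substrate of route 3", glut_formula)
    add_cpd("CINTR3", "intermediate of route 3", glut_formula)
    add_cpd("CGLUT3", "synthesizable precursor 3", glut_formula)
    add_rxn("RCOR3A", "CSUBS3 <=> CINTR3", ec = "3.4.1.1")
    # annotated but written in the wrong (consuming) direction
    add_rxn("RCOR3B", "CGLUT3 => CINTR3", ec = "3.4.1.2")
    annotated <- c(annotated, "RCOR3A", "RCOR3B")
    blocked[["CGLUT3"]] <- list(kind = "reversed",
                                repair = list(list(type = "reverse",
                                                   id = "RCOR3B")))
    synth_targets <- c(synth_targets, "CGLUT3")
  }

  # decoy compounds
  if (config$n_compounds > 0) {
    for (j in seq_len(config$n_compounds)) {
      add_cpd(sprintf("CXTR%03d", j), sprintf("decoy %d", j),
              sprintf("C%dH%dO%d", 2 + j %% 5, 4 + 2 * (j %% 5), 2 + j %% 3))
    }
  }

  # ---- gene annotations ---------------------------------------------
  annotated <- unique(annotated)
  # plain chain reactions may be dropped to emulate partial annotation;
  # the AND/OR showcase reactions and all planted structures stay
  showcase <- c(rid_chain(1L, 1L), rid_chain(1L, 2L))
  plain <- setdiff(grep("^RM", annotated, value = TRUE), showcase)
  if (config$annotation_coverage < 1) {
    keep <- plain[stats::runif(length(plain)) < config$annotation_coverage]
    annotated <- setdiff(annotated, setdiff(plain, keep))
  }
  rxn_ec <- stats::setNames(rxn$ec_numbers, rxn$reaction_id)
  genes <- data.frame(gene_id = character(0), ec_number = character(0),
                      stringsAsFactors = FALSE)
  enzyme_links <- data.frame(ec_number = character(0),
                             reaction_id = character(0),
                             stringsAsFactors = FALSE)
  gcount <- 0L
  next_gene <- function() {
    gcount <<- gcount + 1L
    sprintf("syn:g%04d", gcount)
  }
  for (id in sort(annotated)) {
    ecs <- .split_multi(rxn_ec[[id]])
    if (length(ecs) == 0L) next
    for (ec in ecs) {
      enzyme_links <- rbind(enzyme_links,
                            data.frame(ec_number = ec, reaction_id = id,
                                       stringsAsFactors = FALSE))
      n_genes <- if (id == showcase[1] && ec == ecs[1]) 2L else 1L # AND case
      for (g in seq_len(n_genes)) {
        genes <- rbind(genes, data.frame(gene_id = next_gene(),
                                         ec_number = ec,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  # OR case: a second enzyme reaching the second showcase reaction
  if (showcase[2] %in% annotated) {
    or_ec <- "7.1.1.1"
    enzyme_links <- rbind(enzyme_links,
                          data.frame(ec_number = or_ec,
                                     reaction_id = showcase[2],
                                     stringsAsFactors = FALSE))
    genes <- rbind(genes, data.frame(gene_id = next_gene(),
                                     ec_number = or_ec,
                                     stringsAsFactors = FALSE))
  }

  # ---- compositions and achievable growth ---------------------------
  mw <- function(f) formula_weight(parse_formula(f))
  base_coef <- c(stats::setNames(
    c(1.8, 0.45, 0.3, 0.5, 0.35, 0.6), pre_ids),
    stats::setNames(rep(0.4, length(synth_targets)), synth_targets),
    CMIN01 = 0.05)
  cpd_formula <- stats::setNames(cpd$formula, cpd$compound_id)
  comp_rows <- data.frame(variety = character(0), compound_id = character(0),
                          content = character(0), unit = character(0),
                          stringsAsFactors = FALSE)
  vdf <- config$varieties
  growth <- numeric(nrow(vdf))
  coef_by_variety <- list()
  for (v in seq_len(nrow(vdf))) {
    noise <- stats::runif(length(base_coef), -1, 1) * vdf$perturbation[v]
    coefs <- base_coef * (1 + noise)
    coef_by_variety[[vdf$name[v]]] <- coefs
    moist <- vdf$moisture[v]
    for (cid in names(coefs)) {
      m <- mw(cpd_formula[[cid]])
      if (cid == "CMIN01") { # trace element measured in mg/kg
        content <- coefs[[cid]] * 1000 * m * (1 - moist)
        unit <- "mg/kg"
      } else {
        content <- coefs[[cid]] * m * (1 - moist) / 10
        unit <- "g/100g"
      }
      comp_rows <- rbind(comp_rows, data.frame(
        variety = vdf$name[v], compound_id = cid,
        content = format(content, digits = 17), unit = unit,
        stringsAsFactors = FALSE))
    }
    comp_rows <- rbind(comp_rows, data.frame(
      variety = vdf$name[v], compound_id = "MOISTURE",
      content = format(moist, digits = 17), unit = "fraction",
      stringsAsFactors = FALSE))
    # closed-form bottleneck: each route is an independent chain, so the
    # growth maximum is the tightest uptake-capacity / coefficient ratio
    caps <- c(5 / coefs[c(pre_ids, synth_targets)],
              1 / coefs[["CMIN01"]],
              5 * config$energy_yield / config$maintenance_coefficient)
    growth[v] <- min(caps)
  }

  # ---- sidecar tables -----------------------------------------------
  nutrient_classes <- rbind(
    data.frame(class = "feed_nutrient",
               compound_id = c(pre_ids, "CNRG00",
                               intersect(c("CSUBS1", "CSUBS2", "CSUBS3"),
                                         cpd$compound_id)),
               stringsAsFactors = FALSE),
    data.frame(class = "synthesizable",
               compound_id = c(synth_targets, "CFUEL0", "C00001", "C00080"),
               stringsAsFactors = FALSE),
    data.frame(class = "trace_element", compound_id = "CMIN01",
               stringsAsFactors = FALSE))
  pathways_tbl <- data.frame(pathway_id = pwy, subsystem = subsystems,
                             stringsAsFactors = FALSE)
  alias_tbl <- data.frame(alias_id = names(chiral_aliases),
                          canonical_id = unname(chiral_aliases),
                          stringsAsFactors = FALSE)

  full_cov <- config$annotation_coverage == 1
  # each blocked route leaves one annotated fragment (its own component),
  # and the energy reaction forms one more (its cofactors are currency)
  n_core_components <- sum(config$planted_blocked_single > 0,
                           config$planted_blocked_triple > 0,
                           config$planted_blocked_reversed > 0) + 1L
  wcc_before <- if (full_cov) P + n_core_components else NA_integer_

  ground_truth <- list(
    config = config,
    gap_reactions = data.frame(reaction_id = gap_ids, scale = gap_scale,
                               stringsAsFactors = FALSE),
    unbalanced = unbalanced,
    chiral_aliases = chiral_aliases,
    removable = list(step = sort(step_ids),
                     generic = sort(generic_ids),
                     incomplete_or_symbolic = sort(c(symbolic_ids,
                                                     incomplete_ids)),
                     chiral_duplicate = sort(chiral_dup_ids)),
    metadata_missing = sort(meta_ids),
    blocked = blocked,
    synthesizable_targets = synth_targets,
    wcc_before = wcc_before,
    wcc_after = if (full_cov) wcc_before - config$planted_gaps else
      NA_integer_,
    varieties = data.frame(name = vdf$name, moisture = vdf$moisture,
                           growth = growth, stringsAsFactors = FALSE),
    biomass_coefficients = coef_by_variety,
    annotated_reactions = sort(annotated))

  list(compounds = cpd, reactions = rxn, pathways = pathways_tbl,
       enzyme_links = enzyme_links, genes = genes,
       compositions = comp_rows, nutrient_classes = nutrient_classes,
       alias_policy = alias_tbl, ground_truth = ground_truth)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Generate a synthetic universe (flat files plus ground truth)
#'
#' Writes `compounds.tsv`, `reactions.tsv`, `pathways.tsv`, `enzymes.tsv`
#' and the sidecar `alias_policy.tsv` to `out_dir` in the dialect
#' [parse_universe()] reads.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `files` (named paths) and `ground_truth`.
#' @export
generate_universe <- function(config, out_dir) {
  gen <- .generate_all(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    compounds = .write_tsv(gen$compounds, file.path(out_dir, "compounds.tsv")),
    reactions = .write_tsv(gen$reactions, file.path(out_dir, "reactions.tsv")),
    pathways = .write_tsv(gen$pathways, file.path(out_dir, "pathways.tsv")),
    enzymes = .write_tsv(gen$enzyme_links, file.path(out_dir, "enzymes.tsv")),
    alias_policy = .write_tsv(gen$alias_policy,
                              file.path(out_dir, "alias_policy.tsv")))
  list(files = files, ground_truth = gen$ground_truth)
}

#' Generate the gene annotation table for a synthetic universe
#'
#' @inheritParams generate_universe
#' @return path of the written `genes.tsv`.
#' @export
generate_annotations <- function(config, out_dir) {
  gen <- .generate_all(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(gen$genes, file.path(out_dir, "genes.tsv"))
}

#' Generate per-variety composition tables
#'
#' Writes `compositions.tsv` (all varieties, with MOISTURE sidecar rows)
#' and returns the analytically known achievable growth rate per variety.
#'
#' @inheritParams generate_universe
#' @return list with `file` and `growth` (data.frame name/moisture/growth).
#' @export
generate_compositions <- function(config, out_dir) {
  gen <- .generate_all(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  file <- .write_tsv(gen$compositions, file.path(out_dir, "compositions.tsv"))
  list(file = file, growth = gen$ground_truth$varieties)
}

#' Generate the complete synthetic dataset
#'
#' Universe flat files, gene annotations, composition tables, nutrient
#' class and currency sidecars — everything [run_pipeline()] consumes.
#'
#' @inheritParams generate_universe
#' @return list with `files` (named paths) and `ground_truth`.
#' @export
generate_dataset <- function(config, out_dir) {
  gen <- .generate_all(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    compounds = .write_tsv(gen$compounds, file.path(out_dir, "compounds.tsv")),
    reactions = .write_tsv(gen$reactions, file.path(out_dir, "reactions.tsv")),
    pathways = .write_tsv(gen$pathways, file.path(out_dir, "pathways.tsv")),
    enzymes = .write_tsv(gen$enzyme_links, file.path(out_dir, "enzymes.tsv")),
    genes = .write_tsv(gen$genes, file.path(out_dir, "genes.tsv")),
    compositions = .write_tsv(gen$compositions,
                              file.path(out_dir, "compositions.tsv")),
    nutrient_classes = .write_tsv(gen$nutrient_classes,
                                  file.path(out_dir, "nutrient_classes.tsv")),
    alias_policy = .write_tsv(gen$alias_policy,
                              file.path(out_dir, "alias_policy.tsv")),
    currency = .write_tsv(
      data.frame(compound_id = default_currency_metabolites(),
                 stringsAsFactors = FALSE),
      file.path(out_dir, "currency.tsv")))
  list(files = files, ground_truth = gen$ground_truth)
}
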