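# End-to-end reconstruction pipeline, mirroring the five-phase protocol:
# draft reconstruction, refinement of the network (balancing, chirality,
# redundancy removal, metadata, gap filling, boundary reactions),
# biomass addition, conversion to the mathematical model, and evaluation
# (precursor repair, per-variety growth, nutrient requirements).

#' Pipeline configuration
#'
#' Collects every input path and tunable constant of a reconstruction run.
#' All referenced files must exist at validation time; defaults equal the
#' standard constants (bounds policy, maintenance coefficient 29.8303).
#'
#' @param input_dir directory holding the flat files (as written by
#'   [generate_dataset()]); individual paths can be overridden.
#' @param compounds,reactions,pathways,enzymes,genes,compositions,nutrient_classes,alias_policy,currency
#'   file paths, defaulting to `<input_dir>/<name>.tsv`.
#' @param out_dir output directory.
#' @param policy a [bounds_policy()].
#' @param maintenance_coefficient mmol/gDW maintenance term.
#' @param include_nadph include NADPH in the maintenance set?
#' @param biomass_flux growth rate fixed for requirement profiling (1/h).
#' @param max_additions,search_depth repair-search caps, see
#'   [diagnose_and_repair()].
#' @param skip stages to skip: any of `"gapfill"`, `"evaluation"`,
#'   `"simulation"` (recorded as skipped in the report, for auditability).
#' @param seed integer seed recorded in the report and set before the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir,
                            compounds = file.path(input_dir, "compounds.tsv"),
                            reactions = file.path(input_dir, "reactions.tsv"),
                            pathways = file.path(input_dir, "pathways.tsv"),
                            enzymes = file.path(input_dir, "enzymes.tsv"),
                            genes = file.path(input_dir, "genes.tsv"),
                            compositions = file.path(input_dir,
                                                     "compositions.tsv"),
                            nutrient_classes = file.path(
                              input_dir, "nutrient_classes.tsv"),
                            alias_policy = file.path(input_dir,
                                                     "alias_policy.tsv"),
                            currency = file.path(input_dir, "currency.tsv"),
                            out_dir = file.path(input_dir, "out"),
                            policy = bounds_policy(),
                            maintenance_coefficient = 29.8303,
                            include_nadph = FALSE,
                            biomass_flux = 1,
                            max_additions = 3L,
                            search_depth = 4L,
                            skip = character(0),
                            seed = 1L) {
  cfg <- list(files = list(compounds = compounds, reactions = reactions,
                           pathways = pathways, enzymes = enzymes,
                           genes = genes, compositions = compositions,
                           nutrient_classes = nutrient_classes,
                           alias_policy = alias_policy, currency = currency),
              out_dir = out_dir, policy = policy,
              maintenance_coefficient = maintenance_coefficient,
              include_nadph = include_nadph,
              biomass_flux = biomass_flux,
              max_additions = as.integer(max_additions),
              search_depth = as.integer(search_depth),
              skip = skip, seed = as.integer(seed))
  bad <- setdiff(skip, c("gapfill", "evaluation", "simulation"))
  if (length(bad)) stop("cannot skip stage(s): ", paste(bad, collapse = ", "))
  missing <- Filter(function(p) !file.exists(p), unlist(cfg$files))
  if (length(missing)) {
    stop("pipeline input file(s) not found:\n  ",
         paste(missing, collapse = "\n  "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML maps the arguments of [pipeline_config()]; relative paths
#' resolve against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  args <- list()
  for (k in c("compounds", "reactions", "pathways", "enzymes", "genes",
              "compositions", "nutrient_classes", "alias_policy",
              "currency", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- resolve(y[[k]])
  }
  if (!is.null(y$input_dir)) args$input_dir <- resolve(y$input_dir)
  for (k in c("maintenance_coefficient", "include_nadph", "biomass_flux",
              "max_additions", "search_depth", "skip", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

.read_class_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  lapply(split(df$compound_id, df$class), function(v) sort(unique(v)))
}

#' Run the full reconstruction and simulation pipeline
#'
#' Executes: draft reconstruction; refinement (balancing, chiral
#' standardization, redundancy removal, metadata supplementation); gap
#' filling; boundary (compartments, transport/exchange, bounds policy);
#' biomass addition per variety; evaluation (blocked-precursor repair and
#' per-variety growth); simulation (nutrient requirement profiles at fixed
#' growth). Writes the final model (JSON and SBML), per-variety requirement
#' profiles and a JSON run report with content hashes of all inputs and
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `pipeline_report` (invisibly also written to
#'   `<out_dir>/reports/pipeline_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(config$out_dir, "reports"), showWarnings = FALSE)
  stages <- list()
  t_stage <- function(name, skipped, counts) {
    stages[[length(stages) + 1L]] <<- c(list(stage = name,
                                             status = if (skipped) "skipped"
                                               else "completed"), counts)
  }

  # ---- draft reconstruction -----------------------------------------
  t0 <- proc.time()[3]
  universe <- parse_universe(config$files$compounds, config$files$reactions,
                             config$files$pathways, config$files$enzymes)
  annotations <- parse_annotations(config$files$genes)
  draft <- assemble_draft(universe, annotations)
  s <- summary(draft)
  t_stage("draft_reconstruction", FALSE,
          list(duration = round(proc.time()[3] - t0, 2),
               genes = s$genes, enzymes = s$enzymes, reactions = s$reactions,
               pathways = s$pathways, subsystems = s$subsystems))

  # ---- refinement ----------------------------------------------------
  t0 <- proc.time()[3]
  alias_df <- utils::read.delim(config$files$alias_policy,
                                colClasses = "character")
  alias_policy <- stats::setNames(alias_df$canonical_id, alias_df$alias_id)
  ref <- refine_network(draft, universe, alias_policy)
  network <- ref$network
  t_stage("refinement", FALSE,
          list(duration = round(proc.time()[3] - t0, 2),
               balanced = ref$report$balanced_count,
               chirality_modified = ref$report$modified_chirality_count,
               removed = lapply(ref$report$removed, length),
               metadata_supplemented = ref$report$metadata_supplemented_count,
               reactions = length(network$reactions)))

  # ---- gap filling ---------------------------------------------------
  currency <- utils::read.delim(config$files$currency,
                                colClasses = "character")$compound_id
  gap_report <- NULL
  if ("gapfill" %in% config$skip) {
    t_stage("gap_filling", TRUE, list())
  } else {
    t0 <- proc.time()[3]
    gf <- fill_gaps(network, universe, currency_excluded = currency)
    network <- gf$network
    gap_report <- gf$report
    t_stage("gap_filling", FALSE,
            list(duration = round(proc.time()[3] - t0, 2),
                 wcc_before = gf$report$wcc_before,
                 wcc_after = gf$report$wcc_after,
                 added_pathway = sum(gf$report$added$scale == "pathway"),
                 added_global = sum(gf$report$added$scale == "global")))
  }

  # ---- boundary reactions & model conversion -------------------------
  t0 <- proc.time()[3]
  classes <- .read_class_table(config$files$nutrient_classes)
  model <- network_to_model(network, id = "reconstruction")
  model <- add_boundary_reactions(model, classes)
  model <- apply_bounds_policy(model, config$policy,
                               synthesizable = classes$synthesizable,
                               trace_elements = classes$trace_element)
  validate_model(model)
  system <- build_matrix(model)
  t_stage("model_conversion", FALSE,
          list(duration = round(proc.time()[3] - t0, 2),
               reactions = length(model$reactions),
               metabolites = length(model$metabolites),
               transport = sum(startsWith(names(model$reactions), "TR_")),
               exchange = sum(startsWith(names(model$reactions), "EX_")),
               matrix_rows = nrow(system$S), matrix_cols = ncol(system$S),
               matrix_nonzeros = Matrix::nnzero(system$S)))

  # ---- biomass addition ----------------------------------------------
  t0 <- proc.time()[3]
  comp_all <- utils::read.delim(config$files$compositions,
                                colClasses = "character")
  varieties <- unique(comp_all$variety)
  molar_masses <- vapply(universe$compounds, function(c)
    tryCatch(formula_weight(c$formula), error = function(e) NA_real_),
    numeric(1))
  molar_masses <- molar_masses[!is.na(molar_masses) & molar_masses > 0]
  equations <- list()
  for (v in varieties) {
    comp <- read_composition_table(config$files$compositions, v)
    equations[[v]] <- build_biomass_equation(
      comp, molar_masses,
      maintenance_coefficient = config$maintenance_coefficient,
      include_nadph = config$include_nadph)
  }
  t_stage("biomass_addition", FALSE,
          list(duration = round(proc.time()[3] - t0, 2),
               varieties = length(varieties),
               precursors = length(
                 equations[[1]]$precursor_coefficients)))

  # ---- evaluation: precursor repair + per-variety growth -------------
  repair_report <- NULL
  growth <- stats::setNames(rep(NA_real_, length(varieties)), varieties)
  if ("evaluation" %in% config$skip) {
    t_stage("evaluation", TRUE, list())
  } else {
    t0 <- proc.time()[3]
    targets <- intersect(
      unique(unlist(lapply(equations, function(e)
        names(e$precursor_coefficients)))),
      classes$synthesizable)
    rep_res <- diagnose_and_repair(model, targets, universe,
                                   max_additions = config$max_additions,
                                   search_depth = config$search_depth)
    model <- rep_res$model
    repair_report <- rep_res$report
    for (v in varieties) {
      growth[v] <- max_growth(add_biomass_reaction(model, equations[[v]]))
    }
    t_stage("evaluation", FALSE,
            list(duration = round(proc.time()[3] - t0, 2),
                 targets = length(targets),
                 repaired = sum(vapply(repair_report, function(e)
                   e$status == "repaired", logical(1))),
                 unrepaired = sum(vapply(repair_report, function(e)
                   e$status == "unrepaired", logical(1))),
                 growth = as.list(round(growth, 6))))
  }

  # ---- simulation: nutrient requirements -----------------------------
  profiles <- list()
  if ("simulation" %in% config$skip) {
    t_stage("simulation", TRUE, list())
  } else {
    t0 <- proc.time()[3]
    for (v in varieties) {
      mv <- add_biomass_reaction(model, equations[[v]])
      profiles[[v]] <- nutrient_requirements(mv, config$biomass_flux)
      utils::write.table(profiles[[v]]$profile,
                         file.path(config$out_dir,
                                   paste0("profile_", v, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    t_stage("simulation", FALSE,
            list(duration = round(proc.time()[3] - t0, 2),
                 biomass_flux = config$biomass_flux,
                 varieties = length(profiles)))
  }

  # ---- artifacts and provenance --------------------------------------
  final <- add_biomass_reaction(model, equations[[1]])
  write_model(final, file.path(config$out_dir, "model.json"), "json")
  write_model(final, file.path(config$out_dir, "model.sbml"), "sbml")
  outputs <- c(file.path(config$out_dir, c("model.json", "model.sbml")),
               if (length(profiles))
                 file.path(config$out_dir,
                           paste0("profile_", names(profiles), ".tsv")))
  hashes <- list(
    inputs = as.list(tools::md5sum(unlist(config$files))),
    outputs = as.list(tools::md5sum(outputs)))

  report <- structure(list(stages = stages,
                           growth = growth,
                           gap_report = gap_report,
                           repair_report = repair_report,
                           refinement_report = ref$report,
                           profiles = profiles,
                           model = final,
                           hashes = hashes,
                           seed = config$seed),
                      class = "pipeline_report")
  json <- list(seed = config$seed, stages = stages,
               growth = as.list(growth), hashes = hashes)
  jsonlite::write_json(json, file.path(config$out_dir, "reports",
                                       "pipeline_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ")\n", sep = "")
  for (s in x$stages) {
    cat(sprintf("  %-20s %s", s$stage, s$status))
    if (!is.null(s$duration)) cat(sprintf(" (%.1fs)", s$duration))
    cat("\n")
  }
  if (any(!is.na(x$growth))) {
    cat("Per-variety maximum growth rate (1/h):\n")
    for (v in names(x$growth)) {
      cat(sprintf("  %-12s %.4f\n", v, x$growth[[v]]))
    }
  }
  invisible(x)
}
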