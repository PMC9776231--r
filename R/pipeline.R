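# Config-driven pipeline tying the analysis stages together. The config is
# a plain named list (or a YAML file with the same fields); every stage
# writes one CSV into the output directory and a JSON manifest records
# inputs, parameters, seed and outcomes so a run can be reproduced exactly.

PIPELINE_STAGES <- c("rmsd", "rmsf", "ss", "contacts", "electrostatics",
                     "hbonds", "gauges", "populations")

#' Read a pipeline configuration file
#'
#' @param path YAML file mirroring the fields accepted by [run_pipeline()].
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("parse error: config must be a YAML mapping")
  as_pipeline_config(cfg)
}

#' Coerce a named list to a pipeline configuration
#'
#' Fields: `pdb` (multi-model PDB path), `energies` (energy-table path),
#' `output_dir`, `stages` (subset of rmsd, rmsf, ss, contacts,
#' electrostatics, hbonds, gauges, populations), `seed`, `frame_interval`
#' (ps), `selection` (`chain`, optional `first`/`last`, for rmsd/rmsf),
#' `group_a`/`group_b` (selection specs for the interaction maps),
#' `regions_a`/`regions_b` (lists of `region`/`chain`/`first`/`last` for the
#' contact rubric), `criteria` (overrides for [interaction_criteria()]),
#' `gauges` (`distances`/`angles` site lists for [gauge_spec()]),
#' `windows` (`initial`/`final`, each `[start, end]` ps; default the first
#' and last 5 ns of the trajectory, clipped to its span), and `population`
#' (`temperature`, `steps`).
#'
#' @param cfg named list.
#' @return the list, classed `pipeline_config`.
#' @export
as_pipeline_config <- function(cfg) {
  if (inherits(cfg, "pipeline_config")) return(cfg)
  defaults <- list(output_dir = "postmd_out", seed = 1L,
                   frame_interval = 10, stages = PIPELINE_STAGES)
  cfg <- utils::modifyList(defaults, cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks the configuration against the preconditions of [run_pipeline()]
#' without computing anything; an empty return means the pipeline can run.
#'
#' @param cfg a `pipeline_config` (or named list, or YAML path).
#' @return character vector of issues, each naming the offending field;
#'   empty when the config is valid.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_pipeline_config(cfg)
  cfg <- as_pipeline_config(cfg)
  issues <- character()
  say <- function(...) issues <<- c(issues, paste0(...))
  bad_stages <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad_stages))
    say("stages: unknown stage(s) ", paste(bad_stages, collapse = ", "))
  needs_pdb <- any(cfg$stages %in% setdiff(PIPELINE_STAGES, "populations"))
  if (needs_pdb) {
    if (is.null(cfg$pdb)) say("pdb: required by the structural stages")
    else if (!file.exists(cfg$pdb)) say("pdb: file not found: ", cfg$pdb)
  }
  if ("populations" %in% cfg$stages) {
    if (is.null(cfg$energies)) say("energies: required by stage populations")
    else if (!file.exists(cfg$energies))
      say("energies: file not found: ", cfg$energies)
    st <- cfg$population$steps
    if (!is.null(st) && st < 1) say("population.steps: must be >= 1")
    tp <- cfg$population$temperature
    if (!is.null(tp) && tp <= 0) say("population.temperature: must be positive")
  }
  crit_ok <- TRUE
  if (!is.null(cfg$criteria)) {
    res <- tryCatch(do.call(interaction_criteria, cfg$criteria),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) { say("criteria: ", res); crit_ok <- FALSE }
  }
  traj <- NULL
  if (needs_pdb && !is.null(cfg$pdb) && file.exists(cfg$pdb)) {
    traj <- tryCatch(suppressMessages(
      read_pdb(cfg$pdb, frame_interval = cfg$frame_interval)),
      error = function(e) { say("pdb: ", conditionMessage(e)); NULL })
  }
  if (!is.null(traj)) {
    span <- range(traj$times)
    for (w in intersect(names(cfg$windows), c("initial", "final"))) {
      win <- cfg$windows[[w]]
      if (length(win) != 2L || win[1] < 0 || win[1] >= win[2]) {
        say("windows.", w, ": need 0 <= start < end")
      } else if (win[1] > span[2] || win[2] < span[1]) {
        say("windows.", w, ": window [", win[1], ", ", win[2],
            "] ps lies outside the trajectory span [", span[1], ", ",
            span[2], "] ps")
      }
    }
    for (side in c("regions_a", "regions_b")) {
      for (r in cfg[[side]]) {
        ok <- tryCatch({
          atom_select(traj, r$chain, r$first, r$last); TRUE
        }, error = function(e) FALSE)
        if (!ok) say(side, ": region '", r$region,
                     "' is outside chain '", r$chain, "'")
      }
    }
    if ("gauges" %in% cfg$stages) {
      spec <- tryCatch(
        if (is.null(cfg$gauges)) ide_gauges()
        else gauge_spec(cfg$gauges$distances, cfg$gauges$angles),
        error = function(e) { say("gauges: ", conditionMessage(e)); NULL })
      if (!is.null(spec)) {
        ok <- tryCatch({ gauge_series_sites_exist(traj, spec); TRUE },
                       error = function(e) {
                         say("gauges: ", conditionMessage(e)); FALSE })
      }
    }
    for (side in c("selection", "group_a", "group_b")) {
      g <- cfg[[side]]
      if (!is.null(g)) {
        ok <- tryCatch({
          atom_select(traj, g$chain, g$first, g$last); TRUE
        }, error = function(e) FALSE)
        if (!ok) say(side, ": selection chain '", g$chain,
                     "' range not present in the trajectory")
      }
    }
  }
  issues
}

scheme_from_config <- function(entries) {
  region_scheme(vapply(entries, `[[`, "", "region"),
                vapply(entries, `[[`, "", "chain"),
                vapply(entries, function(r) as.integer(r$first), 0L),
                vapply(entries, function(r) as.integer(r$last), 0L))
}

default_windows <- function(traj, len = 5000) {
  span <- range(traj$times)
  w <- min(len, diff(span))
  list(initial = c(span[1], span[1] + w), final = c(span[2] - w, span[2]))
}

write_stage_csv <- function(df, dir, stage) {
  path <- file.path(dir, paste0(stage, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Validates the configuration (aborting before any computation if it is
#' invalid), executes the requested stages and writes one CSV per stage
#' plus a `manifest.json` recording inputs, parameters, seed, package
#' version and per-stage status. With a fixed seed the outputs are
#' byte-identical across runs. A stage failure stops the run with a
#' stage-named error; CSVs of completed stages are kept and the manifest
#' marks the failure.
#'
#' @param cfg a `pipeline_config`, named list, or YAML path.
#' @return invisibly, a list with `outputs` (stage CSV paths) and
#'   `manifest` (manifest path).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_pipeline_config(cfg)
  cfg <- as_pipeline_config(cfg)
  issues <- validate_config(cfg)
  if (length(issues))
    stop("invalid pipeline config:\n  ", paste(issues, collapse = "\n  "))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  criteria <- if (is.null(cfg$criteria)) interaction_criteria()
    else do.call(interaction_criteria, cfg$criteria)

  traj <- NULL
  if (any(cfg$stages != "populations"))
    traj <- suppressMessages(read_pdb(cfg$pdb,
                                      frame_interval = cfg$frame_interval))
  windows <- NULL
  if (!is.null(traj)) {
    windows <- default_windows(traj)
    for (w in intersect(names(cfg$windows), c("initial", "final")))
      windows[[w]] <- as.numeric(cfg$windows[[w]])
  }
  sel <- cfg$selection
  if (is.null(sel) && !is.null(traj))
    sel <- list(chain = traj$atoms$chain[1L])

  outputs <- list()
  status <- list()
  run_stage <- function(stage, fn) {
    if (!(stage %in% cfg$stages)) return()
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      status[[stage]] <<- paste("failed:", conditionMessage(res))
      write_manifest(cfg, outputs, status)
      stop("stage '", stage, "' failed: ", conditionMessage(res))
    }
    outputs[[stage]] <<- write_stage_csv(res, cfg$output_dir, stage)
    status[[stage]] <<- "ok"
  }
  write_manifest <- function(cfg, outputs, status) {
    manifest <- list(
      package = "postmd",
      version = as.character(utils::packageVersion("postmd")),
      inputs = list(pdb = cfg$pdb, energies = cfg$energies),
      parameters = list(seed = cfg$seed, frame_interval = cfg$frame_interval,
                        criteria = unclass(criteria), windows = windows,
                        population = cfg$population, stages = cfg$stages),
      status = status,
      outputs = lapply(outputs, basename))
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  run_stage("rmsd", function() {
    s <- rmsd_series(traj, sel$chain, sel$first, sel$last)
    data.frame(time_ps = s$time_ps, rmsd_A = round(s$rmsd_A, 6))
  })
  run_stage("rmsf", function() {
    p <- rmsf_profile(traj, sel$chain, sel$first, sel$last)
    data.frame(residue = p$residue, rmsf_A = round(p$rmsf_A, 6))
  })
  run_stage("ss", function() {
    do.call(rbind, lapply(names(windows), function(w) {
      prof <- ss_percentages(traj, analysis_window(windows[[w]][1],
                                                   windows[[w]][2]))
      data.frame(window = w, as.data.frame(prof))
    }))
  })
  group_a <- cfg$group_a; group_b <- cfg$group_b
  run_stage("contacts", function() {
    occ <- hydrophobic_occurrence_map(traj, group_a, group_b, criteria)
    facing <- facing_fractions(traj, occ, criteria)
    out <- data.frame(as.data.frame(occ), facing_fraction = facing)
    if (!is.null(cfg$regions_a) && !is.null(cfg$regions_b)) {
      lv <- classify_region_contacts(occ, facing,
                                     scheme_from_config(cfg$regions_a),
                                     scheme_from_config(cfg$regions_b),
                                     criteria)
      outputs[["contact_levels"]] <<- write_stage_csv(
        as.data.frame(lv), cfg$output_dir, "contact_levels")
    }
    out
  })
  run_stage("electrostatics", function()
    as.data.frame(electrostatic_occurrence_map(traj, group_a, group_b,
                                               criteria)))
  run_stage("hbonds", function()
    as.data.frame(hbond_occurrence_map(traj, group_a, group_b, criteria)))
  run_stage("gauges", function() {
    spec <- if (is.null(cfg$gauges)) ide_gauges()
      else gauge_spec(cfg$gauges$distances, cfg$gauges$angles)
    s <- gauge_series(traj, spec)
    s[-1L] <- lapply(s[-1L], round, 6)
    as.data.frame(s)
  })
  run_stage("populations", function() {
    energies <- read_energy_table(cfg$energies)
    pop_cfg <- population_config(
      temperature = if (is.null(cfg$population$temperature)) 298
        else cfg$population$temperature,
      steps = if (is.null(cfg$population$steps)) 1e6
        else cfg$population$steps,
      seed = cfg$seed)
    est <- mc_populations(energies, pop_cfg)
    dg <- relative_free_energies(est, pop_cfg$temperature)
    data.frame(conformer = est$conformer, N_n = est$visits,
               P_n = est$probability, stderr = signif(est$stderr, 6),
               dG_kcal_mol = round(as.numeric(dg), 6))
  })

  write_manifest(cfg, outputs, status)
  invisible(list(outputs = outputs,
                 manifest = file.path(cfg$output_dir, "manifest.json")))
}
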