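# JSON-configured sequential workflow runner.
#
# A workflow is an ordered list of typed steps with settings and named
# input bindings referencing outputs of earlier steps. Each step writes its
# artifacts into its own subdirectory of the run directory together with a
# status record; a failing step halts the run (partial artifacts are
# retained). The global seed is threaded to every stochastic step, offset
# by the step index so steps draw independent streams. Docking and MD
# engine step types are reserved names that fail validation with a pointer
# to the mock equivalents.

WORKFLOW_STEP_TYPES <- c(
  "read_ligands", "filter_charge", "read_poses", "select_poses",
  "build_map", "synth_study", "mock_nes", "ingest_work",
  "estimate_edges", "solve_graph", "offset_experiment", "metrics", "report"
)

RESERVED_ENGINE_STEPS <- c(
  dock_glide = "select_poses (poses must be docked externally)",
  dock_vina = "select_poses (poses must be docked externally)",
  ligprep = "read_ligands (accepts pre-embedded SDF or SMILES)",
  epik = "filter_charge",
  prepare_simulation = "mock_nes",
  run_simulation = "mock_nes",
  pmx_hybrid = "mock_nes"
)

#' Validate a workflow configuration
#'
#' Parses a JSON workflow file (or takes an equivalent list) and checks:
#' step types are known, step names unique, every input binding references
#' the name of an earlier step. Engine step types (docking, MD) are
#' rejected with a pointer to the mock equivalent.
#'
#' @param config path to a JSON file, or a list with elements `global` and
#'   `steps`.
#' @return object of class `workflow_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- jsonlite::fromJSON(config, simplifyDataFrame = FALSE,
                                 simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  steps <- config$steps
  if (is.null(steps) || length(steps) == 0) {
    stop("workflow has no steps", call. = FALSE)
  }
  seen <- character(0)
  for (k in seq_along(steps)) {
    st <- steps[[k]]
    type <- st$type %||% stop(sprintf("step %d has no type", k), call. = FALSE)
    if (type %in% names(RESERVED_ENGINE_STEPS)) {
      stop(sprintf(
        "unknown step type '%s': external engines are out of scope; use %s",
        type, RESERVED_ENGINE_STEPS[[type]]
      ), call. = FALSE)
    }
    if (!type %in% WORKFLOW_STEP_TYPES) {
      stop(sprintf("unknown step type '%s' (step %d)", type, k),
           call. = FALSE)
    }
    name <- st$name %||% type
    if (name %in% seen) {
      stop(sprintf("duplicate step name '%s'", name), call. = FALSE)
    }
    for (ref in unlist(st$inputs %||% list(), use.names = FALSE)) {
      if (!ref %in% seen) {
        stop(sprintf(
          "step '%s' consumes binding '%s' which no earlier step provides",
          name, ref
        ), call. = FALSE)
      }
    }
    seen <- c(seen, name)
    steps[[k]]$name <- name
  }
  config$steps <- steps
  config$global <- config$global %||% list()
  structure(config, class = "workflow_config")
}

#' @export
print.workflow_config <- function(x, ...) {
  cat(sprintf("<workflow_config: %d steps: %s>\n", length(x$steps),
              paste(vapply(x$steps, function(s) s$name, ""), collapse = " -> ")))
  invisible(x)
}

# Resolve a step's named input bindings against the run context.
step_inputs <- function(st, ctx) {
  lapply(st$inputs %||% list(), function(ref) ctx[[ref]])
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run a validated workflow
#'
#' Executes the steps in order. Each step gets its own subdirectory
#' `NN_name/` under `outdir` for artifacts plus a `status.json`; a
#' structured line per step goes to `workflow.log`. The final `report`
#' step (or the end of the run) writes `report.json` with per-edge ddG,
#' per-node dG and metrics when available. Rerunning with the same config
#' and seed reproduces all numeric outputs exactly.
#'
#' @param config a [validate_config()] result, config list, or JSON path.
#' @param outdir run directory (created; existing artifacts overwritten).
#' @return invisibly, the run context: named list of step outputs plus
#'   `run_dir`.
#' @export
run_workflow <- function(config, outdir) {
  config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "workflow.log")
  cat("", file = log_path)
  global <- config$global
  base_seed <- as.integer(global$seed %||% 1)
  temperature <- as.numeric(global$temperature %||% DEFAULT_TEMPERATURE)
  ctx <- list()

  for (k in seq_along(config$steps)) {
    st <- config$steps[[k]]
    step_dir <- file.path(outdir, sprintf("%02d_%s", k, st$name))
    dir.create(step_dir, recursive = TRUE, showWarnings = FALSE)
    t0 <- Sys.time()
    result <- tryCatch(
      exec_step(st, step_inputs(st, ctx), st$settings %||% list(),
                step_dir, seed = base_seed + k, temperature = temperature,
                ctx = ctx),
      error = function(e) structure(conditionMessage(e), class = "step_error")
    )
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ok <- !inherits(result, "step_error")
    status <- list(step = st$name, type = st$type,
                   status = if (ok) "ok" else "failed",
                   elapsed_s = round(elapsed, 3))
    if (!ok) status$error <- unclass(result)
    write_json_artifact(status, file.path(step_dir, "status.json"))
    cat(sprintf("%s\tstep=%s\ttype=%s\tstatus=%s\telapsed=%.3fs\n",
                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), st$name, st$type,
                status$status, elapsed),
        file = log_path, append = TRUE)
    if (!ok) {
      stop(sprintf("workflow halted at step '%s' (%s): %s",
                   st$name, st$type, unclass(result)), call. = FALSE)
    }
    ctx[[st$name]] <- result
  }

  # final report (also written by an explicit report step)
  if (!any(vapply(config$steps, function(s) s$type == "report", logical(1)))) {
    write_final_report(ctx, outdir)
  }
  ctx$run_dir <- outdir
  invisible(ctx)
}

# Find the most recent context entry carrying a given field.
ctx_find <- function(ctx, field) {
  for (nm in rev(names(ctx))) {
    v <- ctx[[nm]]
    if (is.list(v) && !is.null(v[[field]])) return(v[[field]])
  }
  NULL
}

write_final_report <- function(ctx, outdir) {
  report <- list()
  edges <- ctx_find(ctx, "edges")
  if (!is.null(edges)) {
    report$edges <- lapply(seq_len(nrow(edges)), function(i) {
      list(edge = edges$edge[i], ddg_kcal = edges$ddg[i],
           se_kcal = edges$se[i])
    })
  }
  nodes <- ctx_find(ctx, "nodes")
  if (!is.null(nodes)) {
    report$nodes <- lapply(seq_len(nrow(nodes)), function(i) {
      list(id = nodes$id[i], dg_calc_kcal = nodes$dg_calc[i],
           se_kcal = nodes$se[i])
    })
  }
  metrics <- ctx_find(ctx, "metrics")
  if (!is.null(metrics)) report$metrics <- metrics
  write_json_artifact(report, file.path(outdir, "report.json"))
  report
}

exec_step <- function(st, inputs, settings, step_dir, seed, temperature,
                      ctx) {
  switch(st$type,
    read_ligands = {
      ligands <- read_ligands(settings$path)
      df <- data.frame(
        id = vapply(ligands, function(r) r$id, ""),
        smiles = vapply(ligands, function(r) r$smiles, ""),
        net_charge = vapply(ligands, function(r) r$net_charge, 0L)
      )
      utils::write.csv(df, file.path(step_dir, "ligands.csv"),
                       row.names = FALSE, quote = FALSE)
      list(ligands = ligands)
    },
    filter_charge = {
      ligands <- inputs$ligands$ligands %||% ctx_find(ctx, "ligands")
      parts <- filter_to_single_net_charge(ligands)
      writeLines(vapply(parts$dropped, function(r) r$id, ""),
                 file.path(step_dir, "dropped_ids.txt"))
      list(ligands = parts$kept, dropped = parts$dropped)
    },
    read_poses = {
      list(poses = read_poses(settings$path))
    },
    select_poses = {
      poses <- inputs$poses$poses %||% ctx_find(ctx, "poses")
      ref <- read_sdf_mols(settings$reference)[[1]]
      sel <- filter_poses_by_mcs(poses, ref)
      utils::write.csv(sel, file.path(step_dir, "selected_poses.csv"),
                       row.names = FALSE, quote = FALSE)
      write_poses(attr(sel, "selected"),
                  file.path(step_dir, "selected_poses.sdf"))
      list(selection = sel, poses = attr(sel, "selected"))
    },
    build_map = {
      ligands <- inputs$ligands$ligands %||% ctx_find(ctx, "ligands")
      map <- build_map(ligands,
                       target_degree = settings$target_degree %||% 2)
      write_map(map, file.path(step_dir, "map.csv"))
      list(map = map)
    },
    synth_study = {
      study <- gen_map_study(
        n_ligands = settings$n_ligands %||% 27,
        dg_range = as.numeric(settings$dg_range %||% c(-11.5, -7.2)),
        edge_noise_sd = settings$edge_noise_sd %||% 0.3,
        exp_noise_sd = settings$exp_noise_sd %||% 0.43,
        target_degree = settings$target_degree %||% 3,
        seed = settings$seed %||% seed
      )
      write_map(study$map, file.path(step_dir, "map.csv"))
      write_affinities(study$affinities,
                       file.path(step_dir, "affinities.csv"))
      utils::write.csv(
        data.frame(id = names(study$dg_true), dg_true_kcal = study$dg_true),
        file.path(step_dir, "dg_true.csv"), row.names = FALSE, quote = FALSE
      )
      list(study = study, map = study$map, affinities = study$affinities)
    },
    mock_nes = {
      study <- inputs$study$study %||% ctx_find(ctx, "study")
      if (is.null(study)) stop("mock_nes needs a synth_study input")
      manifests <- list()
      for (i in seq_along(study$ddg_true)) {
        eid <- names(study$ddg_true)[i]
        manifests[[i]] <- mock_nes_backend(
          eid, study$ddg_true[[i]],
          dissipation_sigma = settings$dissipation_sigma %||% 1,
          n_transitions = settings$n_transitions %||% 80,
          n_replicas = settings$n_replicas %||% 3,
          seed = seed + 13 * i, dir = file.path(step_dir, "works"),
          temperature = temperature
        )
      }
      manifest <- do.call(rbind, manifests)
      utils::write.csv(manifest, file.path(step_dir, "manifest.csv"),
                       row.names = FALSE, quote = FALSE)
      list(manifest = manifest)
    },
    ingest_work = {
      manifest <- utils::read.csv(settings$manifest,
                                  stringsAsFactors = FALSE)
      need <- c("edge", "leg", "replica", "forward", "reverse")
      if (!all(need %in% names(manifest))) {
        stop(sprintf("work manifest needs columns %s",
                     paste(need, collapse = ",")))
      }
      list(manifest = manifest)
    },
    estimate_edges = {
      manifest <- inputs$works$manifest %||% ctx_find(ctx, "manifest")
      edges <- list()
      for (eid in unique(manifest$edge)) {
        sub <- manifest[manifest$edge == eid, , drop = FALSE]
        er <- estimate_edge_from_files(
          sub, temperature = temperature,
          n_boot = settings$n_boot %||% 100,
          seed = seed + 101 * match(eid, unique(manifest$edge))
        )
        edges[[eid]] <- data.frame(
          edge = er$edge, ddg = er$ddg, se = er$se,
          dg_complex = er$dg_complex, dg_water = er$dg_water,
          replicas = er$replicas, stringsAsFactors = FALSE
        )
      }
      edges <- do.call(rbind, edges)
      rownames(edges) <- NULL
      utils::write.csv(
        stats::setNames(edges[, c("edge", "ddg", "se")],
                        c("edge", "ddg_kcal", "se_kcal")),
        file.path(step_dir, "edges.csv"), row.names = FALSE, quote = FALSE
      )
      list(edges = edges)
    },
    solve_graph = {
      map <- inputs$map$map %||% ctx_find(ctx, "map")
      edges <- inputs$edges$edges %||% ctx_find(ctx, "edges")
      nodes <- solve_node_dgs(map, edges,
                              se_floor = settings$se_floor %||% 0.1)
      cyc <- cycle_closure_errors(map, edges)
      utils::write.csv(
        data.frame(cycle_edge = names(cyc), closure_kcal = unname(cyc)),
        file.path(step_dir, "cycle_closure.csv"), row.names = FALSE,
        quote = FALSE
      )
      utils::write.csv(
        stats::setNames(nodes, c("ligand", "dg_calc_kcal", "se_kcal")),
        file.path(step_dir, "nodes.csv"), row.names = FALSE, quote = FALSE
      )
      list(nodes = nodes, cycles = cyc, map = map, edges = edges)
    },
    offset_experiment = {
      nodes <- inputs$nodes$nodes %||% ctx_find(ctx, "nodes")
      affinities <- if (!is.null(settings$experiment)) {
        read_affinities(settings$experiment)
      } else {
        inputs$experiment$affinities %||% ctx_find(ctx, "affinities")
      }
      nodes <- offset_to_experiment(nodes, affinities)
      utils::write.csv(
        stats::setNames(nodes, c("ligand", "dg_calc_kcal", "se_kcal")),
        file.path(step_dir, "nodes_offset.csv"), row.names = FALSE,
        quote = FALSE
      )
      list(nodes = nodes, affinities = affinities)
    },
    metrics = {
      nodes <- inputs$nodes$nodes %||% ctx_find(ctx, "nodes")
      affinities <- inputs$experiment$affinities %||%
        ctx_find(ctx, "affinities")
      shared <- intersect(nodes$id, affinities$id)
      calc <- nodes$dg_calc[match(shared, nodes$id)]
      expv <- affinities$dg_exp[match(shared, affinities$id)]
      sig <- affinities$sigma_exp[match(shared, affinities$id)]
      point <- compute_metrics(calc, expv)
      ci <- bootstrap_metric_ci(calc, expv,
                                n_boot = settings$n_boot %||% 1000,
                                seed = seed + 7)
      nullband <- experimental_null_band(
        expv, sig, n_samples = settings$n_samples %||% 1000,
        seed = seed + 8,
        sigma_floor = settings$sigma_floor %||% 0.43
      )
      metrics <- list(point = point[metric_names], ci = ci,
                      null_band = nullband, n = length(shared))
      write_json_artifact(metrics, file.path(step_dir, "metrics.json"))
      list(metrics = metrics, nodes = nodes, affinities = affinities)
    },
    report = {
      write_final_report(ctx, dirname(step_dir))
    },
    stop(sprintf("unhandled step type '%s'", st$type))
  )
}
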