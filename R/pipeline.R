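# End-to-end orchestration: generate or load a trajectory, then run kinetics,
# orientation, interface contacts, lipid environment and the interface score,
# writing tabular outputs, a JSON config side-car and a reproducibility
# manifest.

#' Run the full analysis pipeline
#'
#' Stages are pure functions of the inputs plus the configuration; re-running
#' with the same configuration reproduces every data output bit-exactly.
#' The interface-score stage runs only when the membrane contains
#' cholesterol; contact maps are written only for event classes that occur.
#'
#' @param config one of: a \code{planted_scenario}; a list with elements
#'   \code{scenario} (a scenario label from
#'   \code{\link{reference_scenarios}}, a \code{planted_scenario}, or a list
#'   of \code{planted_scenario} arguments), or \code{gro} + \code{topology}
#'   file paths, plus optional \code{analysis} (named overrides for
#'   \code{\link{analysis_config}}); or a path to a YAML file with the same
#'   structure.
#' @param out_dir output directory (created if needed).
#' @return the run manifest (list), invisibly; written as manifest.json.
#' @export
run_pipeline <- function(config, out_dir) {
  t_start <- Sys.time()
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("pipeline: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "planted_scenario")) config <- list(scenario = config)
  cfg <- modify_config(analysis_config(), config$analysis)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  stage_times <- list()
  logmsg <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dtns <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    stage_times[[name]] <<- dtns
    logmsg(sprintf("stage %-12s %6.1f s", name, dtns))
    res
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  # ---- acquire inputs
  input_files <- character(0)
  truth <- NULL
  if (!is.null(config$gro)) {
    if (is.null(config$topology))
      stop("pipeline: 'gro' input requires a 'topology' file")
    if (!file.exists(config$topology))
      stop("pipeline: topology file not found: ", config$topology)
    if (!file.exists(config$gro))
      stop("pipeline: trajectory file not found: ", config$gro)
    input_files <- c(config$gro, config$topology)
    run <- run_stage("load", {
      g <- read_gro(config$gro)
      top <- read_topology(config$topology)
      list(trajectory = trajectory(
        g$frames, label = if (is.null(config$label)) "input" else config$label,
        composition = if (is.null(config$composition)) 0 else
          config$composition),
        topology = top)
    })
  } else {
    sc <- config$scenario
    if (is.null(sc)) stop("pipeline: config needs 'scenario' or 'gro'+'topology'")
    if (is.character(sc)) {
      all_sc <- reference_scenarios()
      hit <- which(vapply(all_sc, function(s) s$label, "") == sc)
      if (!length(hit)) stop("pipeline: unknown reference scenario '", sc, "'")
      sc <- all_sc[[hit]]
    } else if (!inherits(sc, "planted_scenario")) {
      sc <- do.call(planted_scenario, sc)
    }
    run <- run_stage("generate", generate_trajectory(sc, cfg))
    truth <- run$truth
  }
  traj <- run$trajectory
  top <- run$topology
  comp <- traj$composition
  meta <- list(analysis_config = unclass(cfg), composition = comp,
               label = traj$label)

  # ---- kinetics
  seg <- run_stage("kinetics", {
    ser <- distance_series(traj, top)
    seg <- segment_regimes(ser, cfg)
    utils::write.table(
      data.frame(time = ser$times, min_distance = ser$min_distance),
      file.path(out_dir, "min_distance.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    emit("min_distance.tsv")
    utils::write.table(seg$intervals, file.path(out_dir, "intervals.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit("intervals.tsv")
    ev <- seg$dimer_events
    diss <- count_dissociations(list(seg), comp)
    jsonlite::write_json(
      list(events = ev, dissociation_events = diss$total,
           composition = comp),
      file.path(out_dir, "events.json"), auto_unbox = TRUE, digits = NA)
    emit("events.json")
    hm <- distance_heatmap(list(ser))
    write_matrix(hm + 0, file.path(out_dir, "distance_heatmap.tsv"),
                 metadata = c(meta, list(
                   classes = attr(hm, "labels"), breaks = attr(hm, "breaks"))))
    emit("distance_heatmap.tsv")
    seg
  })
  dimer_fr <- regime_frames(seg, "dimer")
  monomer_fr <- regime_frames(seg, "monomer")

  # ---- orientation
  orient <- run_stage("orientation", {
    os <- orientation_series(traj, top, seg)
    utils::write.table(os, file.path(out_dir, "orientation.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    emit("orientation.tsv")
    dens <- suppressWarnings(orientation_density(os, cfg))
    write_matrix(unclass(dens), file.path(out_dir, "orientation_density.tsv"),
                 metadata = meta)
    emit("orientation_density.tsv")
    conf <- assign_conformer(os$theta1, os$theta2)
    cc <- as.list(table(conf))
    jsonlite::write_json(cc, file.path(out_dir, "conformer_counts.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("conformer_counts.json")
    os
  })

  # ---- interface contacts
  maps <- run_stage("contacts", {
    runlist <- list(list(trajectory = traj, topology = top,
                         segmentation = seg))
    out <- list()
    for (kind in c("stable", "transient")) {
      n_ev <- sum(seg$dimer_events$class == kind)
      if (!n_ev) { logmsg("  no ", kind, " events; map skipped"); next }
      cm <- if (kind == "stable") stable_contact_map(runlist, cfg) else
        transient_contact_map(runlist, cfg)
      write_matrix(cm$matrix,
                   file.path(out_dir, paste0("contact_", kind, ".tsv")),
                   metadata = meta)
      emit(paste0("contact_", kind, ".tsv"))
      write_matrix(symmetrize_contact_map(cm),
                   file.path(out_dir, paste0("contact_", kind, "_sym.tsv")))
      emit(paste0("contact_", kind, "_sym.tsv"))
      write_matrix(cm$raw,
                   file.path(out_dir, paste0("contact_", kind, "_raw.tsv")))
      emit(paste0("contact_", kind, "_raw.tsv"))
      if (nrow(cm$loop_contacts)) {
        utils::write.table(cm$loop_contacts,
                           file.path(out_dir,
                                     paste0("loop_contacts_", kind, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        emit(paste0("loop_contacts_", kind, ".tsv"))
      }
      out[[kind]] <- cm
    }
    out
  })

  # ---- lipid environment
  env <- run_stage("environment", {
    kinds <- intersect(c("CHOL", "POPC"), unique(top$beads$molecule_kind))
    profiles <- list()
    for (kind in kinds) {
      for (reg in c("monomer", "dimer")) {
        fr <- if (reg == "monomer") monomer_fr else dimer_fr
        if (!length(fr)) next
        prof <- residue_occupancy(traj, top, fr, kind, cfg, regime = reg)
        fn <- sprintf("occupancy_%s_%s.tsv", kind, reg)
        utils::write.table(as.data.frame(prof), file.path(out_dir, fn),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        emit(fn)
        profiles[[paste(kind, reg, sep = "_")]] <- prof
      }
    }
    tm <- NULL
    if (length(monomer_fr)) {
      tm <- thickness_map(traj, top, monomer_fr, cfg, receptor = 1L)
      write_matrix(tm$grid, file.path(out_dir, "thickness.tsv"),
                   metadata = c(meta, list(
                     farfield_thickness = tm$farfield_thickness)))
      emit("thickness.tsv")
    }
    list(profiles = profiles, thickness = tm)
  })

  # ---- interface occupancy score (cholesterol-containing membranes only)
  if (comp > 0 && !is.null(maps$stable) &&
      !is.null(env$profiles$CHOL_dimer)) {
    run_stage("score", {
      hocc <- helix_occupancy(env$profiles$CHOL_dimer, top)
      p <- interface_probabilities(maps$stable)
      iom <- interface_occupancy_matrix(hocc, p, cfg, lipid_kind = "CHOL",
                                        composition = comp)
      write_matrix(unclass(iom), file.path(out_dir, "score_CHOL.tsv"),
                   metadata = c(meta, list(
                     helix_occupancy = as.list(hocc),
                     interface_probability = as.list(p))))
      emit("score_CHOL.tsv")
      iom
    })
  } else logmsg("stage score        skipped (",
                if (comp == 0) "no cholesterol" else "no stable dimer regime",
                ")")

  # ---- config side-car, ground truth, manifest
  jsonlite::write_json(meta, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit("config.json")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("ground_truth.json")
  }
  outputs <- unique(outputs)
  paths <- file.path(out_dir, outputs)
  missing <- outputs[!file.exists(paths)]
  if (length(missing)) stop("pipeline: missing declared outputs: ",
                            paste(missing, collapse = ", "))
  cfg_tmp <- tempfile()
  jsonlite::write_json(meta, cfg_tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dimerlens")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = unname(tools::md5sum(cfg_tmp)),
    seed = cfg$seed,
    input_files = if (length(input_files))
      as.list(stats::setNames(unname(tools::md5sum(input_files)),
                              basename(input_files))) else NULL,
    stage_seconds = stage_times,
    outputs = as.list(stats::setNames(unname(tools::md5sum(paths)), outputs)))
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg(sprintf("pipeline complete: %d outputs in %s", length(outputs),
                 out_dir))
  invisible(manifest)
}
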