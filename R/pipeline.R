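## One-call orchestration: thinning -> screening -> replicate fitting ->
## projection -> classification -> area/change/centroid reporting, with a
## fixed artifact layout, per-stage timing log, and a JSON provenance
## record.  Every stage seed is derived from the master seed by a counter
## scheme (stage k uses seed master + 97 * k mod 2^31 - 1), so stages are
## independently reproducible.

#' Assemble a pipeline run configuration
#'
#' @param occurrences An `occurrence_set`, or path to an occurrence CSV.
#' @param scenarios Named list of [grid_stack()]s, or of directories of
#'   `.asc` layer files (one layer per file), or a `scenario_series`.
#' @param baseline Name of the baseline scenario (default `"current"`).
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed.
#' @param thin_radius_km Spatial thinning radius (default 5 km).
#' @param correlation_threshold Screening correlation cut (default 0.8).
#' @param train A [maxent_config()].
#' @param test_fraction,replicates Evaluation split settings (defaults
#'   0.25 and 100).
#' @param suitability_thresholds Class cut points (default
#'   `c(0.1, 0.3, 0.5)`).
#' @param presence_threshold Binary-range threshold (default 0.5).
#' @param write_replicate_maps Write per-replicate suitability rasters
#'   (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(occurrences, scenarios, baseline = "current",
                       out_dir = "maxniche_run", seed = 1,
                       thin_radius_km = 5, correlation_threshold = 0.8,
                       train = maxent_config(seed = seed),
                       test_fraction = 0.25, replicates = 100,
                       suitability_thresholds = c(0.1, 0.3, 0.5),
                       presence_threshold = 0.5,
                       write_replicate_maps = TRUE) {
  if (inherits(scenarios, "scenario_series")) scenarios <- scenarios$stacks
  stopifnot(is.list(scenarios), baseline %in% names(scenarios))
  structure(list(occurrences = occurrences, scenarios = scenarios,
                 baseline = baseline, out_dir = out_dir, seed = seed,
                 thin_radius_km = thin_radius_km,
                 correlation_threshold = correlation_threshold,
                 train = train, test_fraction = test_fraction,
                 replicates = replicates,
                 suitability_thresholds = suitability_thresholds,
                 presence_threshold = presence_threshold,
                 write_replicate_maps = write_replicate_maps),
            class = "run_config")
}

load_scenario <- function(x) {
  if (inherits(x, "grid_stack")) return(x)
  if (is.character(x) && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.asc$", full.names = TRUE))
    if (!length(files)) stop("no .asc layers in ", x)
    return(grid_stack(lapply(files, read_asc)))
  }
  stop("scenario must be a grid_stack or a directory of .asc files")
}

#' Run the full niche-modelling pipeline
#'
#' Executes every stage on the configured inputs and writes a fixed
#' artifact layout under `config$out_dir`: `occurrences_thinned.csv`,
#' `screening.csv` + `screening.json`, `evaluation.csv` (per-replicate
#' AUCs, mean, grade), `importance.csv`, `jackknife.csv`,
#' `response_curves.csv` + `optimal_ranges.csv`,
#' `suitability_<scenario>.asc` (replicate mean; per-replicate maps under
#' `replicates/` when enabled), `classification_<scenario>.asc`,
#' `areas.csv` (signed deltas vs the baseline), `change_<scenario>.asc` +
#' `changes.csv`, `centroids.csv` and `migrations.csv`, a
#' `provenance.json` record and a `run.log` with per-stage timings.
#' A failing stage aborts with the stage name; artifacts already written
#' are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the main in-memory results (`thinned`,
#'   `screening`, `evaluation`, `model`, `areas`, `changes`,
#'   `migrations`, `out_dir`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  t_all <- proc.time()[["elapsed"]]
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logline("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0)
    res
  }
  fmt2 <- function(x) round(x, 2)

  scenarios <- stage("load", lapply(config$scenarios, load_scenario))
  baseline <- config$baseline
  stack0 <- scenarios[[baseline]]

  occ <- stage("occurrences", {
    o <- if (is.character(config$occurrences))
      read_occurrences(config$occurrences) else config$occurrences
    thinned <- thin_occurrences(o, config$thin_radius_km)
    write_occurrences(thinned,
                      file.path(config$out_dir, "occurrences_thinned.csv"))
    thinned
  })

  screening <- stage("screening", {
    cfg <- config$train
    cfg$seed <- stage_seed(config$seed, 1)
    rep <- screen_variables(stack0, occ, cfg,
                            threshold = config$correlation_threshold)
    write_screening_report(rep, file.path(config$out_dir, "screening.csv"),
                           file.path(config$out_dir, "screening.json"))
    rep
  })
  vars <- screening$final_variables
  stacks <- lapply(scenarios, function(s) subset_stack(s, vars))

  evaluation <- stage("evaluate", {
    cfg <- config$train
    cfg$seed <- stage_seed(config$seed, 2)
    ev <- evaluate_replicates(stacks[[baseline]], occ, cfg,
                              test_fraction = config$test_fraction,
                              replicates = config$replicates,
                              seed = stage_seed(config$seed, 3))
    utils::write.csv(data.frame(replicate = seq_along(ev$aucs),
                                auc = round(ev$aucs, 3)),
                     file.path(config$out_dir, "evaluation.csv"),
                     row.names = FALSE)
    cat(jsonlite::toJSON(list(mean_auc = round(ev$mean_auc, 3),
                              grade = ev$grade), auto_unbox = TRUE),
        "\n", file = file.path(config$out_dir, "evaluation.json"))
    ev
  })

  model <- stage("fit_full", {
    cfg <- config$train
    cfg$seed <- stage_seed(config$seed, 2)
    maxent(stacks[[baseline]], occ, cfg)
  })

  stage("importance", {
    pc <- percent_contribution(model)
    pi <- permutation_importance(model, seed = stage_seed(config$seed, 4))
    utils::write.csv(data.frame(variable = names(pc),
                                percent_contribution = round(as.numeric(pc), 2),
                                permutation_importance = round(as.numeric(pi[names(pc)]), 2)),
                     file.path(config$out_dir, "importance.csv"),
                     row.names = FALSE)
    if (length(vars) >= 2) {
      cfg <- config$train
      cfg$seed <- stage_seed(config$seed, 2)
      jk <- jackknife_gains(stacks[[baseline]], occ, cfg)
      utils::write.csv(cbind(jk$gains, gain_full = jk$gain_full),
                       file.path(config$out_dir, "jackknife.csv"),
                       row.names = FALSE)
    }
    NULL
  })

  stage("response_curves", {
    cfg <- config$train
    cfg$seed <- stage_seed(config$seed, 2)
    curves <- lapply(vars, function(v)
      response_curve(v, stacks[[baseline]], occ, cfg))
    names(curves) <- vars
    utils::write.csv(do.call(rbind, lapply(curves, function(cu)
      data.frame(variable = cu$variable, value = cu$curve$value,
                 probability = cu$curve$probability))),
      file.path(config$out_dir, "response_curves.csv"), row.names = FALSE)
    rng <- do.call(rbind, lapply(curves, function(cu) {
      r <- optimal_range(cu)
      if (nrow(r) == 0)
        data.frame(variable = cu$variable, lower = NA_real_,
                   upper = NA_real_)
      else cbind(variable = cu$variable, r)
    }))
    utils::write.csv(rng, file.path(config$out_dir, "optimal_ranges.csv"),
                     row.names = FALSE)
    NULL
  })

  maps <- stage("project", {
    if (config$write_replicate_maps)
      dir.create(file.path(config$out_dir, "replicates"),
                 showWarnings = FALSE)
    out <- list()
    for (sc in names(stacks)) {
      out[[sc]] <- project_mean(evaluation, stacks[[sc]])
      write_asc(out[[sc]],
                file.path(config$out_dir, paste0("suitability_", sc, ".asc")))
      if (config$write_replicate_maps) {
        feats <- evaluation$features
        sv <- stack_values(stacks[[sc]])
        F <- feature_matrix(scale_values(sv$values[, feats$var_names,
                                                   drop = FALSE],
                                         feats$scaling), feats$defs)
        for (i in seq_along(evaluation$models)) {
          m <- evaluation$models[[i]]
          q <- exp(as.numeric(F %*% m$lambdas) - m$log_partition)
          v <- matrix(NA_real_, stacks[[sc]]$header$nrows,
                      stacks[[sc]]$header$ncols)
          v[sv$cells] <- logistic_from_raw(q, m$entropy)
          g <- env_grid(v, stacks[[sc]]$header$xllcorner,
                        stacks[[sc]]$header$yllcorner,
                        stacks[[sc]]$header$cellsize,
                        stacks[[sc]]$header$nodata_value,
                        name = sprintf("%s_rep%03d", sc, i))
          write_asc(g, file.path(config$out_dir, "replicates",
                                 sprintf("suitability_%s_rep%03d.asc", sc, i)))
        }
      }
    }
    out
  })

  areas <- stage("classify", {
    cls0 <- classify_suitability(maps[[baseline]],
                                 config$suitability_thresholds)
    base_area <- class_areas(cls0, period = baseline)
    out <- list()
    for (sc in names(maps)) {
      cls <- classify_suitability(maps[[sc]], config$suitability_thresholds)
      write_asc(cls$grid, file.path(config$out_dir,
                                    paste0("classification_", sc, ".asc")))
      out[[sc]] <- class_areas(cls, baseline = base_area, period = sc)
    }
    tab <- do.call(rbind, lapply(out, as.data.frame))
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], fmt2)
    utils::write.csv(tab, file.path(config$out_dir, "areas.csv"),
                     row.names = FALSE)
    out
  })

  changes <- stage("change", {
    futures <- setdiff(names(maps), baseline)
    if (!length(futures)) return(list())
    bin0 <- binary_map(maps[[baseline]], config$presence_threshold)
    out <- list()
    for (sc in futures) {
      cm <- change_map(bin0, binary_map(maps[[sc]],
                                        config$presence_threshold),
                       period = sc)
      write_asc(cm$grid, file.path(config$out_dir,
                                   paste0("change_", sc, ".asc")))
      out[[sc]] <- cm
    }
    tab <- do.call(rbind, lapply(out, function(cm)
      data.frame(period = cm$summary$period,
                 expansion = fmt2(cm$summary$expansion),
                 retention = fmt2(cm$summary$retention),
                 contraction = fmt2(cm$summary$contraction),
                 net = fmt2(cm$summary$net))))
    utils::write.csv(tab, file.path(config$out_dir, "changes.csv"),
                     row.names = FALSE)
    out
  })

  migrations <- stage("centroids", {
    cents <- list()
    for (sc in names(maps)) {
      bm <- binary_map(maps[[sc]], config$presence_threshold)
      cents[[sc]] <- tryCatch(range_centroid(bm), error = function(e) NULL)
    }
    keep <- !vapply(cents, is.null, TRUE)
    ct <- do.call(rbind, lapply(names(cents)[keep], function(sc)
      data.frame(scenario = sc, longitude = cents[[sc]][["longitude"]],
                 latitude = cents[[sc]][["latitude"]])))
    if (!is.null(ct))
      utils::write.csv(ct, file.path(config$out_dir, "centroids.csv"),
                       row.names = FALSE)
    migs <- list()
    if (!is.null(cents[[baseline]])) {
      for (sc in setdiff(names(cents)[keep], baseline)) {
        migs[[sc]] <- migration_vector(cents[[baseline]], cents[[sc]],
                                       period = paste(baseline, "->", sc))
      }
    }
    if (length(migs)) {
      utils::write.csv(do.call(rbind, lapply(migs, function(mv)
        data.frame(period = mv$period,
                   from_lon = mv$from[["longitude"]],
                   from_lat = mv$from[["latitude"]],
                   to_lon = mv$to[["longitude"]],
                   to_lat = mv$to[["latitude"]],
                   distance_km = mv$distance_km,
                   bearing_deg = mv$bearing_deg))),
        file.path(config$out_dir, "migrations.csv"), row.names = FALSE)
    }
    migs
  })

  stage("provenance", {
    prov <- list(
      package = "maxniche",
      version = as.character(utils::packageVersion("maxniche")),
      seed = config$seed,
      stage_seeds = list(screening = stage_seed(config$seed, 1),
                         training = stage_seed(config$seed, 2),
                         splits = stage_seed(config$seed, 3),
                         permutation = stage_seed(config$seed, 4)),
      thin_radius_km = config$thin_radius_km,
      correlation_threshold = config$correlation_threshold,
      test_fraction = config$test_fraction,
      replicates = config$replicates,
      suitability_thresholds = config$suitability_thresholds,
      presence_threshold = config$presence_threshold,
      baseline = baseline,
      scenarios = names(scenarios),
      final_variables = vars,
      train = unclass(config$train))
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    NULL
  })
  logline("[total] %.2fs", proc.time()[["elapsed"]] - t_all)

  invisible(list(thinned = occ, screening = screening,
                 evaluation = evaluation, model = model, maps = maps,
                 areas = areas, changes = changes, migrations = migrations,
                 out_dir = config$out_dir))
}
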