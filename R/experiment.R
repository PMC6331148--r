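#' Deterministic sub-seed for a named pipeline stage
#'
#' A single master seed drives the whole experiment; each stochastic stage
#' (survey synthesis, calibration, fixtures) draws from its own named
#' substream so stages can be re-run independently with identical results.
#' The sub-seed is a deterministic hash of (master seed, stage name),
#' always a positive 32-bit integer.
#'
#' @param master Master integer seed.
#' @param stage Stage name (string).
#' @return A positive integer seed below 2^31.
#' @export
substream_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483587 + 1)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs: where the calibration
#' target comes from, the optimizer settings, the threat dynamics, the
#' grid resolution and the master seed. The target source is one of
#' * a [calibration_target()] object (used as is),
#' * `list(type = "survey_file", path = ...)` - statistics of a survey file,
#' * `list(type = "stats_file", path = ...)` - a target JSON written by
#'   [write_calibration_target_json()],
#' * `list(type = "synthetic", spec = survey_spec)` - statistics of a
#'   synthetic survey drawn from the spec (seeded from the master seed's
#'   "survey" substream).
#'
#' @param target Target source (see above); default: the synthetic survey.
#' @param pso A [pso_config()]: when supplied, a single calibration run
#'   provides its `keep_top` populations. When `NULL` (default), the
#'   experiment runs `n_populations` independent calibrations, each
#'   seeded from its own "calibration-<r>" substream of the master seed
#'   and contributing its best population — independent optimizer runs
#'   land in different basins, which is what gives the exposed population
#'   set its diversity.
#' @param threat A [threat_params()].
#' @param grid_resolution Number of grid positions D.
#' @param terrorist A terrorist [agent()].
#' @param n_populations Number of calibrated populations to expose to the
#'   scenario (used when `pso` is `NULL`).
#' @param swarm_size,iterations Per-run PSO settings (used when `pso` is
#'   `NULL`).
#' @param out_dir Optional output directory for report files.
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(target = list(type = "synthetic",
                                            spec = synthetic_french_survey_spec()),
                              pso = NULL,
                              threat = threat_params(),
                              grid_resolution = 400,
                              terrorist = make_terrorist(),
                              n_populations = 10, swarm_size = 40,
                              iterations = 150,
                              out_dir = NULL, seed = 1) {
  structure(list(target = target, pso = pso, threat = threat,
                 grid_resolution = grid_resolution, terrorist = terrorist,
                 n_populations = as.integer(n_populations),
                 swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 out_dir = out_dir, seed = seed),
            class = "experiment_config")
}

.resolve_target <- function(config) {
  tg <- config$target
  if (inherits(tg, "calibration_target")) return(tg)
  if (!is.list(tg) || is.null(tg$type)) {
    stop("experiment target must be a calibration_target or a typed list",
         call. = FALSE)
  }
  switch(tg$type,
    survey_file = survey_stats(read_survey(tg$path)),
    stats_file = read_calibration_target_json(tg$path),
    synthetic = survey_stats(
      synth_survey(tg$spec, seed = substream_seed(config$seed, "survey")),
      quiet = TRUE),
    stop("unknown target type: ", tg$type, call. = FALSE)
  )
}

#' Run the full experiment pipeline
#'
#' Resolves the calibration target, calibrates the exposed population set
#' (by default one population per independent seeded PSO run), runs the
#' threat scenario on each, classifies the per-agent attitude evolutions
#' toward the targeted group, and pools them. The whole pipeline is a
#' pure function of (config, master seed). Percentages are pooled both
#' weighted by agent weight (prototype agents represent population
#' shares) and as plain agent counts, since either aggregation basis is
#' defensible.
#'
#' @param config An [experiment_config()].
#' @return An object of class `experiment_report`: `target`, `calibration`
#'   (`errors` data frame and per-run `traces`), `populations`,
#'   `summaries` (per-population `evolution_summary`), `pooled` (weight-
#'   and count-based percentage splits), `population_direction`
#'   (per-population change of the mean attitude toward the targeted
#'   group, with its sign), and the config. If `config$out_dir` is set,
#'   writes `report.json`, `calibration_trace.csv` and `evolutions.csv`
#'   there.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  grid <- position_grid(config$grid_resolution)
  stage <- "target"
  report <- tryCatch({
    target <- .resolve_target(config)
    stage <- "calibration"
    if (!is.null(config$pso)) {
      single <- pso_calibrate(target, config$pso, grid)
      populations <- single$populations
      cal <- list(errors = single$errors, traces = list(single$trace))
    } else {
      runs <- lapply(seq_len(config$n_populations), function(r) {
        pso_calibrate(target,
                      pso_config(seed = substream_seed(config$seed,
                                                       paste0("calibration-", r)),
                                 swarm_size = config$swarm_size,
                                 iterations = config$iterations,
                                 keep_top = 1),
                      grid)
      })
      populations <- lapply(runs, function(x) x$populations[[1L]])
      cal <- list(errors = do.call(rbind, lapply(runs, `[[`, "errors")),
                  traces = lapply(runs, `[[`, "trace"))
    }
    rownames(cal$errors) <- NULL
    stage <- "scenario"
    summaries <- list()
    directions <- data.frame(population = integer(0), delta = numeric(0),
                             direction = character(0))
    for (p in seq_along(populations)) {
      traj <- run_scenario(populations[[p]], config$terrorist,
                           config$threat, grid)
      summ <- classify_evolutions(traj)
      summaries[[p]] <- summ
      w <- agent_weights(traj$states[[1L]])
      pop_delta <- sum(w * summ$per_agent_delta) / sum(w)
      directions <- rbind(directions, data.frame(
        population = p, delta = pop_delta,
        direction = if (pop_delta > 1e-9) "increase" else "decrease_or_unchanged",
        stringsAsFactors = FALSE))
    }
    stage <- "aggregation"
    pool <- function(field) {
      m <- rowMeans(vapply(summaries, function(s) s[[field]], numeric(2)))
      100 * m / sum(m)
    }
    structure(list(target = target, calibration = cal,
                   populations = populations, summaries = summaries,
                   pooled = list(pct_weight = pool("pct_weight"),
                                 pct_count = pool("pct_count")),
                   population_direction = directions,
                   config = config, seed = config$seed),
              class = "experiment_report")
  }, error = function(e) {
    stop(sprintf("experiment stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- do.call(rbind, lapply(seq_along(report$calibration$traces), function(r) {
    tr <- report$calibration$traces[[r]]
    data.frame(run = r, iteration = seq_along(tr), best_error = tr)
  }))
  utils::write.csv(traces, file.path(out_dir, "calibration_trace.csv"),
                   row.names = FALSE, quote = FALSE)
  evo <- do.call(rbind, lapply(seq_along(report$summaries), function(p) {
    s <- report$summaries[[p]]
    data.frame(population = p, agent_id = names(s$per_agent_delta),
               delta = unname(s$per_agent_delta),
               classification = unname(s$classification),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(evo, file.path(out_dir, "evolutions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = report$seed,
         pooled = lapply(report$pooled, as.list),
         population_direction = report$population_direction,
         calibration_errors = report$calibration$errors,
         target = list(mean = as.data.frame(report$target$mean),
                       sd = as.data.frame(report$target$sd),
                       fraction = as.list(report$target$fraction))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf(
    "<experiment_report> %d population(s); pooled increase %.1f%% (weighted), %.1f%% (counts)\n",
    length(x$summaries), x$pooled$pct_weight[["increase"]],
    x$pooled$pct_count[["increase"]]))
  invisible(x)
}

#' Generate the reference fixture bundle
#'
#' Writes, under `dir`:
#' * `worked_example_agents.json` - the two-agent population whose single-position
#'   attitudes at p = 0.2 are the worked values -0.24 / -0.46 (shared
#'   acceptance segment \[-0.85, -0.15\], m.a.positions -0.85 and -0.50);
#' * `prototype_population.json` - a template-sampled six-prototype
#'   population (seeded);
#' * `synthetic_survey.txt` - a synthetic survey of n = 1000 records;
#' * `increase_pair.json` - a hand-built two-agent population satisfying
#'   the four conditions under which a non-M agent's attitude toward an M
#'   agent increases after the threat (lower positive m.a.position,
#'   minimal higher margin, persistent positive overlap, M agent with a
#'   large higher margin).
#'
#' Regeneration with the same seed is byte-identical.
#'
#' @param dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Named list of the paths written, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  worked <- population(list(
    agent("orange", cultural_identity(
      M = acceptance_segment(-0.85, -0.85, -0.15),
      C = acceptance_segment(0.10, 0.50, 0.90),
      A = acceptance_segment(-0.50, 0.00, 0.50)), weight = 0.5),
    agent("green", cultural_identity(
      M = acceptance_segment(-0.85, -0.50, -0.15),
      C = acceptance_segment(0.10, 0.50, 0.90),
      A = acceptance_segment(-0.50, 0.00, 0.50)), weight = 0.5)))
  paths$worked_example <- file.path(dir, "worked_example_agents.json")
  write_population_json(worked, paths$worked_example)

  set.seed(substream_seed(seed, "fixtures"))
  proto <- sample_population(c(M = 0.036, C = 0.606, A = 0.358))
  paths$prototypes <- file.path(dir, "prototype_population.json")
  write_population_json(proto, paths$prototypes)

  survey <- synth_survey(synthetic_french_survey_spec(1000),
                         seed = substream_seed(seed, "survey"))
  paths$survey <- file.path(dir, "synthetic_survey.txt")
  write_survey(survey, paths$survey)

  paths$increase_pair <- file.path(dir, "increase_pair.json")
  write_population_json(increase_condition_pair(), paths$increase_pair)

  invisible(paths)
}

#' Hand-built pair of agents satisfying the attitude-increase conditions
#'
#' A two-agent population designed so the non-M observer's attitude toward
#' the M agent increases after a threat scenario: the C-group observer has
#' a positive m.a.position on M (0.2, below the M agent's 0.3), a higher
#' margin on M already at the minimal width (0.05, so it cannot contract),
#' and a large persistent overlap with the M agent through both lower
#' margins; the M agent's higher margin on M is large (0.6), so it
#' contracts strongly away from the terrorist.
#'
#' @return A [population()] of two agents (`m_agent`, `c_agent`).
#' @export
increase_condition_pair <- function() {
  population(list(
    agent("m_agent", cultural_identity(
      M = acceptance_segment(-0.60, 0.30, 0.90),
      C = acceptance_segment(-0.80, -0.20, 0.30),
      A = acceptance_segment(-0.80, -0.20, 0.30)),
      weight = 0.5, type = "inclusive"),
    agent("c_agent", cultural_identity(
      M = acceptance_segment(-0.50, 0.20, 0.25),
      C = acceptance_segment(0.00, 0.50, 0.90),
      A = acceptance_segment(-0.70, -0.30, 0.10)),
      weight = 0.5, type = "exclusive")))
}
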