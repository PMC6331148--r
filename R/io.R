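#' Read and write populations as JSON
#'
#' Schema: `{"agents": [{"id", "weight", "type", "identity": {"M": {"b",
#' "a", "B"}, ...}}]}`. The worldview order of the first agent fixes the
#' ordering for the whole population; all invariants are re-validated by
#' the constructors on read, so the round trip is schema-checked.
#'
#' @param pop A [population()].
#' @param path File path.
#' @return `write_population_json()` returns `path` invisibly;
#'   `read_population_json()` returns a [population()].
#' @export
write_population_json <- function(pop, path) {
  agents <- lapply(pop$agents, function(ag) {
    list(id = ag$id, weight = ag$weight, type = ag$type,
         identity = lapply(ag$identity, function(s) list(b = s$b, a = s$a, B = s$B)))
  })
  jsonlite::write_json(list(agents = agents), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_population_json
#' @export
read_population_json <- function(path) {
  raw <- jsonlite::read_json(path)
  if (is.null(raw$agents) || !length(raw$agents)) {
    stop("population JSON must contain a non-empty 'agents' array", call. = FALSE)
  }
  agents <- lapply(raw$agents, function(ag) {
    for (f in c("id", "weight", "type", "identity")) {
      if (is.null(ag[[f]])) stop("agent entry missing field: ", f, call. = FALSE)
    }
    segs <- lapply(ag$identity, function(s) acceptance_segment(s$b, s$a, s$B))
    agent(ag$id, cultural_identity(segs), weight = ag$weight, type = ag$type)
  })
  population(agents)
}

#' Write an attitude matrix as CSV
#'
#' One header row and one leading column of agent ids. `digits = 2` gives
#' the two-decimal display mode; the default writes full precision.
#'
#' @param mat A matrix from [attitude_matrix()].
#' @param path File path.
#' @param digits Optional rounding for display output.
#' @return `path`, invisibly.
#' @export
write_attitude_matrix_csv <- function(mat, path, digits = NULL) {
  if (!is.null(digits)) mat <- round(mat, digits)
  df <- data.frame(agent_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write group-attitude statistics as CSV
#'
#' Long format: one row per ordered (observer, target) group pair with the
#' weighted mean and SD, plus the observer group's population fraction.
#'
#' @param stats A `group_attitude_stats` object.
#' @param path File path.
#' @param digits Optional rounding for display output.
#' @return `path`, invisibly.
#' @export
write_group_stats_csv <- function(stats, path, digits = NULL) {
  labs <- rownames(stats$mean)
  df <- expand.grid(observer = labs, target = labs, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)
  df$mean <- stats$mean[cbind(df$observer, df$target)]
  df$sd <- stats$sd[cbind(df$observer, df$target)]
  df$observer_fraction <- stats$fraction[df$observer]
  if (!is.null(digits)) {
    for (col in c("mean", "sd", "observer_fraction")) df[[col]] <- round(df[[col]], digits)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write calibration targets as JSON
#'
#' @param target A [calibration_target()].
#' @param path File path.
#' @return `write_calibration_target_json()` returns `path` invisibly;
#'   `read_calibration_target_json()` a [calibration_target()].
#' @export
write_calibration_target_json <- function(target, path) {
  labs <- rownames(target$mean)
  to_list <- function(m) {
    stats::setNames(lapply(labs, function(g) as.list(stats::setNames(m[g, ], labs))), labs)
  }
  jsonlite::write_json(list(worldviews = labs,
                            mean = to_list(target$mean),
                            sd = to_list(target$sd),
                            fraction = as.list(target$fraction)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_target_json
#' @export
read_calibration_target_json <- function(path) {
  raw <- jsonlite::read_json(path)
  labs <- unlist(raw$worldviews)
  from_list <- function(x) {
    m <- t(vapply(labs, function(g) unlist(x[[g]])[labs], numeric(length(labs))))
    dimnames(m) <- list(labs, labs)
    m
  }
  calibration_target(from_list(raw$mean), from_list(raw$sd),
                     unlist(raw$fraction)[labs])
}

#' Read a scenario configuration file
#'
#' YAML or JSON with fields `alpha`, `epsilon`, `D`, `steps`,
#' `convergence_tol`, `seed` and an optional `terrorist` block
#' (`{M: {b, a, B}, C: {...}, A: {...}}` plus an optional `target`).
#' Missing dynamics fields fall back to the model defaults.
#'
#' @param path File path (`.yaml`/`.yml` parsed as YAML, otherwise JSON).
#' @return A list with `params` ([threat_params()]), `grid`
#'   ([position_grid()]), `terrorist` ([agent()]) and `seed`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path)
  }
  pick <- function(name, default) if (is.null(raw[[name]])) default else raw[[name]]
  params <- threat_params(alpha = pick("alpha", 0.5),
                          epsilon = pick("epsilon", 0.05),
                          steps = pick("steps", 50),
                          convergence_tol = pick("convergence_tol", 1e-6))
  grid <- position_grid(pick("D", 400))
  terrorist <- if (is.null(raw$terrorist)) {
    make_terrorist()
  } else {
    tr <- raw$terrorist
    wv <- setdiff(names(tr), "target")
    target <- if (is.null(tr$target)) "M" else tr$target
    segs <- lapply(tr[wv], function(s) acceptance_segment(s$b, s$a, s$B))
    ident <- cultural_identity(segs)
    if (group_of(ident) != target) {
      stop("scenario terrorist identity does not claim the target worldview",
           call. = FALSE)
    }
    agent("terrorist", ident, weight = 1, type = "terrorist")
  }
  list(params = params, grid = grid, terrorist = terrorist,
       seed = pick("seed", NULL))
}

#' Write trajectory outputs as CSV/JSON
#'
#' `write_trajectory_csv()` writes the per-step reaction records and the
#' per-step group statistics; `write_evolution_json()` writes an
#' [classify_evolutions()] summary.
#'
#' @param traj A `threat_trajectory`.
#' @param records_path,stats_path,path Output paths.
#' @param summary An `evolution_summary`.
#' @return The last path written, invisibly.
#' @export
write_trajectory_csv <- function(traj, records_path, stats_path) {
  utils::write.csv(traj$records, records_path, row.names = FALSE, quote = FALSE)
  labs <- rownames(traj$stats[[1L]]$mean)
  rows <- do.call(rbind, lapply(seq_along(traj$stats), function(t) {
    st <- traj$stats[[t]]
    df <- expand.grid(observer = labs, target = labs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
    df$step <- t - 1L
    df$mean <- st$mean[cbind(df$observer, df$target)]
    df$sd <- st$sd[cbind(df$observer, df$target)]
    df
  }))
  utils::write.csv(rows[, c("step", "observer", "target", "mean", "sd")],
                   stats_path, row.names = FALSE, quote = FALSE)
  invisible(stats_path)
}

#' @rdname write_trajectory_csv
#' @export
write_evolution_json <- function(summary, path) {
  jsonlite::write_json(
    list(per_agent_delta = as.list(summary$per_agent_delta),
         classification = as.list(summary$classification),
         counts = as.list(summary$counts),
         pct_weight = as.list(summary$pct_weight),
         pct_count = as.list(summary$pct_count)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
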