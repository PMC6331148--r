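#' Parameters of the threat-reaction dynamics
#'
#' @param alpha Reaction strength, in (0, 1]. Scales the contraction
#'   intensity; default 0.5.
#' @param epsilon Smallest possible margin-of-acceptance width, a small
#'   positive number; default 0.05. Margins contract toward, and never
#'   below, this width.
#' @param steps Maximum number of broadcast steps of a scenario; default 50.
#' @param convergence_tol Scenario stops early once the largest bound change
#'   in a step falls below this tolerance; default 1e-6.
#' @return An object of class `threat_params`.
#' @export
threat_params <- function(alpha = 0.5, epsilon = 0.05, steps = 50,
                          convergence_tol = 1e-6) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  if (!(epsilon > 0 && epsilon < 1)) stop("epsilon must be in (0, 1)", call. = FALSE)
  if (!(steps >= 1 && steps == round(steps))) {
    stop("steps must be a positive integer", call. = FALSE)
  }
  if (!(convergence_tol > 0)) stop("convergence_tol must be positive", call. = FALSE)
  structure(list(alpha = alpha, epsilon = epsilon, steps = as.integer(steps),
                 convergence_tol = convergence_tol), class = "threat_params")
}

#' Construct a terrorist agent
#'
#' Terrorists hold very narrow acceptance segments: very positive on the
#' worldview they claim (M by default) and very negative on the others.
#' The defaults give the claimed worldview the segment \[0.90, 1.00\] with
#' m.a.position 0.95, and the other worldviews \[-1.00, -0.90\] with
#' m.a.position -0.95 (margin widths 0.05 on every side). All values are
#' configurable; the constructor validates the segment ordering and that
#' the claimed worldview is indeed the terrorist's group.
#'
#' @param worldviews Ordered worldview labels of the run.
#' @param target The worldview claimed by the terrorist.
#' @param target_segment Numeric `(b, a, B)` for the claimed worldview.
#' @param other_segment Numeric `(b, a, B)` for every other worldview.
#' @param id Agent id.
#' @return An [agent()] with `type = "terrorist"`.
#' @export
make_terrorist <- function(worldviews = c("M", "C", "A"), target = "M",
                           target_segment = c(0.90, 0.95, 1.00),
                           other_segment = c(-1.00, -0.95, -0.90),
                           id = "terrorist") {
  if (!target %in% worldviews) stop("target must be one of the worldviews", call. = FALSE)
  segs <- lapply(stats::setNames(worldviews, worldviews), function(k) {
    v <- if (k == target) target_segment else other_segment
    acceptance_segment(v[1], v[2], v[3])
  })
  ident <- cultural_identity(segs)
  if (group_of(ident) != target) {
    stop("terrorist configuration does not make the target worldview its group",
         call. = FALSE)
  }
  agent(id, ident, weight = 1, type = "terrorist")
}

#' Intensity of the margin-of-acceptance modification
#'
#' An agent perceiving the terrorist's attitude about itself as negative is
#' threatened and contracts its margin with intensity
#' \deqn{\mu = \alpha \frac{e^{\omega^{qi}} - 1}{e^{\omega^{qi}} + 1}
#'        = \alpha \tanh(\omega^{qi}/2) \in (-\alpha\tanh(1/2),\, 0).}
#' A non-negative terrorist attitude means the agent is not scared and does
#' not react; the no-reaction marker `NA` is returned in that case.
#'
#' @param omega_qi The terrorist's attitude about the agent, in \[-1, 1\].
#'   Vectorized.
#' @param params A [threat_params()].
#' @return Numeric vector: `NA` where there is no reaction, otherwise the
#'   strictly negative intensity, bounded below by `alpha * tanh(-1/2)`.
#' @export
reaction_intensity <- function(omega_qi, params = threat_params()) {
  stopifnot(inherits(params, "threat_params"))
  ifelse(omega_qi >= 0, NA_real_, params$alpha * tanh(omega_qi / 2))
}

# One bound update of Eq-style contraction: beta <- beta + mu * (beta - a -
# epsilon * sign(beta - a)). `side` resolves sign(0) for hand-built
# zero-width margins: +1 for the upper bound, -1 for the lower, so the
# width then grows toward epsilon (the fixed point of the map).
.update_bound <- function(beta, a, mu, epsilon, side = c("upper", "lower")) {
  side <- match.arg(side)
  d <- beta - a
  sgn <- if (d > 0) 1 else if (d < 0) -1 else if (side == "upper") 1 else -1
  beta + mu * (d - epsilon * sgn)
}

#' Apply one threat-reaction step to an agent
#'
#' Computes the terrorist's attitude about the agent (direction matters:
#' the trigger is how the terrorist values the agent, not the reverse). If
#' it is non-negative the agent is returned unchanged. Otherwise the bound
#' of the agent's segment on the targeted worldview that is closest to the
#' terrorist's m.a.position (ties broken toward the upper bound) contracts:
#' \deqn{\beta(t+1) = \beta(t) + \mu\,(\beta(t) - a - \varepsilon\,
#'   \mathrm{sign}(\beta(t) - a)),}
#' which maps the margin width w to `(1 + mu) w - mu epsilon`: widths above
#' `epsilon` contract strictly toward it and `epsilon` is a fixed point.
#' Only the targeted worldview's segment changes.
#'
#' @param agent A non-terrorist [agent()].
#' @param terrorist The terrorist [agent()].
#' @param params A [threat_params()].
#' @param grid A [position_grid()].
#' @param target_worldview Worldview whose segment reacts; defaults to the
#'   terrorist's group.
#' @return A list with the updated `agent` and a one-row data frame
#'   `record` (fields `agent_id`, `terrorist_attitude`, `intensity`,
#'   `bound`, `bound_before`, `bound_after`).
#' @export
apply_threat_step <- function(agent, terrorist, params = threat_params(),
                              grid = position_grid(),
                              target_worldview = group_of(terrorist$identity)) {
  stopifnot(inherits(agent, "cidyn_agent"), inherits(terrorist, "cidyn_agent"))
  if (agent$type == "terrorist") {
    stop("apply_threat_step() applies to non-terrorist agents", call. = FALSE)
  }
  omega_qi <- identity_attitude(terrorist$identity, agent$identity, grid)
  mu <- reaction_intensity(omega_qi, params)
  seg <- agent$identity[[target_worldview]]
  if (is.na(mu)) {
    record <- data.frame(agent_id = agent$id, terrorist_attitude = omega_qi,
                         intensity = NA_real_, bound = NA_character_,
                         bound_before = NA_real_, bound_after = NA_real_,
                         stringsAsFactors = FALSE)
    return(list(agent = agent, record = record))
  }
  aq <- terrorist$identity[[target_worldview]]$a
  use_upper <- abs(seg$B - aq) <= abs(seg$b - aq)   # tie -> upper bound
  beta <- if (use_upper) seg$B else seg$b
  beta_new <- .update_bound(beta, seg$a, mu, params$epsilon,
                            if (use_upper) "upper" else "lower")
  beta_new <- min(1, max(-1, beta_new))             # growth toward epsilon capped at the axis
  new_seg <- if (use_upper) {
    acceptance_segment(seg$b, seg$a, beta_new)
  } else {
    acceptance_segment(beta_new, seg$a, seg$B)
  }
  agent$identity[[target_worldview]] <- new_seg
  record <- data.frame(agent_id = agent$id, terrorist_attitude = omega_qi,
                       intensity = mu,
                       bound = if (use_upper) "upper" else "lower",
                       bound_before = beta, bound_after = beta_new,
                       stringsAsFactors = FALSE)
  list(agent = agent, record = record)
}

#' Run a threat scenario
#'
#' A scenario is a repeated media broadcast of the terrorist's cultural
#' identity. Each step applies [apply_threat_step()] synchronously to all
#' agents (everyone reacts to the same broadcast; identities update
#' simultaneously). The terrorist's attitude about each agent is recomputed
#' every step from the agent's current identity, and — agents being
#' perfectly informed about each other's acceptance segments — the attitude
#' matrix and group statistics are recorded at t = 0 and after each step.
#' The run stops after `params$steps` steps or as soon as the largest bound
#' change falls below `params$convergence_tol`.
#'
#' @param pop A [population()] (the terrorist is passed separately and takes
#'   no part in the weight normalization).
#' @param terrorist The terrorist [agent()].
#' @param params A [threat_params()].
#' @param grid A [position_grid()].
#' @param record `"full"` records the attitude matrix and group statistics
#'   at every time point; `"states"` records only the agent states (the
#'   matrices needed by [classify_evolutions()] are then computed on
#'   demand), which is much faster for large batches of scenarios.
#' @return An object of class `threat_trajectory`: lists `states`,
#'   `matrices` and `stats` indexed by time (t = 0 first), a `records` data
#'   frame of per-agent reactions, the targeted worldview, `steps_run` and
#'   a `converged` flag.
#' @export
run_scenario <- function(pop, terrorist, params = threat_params(),
                         grid = position_grid(), record = c("full", "states")) {
  stopifnot(inherits(pop, "population"))
  record <- match.arg(record)
  wv <- group_of(terrorist$identity)
  states <- list(pop)
  full <- record == "full"
  mats <- if (full) list(attitude_matrix(pop, grid)) else NULL
  stats_l <- if (full) list(group_stats(pop, mats[[1L]])) else NULL
  recs <- vector("list", params$steps)
  current <- pop
  t <- 0L
  converged <- FALSE
  while (t < params$steps) {
    t <- t + 1L
    out <- lapply(current$agents, apply_threat_step, terrorist = terrorist,
                  params = params, grid = grid, target_worldview = wv)
    rec <- do.call(rbind, lapply(out, `[[`, "record"))
    rec$step <- t
    recs[[t]] <- rec
    current <- structure(list(agents = lapply(out, `[[`, "agent")),
                         class = "population")
    states[[t + 1L]] <- current
    if (full) {
      mats[[t + 1L]] <- attitude_matrix(current, grid)
      stats_l[[t + 1L]] <- group_stats(current, mats[[t + 1L]])
    }
    d <- abs(rec$bound_after - rec$bound_before)
    d <- d[!is.na(d)]
    if (!length(d) || max(d) < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(states = states, matrices = mats, stats = stats_l,
                 records = do.call(rbind, recs[seq_len(t)]),
                 params = params, terrorist = terrorist, grid = grid,
                 target_worldview = wv, steps_run = t, converged = converged),
            class = "threat_trajectory")
}

#' @export
print.threat_trajectory <- function(x, ...) {
  cat(sprintf("<threat_trajectory> %d agents, %d step(s)%s, target worldview %s\n",
              n_agents(x$states[[1L]]), x$steps_run,
              if (x$converged) " (converged)" else "", x$target_worldview))
  invisible(x)
}

#' Classify per-agent attitude evolutions toward the targeted group
#'
#' For every non-terrorist agent, the change between the final and initial
#' weighted mean attitude toward the non-terrorist agents of the targeted
#' group (M by default). Changes above `tol` are classified `increase`,
#' all others `decrease_or_unchanged`. Percentages are reported both
#' weighted by agent weight and as plain agent counts; each pair sums
#' to 100.
#'
#' @param traj A `threat_trajectory` from [run_scenario()] (at least two
#'   recorded states).
#' @param tol Classification tolerance on the attitude change; default 1e-9.
#' @return An object of class `evolution_summary` with fields
#'   `per_agent_delta`, `classification`, `counts`, `pct_weight`,
#'   `pct_count`.
#' @export
classify_evolutions <- function(traj, tol = 1e-9) {
  stopifnot(inherits(traj, "threat_trajectory"))
  if (length(traj$states) < 2L) {
    stop("trajectory must contain at least two recorded states", call. = FALSE)
  }
  pop0 <- traj$states[[1L]]
  keep <- agent_types(pop0) != "terrorist"
  ids <- agent_ids(pop0)[keep]
  grp <- agent_groups(pop0)[keep]
  w <- agent_weights(pop0)[keep]
  targets <- ids[grp == traj$target_worldview]
  if (!length(targets)) {
    stop(sprintf("no non-terrorist agents in targeted group %s: evolution undefined",
                 traj$target_worldview), call. = FALSE)
  }
  tw <- w[targets]
  if (is.null(traj$matrices)) {
    m0 <- attitude_matrix(traj$states[[1L]], traj$grid)
    mT <- attitude_matrix(traj$states[[length(traj$states)]], traj$grid)
  } else {
    m0 <- traj$matrices[[1L]]
    mT <- traj$matrices[[length(traj$matrices)]]
  }
  mean_to_M <- function(m, i) sum(m[i, targets] * tw) / sum(tw)
  delta <- vapply(ids, function(i) mean_to_M(mT, i) - mean_to_M(m0, i), numeric(1))
  cls <- ifelse(delta > tol, "increase", "decrease_or_unchanged")
  pct <- function(x) 100 * c(increase = sum(x[cls == "increase"]),
                             decrease_or_unchanged = sum(x[cls != "increase"])) / sum(x)
  structure(list(per_agent_delta = delta,
                 classification = stats::setNames(cls, ids),
                 counts = c(increase = sum(cls == "increase"),
                            decrease_or_unchanged = sum(cls != "increase")),
                 pct_weight = pct(w),
                 pct_count = pct(rep(1, length(ids)))),
            class = "evolution_summary")
}

#' @export
print.evolution_summary <- function(x, ...) {
  cat(sprintf(
    "<evolution_summary> increase %.1f%% / decrease-or-unchanged %.1f%% (weighted; counts %d / %d)\n",
    x$pct_weight[["increase"]], x$pct_weight[["decrease_or_unchanged"]],
    x$counts[["increase"]], x$counts[["decrease_or_unchanged"]]))
  invisible(x)
}

#' Overlap between two acceptance segments
#'
#' `min(B1, B2) - max(b1, b2)`: the (signed) length of the intersection of
#' the two acceptance segments. Positive values measure shared acceptable
#' positions (similarity); negative values the gap between disjoint
#' segments (dissimilarity).
#'
#' @param s1,s2 [acceptance_segment()] objects.
#' @return A scalar overlap.
#' @export
segment_overlap <- function(s1, s2) {
  min(s1$B, s2$B) - max(s1$b, s2$b)
}
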