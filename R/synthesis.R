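#' Prototype identity template
#'
#' The population synthesis represents each worldview group by two
#' prototype agents, an exclusive and an inclusive one. The templates make
#' the qualitative prototype descriptions quantitative (all thresholds
#' configurable):
#' * exclusive: the own-group segment lies in \[0, 1\] with width at most
#'   `excl_own_width_max`; the other worldviews have m.a.position <= 0 and
#'   at least `excl_neg_frac` of their segment below 0.
#' * inclusive: the own-group m.a.position is positive; every segment has
#'   width at least `incl_width_min` and at least `incl_mass_frac` of its
#'   length above `incl_mass_above`; the other worldviews' m.a.positions
#'   sit near zero (within `incl_other_a_range`).
#'
#' @param group Worldview label of the prototype's group.
#' @param type `"exclusive"` or `"inclusive"`.
#' @param worldviews Ordered worldview labels.
#' @param excl_own_width_max,excl_neg_frac,incl_width_min,incl_mass_above,
#'   incl_mass_frac,incl_other_a_range Quantitative template thresholds.
#' @return An object of class `prototype_template`.
#' @export
prototype_template <- function(group, type = c("exclusive", "inclusive"),
                               worldviews = c("M", "C", "A"),
                               excl_own_width_max = 0.8,
                               excl_neg_frac = 0.6,
                               incl_width_min = 0.7,
                               incl_mass_above = -0.2,
                               incl_mass_frac = 0.6,
                               incl_other_a_range = c(-0.15, 0.3)) {
  type <- match.arg(type)
  if (!group %in% worldviews) stop("group must be one of the worldviews", call. = FALSE)
  structure(list(group = group, type = type, worldviews = worldviews,
                 excl_own_width_max = excl_own_width_max,
                 excl_neg_frac = excl_neg_frac,
                 incl_width_min = incl_width_min,
                 incl_mass_above = incl_mass_above,
                 incl_mass_frac = incl_mass_frac,
                 incl_other_a_range = incl_other_a_range),
            class = "prototype_template")
}

#' The six default prototype templates
#'
#' @param worldviews Ordered worldview labels.
#' @return Named list of [prototype_template()] objects, one inclusive and
#'   one exclusive per group, in worldview order.
#' @export
default_templates <- function(worldviews = c("M", "C", "A")) {
  out <- list()
  for (g in worldviews) {
    out[[paste0(g, "_inclusive")]] <- prototype_template(g, "inclusive", worldviews)
    out[[paste0(g, "_exclusive")]] <- prototype_template(g, "exclusive", worldviews)
  }
  out
}

# Constraint check of an identity against a template; returns character
# vector of violated constraint names (empty when compliant).
.template_violations <- function(identity, template, epsilon = 0.05) {
  viol <- character(0)
  g <- template$group
  for (k in template$worldviews) {
    s <- identity[[k]]
    if (margin_l(s) < epsilon || margin_h(s) < epsilon) {
      viol <- c(viol, paste0("margin_below_epsilon:", k))
    }
  }
  if (group_of(identity) != g) viol <- c(viol, "group_membership")
  own <- identity[[g]]
  if (own$a <= 0) viol <- c(viol, "own_position_not_positive")
  if (template$type == "exclusive") {
    if (own$b < 0) viol <- c(viol, "own_segment_not_positive_side")
    if (own$B - own$b > template$excl_own_width_max) viol <- c(viol, "own_segment_too_wide")
    for (k in setdiff(template$worldviews, g)) {
      s <- identity[[k]]
      if (s$a > 0) viol <- c(viol, paste0("other_position_positive:", k))
      neg <- (min(s$B, 0) - s$b) / (s$B - s$b)
      if (neg < template$excl_neg_frac) viol <- c(viol, paste0("other_not_mostly_negative:", k))
    }
  } else {
    for (k in template$worldviews) {
      s <- identity[[k]]
      if (s$B - s$b < template$incl_width_min) viol <- c(viol, paste0("segment_too_narrow:", k))
      mass <- (s$B - max(s$b, template$incl_mass_above)) / (s$B - s$b)
      if (mass < template$incl_mass_frac) viol <- c(viol, paste0("mass_too_negative:", k))
    }
    r <- template$incl_other_a_range
    for (k in setdiff(template$worldviews, g)) {
      s <- identity[[k]]
      if (s$a < r[1] || s$a > r[2]) viol <- c(viol, paste0("other_position_out_of_range:", k))
    }
  }
  viol
}

#' Sample a prototype cultural identity
#'
#' Rejection sampling of a [cultural_identity()] satisfying a
#' [prototype_template()]'s structural constraints (all margins at least
#' `epsilon`, group membership, and the type-specific constraints). Uses
#' the current RNG state; seed externally for reproducibility.
#'
#' @param template A [prototype_template()].
#' @param epsilon Minimum margin width.
#' @param max_attempts Attempts before giving up.
#' @return A compliant [cultural_identity()].
#' @export
sample_prototype <- function(template, epsilon = 0.05, max_attempts = 1000) {
  stopifnot(inherits(template, "prototype_template"))
  g <- template$group
  last <- "none"
  for (i in seq_len(max_attempts)) {
    segs <- list()
    if (template$type == "exclusive") {
      b <- stats::runif(1, 0, 0.25)
      width <- stats::runif(1, max(2.5 * epsilon, 0.2), template$excl_own_width_max)
      B <- min(b + width, 1)
      segs[[g]] <- acceptance_segment(b, stats::runif(1, b + epsilon, B - epsilon), B)
      for (k in setdiff(template$worldviews, g)) {
        b <- stats::runif(1, -1, -0.4)
        B <- min(b + stats::runif(1, max(2.5 * epsilon, 0.2), 0.9), 0.35)
        segs[[k]] <- acceptance_segment(b, stats::runif(1, b + epsilon, min(B - epsilon, 0)), B)
      }
    } else {
      b <- stats::runif(1, -0.2, 0.15)
      B <- stats::runif(1, max(b + template$incl_width_min, 0.6), 1)
      own_a <- stats::runif(1, max(b + epsilon, 0.05), B - epsilon)
      segs[[g]] <- acceptance_segment(b, own_a, B)
      r <- template$incl_other_a_range
      for (k in setdiff(template$worldviews, g)) {
        a <- stats::runif(1, r[1], min(r[2], own_a - 1e-3))
        b <- stats::runif(1, max(-1, a - 0.45), a - epsilon)
        B <- stats::runif(1, max(b + template$incl_width_min, a + epsilon), 1)
        segs[[k]] <- acceptance_segment(b, a, B)
      }
    }
    ident <- cultural_identity(segs[template$worldviews])
    viol <- .template_violations(ident, template, epsilon)
    if (!length(viol)) return(ident)
    last <- viol[1L]
  }
  stop(sprintf("sample_prototype: no compliant identity for %s/%s after %d attempts (last violation: %s)",
               template$group, template$type, max_attempts, last), call. = FALSE)
}

#' Sample a full six-prototype population
#'
#' One inclusive and one exclusive prototype per group, with group weights
#' given by `fractions` split between the two prototypes by the inclusive
#' shares `x` (weight of the inclusive prototype = fraction * share).
#'
#' @param fractions Named group fractions summing to 1.
#' @param shares Named per-group inclusive shares in (0, 1); default 0.5.
#' @param templates List of templates from [default_templates()].
#' @param epsilon Minimum margin width.
#' @return A [population()] of six agents.
#' @export
sample_population <- function(fractions,
                              shares = stats::setNames(rep(0.5, length(fractions)),
                                                       names(fractions)),
                              templates = default_templates(names(fractions)),
                              epsilon = 0.05) {
  wv <- names(fractions)
  agents <- list()
  for (g in wv) {
    for (ty in c("inclusive", "exclusive")) {
      tpl <- templates[[paste0(g, "_", ty)]]
      w <- fractions[[g]] * if (ty == "inclusive") shares[[g]] else 1 - shares[[g]]
      agents[[paste0(g, "_", ty)]] <- agent(paste0(g, "_", ty),
                                            sample_prototype(tpl, epsilon),
                                            weight = w, type = ty)
    }
  }
  population(unname(agents), normalize = TRUE)
}

# ---- 57-dimensional encoding ------------------------------------------------

# Layout: for each group g in worldview order, prototypes (inclusive,
# exclusive); each prototype contributes (b, a, B) for each worldview in
# order (9 values for K = 3); the last K entries are the per-group
# inclusive shares. Total 6 * 3K + K = 57 for K = 3.

#' Encode a six-prototype population as a 57-vector
#'
#' The population synthesis works in a 57-dimensional space: 54 identity
#' values (6 prototypes x 9 segment values) plus the 3 per-group inclusive
#' shares. `encode_population()` and `decode_population()` are lossless
#' inverses on feasible populations; group fractions are carried externally
#' (they come from the calibration target, not the optimizer).
#'
#' @param pop A [population()] of six prototype agents (one inclusive and
#'   one exclusive per group, ids `<group>_<type>`).
#' @return Numeric vector of length `6 * 3K + K` (57 for K = 3): the
#'   identity values followed by the inclusive shares.
#' @export
encode_population <- function(pop) {
  wv <- worldviews(pop$agents[[1L]]$identity)
  types <- agent_types(pop)
  grps <- agent_groups(pop)
  ids <- agent_ids(pop)
  w <- agent_weights(pop)
  vals <- c()
  shares <- c()
  for (g in wv) {
    pair <- list()
    for (ty in c("inclusive", "exclusive")) {
      sel <- which(grps == g & types == ty)
      if (length(sel) != 1L) {
        stop(sprintf("population must hold exactly one %s prototype of group %s", ty, g),
             call. = FALSE)
      }
      ag <- pop$agents[[sel]]
      for (k in wv) {
        s <- ag$identity[[k]]
        vals <- c(vals, s$b, s$a, s$B)
      }
      pair[[ty]] <- w[[sel]]
    }
    shares <- c(shares, pair$inclusive / (pair$inclusive + pair$exclusive))
  }
  c(vals, shares)
}

#' @rdname encode_population
#' @param vec A 57-vector (54 identity values + 3 inclusive shares); run
#'   [repair_constraints()] first if it may be infeasible.
#' @param fractions Named group fractions (worldview order fixes the
#'   decoding order).
#' @param epsilon Minimum margin width (validated, not altered).
#' @return `decode_population()`: a [population()] of six agents.
#' @export
decode_population <- function(vec, fractions, epsilon = 0.05) {
  wv <- names(fractions)
  K <- length(wv)
  if (length(vec) != 6 * 3 * K + K) {
    stop(sprintf("expected a vector of length %d, got %d", 6 * 3 * K + K, length(vec)),
         call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1", call. = FALSE)
  agents <- list()
  idx <- 1L
  shares <- vec[(length(vec) - K + 1):length(vec)]
  si <- 1L
  for (g in wv) {
    x <- shares[si]
    si <- si + 1L
    if (!(x > 0 && x < 1)) {
      stop(sprintf("inclusive share for group %s must lie in (0, 1), got %g", g, x),
           call. = FALSE)
    }
    for (ty in c("inclusive", "exclusive")) {
      segs <- list()
      for (k in wv) {
        segs[[k]] <- acceptance_segment(vec[idx], vec[idx + 1L], vec[idx + 2L])
        idx <- idx + 3L
      }
      w <- fractions[[g]] * if (ty == "inclusive") x else 1 - x
      agents[[length(agents) + 1L]] <- agent(paste0(g, "_", ty),
                                             cultural_identity(segs),
                                             weight = w, type = ty)
    }
  }
  population(agents)
}

#' Repair a 57-vector into the feasible region
#'
#' Projects an arbitrary optimizer iterate onto the feasible encoding:
#' identity values are clipped to \[-1, 1\] and each worldview triple
#' sorted ascending into (b, a, B); margins below `epsilon` are widened
#' symmetrically around the m.a.position (which is first pulled into
#' \[-1 + epsilon, 1 - epsilon\] so the widening stays on the axis); group
#' membership is re-imposed by minimally shifting the own-group
#' m.a.position above the others (tie-break offset 1e-6) and above zero;
#' inclusive shares are clipped to \[0.01, 0.99\] so no prototype gets
#' weight zero. The repair is idempotent.
#'
#' @param vec A numeric vector of length 57.
#' @param worldviews Ordered worldview labels.
#' @param epsilon Minimum margin width.
#' @return A feasible vector of the same length.
#' @export
repair_constraints <- function(vec, worldviews = c("M", "C", "A"), epsilon = 0.05) {
  K <- length(worldviews)
  n_id <- 6 * 3 * K
  stopifnot(length(vec) == n_id + K)
  out <- vec
  proto <- 0L
  for (g in worldviews) {
    for (ty in c("inclusive", "exclusive")) {
      base <- proto * 3 * K
      proto <- proto + 1L
      a_vals <- numeric(K)
      trip <- vector("list", K)
      for (ki in seq_len(K)) {
        i0 <- base + (ki - 1L) * 3L + 1L
        v <- sort(pmin(pmax(out[i0:(i0 + 2L)], -1), 1))
        b <- v[1]; a <- v[2]; B <- v[3]
        a <- min(max(a, -1 + epsilon), 1 - epsilon)
        b <- min(b, a - epsilon)
        B <- max(B, a + epsilon)
        trip[[ki]] <- c(b, a, B)
        a_vals[ki] <- a
      }
      gi <- match(g, worldviews)
      amax_other <- max(a_vals[-gi])
      ao <- a_vals[gi]
      if (ao <= amax_other) ao <- amax_other + 1e-6
      ao <- min(max(ao, 0.01), 1 - epsilon)
      if (ao <= amax_other) {
        a_vals[-gi] <- pmin(a_vals[-gi], ao - 1e-6)
      }
      a_vals[gi] <- ao
      for (ki in seq_len(K)) {
        b <- min(trip[[ki]][1], a_vals[ki] - epsilon)
        B <- max(trip[[ki]][3], a_vals[ki] + epsilon)
        i0 <- base + (ki - 1L) * 3L + 1L
        out[i0:(i0 + 2L)] <- c(b, a_vals[ki], B)
      }
    }
  }
  sh <- (n_id + 1L):length(out)
  out[sh] <- pmin(pmax(out[sh], 0.01), 0.99)
  out
}

#' Calibration error of a population against a target
#'
#' The absolute error is the sum, over the 9 ordered group pairs, of the
#' absolute differences of the simulated and target mean attitudes plus
#' the absolute differences of the standard deviations (18 terms). The
#' per-term relative error divides by `max(|target value|, floor)`; the
#' floor (default 0.05 on the normalized attitude scale) prevents blow-up
#' for near-zero targets. Undefined target cells (`NA`) are excluded from
#' all three summaries.
#'
#' @param pop A [population()].
#' @param target A [calibration_target()].
#' @param grid A [position_grid()].
#' @param floor Relative-error denominator floor.
#' @param include_self Passed to [group_stats()].
#' @return Named numeric vector `(absolute_error, relative_avg_error,
#'   relative_max_error)`.
#' @export
population_error <- function(pop, target, grid = position_grid(),
                             floor = 0.05, include_self = TRUE) {
  st <- group_stats(pop, attitude_matrix(pop, grid), include_self = include_self)
  labs <- rownames(target$mean)
  sim <- c(st$mean[labs, labs], st$sd[labs, labs])
  dat <- c(target$mean[labs, labs], target$sd[labs, labs])
  ok <- !is.na(dat) & !is.na(sim)
  d <- abs(sim[ok] - dat[ok])
  rel <- d / pmax(abs(dat[ok]), floor)
  c(absolute_error = sum(d),
    relative_avg_error = mean(rel),
    relative_max_error = max(rel))
}

#' Configuration of the particle swarm optimizer
#'
#' Global-best PSO hyperparameters. The defaults are tuned for the
#' 57-dimensional population encoding: cognitive = social = 1.49 with the
#' inertia decaying linearly from 0.9 to 0.3 over the run, a velocity
#' clamp of 0.1, a template-sampled pre-screen of five candidate
#' populations per particle, a prototype-reseeding escape move, and a
#' final intensification phase (see [pso_calibrate()]).
#'
#' @param seed Integer seed (mandatory: the calibration is stochastic and
#'   must be reproducible).
#' @param swarm_size Number of particles.
#' @param iterations Number of velocity/position updates.
#' @param inertia Length-2 numeric: inertia at the first and last
#'   iteration (linear schedule); a single value keeps it constant.
#' @param cognitive,social Velocity-update coefficients.
#' @param keep_top Number of distinct best populations to return.
#' @param vmax Per-dimension velocity clamp of the exploration phase.
#' @param prescreen Number of template-sampled populations to draw
#'   initially, of which the `swarm_size` best by error become the swarm
#'   (a screen-then-optimize warm start); default five per particle.
#' @param intensify_after Fraction of the iterations after which the
#'   swarm is re-centered on the incumbent for local refinement (with
#'   velocity clamp `vmax_intense`); set to 1 to disable.
#' @param vmax_intense Velocity clamp of the intensification phase.
#' @param escape Re-seed one prototype of the worst particle from its
#'   template each exploration iteration (escape move for prototypes
#'   stuck in a wrong configuration).
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(seed, swarm_size = 40, iterations = 500,
                       inertia = c(0.9, 0.3), cognitive = 1.49, social = 1.49,
                       keep_top = 120, vmax = 0.1,
                       prescreen = 5 * swarm_size,
                       intensify_after = 0.66, vmax_intense = 0.03,
                       escape = TRUE) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory", call. = FALSE)
  if (length(inertia) == 1L) inertia <- c(inertia, inertia)
  vals <- c(swarm_size, iterations, inertia, cognitive, social, keep_top,
            vmax, vmax_intense, intensify_after)
  if (any(vals <= 0)) stop("all PSO parameters must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed), swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social,
                 keep_top = as.integer(keep_top), vmax = vmax,
                 prescreen = as.integer(prescreen),
                 intensify_after = intensify_after,
                 vmax_intense = vmax_intense, escape = isTRUE(escape)),
            class = "pso_config")
}

#' Calibrate populations to a target by particle swarm optimization
#'
#' Global-best PSO over the 57-dimensional population encoding. Particles
#' are seeded from template-sampled prototype populations pre-screened by
#' error, every iterate is projected into the feasible region by
#' [repair_constraints()] before evaluation, and the objective is the
#' absolute calibration error of [population_error()]. Velocities follow
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with per-dimension
#' uniform `r1, r2`, a linearly decaying inertia `w` and clamping at
#' `vmax`. Two refinements make the search reliable on this landscape:
#' during exploration the worst particle is re-proposed each iteration as
#' the incumbent with one prototype re-sampled from its template (an
#' escape move for prototypes stuck in a wrong configuration), and after
#' `intensify_after` of the iterations the swarm is re-centered on the
#' incumbent with a small velocity clamp for local refinement (the
#' incumbent itself is carried over, so the best-so-far error never
#' regresses). The run is a deterministic function of the seed.
#' Non-convergence is a quality outcome (visible in the returned errors
#' and trace), not an error.
#'
#' @param target A [calibration_target()]; its group fractions fix the
#'   prototype weights.
#' @param config A [pso_config()].
#' @param grid A [position_grid()].
#' @param templates Prototype templates for swarm seeding.
#' @param epsilon Minimum margin width.
#' @param floor Relative-error floor of [population_error()].
#' @return An object of class `pso_calibration`: `populations` (the
#'   `keep_top` distinct all-time per-particle bests, best first — the
#'   exploration phase keeps these diverse while the incumbent lineage is
#'   refined), `errors` (data frame of their error triples), `trace`
#'   (best absolute error per iteration, non-increasing), and the
#'   `config`.
#' @export
pso_calibrate <- function(target, config, grid = position_grid(),
                          templates = default_templates(names(target$fraction)),
                          epsilon = 0.05, floor = 0.05) {
  stopifnot(inherits(target, "calibration_target"), inherits(config, "pso_config"))
  set.seed(config$seed)
  fractions <- target$fraction
  wv <- names(fractions)
  K <- length(wv)
  evaluate <- function(v) {
    pop <- decode_population(v, fractions, epsilon)
    population_error(pop, target, grid, floor = floor)
  }
  n_init <- max(config$swarm_size, config$prescreen)
  X <- vapply(seq_len(n_init), function(i) {
    shares <- stats::setNames(stats::runif(K, 0.1, 0.9), wv)
    repair_constraints(encode_population(
      sample_population(fractions, shares, templates, epsilon)), wv, epsilon)
  }, numeric(6 * 3 * K + K))
  errs <- apply(X, 2, function(v) evaluate(v)[["absolute_error"]])
  if (n_init > config$swarm_size) {
    keep <- order(errs)[seq_len(config$swarm_size)]
    X <- X[, keep, drop = FALSE]
    errs <- errs[keep]
  }
  dim_n <- nrow(X)
  S <- ncol(X)
  V <- matrix(stats::runif(dim_n * S, -0.05, 0.05), dim_n, S)
  P <- X          # working personal bests (reset when the swarm recenters)
  p_err <- errs
  A <- X          # all-time personal bests: never regress, returned at the end
  a_err <- errs
  trace <- numeric(config$iterations)
  vmax <- config$vmax
  intensified <- FALSE
  reseed_prototype <- function(v) {
    # replace one random prototype block (9 values) by a fresh template draw
    pk <- sample.int(6, 1)
    idx <- ((pk - 1L) * 3L * K + 1L):(pk * 3L * K)
    grp <- wv[ceiling(pk / 2)]
    ty <- if (pk %% 2L == 1L) "inclusive" else "exclusive"
    id <- sample_prototype(templates[[paste0(grp, "_", ty)]], epsilon)
    v[idx] <- unlist(lapply(wv, function(k) c(id[[k]]$b, id[[k]]$a, id[[k]]$B)),
                     use.names = FALSE)
    v
  }
  for (it in seq_len(config$iterations)) {
    if (!intensified && it > config$intensify_after * config$iterations) {
      intensified <- TRUE
      gb <- A[, which.min(a_err)]
      X <- gb + matrix(stats::rnorm(dim_n * S, 0, 0.05), dim_n, S)
      X[, 1L] <- gb                     # the incumbent survives recentering
      X <- apply(X, 2, repair_constraints, worldviews = wv, epsilon = epsilon)
      V <- matrix(stats::runif(dim_n * S, -0.01, 0.01), dim_n, S)
      p_err <- apply(X, 2, function(v) evaluate(v)[["absolute_error"]])
      P <- X
      vmax <- config$vmax_intense
    }
    w <- config$inertia[1] +
      (config$inertia[2] - config$inertia[1]) * (it - 1) / max(1, config$iterations - 1)
    g_idx <- which.min(p_err)
    r1 <- matrix(stats::runif(dim_n * S), dim_n, S)
    r2 <- matrix(stats::runif(dim_n * S), dim_n, S)
    V <- w * V +
      config$cognitive * r1 * (P - X) +
      config$social * r2 * (P[, g_idx] - X)
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    if (config$escape && !intensified) {
      worst <- which.max(p_err)
      X[, worst] <- reseed_prototype(P[, g_idx])
      V[, worst] <- stats::runif(dim_n, -0.05, 0.05)
    }
    X <- apply(X, 2, repair_constraints, worldviews = wv, epsilon = epsilon)
    errs <- apply(X, 2, function(v) evaluate(v)[["absolute_error"]])
    better <- errs < p_err
    P[, better] <- X[, better]
    p_err[better] <- errs[better]
    best_ever <- errs < a_err
    A[, best_ever] <- X[, best_ever]
    a_err[best_ever] <- errs[best_ever]
    trace[it] <- min(a_err)
  }
  ord <- order(a_err)
  cols <- ord[!duplicated(lapply(ord, function(j) A[, j]))]
  cols <- cols[seq_len(min(config$keep_top, length(cols)))]
  pops <- lapply(cols, function(j) decode_population(A[, j], fractions, epsilon))
  errors <- do.call(rbind, lapply(pops, population_error, target = target,
                                  grid = grid, floor = floor))
  errors <- as.data.frame(errors)
  structure(list(populations = pops, errors = errors, trace = trace,
                 best = pops[[1L]], config = config, target = target),
            class = "pso_calibration")
}

#' @export
print.pso_calibration <- function(x, ...) {
  cat(sprintf(
    "<pso_calibration> %d population(s) kept; best absolute error %.4f (relative avg %.3f, max %.3f)\n",
    length(x$populations), x$errors$absolute_error[1L],
    x$errors$relative_avg_error[1L], x$errors$relative_max_error[1L]))
  invisible(x)
}
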