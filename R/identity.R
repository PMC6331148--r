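#' Acceptance segment on a cultural worldview
#'
#' An acceptance segment is the latitude of acceptance of one agent on one
#' cultural worldview: the interval `[lower, upper]` of positions (on the
#' \[-1, 1\] axis) the agent finds acceptable, together with its most
#' acceptable position (`position`, the m.a.position) inside it. The
#' sub-interval `[lower, position]` is the lower margin of acceptance
#' (margin(l)), `[position, upper]` the higher margin (margin(h)).
#'
#' @param lower Lower bound b of the acceptable interval, in \[-1, 1\].
#' @param position Most acceptable position a, with `lower <= position <= upper`.
#' @param upper Upper bound B of the acceptable interval, in \[-1, 1\].
#'
#' @return An object of class `acceptance_segment` with fields `b`, `a`, `B`.
#' @seealso [position_attitude()], [cultural_identity()]
#' @examples
#' seg <- acceptance_segment(-0.85, -0.5, -0.15)
#' margin_h(seg)
#' @export
acceptance_segment <- function(lower, position, upper) {
  if (!is.numeric(lower) || !is.numeric(position) || !is.numeric(upper) ||
      length(lower) != 1L || length(position) != 1L || length(upper) != 1L ||
      anyNA(c(lower, position, upper))) {
    stop("acceptance_segment() expects three finite scalars (lower, position, upper)",
         call. = FALSE)
  }
  if (!(-1 <= lower && lower <= position && position <= upper && upper <= 1)) {
    stop(sprintf(
      "invalid acceptance segment: need -1 <= lower <= position <= upper <= 1, got (%g, %g, %g)",
      lower, position, upper), call. = FALSE)
  }
  structure(list(b = lower, a = position, B = upper), class = "acceptance_segment")
}

#' @export
print.acceptance_segment <- function(x, ...) {
  cat(sprintf("<acceptance_segment> [%.3f, %.3f] m.a.position %.3f\n", x$b, x$B, x$a))
  invisible(x)
}

#' Margin widths of an acceptance segment
#'
#' `margin_l()` is the width of the lower margin of acceptance (a - b),
#' `margin_h()` the width of the higher margin (B - a).
#'
#' @param segment An [acceptance_segment()].
#' @return A non-negative scalar.
#' @export
margin_l <- function(segment) segment$a - segment$b

#' @rdname margin_l
#' @export
margin_h <- function(segment) segment$B - segment$a

#' Cultural identity: one acceptance segment per worldview
#'
#' A cultural identity is the collection of an agent's acceptance segments
#' for the K cultural worldviews present in the environment (by default
#' M = Muslim, C = Christian, A = areligious). The order of the worldview
#' labels is fixed for a run and is used for deterministic iteration and
#' tie-breaking.
#'
#' @param ... Named [acceptance_segment()] objects, one per worldview
#'   (e.g. `M = seg1, C = seg2, A = seg3`), or a single named list of them.
#' @return An object of class `cultural_identity`: a named list of segments,
#'   with the worldview ordering recorded in attribute `worldviews`.
#' @seealso [group_of()], [identity_attitude()]
#' @export
cultural_identity <- function(...) {
  segs <- list(...)
  if (length(segs) == 1L && is.list(segs[[1L]]) &&
      !inherits(segs[[1L]], "acceptance_segment")) {
    segs <- segs[[1L]]
  }
  labs <- names(segs)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs)) {
    stop("cultural_identity() requires uniquely named segments, one per worldview",
         call. = FALSE)
  }
  if (length(segs) < 2L) {
    stop("a cultural identity needs at least two worldviews", call. = FALSE)
  }
  ok <- vapply(segs, inherits, logical(1), "acceptance_segment")
  if (!all(ok)) {
    stop("all components of a cultural identity must be acceptance_segment objects",
         call. = FALSE)
  }
  structure(segs, class = "cultural_identity", worldviews = labs)
}

#' @export
print.cultural_identity <- function(x, ...) {
  cat("<cultural_identity> group:", group_of(x), "\n")
  for (k in worldviews(x)) {
    s <- x[[k]]
    cat(sprintf("  %s: [%.3f, %.3f] a = %.3f\n", k, s$b, s$B, s$a))
  }
  invisible(x)
}

#' Worldview labels of a cultural identity
#'
#' @param identity A [cultural_identity()].
#' @return Character vector of worldview labels in their fixed order.
#' @export
worldviews <- function(identity) attr(identity, "worldviews")

#' Cultural group of an identity
#'
#' An agent's cultural group is the worldview for which its most acceptable
#' position is the highest. Ties are broken by the fixed worldview ordering
#' (first label wins), so the result is deterministic.
#'
#' @param identity A [cultural_identity()].
#' @return A single worldview label.
#' @examples
#' id <- cultural_identity(
#'   M = acceptance_segment(-0.2, 0.8, 0.9),
#'   C = acceptance_segment(-0.5, -0.2, 0.1),
#'   A = acceptance_segment(-0.3, 0.1, 0.4)
#' )
#' group_of(id)  # "M"
#' @export
group_of <- function(identity) {
  a <- vapply(identity, function(s) s$a, numeric(1))
  worldviews(identity)[which.max(a)]
}

#' An agent of the population
#'
#' @param id Unique agent identifier (string).
#' @param identity The agent's [cultural_identity()].
#' @param weight Share of the population the agent represents, in (0, 1].
#'   Prototype agents stand for population fractions, so weights of the
#'   non-terrorist agents of a [population()] must sum to one.
#' @param type One of `"exclusive"`, `"inclusive"`, `"terrorist"`. Terrorist
#'   agents are excluded from group statistics and evolution classification.
#' @return An object of class `cidyn_agent`.
#' @export
agent <- function(id, identity, weight = 1,
                  type = c("exclusive", "inclusive", "terrorist")) {
  type <- match.arg(type)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("agent id must be a non-empty string", call. = FALSE)
  }
  if (!inherits(identity, "cultural_identity")) {
    stop("identity must be a cultural_identity", call. = FALSE)
  }
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight <= 0 || weight > 1) {
    stop("agent weight must be in (0, 1]", call. = FALSE)
  }
  if (type != "terrorist") {
    a <- vapply(identity, function(s) s$a, numeric(1))
    if (!any(a > 0)) {
      stop("population agents must have a positive m.a.position on at least one worldview",
           call. = FALSE)
    }
  }
  structure(list(id = id, identity = identity, weight = weight, type = type),
            class = "cidyn_agent")
}

#' @export
print.cidyn_agent <- function(x, ...) {
  cat(sprintf("<agent> %s (%s, weight %.3f, group %s)\n",
              x$id, x$type, x$weight, group_of(x$identity)))
  invisible(x)
}

#' A weighted population of agents
#'
#' @param agents A list of [agent()] objects sharing the same worldview set.
#'   Non-terrorist weights must sum to 1 (tolerance 1e-9) unless
#'   `normalize = TRUE`, in which case they are rescaled.
#' @param normalize Rescale non-terrorist weights to sum to one.
#' @return An object of class `population` with component `agents`.
#' @export
population <- function(agents, normalize = FALSE) {
  if (!length(agents) || !all(vapply(agents, inherits, logical(1), "cidyn_agent"))) {
    stop("population() expects a non-empty list of agents", call. = FALSE)
  }
  ids <- vapply(agents, function(x) x$id, character(1))
  if (anyDuplicated(ids)) {
    stop("agent ids must be unique, duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  wv <- lapply(agents, function(x) worldviews(x$identity))
  if (!all(vapply(wv, identical, logical(1), wv[[1L]]))) {
    stop("all agents must share the same ordered worldview set", call. = FALSE)
  }
  non_terror <- vapply(agents, function(x) x$type != "terrorist", logical(1))
  w <- vapply(agents, function(x) x$weight, numeric(1))
  total <- sum(w[non_terror])
  if (normalize) {
    if (total <= 0) stop("cannot normalize: no non-terrorist weight", call. = FALSE)
    agents[non_terror] <- lapply(agents[non_terror], function(x) {
      x$weight <- x$weight / total
      x
    })
  } else if (abs(total - 1) > 1e-9) {
    stop(sprintf("non-terrorist agent weights must sum to 1 (got %.12f); use normalize = TRUE",
                 total), call. = FALSE)
  }
  structure(list(agents = agents), class = "population")
}

#' @export
print.population <- function(x, ...) {
  g <- agent_groups(x)
  cat(sprintf("<population> %d agents (%s)\n", length(x$agents),
              paste(sprintf("%s: %d", names(table(g)), table(g)), collapse = ", ")))
  invisible(x)
}

#' Population accessors
#'
#' `agent_ids()`, `agent_weights()`, `agent_groups()` and `agent_types()`
#' return the per-agent vectors in population order; `n_agents()` the
#' number of agents.
#'
#' @param pop A [population()].
#' @return A vector with one entry per agent.
#' @export
agent_ids <- function(pop) vapply(pop$agents, function(x) x$id, character(1))

#' @rdname agent_ids
#' @export
agent_weights <- function(pop) {
  stats::setNames(vapply(pop$agents, function(x) x$weight, numeric(1)), agent_ids(pop))
}

#' @rdname agent_ids
#' @export
agent_groups <- function(pop) {
  stats::setNames(vapply(pop$agents, function(x) group_of(x$identity), character(1)),
                  agent_ids(pop))
}

#' @rdname agent_ids
#' @export
agent_types <- function(pop) {
  stats::setNames(vapply(pop$agents, function(x) x$type, character(1)), agent_ids(pop))
}

#' @rdname agent_ids
#' @export
n_agents <- function(pop) length(pop$agents)

#' Regular grid of positions on the worldview axis
#'
#' The position axis \[-1, 1\] is divided regularly into `resolution` values
#' p_d, endpoints included, so the spacing is `2 / (resolution - 1)`. The
#' default resolution D = 400 is the one used throughout the model.
#'
#' @param resolution Number of grid points D (at least 2).
#' @return An object of class `position_grid` with fields `resolution` and
#'   `points`.
#' @export
position_grid <- function(resolution = 400) {
  if (!is.numeric(resolution) || length(resolution) != 1L || is.na(resolution) ||
      resolution < 2 || resolution != round(resolution)) {
    stop("grid resolution must be an integer >= 2", call. = FALSE)
  }
  resolution <- as.integer(resolution)
  structure(list(resolution = resolution,
                 points = seq(-1, 1, length.out = resolution)),
            class = "position_grid")
}

#' @export
print.position_grid <- function(x, ...) {
  cat(sprintf("<position_grid> D = %d, spacing %.5f\n",
              x$resolution, 2 / (x$resolution - 1)))
  invisible(x)
}
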