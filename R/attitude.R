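#' Attitude of an observer about a single position
#'
#' The three-branch attitude kernel of the model. A position strictly inside
#' the observer's acceptance segment is valued 1; a position exactly at a
#' bound is valued 0; outside, the attitude decreases with the distance to
#' the nearest bound, with an asymptote at -1, and the decrease is faster
#' when the margin of acceptance on that side is smaller:
#' \deqn{\omega(p) = \tanh(y/2), \quad y = 1 + \frac{p - a}{a - b} \;(p < b),
#' \qquad y = 1 + \frac{a - p}{B - a} \;(p > B).}
#' (`tanh(y/2)` equals `(e^y - 1)/(e^y + 1)`.)
#'
#' A degenerate margin (zero width) on the side being evaluated gives the
#' limit value -1: the decline becomes infinitely steep as the margin
#' shrinks. No error is raised.
#'
#' @param segment The observer's [acceptance_segment()].
#' @param p Numeric vector of positions; values outside \[-1, 1\] are
#'   accepted and handled by the same formulas.
#' @return Numeric vector of attitudes in \[-1, 1\], same length as `p`.
#' @examples
#' seg <- acceptance_segment(-0.85, -0.5, -0.15)
#' position_attitude(seg, c(-0.5, -0.15, 0.2))
#' @export
position_attitude <- function(segment, p) {
  if (!inherits(segment, "acceptance_segment")) {
    stop("segment must be an acceptance_segment", call. = FALSE)
  }
  b <- segment$b
  a <- segment$a
  B <- segment$B
  out <- numeric(length(p))      # bound hits (p == b or p == B) stay 0
  out[p > b & p < B] <- 1
  lo <- p < b
  if (any(lo)) {
    ml <- a - b
    out[lo] <- if (ml == 0) -1 else tanh((1 + (p[lo] - a) / ml) / 2)
  }
  hi <- p > B
  if (any(hi)) {
    mh <- B - a
    out[hi] <- if (mh == 0) -1 else tanh((1 + (a - p[hi]) / mh) / 2)
  }
  out
}

#' Attitude of an observer about another acceptance segment
#'
#' The observer's single-position attitudes are averaged over the grid
#' points that the target finds acceptable:
#' \deqn{\omega^{ij}_k = \frac{\sum_d \omega_k^i(p_d)\,\max(\omega_k^j(p_d), 0)}
#' {\sum_d \max(\omega_k^j(p_d), 0)}.}
#' Because the target's kernel is 1 strictly inside its segment and at most
#' 0 elsewhere, this is the mean of the observer's kernel over the grid
#' points strictly inside the target segment. It equals 1 exactly when all
#' of those points also lie strictly inside the observer's segment.
#'
#' @param observer,target [acceptance_segment()] objects on the same worldview.
#' @param grid A [position_grid()].
#' @return A scalar attitude in \[-1, 1\].
#' @examples
#' g <- position_grid(400)
#' s <- acceptance_segment(-0.85, -0.5, -0.15)
#' segment_attitude(s, s, g)  # 1: identical segments
#' @export
segment_attitude <- function(observer, target, grid) {
  stopifnot(inherits(grid, "position_grid"))
  w <- pmax(position_attitude(target, grid$points), 0)
  sw <- sum(w)
  if (sw == 0) {
    stop(sprintf(
      "target segment [%g, %g] unresolvable at resolution D = %d: no grid point strictly inside; raise D",
      target$b, target$B, grid$resolution), call. = FALSE)
  }
  sum(position_attitude(observer, grid$points) * w) / sw
}

#' Attitude of an observer about a whole cultural identity
#'
#' The average, over the K worldviews, of the observer's segment attitudes
#' about the target's acceptance segments. An agent's attitude about its own
#' cultural identity is 1.
#'
#' @param observer,target [cultural_identity()] objects over the same
#'   ordered worldview set.
#' @param grid A [position_grid()].
#' @return A scalar attitude in \[-1, 1\].
#' @export
identity_attitude <- function(observer, target, grid) {
  if (!identical(worldviews(observer), worldviews(target))) {
    stop("observer and target identities must share the same ordered worldview set",
         call. = FALSE)
  }
  vals <- vapply(worldviews(observer), function(k) {
    tryCatch(segment_attitude(observer[[k]], target[[k]], grid),
             error = function(e) {
               stop(sprintf("worldview %s: %s", k, conditionMessage(e)), call. = FALSE)
             })
  }, numeric(1))
  mean(vals)
}

# Per-agent position-attitude profiles: for each worldview a list with the
# n x D kernel matrix and its positive part. Shared by attitude_matrix().
.population_profiles <- function(pop, grid) {
  wv <- worldviews(pop$agents[[1L]]$identity)
  D <- grid$resolution
  lapply(stats::setNames(wv, wv), function(k) {
    prof <- t(vapply(pop$agents,
                     function(ag) position_attitude(ag$identity[[k]], grid$points),
                     numeric(D)))
    list(prof = prof, wpos = pmax(prof, 0))
  })
}

#' Pairwise attitude matrix of a population
#'
#' Entry (i, j) is agent i's attitude about agent j's cultural identity;
#' the diagonal is forced to exactly 1 (self-attitude is maximal by
#' definition of the model).
#'
#' @param pop A [population()].
#' @param grid A [position_grid()].
#' @return An N x N numeric matrix with agent ids as dimnames.
#' @export
attitude_matrix <- function(pop, grid = position_grid()) {
  stopifnot(inherits(pop, "population"), inherits(grid, "position_grid"))
  ids <- agent_ids(pop)
  n <- length(ids)
  profiles <- .population_profiles(pop, grid)
  acc <- matrix(0, n, n)
  for (k in names(profiles)) {
    pk <- profiles[[k]]
    rs <- rowSums(pk$wpos)
    if (any(rs == 0)) {
      bad <- ids[rs == 0][1L]
      stop(sprintf(
        "worldview %s: segment of agent %s unresolvable at resolution D = %d; raise D",
        k, bad, grid$resolution), call. = FALSE)
    }
    acc <- acc + (pk$prof %*% t(pk$wpos)) / matrix(rs, n, n, byrow = TRUE)
  }
  mat <- acc / length(profiles)
  diag(mat) <- 1
  dimnames(mat) <- list(ids, ids)
  mat
}

# Weighted mean / population-style weighted SD.
.wmean <- function(x, w) sum(w * x) / sum(w)
.wsd <- function(x, w) {
  m <- .wmean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' Group-to-group attitude statistics of a population
#'
#' For every ordered pair (observer group G, target group H) the weighted
#' mean and weighted standard deviation of the attitudes of agents of G
#' about agents of H, with pair weight `weight_i * weight_j`. Terrorist
#' agents are excluded. Self-pairs (i = j, attitude exactly 1) are included
#' in the in-group cells by default, because self-attitude is part of the
#' model; `include_self = FALSE` exposes the exclude-self alternative for
#' sensitivity analysis. The SD is population-style (denominator = total
#' weight). Cells involving an empty group are `NA` (undefined, not zero).
#'
#' @param pop A [population()].
#' @param matrix The [attitude_matrix()] computed from `pop`.
#' @param include_self Include i = j pairs in in-group cells.
#' @return An object of class `group_attitude_stats`: list with `mean` and
#'   `sd` (K x K matrices, rows = observer group, columns = target group)
#'   and `fraction` (named per-group weight totals, summing to 1).
#' @export
group_stats <- function(pop, matrix, include_self = TRUE) {
  stopifnot(inherits(pop, "population"))
  keep <- agent_types(pop) != "terrorist"
  ids <- agent_ids(pop)[keep]
  grp <- agent_groups(pop)[keep]
  w <- agent_weights(pop)[keep]
  labs <- worldviews(pop$agents[[1L]]$identity)
  m <- s <- base::matrix(NA_real_, length(labs), length(labs),
                         dimnames = list(labs, labs))
  for (G in labs) {
    I <- which(grp == G)
    for (H in labs) {
      J <- which(grp == H)
      if (!length(I) || !length(J)) next
      pw <- outer(w[I], w[J])
      vals <- matrix[ids[I], ids[J], drop = FALSE]
      if (!include_self && G == H) {
        self <- outer(ids[I], ids[J], "==")
        pw[self] <- 0
        if (sum(pw) == 0) next
      }
      m[G, H] <- .wmean(as.vector(vals), as.vector(pw))
      s[G, H] <- .wsd(as.vector(vals), as.vector(pw))
    }
  }
  fraction <- vapply(stats::setNames(labs, labs),
                     function(G) sum(w[grp == G]), numeric(1))
  structure(list(mean = m, sd = s, fraction = fraction),
            class = "group_attitude_stats")
}

#' @export
print.group_attitude_stats <- function(x, digits = 3, ...) {
  cat("<group_attitude_stats> (rows: observer group, cols: target group)\n")
  cat("means:\n")
  print(round(x$mean, digits))
  cat("sds:\n")
  print(round(x$sd, digits))
  cat("fractions:", paste(sprintf("%s = %.3f", names(x$fraction), x$fraction),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a calibration target from explicit statistics
#'
#' A calibration target carries the group-attitude statistics the population
#' synthesis must reproduce: 3 x 3 means and SDs (observer group x target
#' group, on the normalized \[-1, 1\] attitude scale) plus per-group
#' population fractions.
#'
#' @param mean,sd K x K numeric matrices with identical worldview dimnames.
#' @param fraction Named per-group fractions summing to 1 (tolerance 1e-9).
#' @return An object of class `c("calibration_target", "group_attitude_stats")`.
#' @seealso [survey_stats()]
#' @export
calibration_target <- function(mean, sd, fraction) {
  mean <- as.matrix(mean)
  sd <- as.matrix(sd)
  labs <- rownames(mean)
  if (is.null(labs) || !identical(dimnames(mean), dimnames(sd)) ||
      !identical(colnames(mean), labs)) {
    stop("mean and sd must be square matrices with identical worldview dimnames",
         call. = FALSE)
  }
  if (!identical(sort(names(fraction)), sort(labs))) {
    stop("fraction must be named by the same worldview labels", call. = FALSE)
  }
  fraction <- fraction[labs]
  if (abs(sum(fraction) - 1) > 1e-9 || any(fraction < 0)) {
    stop("group fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (any(stats::na.omit(abs(as.vector(mean))) > 1) ||
      any(stats::na.omit(as.vector(sd)) < 0)) {
    stop("means must lie in [-1, 1] and sds must be non-negative", call. = FALSE)
  }
  structure(list(mean = mean, sd = sd, fraction = fraction),
            class = c("calibration_target", "group_attitude_stats"))
}
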