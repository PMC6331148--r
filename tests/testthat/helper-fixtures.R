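# Shared fixtures and generators, all built in code.

# The two agents of the worked single-position example: a shared acceptance
# segment [-0.85, -0.15] with m.a.positions -0.85 (orange) and -0.50 (green).
worked_orange <- function() acceptance_segment(-0.85, -0.85, -0.15)
worked_green <- function() acceptance_segment(-0.85, -0.50, -0.15)

# Independent oracle for the single-position attitude kernel: literal
# evaluation of (e^y - 1)/(e^y + 1) on each branch, scalar only.
oracle_position_attitude <- function(b, a, B, p) {
  if (p > b && p < B) return(1)
  if (p == b || p == B) return(0)
  y <- if (p < b) 1 + (p - a) / (a - b) else 1 + (a - p) / (B - a)
  (exp(y) - 1) / (exp(y) + 1)
}

# Independent oracle for the segment attitude: direct summation over an
# explicitly constructed regular grid of D points.
oracle_segment_attitude <- function(obs, tgt, D) {
  pts <- seq(-1, 1, length.out = D)
  wo <- vapply(pts, function(p) oracle_position_attitude(obs$b, obs$a, obs$B, p), numeric(1))
  wt <- vapply(pts, function(p) oracle_position_attitude(tgt$b, tgt$a, tgt$B, p), numeric(1))
  wt <- pmax(wt, 0)
  sum(wo * wt) / sum(wt)
}

random_segment <- function(min_width = 0.05, lo = -1, hi = 1) {
  repeat {
    v <- sort(stats::runif(3, lo, hi))
    if (v[2] - v[1] >= min_width && v[3] - v[2] >= min_width) {
      return(acceptance_segment(v[1], v[2], v[3]))
    }
  }
}

random_identity <- function(min_width = 0.05, worldviews = c("M", "C", "A")) {
  repeat {
    segs <- lapply(stats::setNames(worldviews, worldviews),
                   function(k) random_segment(min_width))
    if (any(vapply(segs, function(s) s$a, numeric(1)) > 0)) {
      return(cultural_identity(segs))
    }
  }
}

random_population <- function(n, min_width = 0.05) {
  agents <- lapply(seq_len(n), function(i) {
    agent(paste0("ag", i), random_identity(min_width), weight = 1 / n)
  })
  population(agents, normalize = TRUE)
}

# Six-agent deterministic fixture with distinct hand-picked identities
# covering all three groups.
fixture_population6 <- function() {
  seg <- acceptance_segment
  population(list(
    agent("m1", cultural_identity(M = seg(0.0, 0.5, 0.8), C = seg(-0.8, -0.4, 0.0),
                                  A = seg(-0.6, -0.2, 0.2)), weight = 0.05, type = "exclusive"),
    agent("m2", cultural_identity(M = seg(-0.3, 0.4, 0.9), C = seg(-0.5, 0.0, 0.6),
                                  A = seg(-0.4, 0.1, 0.7)), weight = 0.05, type = "inclusive"),
    agent("c1", cultural_identity(M = seg(-0.9, -0.5, -0.1), C = seg(0.1, 0.6, 0.9),
                                  A = seg(-0.7, -0.3, 0.1)), weight = 0.30, type = "exclusive"),
    agent("c2", cultural_identity(M = seg(-0.4, 0.1, 0.6), C = seg(-0.1, 0.5, 0.95),
                                  A = seg(-0.5, 0.05, 0.7)), weight = 0.30, type = "inclusive"),
    agent("a1", cultural_identity(M = seg(-0.85, -0.45, -0.05), C = seg(-0.75, -0.35, 0.05),
                                  A = seg(0.05, 0.55, 0.85)), weight = 0.15, type = "exclusive"),
    agent("a2", cultural_identity(M = seg(-0.35, 0.05, 0.55), C = seg(-0.45, 0.1, 0.65),
                                  A = seg(-0.05, 0.45, 0.9)), weight = 0.15, type = "inclusive")))
}
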