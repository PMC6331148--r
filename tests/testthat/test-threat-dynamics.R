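test_that("reaction intensity follows alpha * tanh(omega/2) below zero, no reaction above", {
  p <- threat_params()
  expect_true(is.na(reaction_intensity(0.3, p)))   # not scared, no reaction
  expect_true(is.na(reaction_intensity(0, p)))
  # frozen from the closed form: 0.5 * tanh(-0.5)
  expect_equal(reaction_intensity(-1, p), -0.23105857863000487, tolerance = 1e-12)
  # continuity toward zero from below
  expect_equal(reaction_intensity(-1e-9, p), 0, tolerance = 1e-9)
  omega <- seq(-1, -0.01, length.out = 50)
  mu <- reaction_intensity(omega, p)
  expect_true(all(mu < 0 & mu > p$alpha * tanh(-1 / 2) - 1e-15))
})

test_that("default terrorist is an extremist of the targeted group", {
  q <- make_terrorist()
  expect_identical(q$type, "terrorist")
  expect_identical(group_of(q$identity), "M")
  expect_equal(q$identity$M$a, 0.95)
  expect_equal(margin_l(q$identity$M), 0.05)
  expect_equal(margin_h(q$identity$M), 0.05)
  g <- position_grid(400)
  expect_identical(identity_attitude(q$identity, q$identity, g), 1)
  expect_error(make_terrorist(target_segment = c(0.95, 0.9, 1)), "invalid acceptance")
})

test_that("bound update maps margin width w to (1 + mu) w - mu epsilon", {
  # hand evaluation: w = 0.5, mu = -0.2, eps = 0.05 -> w' = 0.41
  up <- cidyn:::.update_bound(beta = 0.7, a = 0.2, mu = -0.2, epsilon = 0.05, side = "upper")
  expect_equal(up - 0.2, 0.41, tolerance = 1e-12)
  lo <- cidyn:::.update_bound(beta = -0.3, a = 0.2, mu = -0.2, epsilon = 0.05, side = "lower")
  expect_equal(0.2 - lo, 0.41, tolerance = 1e-12)
  # zero-width margin grows toward epsilon
  z <- cidyn:::.update_bound(beta = 0.2, a = 0.2, mu = -0.2, epsilon = 0.05, side = "upper")
  expect_gt(z, 0.2)
})

test_that("a margin exactly at epsilon is a fixed point of the threat step", {
  g <- position_grid(400)
  q <- make_terrorist()
  ag <- agent("x", cultural_identity(
    M = acceptance_segment(-0.5, 0.2, 0.25),   # margin(h) = epsilon
    C = acceptance_segment(0.0, 0.5, 0.9),
    A = acceptance_segment(-0.7, -0.3, 0.1)))
  out <- apply_threat_step(ag, q, threat_params(), g)
  expect_lt(out$record$terrorist_attitude, 0)  # it does react...
  expect_equal(out$agent$identity$M$B, 0.25, tolerance = 1e-12)  # ...but stays put
})

test_that("a positively-valued agent is returned bit-identical", {
  g <- position_grid(400)
  # terrorist whose segments are wide enough to value this agent positively
  q <- agent("q", cultural_identity(
    M = acceptance_segment(-0.9, 0.9, 1.0),
    C = acceptance_segment(-1.0, -0.2, 1.0),
    A = acceptance_segment(-1.0, -0.1, 1.0)), type = "terrorist")
  ag <- agent("x", cultural_identity(
    M = acceptance_segment(0.0, 0.5, 0.8),
    C = acceptance_segment(-0.5, 0.0, 0.5),
    A = acceptance_segment(-0.4, 0.1, 0.6)))
  out <- apply_threat_step(ag, q, threat_params(), g)
  expect_gte(out$record$terrorist_attitude, 0)
  expect_identical(out$agent, ag)
})

test_that("threatened margins contract strictly and monotonically toward epsilon", {
  set.seed(107)
  g <- position_grid(200)
  q <- make_terrorist()
  p <- threat_params()
  for (r in 1:60) {
    ag <- agent(paste0("r", r), random_identity(min_width = 0.06))
    pop <- population(list(ag), normalize = TRUE)
    traj <- run_scenario(pop, q, p, g, record = "states")
    # the updated side is whichever bound is closest to the terrorist position;
    # track both margins and assert the global contraction facts
    mh <- vapply(traj$states, function(st) margin_h(st$agents[[1]]$identity$M), numeric(1))
    ml <- vapply(traj$states, function(st) margin_l(st$agents[[1]]$identity$M), numeric(1))
    expect_true(all(diff(mh) <= 1e-12) || all(diff(ml) <= 1e-12))
    expect_true(all(mh >= p$epsilon - 1e-9) && all(ml >= p$epsilon - 1e-9))
    reacted <- !is.na(traj$records$intensity)
    if (any(reacted)) {
      ch <- abs(traj$records$bound_after - traj$records$bound_before)[reacted]
      first <- traj$records$step[reacted][1]
      w0 <- if (traj$records$bound[reacted][1] == "upper") mh[first] else ml[first]
      if (w0 > p$epsilon + 1e-9) expect_gt(ch[1], 0)  # strict contraction above epsilon
    }
  }
})

test_that("a scenario over non-reacting agents has a constant trajectory", {
  g <- position_grid(400)
  q <- agent("q", cultural_identity(
    M = acceptance_segment(-1.0, 0.5, 1.0),
    C = acceptance_segment(-1.0, 0.0, 1.0),
    A = acceptance_segment(-1.0, 0.0, 1.0)), type = "terrorist")
  pop <- fixture_population6()
  omegas <- vapply(pop$agents, function(a) identity_attitude(q$identity, a$identity, g),
                   numeric(1))
  expect_true(all(omegas >= 0))  # precondition of the scenario under test
  traj <- run_scenario(pop, q, threat_params(), g)
  expect_identical(traj$steps_run, 1L)
  expect_true(traj$converged)
  expect_identical(traj$matrices[[1]], traj$matrices[[2]])
  summ <- classify_evolutions(traj)
  expect_identical(unname(summ$pct_weight), c(0, 100))
})

test_that("one scenario step equals the entrywise hand-applied update on the fixture", {
  g <- position_grid(400)
  q <- make_terrorist()
  p <- threat_params(steps = 1)
  pop <- fixture_population6()
  traj <- run_scenario(pop, q, p, g)
  # independent recomputation: per agent, apply the bound formula by hand
  for (i in seq_len(n_agents(pop))) {
    ag <- pop$agents[[i]]
    omega <- mean(vapply(c("M", "C", "A"), function(k) {
      oracle_segment_attitude(q$identity[[k]], ag$identity[[k]], 400)
    }, numeric(1)))
    s <- ag$identity$M
    if (omega >= 0) {
      expect_identical(traj$states[[2]]$agents[[i]]$identity$M, s)
    } else {
      mu <- 0.5 * tanh(omega / 2)
      use_upper <- abs(s$B - 0.95) <= abs(s$b - 0.95)
      beta <- if (use_upper) s$B else s$b
      beta_new <- beta + mu * (beta - s$a - 0.05 * sign(beta - s$a))
      got <- traj$states[[2]]$agents[[i]]$identity$M
      expect_equal(if (use_upper) got$B else got$b, beta_new, tolerance = 1e-12)
    }
  }
  # final matrix equals entrywise oracle recomputation of the updated identities
  mat <- traj$matrices[[2]]
  new_pop <- traj$states[[2]]
  for (i in 1:6) for (j in 1:6) {
    expected <- if (i == j) 1 else mean(vapply(c("M", "C", "A"), function(k) {
      oracle_segment_attitude(new_pop$agents[[i]]$identity[[k]],
                              new_pop$agents[[j]]$identity[[k]], 400)
    }, numeric(1)))
    expect_equal(mat[i, j], expected, tolerance = 1e-10)
  }
})

test_that("classification weights and percentage bookkeeping", {
  g <- position_grid(400)
  q <- make_terrorist()
  pop <- population(list(
    increase_condition_pair()$agents[[1]],
    increase_condition_pair()$agents[[2]]), normalize = TRUE)
  pop$agents[[1]]$weight <- 0.75
  pop$agents[[2]]$weight <- 0.25
  traj <- run_scenario(pop, q, threat_params(), g)
  summ <- classify_evolutions(traj)
  # c_agent (weight 0.25) increases, m_agent (weight 0.75) is unchanged
  expect_identical(unname(summ$classification),
                   c("decrease_or_unchanged", "increase"))
  expect_equal(unname(summ$pct_weight), c(25, 75), tolerance = 1e-9)
  expect_equal(unname(summ$pct_count), c(50, 50), tolerance = 1e-9)
  expect_equal(sum(summ$pct_weight), 100, tolerance = 1e-9)
})

test_that("classification requires targeted-group agents", {
  g <- position_grid(400)
  q <- make_terrorist()
  id <- cultural_identity(M = acceptance_segment(-0.9, -0.5, -0.1),
                          C = acceptance_segment(0.1, 0.6, 0.9),
                          A = acceptance_segment(-0.7, -0.3, 0.1))
  pop <- population(list(agent("c_only", id, weight = 1)))
  traj <- run_scenario(pop, q, threat_params(steps = 1), g)
  expect_error(classify_evolutions(traj), "targeted group")
})

test_that("segment overlap is the signed intersection length", {
  w <- acceptance_segment(-0.5, -0.2, 0.3)
  expect_equal(segment_overlap(w, w), 0.8)                       # width of itself
  expect_equal(segment_overlap(acceptance_segment(-0.8, -0.5, -0.2),
                               acceptance_segment(0.1, 0.3, 0.6)), -0.3)
  expect_equal(segment_overlap(acceptance_segment(-0.5, 0.0, 0.3),
                               acceptance_segment(0.0, 0.5, 0.9)), 0.3)
  expect_equal(segment_overlap(acceptance_segment(0.0, 0.5, 0.9),
                               acceptance_segment(-0.5, 0.0, 0.3)), 0.3)  # symmetric
})

test_that("terrorist attitude about distant narrow agents approaches -1", {
  g <- position_grid(400)
  q <- make_terrorist()
  far <- agent("far", cultural_identity(
    M = acceptance_segment(-1.0, -0.95, -0.9),
    C = acceptance_segment(0.9, 0.95, 1.0),
    A = acceptance_segment(0.9, 0.95, 1.0)))
  omega <- identity_attitude(q$identity, far$identity, g)
  expect_lt(omega, -0.95)
  expect_equal(reaction_intensity(omega, threat_params()),
               0.5 * tanh(omega / 2), tolerance = 1e-12)
})
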