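# Analytical sign results about the change of segment attitude on the
# threatened worldview, after a full default scenario.

delta_omega_M <- function(pop, observer, target, grid,
                          params = threat_params(), q = make_terrorist()) {
  traj <- run_scenario(pop, q, params, grid, record = "states")
  segM <- function(st, id) st$agents[[match(id, agent_ids(st))]]$identity$M
  st0 <- traj$states[[1]]
  stT <- traj$states[[length(traj$states)]]
  segment_attitude(segM(stT, observer), segM(stT, target), grid) -
    segment_attitude(segM(st0, observer), segM(st0, target), grid)
}

pair_population <- function(si, sj) {
  population(list(
    agent("i", cultural_identity(M = si, C = acceptance_segment(0, 0.4, 0.8),
                                 A = acceptance_segment(-0.6, -0.2, 0.2))),
    agent("j", cultural_identity(M = sj, C = acceptance_segment(0, 0.4, 0.8),
                                 A = acceptance_segment(-0.6, -0.2, 0.2)))),
    normalize = TRUE)
}

test_that("higher observer's attitude toward a lower disjoint target never increases", {
  # scope: ordered m.a.positions a_i <= a_j below the terrorist's, and the
  # two M segments disjoint (the lower agent then lies entirely below)
  set.seed(108)
  g <- position_grid(400)
  n <- 0
  while (n < 150) {
    si <- random_segment(); sj <- random_segment()
    if (!(si$a <= sj$a && sj$a < 0.95 && segment_overlap(si, sj) <= 0)) next
    n <- n + 1
    expect_lte(delta_omega_M(pair_population(si, sj), "j", "i", g), 1e-6)
  }
})

test_that("higher observer's attitude never increases when the target does not overtop it", {
  # scope: a_i <= a_j and B_i <= B_j, so the contraction never removes
  # target positions the observer valued negatively through its margin(h)
  set.seed(109)
  g <- position_grid(400)
  n <- 0
  while (n < 150) {
    si <- random_segment(); sj <- random_segment()
    if (!(si$a <= sj$a && sj$a < 0.95 && si$B <= sj$B)) next
    n <- n + 1
    expect_lte(delta_omega_M(pair_population(si, sj), "j", "i", g), 1e-6)
  }
})

test_that("renormalization can raise the higher observer's attitude when the target overtops it", {
  # the counterexample configuration: the lower agent's wide margin(h)
  # extends far above the higher agent's small segment; its contraction
  # removes exactly the positions the observer valued most negatively
  g <- position_grid(400)
  si <- acceptance_segment(-0.2, 0.0, 0.9)   # lower a, B_i far above B_j
  sj <- acceptance_segment(-0.3, 0.1, 0.15)  # higher a, margin(h) at the minimum
  d <- delta_omega_M(pair_population(si, sj), "j", "i", g)
  expect_gt(d, 0.5)
})

test_that("the four increase conditions produce a positive attitude change", {
  g <- position_grid(400)
  pop <- increase_condition_pair()
  expect_gt(delta_omega_M(pop, "c_agent", "m_agent", g), 0)
  # one step already suffices
  expect_gt(delta_omega_M(pop, "c_agent", "m_agent", g,
                          params = threat_params(steps = 1)), 0)
  # check the stated conditions actually hold in the fixture
  sm <- pop$agents[[1]]$identity$M
  sc <- pop$agents[[2]]$identity$M
  expect_lt(sc$a, sm$a); expect_gt(sc$a, 0)
  expect_equal(margin_h(sc), 0.05)
  expect_gt(segment_overlap(sc, sm), 0)
  expect_gt(margin_h(sm), 0.5)
})

test_that("the increase grows with the M agent's margin(h) and shrinks with the position gap", {
  g <- position_grid(400)
  base_c <- cultural_identity(M = acceptance_segment(-0.5, 0.2, 0.25),
                              C = acceptance_segment(0, 0.5, 0.9),
                              A = acceptance_segment(-0.7, -0.3, 0.1))
  mk_pop <- function(aM, BM) population(list(
    agent("m_agent", cultural_identity(M = acceptance_segment(-0.6, aM, BM),
                                       C = acceptance_segment(-0.8, -0.2, 0.3),
                                       A = acceptance_segment(-0.8, -0.2, 0.3)),
          weight = 0.5, type = "inclusive"),
    agent("c_agent", base_c, weight = 0.5, type = "exclusive")))
  margin_sweep <- vapply(seq(0.4, 0.9, by = 0.1), function(BM) {
    delta_omega_M(mk_pop(0.3, BM), "c_agent", "m_agent", g)
  }, numeric(1))
  expect_true(all(margin_sweep > 0))
  expect_true(all(diff(margin_sweep) > 0))
  gap_sweep <- vapply(c(0.25, 0.35, 0.45, 0.55), function(aj) {
    delta_omega_M(mk_pop(aj, 0.9), "c_agent", "m_agent", g)
  }, numeric(1))
  expect_true(all(gap_sweep > 0))
  expect_true(all(diff(gap_sweep) < 0))
})
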