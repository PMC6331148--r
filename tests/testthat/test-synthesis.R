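test_that("sampled prototypes satisfy their template constraints", {
  set.seed(110)
  for (tpl in default_templates()) {
    for (r in 1:50) {
      id <- sample_prototype(tpl)
      expect_identical(group_of(id), tpl$group)
      expect_gt(id[[tpl$group]]$a, 0)
      for (k in c("M", "C", "A")) {
        expect_gte(margin_l(id[[k]]), 0.05)
        expect_gte(margin_h(id[[k]]), 0.05)
      }
      if (tpl$type == "exclusive") {
        expect_gte(id[[tpl$group]]$b, 0)
        expect_lte(id[[tpl$group]]$B - id[[tpl$group]]$b, 0.8)
        for (k in setdiff(c("M", "C", "A"), tpl$group)) {
          s <- id[[k]]
          expect_lte(s$a, 0)
          expect_gte((min(s$B, 0) - s$b) / (s$B - s$b), 0.6)
        }
      } else {
        for (k in c("M", "C", "A")) {
          s <- id[[k]]
          expect_gte(s$B - s$b, 0.7)
          expect_gte((s$B - max(s$b, -0.2)) / (s$B - s$b), 0.6)
        }
      }
    }
  }
})

test_that("encode/decode is a lossless round trip", {
  set.seed(111)
  fr <- c(M = 0.036, C = 0.606, A = 0.358)
  pop <- sample_population(fr, shares = c(M = 0.5, C = 0.3, A = 0.7))
  vec <- encode_population(pop)
  expect_length(vec, 57)
  back <- decode_population(vec, fr)
  for (i in 1:6) {
    expect_identical(back$agents[[i]]$identity, pop$agents[[i]]$identity)
    expect_identical(back$agents[[i]]$id, pop$agents[[i]]$id)
    expect_equal(back$agents[[i]]$weight, pop$agents[[i]]$weight, tolerance = 1e-12)
  }
  expect_equal(encode_population(back), vec, tolerance = 1e-12)
  # weight arithmetic: M-group inclusive share 0.5 of fraction 0.036
  expect_equal(agent_weights(back)[["M_inclusive"]], 0.018, tolerance = 1e-12)
  # degenerate shares are rejected at decode time
  bad <- vec; bad[55:57] <- 1
  expect_error(decode_population(bad, fr), "share")
})

test_that("constraint repair is idempotent and produces decodable vectors", {
  set.seed(112)
  fr <- c(M = 0.2, C = 0.5, A = 0.3)
  idem_ok <- TRUE
  for (r in 1:1000) {
    v <- runif(57, -1.5, 1.5)
    rep1 <- repair_constraints(v)
    idem_ok <- idem_ok && identical(repair_constraints(rep1), rep1)
    if (r <= 50) {
      pop <- decode_population(rep1, fr)
      margins <- unlist(lapply(pop$agents, function(ag) {
        vapply(c("M", "C", "A"),
               function(k) c(margin_l(ag$identity[[k]]), margin_h(ag$identity[[k]])),
               numeric(2))
      }))
      expect_true(all(margins >= 0.05 - 1e-12))
      expect_identical(unname(agent_groups(pop)), c("M", "M", "C", "C", "A", "A"))
    }
  }
  expect_true(idem_ok)
  # sorted-triple example and a no-op on feasible input
  v <- repair_constraints(runif(57, -1, 1))
  expect_identical(repair_constraints(v), v)
})

test_that("population error is zero on its own statistics and additive per term", {
  g <- position_grid(400)
  pop <- fixture_population6()
  st <- group_stats(pop, attitude_matrix(pop, g))
  tgt <- calibration_target(st$mean, st$sd, st$fraction)
  err <- population_error(pop, tgt, g)
  expect_equal(unname(err), c(0, 0, 0), tolerance = 1e-12)
  # one mean off by 0.1: absolute error 0.1, relative uses the floored denominator
  tgt2 <- tgt
  tgt2$mean["M", "C"] <- tgt$mean["M", "C"] + 0.1
  err2 <- population_error(pop, tgt2, g)
  expect_equal(err2[["absolute_error"]], 0.1, tolerance = 1e-12)
  denom <- max(abs(tgt2$mean["M", "C"]), 0.05)
  expect_equal(err2[["relative_max_error"]], 0.1 / denom, tolerance = 1e-12)
  expect_equal(err2[["relative_avg_error"]], 0.1 / denom / 18, tolerance = 1e-12)
})

test_that("population error equals the hand-summed 18-term oracle on a fixture", {
  g <- position_grid(400)
  pop <- fixture_population6()
  set.seed(113)
  other <- sample_population(c(M = 0.1, C = 0.6, A = 0.3))
  st <- group_stats(other, attitude_matrix(other, g))
  tgt <- calibration_target(st$mean, st$sd, st$fraction)
  got <- population_error(pop, tgt, g)
  sim <- group_stats(pop, attitude_matrix(pop, g))
  terms <- c()
  dat <- c()
  for (G in c("M", "C", "A")) for (H in c("M", "C", "A")) {
    terms <- c(terms, abs(sim$mean[G, H] - tgt$mean[G, H]),
               abs(sim$sd[G, H] - tgt$sd[G, H]))
    dat <- c(dat, tgt$mean[G, H], tgt$sd[G, H])
  }
  expect_length(terms, 18)
  expect_equal(got[["absolute_error"]], sum(terms), tolerance = 1e-12)
  rel <- terms / pmax(abs(dat), 0.05)
  expect_equal(got[["relative_avg_error"]], mean(rel), tolerance = 1e-12)
  expect_equal(got[["relative_max_error"]], max(rel), tolerance = 1e-12)
})

test_that("short PSO runs are seed-deterministic with a non-increasing best trace", {
  g <- position_grid(100)
  set.seed(114)
  known <- sample_population(c(M = 0.2, C = 0.5, A = 0.3))
  st <- group_stats(known, attitude_matrix(known, g))
  tgt <- calibration_target(st$mean, st$sd, st$fraction)
  cfg <- pso_config(seed = 21, swarm_size = 8, iterations = 15, keep_top = 3)
  cal1 <- pso_calibrate(tgt, cfg, g)
  cal2 <- pso_calibrate(tgt, cfg, g)
  expect_identical(cal1$errors, cal2$errors)
  expect_identical(lapply(cal1$populations, encode_population),
                   lapply(cal2$populations, encode_population))
  expect_true(all(diff(cal1$trace) <= 0))
  expect_length(cal1$populations, 3)
  expect_true(!is.unsorted(cal1$errors$absolute_error))
  # optimization improved on the initial template draws
  expect_lt(tail(cal1$trace, 1), cal1$trace[1] + 1e-12)
  # every calibrated population passes the core invariants
  for (pop in cal1$populations) {
    m <- attitude_matrix(pop, g)
    expect_true(all(m >= -1 & m <= 1))
    expect_equal(sum(agent_weights(pop)), 1, tolerance = 1e-9)
  }
})
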