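test_that("violation profile separates parallel from nonparallel processes", {
  # unequal means but constant effect: g constant and nonzero
  vp1 <- violation_profile(make_scenario("1"))
  expect_true(vp1$is_parallel)
  expect_equal(diff(range(vp1$g)), 0)
  expect_true(all(vp1$g != 0))

  # equal means annihilate g regardless of the schedule
  vp3 <- violation_profile(make_scenario("3"))
  expect_true(vp3$is_parallel)
  expect_equal(vp3$g, rep(0, 10))

  # lambda_t = t with a unit mean gap gives g = (1, ..., T)
  cfg <- make_scenario("2", list(lambda_values = 1:10, mu0 = 0, mu1 = 1))
  vp <- violation_profile(cfg)
  expect_equal(vp$g, as.numeric(1:10))
  expect_false(vp$is_parallel)

  # scenario 6 untreated paths are parallel (delta is a treatment effect,
  # not a parallel-trends violation), but the mediation flag is raised
  vp6 <- violation_profile(make_scenario("6b"))
  expect_true(vp6$is_parallel)
  expect_true(vp6$treatment_affects_covariate)
})

test_that("violation profile depends only on the schedule and covariate paths", {
  base <- violation_profile(make_scenario("5b"))
  shifted <- violation_profile(make_scenario("5b", list(
    alpha0 = 7, alpha1 = -3, zeta = 0.1 * (1:10) + 5)))
  expect_equal(shifted$g, base$g)
  expect_equal(shifted$is_parallel, base$is_parallel)
})

test_that("confounding classification matches the canonical taxonomy", {
  expected <- c("1" = "none", "2" = "covariate_confounding", "3" = "none",
                "4a" = "none", "4b" = "covariate_confounding",
                "5a" = "covariate_confounding", "5b" = "covariate_confounding",
                "6a" = "treatment_affected_covariate",
                "6b" = "treatment_affected_covariate")
  for (id in names(expected)) {
    expect_equal(classify_confounding(make_scenario(id)), unname(expected[id]),
                 label = paste("scenario", id))
  }
  # computed, not stored: equalizing scenario 1 means leaves it unconfounded,
  # and making scenario 3 means unequal creates confounding
  expect_equal(classify_confounding(make_scenario("1", list(mu1 = 0))), "none")
  expect_equal(classify_confounding(make_scenario("3", list(a1 = 1))),
               "covariate_confounding")
})

test_that("true ATT is gamma without mediation and adds the mediated path with it", {
  for (id in c("1", "2", "3", "4a", "4b", "5a", "5b")) {
    expect_identical(true_att(make_scenario(id)), 1)
  }
  expect_identical(true_att(make_scenario("5a", list(gamma = 2.5))), 2.5)
  expect_identical(true_att(make_scenario("4a", list(gamma = 0))), 0)

  # gamma = 1, delta = 0.2, constant lambda = 0.5, t0 = 6, T = 10:
  # mediated part = 0.5 * 0.2 * mean(1:5) = 0.3
  cfg <- make_scenario("6a", list(gamma = 1, delta = 0.2, lambda = 0.5))
  expect_equal(true_att(cfg), 1.3)
})

test_that("true ATT equals the simulated potential-outcome contrast", {
  # same seed => same group draw; with all noise off the panels are the
  # treated and untreated potential outcome surfaces of the same units
  cfg1 <- make_scenario("6b", list(sigma_x = 0, sigma_y = 0, n_units = 400))
  cfg0 <- make_scenario("6b", list(sigma_x = 0, sigma_y = 0, n_units = 400,
                                   gamma = 0, delta = 0))
  p1 <- draw_panel(cfg1, rng_spec(11))
  p0 <- draw_panel(cfg0, rng_spec(11))
  expect_equal(p1$treated, p0$treated)
  sel <- p1$treated == 1 & p1$post == 1
  expect_equal(mean(p1$y[sel] - p0$y[sel]), true_att(cfg1), tolerance = 1e-12)
})

test_that("brute-force group trend differences match the closed form", {
  # simulate untreated potential outcomes (gamma = 0, delta = 0) at large n;
  # the group difference-in-differences between times must equal g(t) - g(t')
  for (id in c("2", "5b")) {
    cfg <- make_scenario(id, list(n_units = 200000, gamma = 0, delta = 0))
    g <- violation_profile(cfg)$g
    panel <- draw_panel(cfg, rng_spec(5))
    gm <- tapply(panel$y, list(panel$treated, panel$time), mean)
    gap <- gm["1", ] - gm["0", ]
    n1 <- sum(panel$treated[panel$time == 1])
    n0 <- cfg$n_units - n1
    lam <- lambda_schedule(cfg)
    # var of group gap at t: (sigma_y^2 + lambda_t^2 sigma_x^2) * (1/n1 + 1/n0)
    se_gap <- sqrt((cfg$sigma_y^2 + lam^2 * cfg$sigma_x^2) * (1 / n1 + 1 / n0))
    for (t in c(5, 10)) {
      mc_se <- sqrt(se_gap[t]^2 + se_gap[1]^2)
      expect_lt(abs((gap[t] - gap[1]) - (g[t] - g[1])), 3 * mc_se,
                label = paste("scenario", id, "t =", t))
    }
  }
})
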