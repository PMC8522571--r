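test_that("group assignment is Bernoulli, guarded, and reproducible", {
  expect_error(assign_groups(10, 0, rng_spec(1)), "degenerate")
  expect_error(assign_groups(10, 1, rng_spec(1)), "degenerate")

  d1 <- assign_groups(800, 0.5, rng_spec(3, 7))
  d2 <- assign_groups(800, 0.5, rng_spec(3, 7))
  expect_identical(d1, d2)
  expect_true(all(d1 %in% 0:1))

  # Bin(800, 0.5) puts ~2e-5 mass outside [340, 460]; 20 draws all inside
  counts <- vapply(1:20, function(k) sum(assign_groups(800, 0.5, rng_spec(17, k))),
                   numeric(1))
  expect_true(all(counts >= 340 & counts <= 460))
})

test_that("covariate draws follow the scenario mean paths", {
  # parallel evolution, no noise: both groups share the slope b0 and differ
  # only by the constant level a1
  cfg <- noiseless("4a")
  d <- assign_groups(cfg$n_units, 0.5, rng_spec(2))
  x <- draw_covariates(cfg, d, rng_spec(2, 1))
  cp <- cfg$cov_process
  for (t in c(1, 6, 10)) {
    expect_equal(unname(x[, t]),
                 cp$a0 + cp$a1 * d + cp$b0 * t)
  }
  # group gap constant over time: parallel paths
  expect_equal(unname(x[d == 1, 10][1] - x[d == 0, 10][1]),
               unname(x[d == 1, 1][1] - x[d == 0, 1][1]))

  # post-divergence: treated unit at t = 8 sits at a0 + b0*8 + delta*3
  cfg6 <- noiseless("6a")
  d6 <- assign_groups(cfg6$n_units, 0.5, rng_spec(2))
  x6 <- draw_covariates(cfg6, d6, rng_spec(2, 1))
  i_tr <- which(d6 == 1)[1]
  i_co <- which(d6 == 0)[1]
  cp <- cfg6$cov_process
  expect_equal(x6[i_tr, 8], cp$a0 + cp$b0 * 8 + cp$delta * 3)
  expect_equal(x6[i_co, 8], cp$a0 + cp$b0 * 8)
  # no divergence before t0
  expect_equal(x6[i_tr, 5], x6[i_co, 5])

  # time-invariant draws: constant across time, group means within CLT bounds
  cfg1 <- make_scenario("1")
  d1 <- assign_groups(cfg1$n_units, 0.5, rng_spec(4))
  x1 <- draw_covariates(cfg1, d1, rng_spec(4, 1))
  expect_true(all(x1 == x1[, 1]))
  mu1 <- cfg1$cov_process$a0 + cfg1$cov_process$a1
  expect_lt(abs(mean(x1[d1 == 1, 1]) - mu1),
            3 * cfg1$sigma_x / sqrt(sum(d1 == 1)))
})

test_that("panels are balanced, reproducible, and deterministic without noise", {
  cfg <- make_scenario("2", list(n_units = 60))
  p1 <- draw_panel(cfg, rng_spec(9, 3))
  p2 <- draw_panel(cfg, rng_spec(9, 3))
  expect_identical(p1, p2)
  p3 <- draw_panel(cfg, rng_spec(9, 4))
  expect_false(identical(p1$y, p3$y))

  expect_equal(nrow(p1), 60 * 10)
  expect_true(all(table(p1$unit, p1$time) == 1))
  expect_true(all(tapply(p1$treated, p1$unit, function(v) length(unique(v))) == 1))
  expect_equal(p1$post, as.integer(p1$time >= 6))
  # time-invariant covariate constant within unit
  expect_true(all(tapply(p1$x, p1$unit, function(v) length(unique(v))) == 1))

  # noiseless closed form: control unit in scenario 1 at t = 3
  cfgn <- noiseless("1")
  pn <- draw_panel(cfgn, rng_spec(1))
  row <- pn[pn$treated == 0 & pn$time == 3, ][1, ]
  lam <- lambda_schedule(cfgn)[3]
  mu0 <- cfgn$cov_process$a0
  expect_equal(row$y, cfgn$alpha0 + cfgn$zeta[3] + lam * mu0)
})

test_that("group-time outcome means match the closed-form expectation", {
  # distributional oracle at 10^5 units for each canonical scenario
  for (id in scenario_ids()) {
    cfg <- make_scenario(id, list(n_units = 100000))
    panel <- draw_panel(cfg, rng_spec(31))
    lam <- lambda_schedule(cfg)
    cp <- cfg$cov_process
    gm <- tapply(panel$y, list(panel$treated, panel$time), mean)
    n1 <- sum(panel$treated[panel$time == 1])
    n0 <- cfg$n_units - n1
    for (d in 0:1) {
      t_ <- seq_len(cfg$n_times)
      post <- as.integer(t_ >= cfg$t0)
      m_d <- cp$a0 + cp$a1 * d + (cp$b0 + cp$b1 * d) * t_ +
        cp$delta * d * post * (t_ - cfg$t0 + 1)
      ey <- cfg$alpha0 + cfg$alpha1 * d + cfg$zeta + lam * m_d +
        cfg$gamma * post * d
      mc_se <- sqrt((cfg$sigma_y^2 + lam^2 * cfg$sigma_x^2) /
                      (if (d == 1) n1 else n0))
      expect_true(all(abs(gm[as.character(d), ] - ey) < 3.5 * mc_se),
                  label = paste("scenario", id, "group", d))
    }
  }
})

test_that("panels round-trip through long-format CSV", {
  cfg <- make_scenario("5a", list(n_units = 30))
  p <- draw_panel(cfg, rng_spec(8))
  path <- withr::local_tempfile(fileext = ".csv")
  panel_write(p, path)
  expect_identical(readLines(path, n = 1), "\"unit\",\"time\",\"treated\",\"post\",\"x\",\"y\"")
  back <- panel_read(path)
  expect_equal(attr(back, "t0"), attr(p, "t0"))
  expect_equal(as.data.frame(back), as.data.frame(p), tolerance = 1e-12)
  # inconsistent post column is rejected
  bad <- as.data.frame(p)
  bad$post[1] <- 1L
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(panel_read(path2, t0 = 6), "post")
})
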