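test_that("uniform generator has the right moments and is reproducible", {
  set.seed(10)
  d <- draw_uniform_distances(1e6, 10)$distances
  expect_true(all(d > 0 & d < 10))
  expect_lt(abs(mean(d) - 5), 3 * sd(d) / sqrt(1e6))

  set.seed(123)
  a <- draw_uniform_distances(100, 10)$distances
  set.seed(123)
  b <- draw_uniform_distances(100, 10)$distances
  expect_identical(a, b)

  # counts in the covered strip are binomial: var/(N p (1-p)) near 1
  set.seed(20)
  counts <- replicate(800, sum(draw_uniform_distances(1e4, 10)$distances <= 1))
  ratio <- var(counts) / (1e4 * 0.1 * 0.9)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("overdispersion alpha inverts the dispersion relation", {
  expect_equal(overdispersion_alpha(1667, 2), 1665)
  a <- overdispersion_alpha(1667, 2)
  expect_equal((a + 1667) / (a + 1), 2, tolerance = 1e-12)
  expect_error(overdispersion_alpha(100, 1), class = "ds_validation_error")
  expect_error(overdispersion_alpha(100, 100), class = "ds_validation_error")
})

test_that("Dirichlet generator keeps the uniform mean but inflates variance", {
  set.seed(31)
  draw <- draw_overdispersed_distances(1667, 10, 2, 1000)
  expect_length(draw$phi, 1000)
  expect_true(all(draw$phi >= 0))
  expect_equal(sum(draw$phi), 1, tolerance = 1e-12)
  expect_true(all(draw$distances > 0 & draw$distances < 10))
  # support points are bin midpoints: none on a 0.01-grid strip boundary
  expect_true(all(abs(draw$distances * 100 - round(draw$distances * 100))
                  > 1e-9))

  # E[n(v)] = N v P for interval [0, v*M]; 400 replicate draws
  set.seed(32)
  counts <- replicate(400, {
    d <- draw_overdispersed_distances(1667, 10, 2, 1000)$distances
    c(sum(d <= 0.5), sum(d <= 1), sum(d <= 5))
  })
  for (k in 1:3) {
    v <- c(0.05, 0.1, 0.5)[k]
    se <- sd(counts[k, ]) / sqrt(400)
    expect_lt(abs(mean(counts[k, ]) - 1667 * v), 3 * se)
  }
  # variance of the covered count is visibly above binomial at c = 2
  expect_gt(var(counts[2, ]), 1.4 * 1667 * 0.1 * 0.9)
})

test_that("detection thinning keeps the expected fraction", {
  fam1 <- uniform_family()
  d <- seq(0.05, 0.95, by = 0.1)
  expect_identical(thin_by_detection(c(d, 3, 5), fam1, 1, w = 1), d)

  set.seed(40)
  expect_length(thin_by_detection(runif(500), "half_normal", 1e-8), 0)

  # §-style settings: E[n] = N P gbar = 0.06 N
  set.seed(41)
  n <- replicate(300, length(thin_by_detection(
    runif(1667, 0, 10), "half_normal", 0.502, w = 1)))
  expect_lt(abs(mean(n) - 1667 * 0.1 * gbar("half_normal", 0.502)),
            3 * sd(n) / sqrt(300))
})

test_that("sim_config derives abundance and validates", {
  cfg <- sim_config("half_normal", 0.502, E_n = 100, P = 0.1, reps = 10)
  expect_equal(cfg$N, round(100 / (0.1 * gbar("half_normal", 0.502))))
  expect_equal(cfg$M, 10)
  expect_error(sim_config("half_normal", 0.502, E_n = 100, c = 0.5),
               class = "ds_validation_error")
  expect_error(sim_config("half_normal", 0.502, E_n = -5),
               class = "ds_validation_error")
  expect_output(print(cfg), "overdispersion")
})

test_that("harness is seed-deterministic and self-consistent", {
  cfg <- sim_config("half_normal", 0.502, E_n = 60, reps = 40, seed = 90)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$cds, s2$cds)

  # MSE decomposition and RRMSE definition
  expect_equal(s1$summary$mse, s1$summary$var + s1$summary$bias^2,
               tolerance = 1e-10)
  expect_equal(s1$summary$rrmse_pct, 100 * sqrt(s1$summary$mse) / s1$N)

  # strip identity at w' = w: exactly n / P
  expect_equal(s1$strip[, ncol(s1$strip)], s1$n_det / cfg$P)

  # known-theta estimator is n scaled by the true mean detection
  expect_equal(s1$known, s1$n_det / (cfg$P * cfg$gbar_true))

  # single replicate is a deterministic record
  cfg1 <- sim_config("half_normal", 0.502, E_n = 60, reps = 1, seed = 5)
  r1 <- run_simulation(cfg1)
  r2 <- run_simulation(cfg1)
  expect_identical(r1$n_det, r2$n_det)
  expect_identical(r1$strip, r2$strip)
  expect_output(print(r1), "replicates")
})

test_that("overdispersed harness draws fresh weights each replicate", {
  cfg <- sim_config("half_normal", 0.502, E_n = 60, c = 2, reps = 30,
                    seed = 17, fit_families = character(0))
  s <- run_simulation(cfg)
  # at c = 2 the replicate counts overdisperse relative to binomial
  expect_gt(var(s$n_det), var(rbinom(3e4, cfg$N, 0.06)) * 1.2)
  expect_null(s$cds)
})

test_that("empirical penalty, optimal width and crossing range contracts", {
  fake <- structure(list(
    known = c(1, 2, 3, 4), cds = cbind(hn = c(1, 2, 3, 4))),
    class = "cds_sim")
  expect_equal(empirical_penalty(fake), 1)

  mono <- structure(list(summary = data.frame(
    estimator = "strip", w_prime = c(0.1, 0.2, 0.3),
    mse = c(1, 1, 2))), class = "cds_sim")
  expect_equal(optimal_strip_width(mono), 0.1)  # tie toward smaller width

  nofit <- structure(list(summary = data.frame(
    estimator = c("cds_hn", "strip", "strip"),
    w_prime = c(NA, 0.1, 0.2), mse = c(1, 5, 6)),
    cds = cbind(hn = 1:3)), class = "cds_sim")
  expect_equal(crossing_range(nofit, "hn"),
               c(low = NA_real_, high = NA_real_))
})

test_that("finite-sample penalty approaches the asymptotic factor", {
  # very-narrow-shoulder hazard rate: the asymptotic approximation is
  # already good at E[n] = 100 with no overdispersion
  cfg <- sim_config("hazard_rate", c(0.405, 1.25), E_n = 100, c = 1,
                    reps = 1500, seed = 2026)
  sim <- suppressWarnings(run_simulation(cfg))
  Fhat <- empirical_penalty(sim)
  Fasy <- penalty_F("hazard_rate", c(0.405, 1.25), 0.1)
  expect_lt(abs(Fhat - Fasy) / Fasy, 0.15)
})
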