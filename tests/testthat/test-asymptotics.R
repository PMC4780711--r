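test_that("Delta is the conditional variance of h(D)/g(D)", {
  expect_equal(delta_matrix(uniform_family(), 1), matrix(0, 1, 1))

  set.seed(123)
  mc <- oracle_delta_mc("half_normal", 0.502, 2e5)
  D <- delta_matrix("half_normal", 0.502)
  expect_true(abs(D[1, 1] - mc$est[1, 1]) < 3 * mc$se[1, 1])

  mc2 <- oracle_delta_mc("hazard_rate", c(0.448, 2), 2e5)
  D2 <- delta_matrix("hazard_rate", c(0.448, 2))
  expect_true(all(abs(D2 - mc2$est) < 3 * mc2$se))
  expect_equal(D2, t(D2))
  expect_true(all(eigen(D2, symmetric = TRUE)$values > 0))
})

test_that("known-theta variance follows the binomial count", {
  expect_equal(var_known_theta(1000, 0.1, gbar_value = 0.6),
               1000 / 0.06 * 0.94)  # 15,666.67
  expect_equal(var_known_theta(500, 1, uniform_family(), 1), 0)
  # Monte-Carlo: variance of n / (P gbar) over binomial draws
  set.seed(5)
  gb <- gbar("hazard_rate", c(0.448, 2))
  n <- rbinom(1e5, 833, 0.1 * gb)
  est <- n / (0.1 * gb)
  v_mc <- var(est)
  se <- sd((est - mean(est))^2) / sqrt(1e5)
  expect_true(abs(var_known_theta(833, 0.1, "hazard_rate", c(0.448, 2)) -
                  v_mc) < 3 * se)
})

test_that("penalty F matches printed values and the Fisher-inverse ratio", {
  s <- calibrate_scale("hazard_rate", 0.3, shape = 1.1)
  expect_equal(round(penalty_F("hazard_rate", c(s, 1.1), 0.1) * 100) / 100,
               6.60)
  s2 <- calibrate_scale("half_normal", 0.3)
  expect_equal(round(penalty_F("half_normal", s2, 0.1) * 100) / 100, 1.52)

  # equivalence with V11 / var_known by numeric inversion, random configs
  set.seed(99)
  for (i in 1:8) {
    cfgs <- list(
      list(fam = "half_normal", th = runif(1, 0.2, 1.2)),
      list(fam = "hazard_rate", th = c(runif(1, 0.2, 1), runif(1, 1.1, 3))))
    for (cfg in cfgs) {
      P <- runif(1, 0.05, 0.95)
      blocks <- fisher_blocks(cfg$fam, cfg$th, N = 1000, P = P)
      ratio <- oracle_v11_numeric(blocks) /
        var_known_theta(1000, P, gbar_value = blocks$gbar)
      expect_equal(penalty_F(cfg$fam, cfg$th, P), ratio, tolerance = 1e-6)
    }
  }
  expect_equal(penalty_F(uniform_family(), 1, 0.5), 1)
})

test_that("Fisher blocks take their closed-form values", {
  # I_NN = P gbar / (N (1 - P gbar)) at N=1000, P=0.1, gbar=0.6
  b <- fisher_blocks("half_normal", calibrate_scale("half_normal", 0.6),
                     N = 1000, P = 0.1)
  expect_equal(b$I_NN, 0.06 / (1000 * 0.94), tolerance = 1e-7)
  b0 <- fisher_blocks(uniform_family(), 1, N = 1000, P = 0.1)
  expect_equal(b0$I_Ntheta, 0)
  expect_equal(b0$I_thetatheta, matrix(0, 1, 1))
})

test_that("assembled Fisher matrix and variance blocks are mutual inverses", {
  for (cfg in list(list(fam = "half_normal", th = 0.502, N = 1000),
                   list(fam = "hazard_rate", th = c(0.448, 2), N = 1667))) {
    b <- fisher_blocks(cfg$fam, cfg$th, N = cfg$N, P = 0.1)
    b <- variance_blocks(b, N = cfg$N, P = 0.1)
    p <- length(b$I_Ntheta)
    I <- rbind(c(b$I_NN, b$I_Ntheta),
               cbind(b$I_Ntheta, b$I_thetatheta))
    V <- rbind(c(b$V11, b$V21), cbind(b$V21, b$V22))
    expect_equal(I %*% V, diag(1 + p), tolerance = 1e-6)
    # V11 = var_known * F and the closed-form V21 sign/value
    vk <- var_known_theta(cfg$N, 0.1, gbar_value = b$gbar)
    expect_equal(b$V11 / vk, penalty_F(cfg$fam, cfg$th, 0.1),
                 tolerance = 1e-9)
    expect_equal(b$V21,
                 -solve(b$Delta, b$hbar) / (b$gbar^2 * 0.1),
                 tolerance = 1e-9)
    # numeric-inverse V22 block agrees with the closed form
    expect_equal(solve(I)[-1, -1, drop = FALSE], b$V22, tolerance = 1e-6)
  }
  # h = 0 limit: no penalty
  b0 <- variance_blocks(fisher_blocks(uniform_family(), 1, 500, 0.5),
                        500, 0.5)
  expect_equal(b0$V11, var_known_theta(500, 0.5, gbar_value = 1))
})

test_that("asymptotic summary collects consistent pieces", {
  s <- asymptotic_summary("hazard_rate", c(0.448, 2), N = 1667, P = 0.1)
  expect_s3_class(s, "cds_asymptotics")
  expect_equal(s$F_penalty, s$V11 / s$var_known, tolerance = 1e-12)
  expect_gte(s$F_penalty, 1)
  expect_equal(s$cv, cv_cds(s$F_penalty, s$E_n, s$N))
  expect_output(print(s), "penalty F")
})

test_that("CV and sample-size formulas invert each other", {
  expect_equal(cv_cds(1.78, 60, 1000), 0.167, tolerance = 5e-4)
  expect_equal(cv_cds(1, 100, 1e9), 0.10, tolerance = 1e-4)
  expect_lt(cv_cds(1.5, 999.999, 1000), 1e-3)  # census limit
  expect_error(cv_cds(1.5, 1000, 1000), class = "ds_validation_error")

  expect_equal(sample_size(0.2, 2), 50)
  expect_equal(sample_size(0.1, 2, N = 1000), 1000 / 6, tolerance = 1e-9)
  expect_equal(sample_size(0.1, 1), 100)
  # round trip: CV at the required E[n] equals the target
  En <- sample_size(0.15, 2.5, N = 2000)
  expect_equal(cv_cds(2.5, En, 2000), 0.15, tolerance = 1e-9)
})

test_that("penalty_table layout, single-cell consistency, and monotonic trends", {
  one <- penalty_table("hazard_rate", P_list = 0.1, gbar_list = 0.3,
                       shape_list = 1.1, digits = NULL)
  expect_equal(nrow(one), 1L)
  s <- calibrate_scale("hazard_rate", 0.3, shape = 1.1)
  expect_equal(one$F, penalty_F("hazard_rate", c(s, 1.1), 0.1))

  tab <- penalty_table("hazard_rate", P_list = c(0.1, 0.9),
                       gbar_list = c(0.3, 0.9),
                       shape_list = c(1.1, 2, 3), digits = NULL)
  expect_equal(nrow(tab), 12L)
  # F decreases in the shape (wider shoulder) for fixed P and gbar,
  # and increases in P for fixed gbar and shape
  for (gv in c(0.3, 0.9)) for (pv in c(0.1, 0.9)) {
    Fs <- tab$F[tab$P == pv & tab$gbar == gv]
    expect_true(all(diff(Fs) < 0))
  }
  for (gv in c(0.3, 0.9)) for (sv in c(1.1, 2, 3)) {
    Fs <- tab$F[tab$gbar == gv & tab$shape == sv]
    expect_true(all(diff(Fs) > 0))
  }
})
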