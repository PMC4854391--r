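test_that("threshold estimation matches the inverse-normal rule", {
  # girls' caring endorsement: 1.33 / 17.67 / 81.00 percent
  tau <- estimate_thresholds(c(133, 1767, 8100))
  expect_equal(round(tau, 3), c(-2.217, -0.878))
  expect_equal(estimate_thresholds(c(50, 25, 25))[1], 0)
  # girls' tantrum "not true" 49.01 percent
  tau2 <- estimate_thresholds(c(4901, 4008, 1092) / 100)
  expect_equal(round(tau2[1], 3), -0.025)
  expect_error(estimate_thresholds(c(0, 0, 0)), "empty")
  # boundary clamp keeps thresholds finite
  expect_true(all(is.finite(estimate_thresholds(c(0, 10, 0)))))
})

test_that("bivariate normal CDF agrees with a numerical-integration oracle", {
  # oracle: P(X<=h, Y<=k) = int_{-Inf}^{h} phi(x) Phi((k-rho x)/sqrt(1-rho^2)) dx
  oracle <- function(h, k, rho) {
    integrate(function(x) dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2)),
              -Inf, h, rel.tol = 1e-12)$value
  }
  for (rho in c(-0.95, -0.4, 0.2, 0.7, 0.99)) {
    for (hk in list(c(-1.5, 0.3), c(0, 0), c(2, -2), c(0.8, 1.2))) {
      expect_equal(pbinorm(hk[1], hk[2], rho), oracle(hk[1], hk[2], rho),
                   tolerance = 1e-9)
    }
  }
  expect_equal(pbinorm(Inf, 1.3, 0.6), pnorm(1.3))
})

test_that("polychoric correlation maximizes the table likelihood", {
  # independence table: outer product of margins
  tab <- outer(c(5000, 3000, 2000), c(6000, 3000, 1000)) / 1e4
  expect_lt(abs(polychoric_corr(tab)$rho), 0.02)

  # grid-search oracle on a fixed dependent table
  tab2 <- matrix(c(520, 210, 60, 180, 340, 110, 40, 190, 350), 3, 3)
  est <- polychoric_corr(tab2)
  tr <- estimate_thresholds(rowSums(tab2))
  tc <- estimate_thresholds(colSums(tab2))
  loglik <- function(r) {
    g <- expand.grid(a = c(-Inf, tr, Inf), b = c(-Inf, tc, Inf))
    P <- matrix(pbinorm(g$a, g$b, r), 4, 4)
    pr <- P[-1, -1] - P[-4, -1] - P[-1, -4] + P[-4, -4]
    sum(tab2 * log(pmax(pr, 1e-12)))
  }
  grid <- seq(-0.999, 0.999, by = 1e-3)
  rho_grid <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_within(est$rho, rho_grid, 1e-3)

  # symmetry in the arguments
  expect_equal(polychoric_corr(t(tab2))$rho, est$rho, tolerance = 1e-6)

  # estimator consistency on simulated latent rho = 0.5
  set.seed(99)
  n <- 20000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  x <- cut(z1, c(-Inf, -0.3, 0.9, Inf), labels = FALSE)
  y <- cut(z2, c(-Inf, 0.1, 1.2, Inf), labels = FALSE)
  pc <- polychoric_corr(table(x, y))
  expect_within(pc$rho, 0.5, 3 * sqrt(pc$var))
})

test_that("degenerate tables collapse or error", {
  tab <- matrix(c(10, 0, 5, 0, 0, 0, 3, 0, 8), 3, 3)  # middle row/col empty
  expect_silent(polychoric_corr(tab))
  single <- matrix(c(12, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(polychoric_corr(single), "degenerate")
})

test_that("polychoric matrix handles comonotone and excluded items", {
  x <- c(rep(0L, 30), rep(1L, 40), rep(2L, 30))
  m <- cbind(a = x, b = x)
  ps <- polychoric_matrix(m, acov = "diag")
  expect_gte(ps$rho["a", "b"], 0.99)

  m2 <- cbind(a = x, b = x, c = rep(1L, 100))
  expect_warning(ps2 <- polychoric_matrix(m2, acov = "diag"),
                 "single-category")
  expect_equal(ps2$excluded, "c")
  expect_equal(ps2$items, c("a", "b"))
})

test_that("estimated matrix converges to the model-implied correlations", {
  spec <- make_population_spec("no_dif", n = c(20000, 200), missing_rate = 0)
  m <- simulate_responses(spec, seed = 17)
  ps <- polychoric_matrix(m, group = "girls", acov = "diag")
  truth <- spec_implied_corr(spec, 1)
  dev <- abs(ps$rho - truth)[upper.tri(truth)]
  se <- sqrt(ps$rho_var[upper.tri(truth)])
  expect_lt(mean(dev > 3 * se), 0.02)      # at most ~1% beyond 3 SEs
  expect_lt(max(dev), 0.05)
  # thresholds recovered too
  tse <- sqrt(pnorm(spec$tau[[1]]) * (1 - pnorm(spec$tau[[1]])) / 20000) /
    dnorm(spec$tau[[1]])
  expect_true(all(abs(ps$thresholds - spec$tau[[1]]) < 3.5 * tse))
})

test_that("pairwise deletion is robust to MCAR missingness", {
  spec <- make_population_spec("no_dif", n = c(8000, 200), missing_rate = 0)
  m <- simulate_responses(spec, seed = 23)
  girls <- m$responses[m$group == "girls", ]
  ps_full <- polychoric_matrix(girls, acov = "diag")
  set.seed(1)
  holes <- girls
  holes[matrix(runif(length(holes)) < 0.015, nrow(holes))] <- NA
  ps_miss <- polychoric_matrix(holes, acov = "diag")
  dev <- abs(ps_full$rho - ps_miss$rho)[upper.tri(ps_full$rho)]
  se <- sqrt(ps_miss$rho_var[upper.tri(ps_miss$rho)])
  expect_true(all(dev < 3 * se))
})

test_that("influence-function variances calibrate the polychoric sampling error", {
  # the full-Gamma diagonal should match the observed MC scatter
  spec <- make_population_spec("no_dif", n = c(2000, 200))
  reps <- vapply(1:8, function(s) {
    m <- simulate_responses(spec, seed = 100 + s)
    ps <- polychoric_matrix(m, group = "girls", acov = "full")
    i <- which(ps$layout$name == "worries~~unhappy")
    c(sdqmi:::moment_vector(ps)[i], ps$Gamma[i, i] / ps$n)
  }, numeric(2))
  emp_sd <- sd(reps[1, ])
  avg_se <- sqrt(mean(reps[2, ]))
  expect_within(emp_sd / avg_se, 1, 0.8)   # same order, loose MC bound
})

test_that("reliability reproduces the closed-form ordinal alpha", {
  lam <- c(0.578, 0.670, 0.814, 0.595, 0.650)
  R <- outer(lam, lam); diag(R) <- 1
  expect_equal(round(alpha_from_corr(R), 3), 0.794)
  expect_equal(alpha_from_corr(diag(5) * 0 + diag(5)), 0)  # all r = 0
  R1 <- matrix(1, 5, 5)
  expect_equal(alpha_from_corr(R1), 1)

  rel <- reliability(fx_nodif()$m)
  expect_equal(rel$scale, c(sdqmi:::sdq_scales(), "total"))
  expect_true(all(rel$cronbach_alpha <= 1 & rel$ordinal_alpha <= 1))
  # ordinal alpha exceeds Pearson alpha on 3-category data in practice
  expect_true(all(rel$ordinal_alpha > rel$cronbach_alpha))
})

test_that("ordinal alpha is invariant to consistent item reversal", {
  m <- fx_nodif()$m
  flip <- m
  flip$responses[, "worries"] <- 2L - flip$responses[, "worries"]
  ps_a <- polychoric_matrix(m, items = sdq_item_meta()$item_id[1:5],
                            acov = "diag")
  ps_b <- polychoric_matrix(flip, items = sdq_item_meta()$item_id[1:5],
                            acov = "diag")
  Rb <- ps_b$rho
  Rb["worries", ] <- -Rb["worries", ]; Rb[, "worries"] <- -Rb[, "worries"]
  diag(Rb) <- 1
  expect_equal(alpha_from_corr(Rb), alpha_from_corr(ps_a$rho),
               tolerance = 1e-6)
})
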