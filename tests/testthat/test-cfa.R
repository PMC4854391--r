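test_that("implied moments follow the delta-parameterized factor algebra", {
  mspec <- sdq_model_spec()
  tau <- matrix(c(-1, 1), 25, 2, byrow = TRUE,
                dimnames = list(mspec$items, NULL))
  # all loadings zero: identity plus the residual-correlation entries
  pz <- list(primary = rep(0, 25), cross = 0, Phi = diag(5),
             residual_cor = c(0.5, 0.3), tau = tau)
  im <- implied_moments(pz, mspec)
  expect_equal(im$corr["restless", "fidgety"], 0.5)
  expect_equal(im$corr["distractible", "attends"], 0.3)
  off <- im$corr; off[cbind(c("restless", "distractible", "fidgety", "attends"),
                            c("fidgety", "attends", "restless", "distractible"))] <- 0
  expect_equal(off, diag(25), ignore_attr = TRUE)

  # two loaded items on one factor: rho = lambda_i * lambda_j
  p2 <- pz; p2$primary[1:2] <- c(0.6, 0.8)
  im2 <- implied_moments(p2, mspec)
  expect_equal(im2$corr["somatic", "worries"], 0.48)

  # generator and engine agree exactly on the published population
  spec <- make_population_spec("table2_full")
  im3 <- implied_moments(list(Lambda = spec$Lambda[[1]], Phi = spec$Phi[[1]],
                              residual_cor = spec$residual_cor$value,
                              tau = spec$tau[[1]]), mspec)
  expect_equal(im3$corr, spec_implied_corr(spec, 1), tolerance = 1e-12)
})

test_that("DWLS fitting of exact moments is a zero-residual fixed point", {
  fit <- fx_exact_fit()
  expect_lt(fit$discrepancy, 1e-10)
  expect_true(fit$converged)

  spec <- make_population_spec("table2_full")
  std <- standardize(fit)
  truthL <- spec$Lambda[[1]]
  prim <- truthL[cbind(1:25, sdqmi:::.spec_factor_index())]
  expect_equal(std$loading, unname(prim), tolerance = 1e-5)
  expect_equal(std$cross[std$item_id == "tantrum"], 0.353, tolerance = 1e-5)
  expect_equal(attr(std, "phi")[[1]]["emotion", "conduct"], 0.310,
               tolerance = 1e-5)
  expect_equal(attr(std, "residual_cor")[[1]], c(0.555, 0.332),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("loadings are identified by the triad algebra", {
  # independent oracle: for three indicators of one factor,
  # lambda_1 = sqrt(r12 * r13 / r23)
  fit <- fx_exact_fit()
  ps <- fx_exact_ps()
  R <- ps$rho
  lam_somatic <- sqrt(R["somatic", "worries"] * R["somatic", "clingy"] /
                        R["worries", "clingy"])
  std <- standardize(fit)
  expect_equal(std$loading[std$item_id == "somatic"], lam_somatic,
               tolerance = 1e-4)
})

test_that("degrees of freedom follow the moment/parameter count", {
  # 25 items: 300 correlations + 50 thresholds; modified five-factor model:
  # 25 primary + 1 cross + 10 factor correlations + 2 residual correlations
  # + 50 thresholds free
  fit <- fx_exact_fit()
  n_mom <- 300L + 50L
  n_par <- 25L + 1L + 10L + 2L + 50L
  expect_identical(fit$df, n_mom - n_par)
  expect_identical(fit$df, 262L)
})

test_that("fit indices match their closed forms", {
  mk <- function(T, df) list(T_ms = T, df = df, n = 1001, n_groups = 1)
  fi <- fit_indices(mk(200, 100), list(T_ms = 2100, df = 120))
  expect_equal(fi$cfi, 1 - 100 / 1980)
  expect_equal(fi$rmsea, sqrt(100 / (100 * 1000)))
  expect_equal(fi$tli, ((2100 / 120) - 2) / ((2100 / 120) - 1))
  expect_true(fi$rmsea_lo <= fi$rmsea && fi$rmsea <= fi$rmsea_hi)

  # chi2 = df: perfect fit
  fi2 <- fit_indices(mk(100, 100), list(T_ms = 2100, df = 120))
  expect_equal(fi2$cfi, 1)
  expect_equal(fi2$rmsea, 0)

  # baseline no better than the model: max-guard pins CFI at 0
  fi3 <- fit_indices(mk(300, 100), list(T_ms = 120, df = 120))
  expect_equal(fi3$cfi, 0)
})

test_that("the adjusted statistic is calibrated under a true model", {
  # T_ms should sit near its df when the fitted model generated the data
  nd <- fx_nodif()
  fit <- fit_dwls(nd$ps[[1]])
  expect_within(fit$T_ms / fit$df, 1, 0.25)
})

test_that("standardization is invariant to the latent scale", {
  # doubling a factor variance while halving its loadings leaves the
  # standardized solution unchanged
  spec <- make_population_spec("table2_full")
  mspec <- sdq_model_spec()
  L <- spec$Lambda[[1]]; Phi <- spec$Phi[[1]]
  L2 <- L; L2[, "emotion"] <- L2[, "emotion"] / 2
  Phi2 <- Phi
  Phi2["emotion", ] <- Phi2["emotion", ] * 2
  Phi2[, "emotion"] <- Phi2[, "emotion"] * 2    # variance x4, cov x2
  a <- implied_moments(list(Lambda = L, Phi = Phi,
                            residual_cor = spec$residual_cor$value,
                            tau = spec$tau[[1]]), mspec)
  b <- implied_moments(list(Lambda = L2, Phi = Phi2,
                            residual_cor = spec$residual_cor$value,
                            tau = spec$tau[[1]]), mspec)
  expect_equal(a$corr, b$corr, tolerance = 1e-12)
})
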