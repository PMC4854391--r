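test_that("presets encode the published population", {
  nd <- make_population_spec("no_dif")
  expect_identical(nd$Lambda[[1]], nd$Lambda[[2]])
  expect_identical(nd$tau[[1]], nd$tau[[2]])
  expect_equal(nd$kappa[[2]], rep(0, 5), ignore_attr = TRUE)

  tf <- make_population_spec("table2_full")
  expect_equal(tf$Lambda[[1]]["somatic", "emotion"], 0.578)
  expect_equal(unname(tf$tau[[1]]["caring", ]), c(-2.217, -0.878))
  expect_equal(tf$Lambda[[1]]["tantrum", "emotion"], 0.353)
  # non-DIF items shared, DIF items group-specific
  expect_equal(tf$Lambda[[2]]["somatic", "emotion"], 0.578)
  expect_equal(tf$Lambda[[2]]["caring", "prosocial"], 0.635)
  expect_equal(unname(tf$tau[[2]]["caring", ]), c(-1.940, -0.331))
  expect_equal(tf$n, c(5399L, 4854L))
  expect_equal(tf$kappa[[2]][["emotion"]], -0.65)
  # girls' Phi above-diagonal / boys' below-diagonal published values
  expect_equal(tf$Phi[[1]]["emotion", "conduct"], 0.310)
  expect_equal(tf$Phi[[2]]["emotion", "conduct"], 0.488)
})

test_that("invalid overrides are rejected", {
  phi_bad <- sdq_published_phi()$girls
  phi_bad["emotion", "conduct"] <- phi_bad["conduct", "emotion"] <- 1.2
  expect_error(make_population_spec("no_dif", overrides = list(
    Phi = list(sdq_published_phi()$girls, phi_bad))), "positive definite")

  spec <- make_population_spec("no_dif")
  spec$tau[[1]]["somatic", ] <- c(1, 0.5)
  expect_error(sdqmi:::.validate_spec(spec), "increasing")
})

test_that("simulation is deterministic and respects the missing rate", {
  spec <- make_population_spec("no_dif", n = c(10, 10), missing_rate = 0)
  a <- simulate_responses(spec, seed = 4)
  b <- simulate_responses(spec, seed = 4)
  expect_identical(a$responses, b$responses)
  expect_equal(dim(a$responses), c(20L, 25L))
  expect_false(anyNA(a$responses))

  spec2 <- make_population_spec("no_dif", n = c(20000, 200),
                                missing_rate = 0.015)
  m2 <- simulate_responses(spec2, seed = 4)
  miss <- mean(is.na(m2$responses))
  expect_within(miss, 0.015, 3 * sqrt(0.015 * 0.985 / length(m2$responses)))
})

test_that("reference-group margins converge to the probit thresholds", {
  spec <- make_population_spec("table2_full", n = c(50000, 500),
                               missing_rate = 0)
  m <- simulate_responses(spec, seed = 13)
  # thresholds are parameters of the reversed (problem-direction) responses
  girls <- sdqmi:::reverse_items(m$responses)[m$group == "girls", ]
  n <- 50000
  for (j in seq_len(25)) {
    tau <- spec$tau[[1]][j, ]
    p_cum <- pnorm(tau)
    emp <- cumsum(tabulate(girls[, j] + 1L, 3L) / n)[1:2]
    se <- sqrt(p_cum * (1 - p_cum) / n)
    expect_true(all(abs(emp - p_cum) <= 3.5 * se),
                label = paste("margins of", colnames(girls)[j]))
  }
})

test_that("girls' caring category proportions match the published rates", {
  spec <- make_population_spec("table2_full")
  m <- simulate_responses(spec, seed = 21)
  et <- endorsement_table(m)
  row <- et[et$item_id == "caring" & et$sample == "girls", ]
  pub <- c(1.33, 17.67, 81.00)
  n <- sum(m$group == "girls")
  se <- 100 * sqrt(pub / 100 * (1 - pub / 100) / n)
  expect_true(all(abs(unlist(row[, c("cat0", "cat1", "cat2")]) - pub)
                  <= 3 * se))
})

test_that("empirical polychoric association matches the implied correlation", {
  spec <- make_population_spec("no_dif", n = c(20000, 200), missing_rate = 0)
  m <- simulate_responses(spec, seed = 17)
  girls <- m$responses[m$group == "girls", ]
  truth <- spec_implied_corr(spec, 1)
  pc <- polychoric_corr(table(girls[, "worries"], girls[, "unhappy"]))
  expect_within(pc$rho, truth["worries", "unhappy"], 3 * sqrt(pc$var))
  # a residual-correlation pair carries the extra association
  pc2 <- polychoric_corr(table(girls[, "restless"], girls[, "fidgety"]))
  expect_within(pc2$rho, truth["restless", "fidgety"], 3 * sqrt(pc2$var))
  expect_gt(truth["restless", "fidgety"],
            spec$Lambda[[1]]["restless", "hyper"] *
              spec$Lambda[[1]]["fidgety", "hyper"])
})

test_that("inject_dif shifts group-2 parameters and revalidates", {
  spec <- make_population_spec("no_dif")
  same <- inject_dif(spec, "obeys", 0, 0)
  expect_identical(same$Lambda, spec$Lambda)
  expect_identical(same$tau, spec$tau)

  sh <- inject_dif(spec, "obeys", d_threshold = 0.5)
  expect_equal(unname(sh$tau[[2]]["obeys", ] - spec$tau[[2]]["obeys", ]),
               c(0.5, 0.5))
  expect_error(inject_dif(spec, "caring", d_loading = 0.9), "residual variance")
})
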