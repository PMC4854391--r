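test_that("configural fit treats identical groups identically", {
  spec <- make_population_spec("no_dif", n = c(600, 600), missing_rate = 0)
  m <- simulate_responses(spec, seed = 31)
  girls <- m$responses[m$group == "girls", ]
  dup <- sdq_matrix(rbind(girls, girls), rep(c("g1", "g2"), each = nrow(girls)))
  cfg <- fit_configural(dup)
  expect_equal(cfg$groups[[1]]$par, cfg$groups[[2]]$par, tolerance = 1e-4)
})

test_that("no-DIF data passes strong invariance with near-zero latent means", {
  nd <- fx_nodif()
  cfg <- fit_configural(mspec = sdq_model_spec(), ps_list = nd$ps)
  expect_gt(cfg$indices$cfi, 0.95)    # true model
  strong <- constrain_strong(cfg)
  expect_equal(strong$decision$verdict, "invariant")
  expect_lte(strong$decision$delta_cfi, 0.002)
  lm2 <- latent_mean_differences(strong)
  expect_true(all(abs(lm2$kappa2) < 3.5 * lm2$se))
  # df bookkeeping: equating 26 loadings + 50 thresholds while freeing
  # 5 means + 5 factor variances + 25 scale factors nets 41 df
  expect_identical(strong$df - cfg$df, 41L)
})

test_that("dropping the true cross-loading worsens the fit", {
  nd <- fx_nodif()
  cfg_full <- fit_configural(mspec = sdq_model_spec(), ps_list = nd$ps)
  cfg_nocross <- fit_configural(mspec = sdq_model_spec(cross_loading = FALSE),
                                ps_list = nd$ps)
  expect_lt(cfg_nocross$indices$cfi, cfg_full$indices$cfi)
})

test_that("a single injected DIF item is found and freed", {
  od <- fx_onedif()
  expect_equal(od$strong$decision$verdict, "non-invariant")
  mi <- modification_indices(od$strong)
  expect_equal(mi$item[1], "obeys")

  search <- partial_invariance_search(configural = od$cfg)
  expect_equal(search$decision$freed_items, "obeys")
  expect_lte(search$decision$delta_cfi, 0.002)

  # freeing one non-tantrum item adds loading + 2 thresholds and fixes its
  # scale factor: net 2 df fewer
  expect_identical(od$strong$df - search$fit$df, 2L)
})

test_that("the LM approximation agrees with the refit oracle on the top item", {
  od <- fx_onedif()
  cand <- c("obeys", "somatic", "caring", "loner")
  mi_lm <- modification_indices(od$strong, candidates = cand)
  mi_refit <- modification_indices(od$strong, candidates = cand,
                                   method = "refit", configural = od$cfg)
  expect_equal(mi_lm$item[1], mi_refit$item[1])
  expect_equal(mi_lm$item[1], "obeys")
})

test_that("larger injected DIF ranks above smaller injected DIF", {
  spec <- inject_dif(make_population_spec("no_dif", n = c(2500, 2500)),
                     "obeys", d_threshold = 0.6)
  spec <- inject_dif(spec, "loner", d_threshold = 0.25)
  m <- simulate_responses(spec, seed = 19)
  cfg <- fit_configural(m)
  strong <- constrain_strong(cfg)
  mi <- modification_indices(strong)
  expect_equal(mi$item[1], "obeys")
  expect_true(which(mi$item == "loner") <= 4L)
})

test_that("the constraint ladder is monotone in df and discrepancy", {
  od <- fx_onedif()
  cfg_F <- sum(vapply(seq_along(od$cfg$groups), function(g)
    od$cfg$groups[[g]]$discrepancy * od$cfg$groups[[g]]$n, numeric(1))) /
    od$cfg$n
  expect_gte(od$strong$df, od$cfg$df)
  expect_gte(od$strong$discrepancy, cfg_F)
})

test_that("structural equivalence keeps equal covariances and frees unequal ones", {
  # no_dif has Phi_1 = Phi_2: nothing should be freed
  nd <- fx_nodif()
  cfg <- fit_configural(mspec = sdq_model_spec(), ps_list = nd$ps)
  search <- partial_invariance_search(configural = cfg)
  se <- structural_equivalence(search)
  expect_equal(nrow(se$freed_cov), 0L)
  expect_equal(se$fit$decision$verdict, "equivalent")
})

test_that("the zero-DIF search rarely frees items", {
  # calibration of the delta-CFI rule under the null, small replicate set
  freed <- vapply(1:5, function(s) {
    spec <- make_population_spec("no_dif", n = c(1200, 1200))
    m <- simulate_responses(spec, seed = 300 + s)
    res <- partial_invariance_search(m)
    length(res$decision$freed_items)
  }, numeric(1))
  expect_lte(mean(freed > 0), 0.4)   # loose bound for 5 replicates
})
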