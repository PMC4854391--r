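# Shared fixtures, memoized so the expensive simulations and fits are built
# once per test run.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, make) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- make()
  .fx_cache[[name]]
}

# small no-DIF two-group sample and its per-group polychorics
fx_nodif <- function() fx("nodif", function() {
  spec <- make_population_spec("no_dif", n = c(1500, 1500))
  m <- simulate_responses(spec, seed = 42)
  list(spec = spec, m = m,
       ps = list(polychoric_matrix(m, group = "girls"),
                 polychoric_matrix(m, group = "boys")))
})

# single injected DIF (obeys thresholds +0.5 in group 2)
fx_onedif <- function() fx("onedif", function() {
  spec <- inject_dif(make_population_spec("no_dif", n = c(2000, 2000)),
                     "obeys", d_threshold = 0.5)
  m <- simulate_responses(spec, seed = 7)
  cfg <- fit_configural(m)
  strong <- constrain_strong(cfg)
  list(spec = spec, m = m, cfg = cfg, strong = strong)
})

# polychoric summary holding the exact model-implied moments of the girls'
# population (identity Gamma: pure zero-residual algebra)
fx_exact_ps <- function() fx("exact_ps", function() {
  spec <- make_population_spec("table2_full")
  items <- sdq_item_meta()$item_id
  lay <- sdqmi:::moment_layout(items)
  structure(list(items = items, thresholds = spec$tau[[1]],
                 rho = spec_implied_corr(spec, 1), n = 1e5, layout = lay,
                 Gamma = diag(nrow(lay))),
            class = "polychoric_summary")
})

fx_exact_fit <- function() fx("exact_fit", function() fit_dwls(fx_exact_ps()))

# moderate GRM sample for information/monotonicity checks
fx_grm <- function() fx("grm", function() {
  spec <- make_population_spec("no_dif", n = c(3000, 3000))
  m <- simulate_responses(spec, seed = 5)
  fit_grm(m, "emotion")
})

expect_within <- function(est, truth, half_width) {
  expect_true(abs(est - truth) <= half_width,
              label = sprintf("|%.4f - %.4f| <= %.4f", est, truth, half_width))
}
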