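test_that("item metadata has the SDQ structure", {
  meta <- sdq_item_meta()
  expect_equal(nrow(meta), 25L)
  expect_equal(unname(table(meta$scale)[sdqmi:::sdq_scales()]),
               rep(5L, 5), ignore_attr = TRUE)
  expect_setequal(meta$item_id[meta$reverse_scored],
                  c("obeys", "reflective", "attends", "friend", "popular"))
  # prosocial items are positively worded but not reverse scored
  pro <- meta[meta$scale == "prosocial", ]
  expect_true(all(pro$positively_worded) && !any(pro$reverse_scored))
})

test_that("CSV loading validates values and round-trips", {
  meta <- sdq_item_meta()
  f <- withr::local_tempfile(fileext = ".csv")
  df <- as.data.frame(matrix(0L, 3, 25, dimnames = list(NULL, meta$item_id)))
  df <- cbind(group = c("g", "g", "b"), df)
  write.csv(df, f, row.names = FALSE, quote = FALSE)
  m <- load_item_responses(f)
  expect_equal(unname(m$responses), matrix(0L, 3, 25), ignore_attr = TRUE)
  expect_false(anyNA(m$responses))

  df2 <- df; df2$somatic[2] <- 3L
  write.csv(df2, f, row.names = FALSE, quote = FALSE)
  expect_error(load_item_responses(f), "row 2")

  # simulated file round-trips bit-identically
  spec <- make_population_spec("no_dif", n = c(30, 30))
  sim <- simulate_responses(spec, seed = 9)
  write_item_responses(sim, f)
  back <- load_item_responses(f)
  expect_identical(back$responses, sim$responses)
  expect_identical(as.character(back$group), as.character(sim$group))
})

test_that("scale scoring applies reversal and missingness policy", {
  meta <- sdq_item_meta()
  mk <- function(vals) {
    resp <- matrix(vals, 1, 25, dimnames = list(NULL, meta$item_id))
    sdq_matrix(rbind(resp, resp[1, ]), c("a", "b"))  # need two groups
  }
  s0 <- score_sdq(mk(rep(0L, 25)))
  expect_equal(s0$emotion[1], 0)
  expect_equal(s0$conduct[1], 2)     # obeys=0 reverses to 2
  expect_equal(s0$prosocial[1], 0)
  s2 <- score_sdq(mk(rep(2L, 25)))
  expect_equal(s2$emotion[1], 10)
  expect_equal(s2$prosocial[1], 10)

  v <- rep(0L, 25); v[1:5] <- c(2L, 1L, 0L, 1L, 2L)
  expect_equal(score_sdq(mk(v))$emotion[1], 6)

  # any missing item in a scale => missing scale score; total needs all four
  v2 <- rep(0L, 25); v2[1] <- NA
  sc <- score_sdq(mk(v2))
  expect_true(is.na(sc$emotion[1]) && is.na(sc$total[1]))
  expect_false(is.na(sc$conduct[1]))
})

test_that("reversal is an involution for scoring", {
  spec <- make_population_spec("no_dif", n = c(50, 50))
  m <- simulate_responses(spec, seed = 3)
  twice <- m
  twice$responses <- sdqmi:::reverse_items(sdqmi:::reverse_items(m$responses))
  expect_identical(score_sdq(twice), score_sdq(m))
})

test_that("endorsement percentages are correct and sum to 100", {
  meta <- sdq_item_meta()
  resp <- matrix(0L, 4, 25, dimnames = list(NULL, meta$item_id))
  resp[, "fights"] <- c(0L, 0L, 0L, 1L)
  m <- sdq_matrix(resp, c("a", "a", "b", "b"))
  et <- endorsement_table(m)
  fights <- et[et$item_id == "fights" & et$sample == "full", ]
  expect_equal(unlist(fights[, c("cat0", "cat1", "cat2")]),
               c(75, 25, 0), ignore_attr = TRUE)
  # single-category column
  somatic <- et[et$item_id == "somatic" & et$sample == "full", ]
  expect_equal(unlist(somatic[, c("cat0", "cat1", "cat2")]),
               c(100, 0, 0), ignore_attr = TRUE)

  sim <- fx_nodif()$m
  et2 <- endorsement_table(sim)
  sums <- rowSums(as.matrix(et2[, c("cat0", "cat1", "cat2")]))
  expect_true(all(abs(sums - 100) < 0.05))
})

test_that("large-sample endorsement converges to the normal-CDF margins", {
  # one item with loading 0, thresholds (0, 1): margins Phi(0), Phi(1)-Phi(0)
  spec <- make_population_spec("no_dif", n = c(50000, 500), missing_rate = 0)
  spec$Lambda[[1]]["somatic", ] <- 0
  spec$Lambda[[2]]["somatic", ] <- 0
  spec$tau[[1]]["somatic", ] <- c(0, 1)
  spec$tau[[2]]["somatic", ] <- c(0, 1)
  m <- simulate_responses(spec, seed = 11)
  et <- endorsement_table(m)
  row <- et[et$item_id == "somatic" & et$sample == "girls", ]
  n <- 50000
  se0 <- 100 * sqrt(0.5 * 0.5 / n)
  expect_within(row$cat0, 100 * pnorm(0), 3 * se0)
  p1 <- pnorm(1) - pnorm(0)
  expect_within(row$cat1, 100 * p1, 3 * 100 * sqrt(p1 * (1 - p1) / n))
  p2 <- 1 - pnorm(1)
  expect_within(row$cat2, 100 * p2, 3 * 100 * sqrt(p2 * (1 - p2) / n))
})

test_that("total difficulties equals the sum of the four problem subscales", {
  sc <- score_sdq(fx_nodif()$m)
  ok <- complete.cases(sc[, c("emotion", "conduct", "hyper", "peer")])
  expect_equal(sc$total[ok],
               (sc$emotion + sc$conduct + sc$hyper + sc$peer)[ok])
  expect_true(all(sc$total[ok] >= 0 & sc$total[ok] <= 40))
})
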