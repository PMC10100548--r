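# standardized one- and two-property tables for point-mass prediction tests
props1 <- data.frame(substance_id = c("S1", "S2", "S3"), a = c(0, 1, 2),
                     stringsAsFactors = FALSE)
h1 <- hierarchy_index(c(`1101` = "11"))

test_that("detection probabilities follow the logistic arithmetic exactly", {
  # all-zero parameters and x = 0: p = 0.5 for every draw
  m0 <- point_mass_model(h1, "a", b_detect = 0, beta_detect = 0,
                         b_conc = 0, beta_conc = 0, n_draws = 10)
  p0 <- predict_detection(m0, data.frame(substance_id = "S1",
                                         subsector = "1101"), props1)
  expect_equal(unname(p0), matrix(0.5, 10, 1))

  # hand-computed eta = 1.2: p = plogis(1.2) = 0.7685
  m1 <- point_mass_model(h1, "a", b_detect = 1.2, beta_detect = 0,
                         b_conc = 0, beta_conc = 0)
  p1 <- predict_detection(m1, data.frame(substance_id = "S1",
                                         subsector = "1101"), props1)
  expect_equal(unname(p1[1, 1]), plogis(1.2))
  expect_equal(unname(p1[1, 1]), 0.7685248, tolerance = 1e-7)

  # a predictor with all-positive coefficient draws is monotone in x
  m2 <- point_mass_model(h1, "a", b_detect = -0.3, beta_detect = 0.8,
                         b_conc = 0, beta_conc = 0, n_draws = 5)
  p2 <- predict_detection(m2, data.frame(substance_id = c("S1", "S2", "S3"),
                                         subsector = "1101"), props1)
  expect_true(all(diff(t(p2)[, 1]) > 0))
})

test_that("conditional concentration draws honour the residual switch", {
  m <- point_mass_model(h1, "a", b_detect = 0, beta_detect = 0,
                        b_conc = -1.5, beta_conc = 2, sigma_eps = 1,
                        n_draws = 100000)
  q <- data.frame(substance_id = "S2", subsector = "1101")
  # residual off: exactly eta2 = -1.5 + 2 * 1
  mean_draws <- predict_concentration(m, q, props1, include_residual = FALSE)
  expect_equal(unname(mean_draws), matrix(0.5, 100000, 1))

  # residual on with sigma_eps = 1: 95% interval approaches eta2 +/- 1.96
  pp <- predict_concentration(m, q, props1, include_residual = TRUE,
                              seed = 42)
  s <- summarize_prediction(pp, level = 0.95)
  expect_equal(s$lower, 0.5 - 1.96, tolerance = 0.03 / 1.96)
  expect_equal(s$upper, 0.5 + 1.96, tolerance = 0.03 / 1.96)

  # quantile nesting: the 95% interval contains the 50% interval
  s50 <- summarize_prediction(pp, level = 0.5)
  expect_lte(s$lower, s50$lower)
  expect_gte(s$upper, s50$upper)
})

test_that("prediction summaries are equal-tailed quantiles", {
  s <- summarize_prediction(1:100, level = 0.5)
  expect_equal(s$median, 50.5)
  expect_equal(s$span, s$upper - s$lower)
  const <- summarize_prediction(rep(2.5, 40))
  expect_equal(const$span, 0)
  s0 <- summarize_prediction(rnorm(100), level = 0)
  expect_equal(s0$lower, s0$median)
  expect_equal(s0$upper, s0$median)
  expect_error(summarize_prediction(numeric()), "no draws")
})

test_that("novel subsectors use fixed effects only, known ones need no flag", {
  m <- point_mass_model(h1, "a", b_detect = 0.7, beta_detect = 0.4,
                        b_conc = 0.1, beta_conc = -0.2)
  qn <- data.frame(substance_id = "S3", subsector = "9999", novel = TRUE)
  p <- predict_detection(m, qn, props1)
  expect_equal(unname(p[1, 1]), plogis(0.4 * 2))  # zero intercept
  cc <- predict_concentration(m, qn, props1)
  expect_equal(unname(cc[1, 1]), -0.2 * 2)
  expect_error(
    predict_detection(m, data.frame(substance_id = "S3", subsector = "9999"),
                      props1),
    "novel flag"
  )
})

test_that("group summaries pool draws and respect partitions", {
  h <- hierarchy_index(c(`1101` = "11", `1201` = "12"))
  props <- data.frame(substance_id = c("S1", "S2"), a = c(-1, 1),
                      stringsAsFactors = FALSE)
  m <- point_mass_model(h, "a", b_detect = c(0.2, -0.4),
                        beta_detect = 0.5, b_conc = c(1, 0),
                        beta_conc = 0.3, sigma_eps = 0.5, n_draws = 400)
  obs <- data.frame(
    substance_id = c("S1", "S2", "S1"),
    subsector = c("1101", "1101", "1201"),
    sector = c("11", "11", "12"),
    stringsAsFactors = FALSE
  )
  by_sector <- summarize_by_group(m, obs, props, "sector", seed = 1)
  expect_equal(nrow(by_sector), 2L)
  # medians lie inside their own intervals
  expect_true(all(by_sector$p_median >= by_sector$p_lower &
                    by_sector$p_median <= by_sector$p_upper))
  expect_true(all(by_sector$conc_median >= by_sector$conc_lower &
                    by_sector$conc_median <= by_sector$conc_upper))

  # a single group equals the pooled per-query summary
  one <- obs[obs$sector == "12", ]
  g1 <- summarize_by_group(m, one, props, "sector", seed = 7)
  p_draws <- predict_detection(m, one[c("substance_id", "subsector")], props)
  expect_equal(g1$p_median, summarize_prediction(as.vector(p_draws))$median)

  # disjoint groups match computing each subset separately
  g_all <- summarize_by_group(m, obs, props, "sector",
                              include_residual = FALSE)
  g_11 <- summarize_by_group(m, obs[obs$sector == "11", ], props, "sector",
                             include_residual = FALSE)
  expect_equal(g_all[g_all$sector == "11", -1], g_11[, -1],
               ignore_attr = TRUE)

  expect_error(summarize_by_group(m, obs, props, "warehouse"))
})

test_that("substance ranking is descending, stable and order-invariant", {
  preds <- data.frame(
    substance_id = c("a", "b", "c"),
    p_median = c(0.9, 0.3, 0.6),
    conc_median = c(-1, 2, 2),
    stringsAsFactors = FALSE
  )
  r <- rank_substances(preds)
  expect_equal(r$substance_id[order(r$rank_detection)], c("a", "c", "b"))
  # concentration tie between b and c broken by id
  expect_equal(r$rank_concentration[r$substance_id == "b"], 1L)
  expect_equal(r$rank_concentration[r$substance_id == "c"], 2L)

  shuffled <- preds[c(3, 1, 2), ]
  r2 <- rank_substances(shuffled)
  expect_equal(r2[order(r2$substance_id), ], r[order(r$substance_id), ],
               ignore_attr = TRUE)

  single <- rank_substances(preds[1, ])
  expect_equal(single$rank_detection, 1L)
  expect_equal(single$rank_concentration, 1L)
})

test_that("the screening table back-transforms the median concentration", {
  m <- point_mass_model(h1, "a", b_detect = 0, beta_detect = 0,
                        b_conc = 2, beta_conc = 0, n_draws = 50)
  out <- predict(m, data.frame(substance_id = "S1", subsector = "1101"),
                 props1, include_residual = FALSE)
  expect_equal(out$conc_median_log10, 2)
  expect_equal(out$conc_median_mgm3, 100)
  expect_true(all(out$p_lower <= out$p_median & out$p_median <= out$p_upper))
})
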