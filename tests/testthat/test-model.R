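test_that("hurdle log-likelihood matches closed-form single-row values", {
  obs_nd <- data.frame(subsector = "SS1", detected = FALSE,
                       log10_conc = NA_real_, stringsAsFactors = FALSE)
  params <- list(
    detect = list(subsector_intercepts = c(SS1 = 0), coefficients = 0),
    concentration = list(subsector_intercepts = c(SS1 = 0),
                         coefficients = 0, sigma_eps = 1)
  )
  X <- matrix(0, 1, 1)
  # one nondetect at eta1 = 0: log(0.5)
  expect_equal(hurdle_log_likelihood(params, X, obs_nd), log(0.5))

  # one detect at y = eta2, sigma_eps = 1, detection probability -> 1:
  # the Gaussian density at its mean, -0.5 * log(2*pi)
  params2 <- params
  params2$detect$subsector_intercepts <- c(SS1 = 40)
  obs_d <- data.frame(subsector = "SS1", detected = TRUE, log10_conc = 0,
                      stringsAsFactors = FALSE)
  expect_equal(hurdle_log_likelihood(params2, X, obs_d), -0.5 * log(2 * pi),
               tolerance = 1e-12)

  params_bad <- params
  params_bad$concentration$sigma_eps <- 0
  expect_error(hurdle_log_likelihood(params_bad, X, obs_nd), "sigma_eps")
})

test_that("vectorized likelihood equals the brute-force oracle", {
  for (seed in 1:50) {
    inst <- random_likelihood_instance(seed)
    expect_equal(
      hurdle_log_likelihood(inst$params, inst$design, inst$obs),
      brute_force_loglik(inst$params, inst$design, inst$obs),
      tolerance = 1e-12
    )
  }
})

small_fit_data <- function(seed = 21, n = 800) {
  hierarchy <- generate_hierarchy(3, 2)
  substances <- generate_substances(30, n_properties = 2, seed = seed)
  std <- standardize(substances)
  truth <- draw_true_parameters(hierarchy, 3, seed = seed + 1)
  obs <- generate_observations(truth, std$data, hierarchy, n, seed = seed + 2)
  X <- build_design_matrix(std$data, obs)
  list(hierarchy = hierarchy, obs = obs, X = X, truth = truth,
       std = std, substances = substances)
}

test_that("stage fitting enforces its data contracts", {
  d <- small_fit_data()
  bad_obs <- d$obs
  bad_obs$subsector[1] <- "9999"
  expect_error(fit_stage("detect", d$X, bad_obs, d$hierarchy), "absent from hierarchy")

  no_det <- d$obs
  no_det$detected <- FALSE
  expect_error(fit_stage("concentration", d$X, no_det, d$hierarchy),
               "at least one detect")
})

test_that("fitting is deterministic given the seed", {
  d <- small_fit_data()
  cfg <- model_config(n_draws = 200, seed = 5)
  f1 <- fit_stage("detect", d$X, d$obs, d$hierarchy, cfg)
  f2 <- fit_stage("detect", d$X, d$obs, d$hierarchy, cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("a fitted model round-trips through disk bit-identically", {
  d <- small_fit_data()
  cfg <- model_config(n_draws = 150, seed = 9)
  model <- fit_hurdle(d$X, d$obs, d$hierarchy, cfg,
                      standardization = d$std$params)
  dir <- withr::local_tempdir()
  write_hurdle_model(model, dir)
  back <- read_hurdle_model(dir)
  expect_identical(back$detect$draws, model$detect$draws)
  expect_identical(back$concentration$draws, model$concentration$draws)
  expect_equal(back$standardization, model$standardization)
  expect_equal(back$hierarchy$sector_of, model$hierarchy$sector_of)
})

test_that("posterior draws are finite, positively scaled and well shaped", {
  d <- small_fit_data()
  cfg <- model_config(n_draws = 300, seed = 2)
  model <- fit_hurdle(d$X, d$obs, d$hierarchy, cfg)
  for (stage in c("detect", "concentration")) {
    pd <- model[[stage]]
    expect_true(all(is.finite(pd$draws)))
    expect_gte(nrow(pd$draws), cfg$n_draws)
    expect_equal(ncol(pd$draws),
                 1 + d$hierarchy$n_sectors + d$hierarchy$n_subsectors +
                   ncol(d$X) + 2 + (stage == "concentration"))
    expect_true(all(pd$draws[, pd$index$scales] > 0))
  }
})

test_that("sparse subsectors shrink toward their sector mean", {
  h <- hierarchy_index(c(`1101` = "11", `1102` = "11"))
  set.seed(4)
  n_big <- 200
  obs <- rbind(
    obs_table(sprintf("A%d", 1:n_big), "S1", "1101", "11", TRUE,
              rnorm(n_big, 0, 1)),
    obs_table(c("B1", "B2"), "S1", "1102", "11", TRUE, c(3, 3))
  )
  X <- matrix(rnorm(nrow(obs), 0, 0.1), ncol = 1,
              dimnames = list(NULL, "x"))
  fit <- fit_stage("concentration", X, obs, h, model_config(n_draws = 500))
  post <- colMeans(fit$draws)
  b_sparse <- post[["subsector[1102]"]]
  s_mean <- post[["sector[11]"]]
  raw_sparse <- 3
  # pulled toward the sector mean relative to its raw empirical estimate
  expect_lt(abs(b_sparse - s_mean), abs(raw_sparse - s_mean))
  expect_lt(b_sparse, raw_sparse)
})

test_that("laplace and MCMC posteriors agree on a small instance", {
  d <- small_fit_data()
  for (stage in c("detect", "concentration")) {
    lap <- fit_stage(stage, d$X, d$obs, d$hierarchy,
                     model_config(n_draws = 1000, seed = 3))
    mc <- fit_stage(stage, d$X, d$obs, d$hierarchy,
                    model_config(method = "mcmc", n_draws = 1500, seed = 3,
                                 mcmc = list(n_adapt = 500, n_burnin = 1000,
                                             thin = 2)))
    cl <- colMeans(lap$draws[, lap$index$coefficients, drop = FALSE])
    cm <- colMeans(mc$draws[, mc$index$coefficients, drop = FALSE])
    expect_lt(max(abs(cl - cm)), 0.1)
  }
})

test_that("with no data the posterior reproduces the prior", {
  h <- generate_hierarchy(2, 2)
  empty <- obs_table(character(), character(), character(), character(),
                     logical(), numeric())
  X <- matrix(numeric(), 0, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_stage("detect", X, empty, h,
                   model_config(method = "mcmc", n_draws = 4000, seed = 8,
                                mcmc = list(n_adapt = 500, n_burnin = 500)))
  # sigma0 ~ half-Cauchy(2.5): median equals the scale
  s0 <- fit$draws[, "sigma0"]
  expect_equal(unname(median(s0)), 2.5, tolerance = 0.25)
  expect_equal(mean(s0 < 2.5), 0.5, tolerance = 0.1)
  # mu ~ Normal(0, 5)
  mu <- fit$draws[, "mu"]
  expect_equal(unname(sd(mu)), 5, tolerance = 0.15)
  expect_equal(unname(mean(mu)), 0, tolerance = 0.4)
})
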