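# Shared fixtures, built lazily and cached for the whole test run. All are
# deterministic (fixed seeds), so expensive fits happen once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Full synthetic study at the default scale: 8 sectors / 30 subsectors,
# 300 substances, 6 properties (21 predictors), 30,000 observations.
study_fixture <- function() {
  fixture("study", function() run_pipeline(default_run_config(seed = 42)))
}

# Independent validation set drawn from the study's ground truth (never seen
# by the fit), used for coverage and closed-form error-rate checks.
validation_fixture <- function(n = 6000L) {
  fixture("validation", function() {
    res <- study_fixture()
    std_all <- standardize(res$substances)
    generate_observations(res$truth, std_all$data, res$hierarchy, n,
                          seed = 991L)
  })
}

# Small hierarchy + clean/raw data with known corruption for the
# preprocessing round-trip checks: every subsector gets ~100+ detects so the
# clean table is comfortably free of incidental |z|>4 rows and sparse
# subsectors.
roundtrip_fixture <- function() {
  fixture("roundtrip", function() {
    hierarchy <- generate_hierarchy(3, 3)
    substances <- generate_substances(40, seed = 11)
    std <- standardize(substances)
    truth <- draw_true_parameters(hierarchy, 21, seed = 12)
    clean <- generate_observations(truth, std$data, hierarchy, 2500,
                                   seed = 13)
    cfg <- corruption_config(n_blanks = 7, n_wipes = 4, n_nonconvertible = 9,
                             n_unmappable = 6, n_ambiguous = 3,
                             n_outliers = 2, outlier_min_group = 25)
    raw <- generate_raw_samples(clean, substances, cfg, seed = 14)
    list(hierarchy = hierarchy, substances = substances, clean = clean,
         raw = raw)
  })
}

# A hurdle model whose posterior is a point mass at hand-chosen parameters,
# for exact prediction arithmetic. `n_draws` identical rows.
point_mass_model <- function(hierarchy, property_names,
                             b_detect, beta_detect,
                             b_conc, beta_conc, sigma_eps = 1,
                             mu = 0, n_draws = 1L) {
  P <- length(property_names) + choose(length(property_names), 2L)
  coef_names <- colnames(design_rows(data.frame(
    substance_id = "x",
    stats::setNames(as.data.frame(matrix(0, 1, length(property_names))),
                    property_names)
  )))
  row <- function(stage, b, beta, extra = NULL) {
    c(mu, rep(mu, hierarchy$n_sectors), b, beta, 0.5, 0.5, extra)
  }
  mk <- function(stage, b, beta, extra = NULL) {
    draws <- matrix(rep(row(stage, b, beta, extra), each = n_draws),
                    nrow = n_draws)
    airhurdle:::new_posterior_draws(stage, draws, hierarchy, coef_names,
                                    method = "laplace", seed = 1L)
  }
  structure(
    list(detect = mk("detect", b_detect, beta_detect),
         concentration = mk("concentration", b_conc, beta_conc, sigma_eps),
         standardization = NULL, properties = property_names,
         hierarchy = hierarchy, config = model_config()),
    class = "hurdle_model"
  )
}

# Independent brute-force hurdle likelihood: a plain per-row loop over
# stats densities, kept deliberately naive as the oracle for the vectorized
# implementation.
brute_force_loglik <- function(params, design, observations) {
  total <- 0
  for (i in seq_len(nrow(observations))) {
    ss <- observations$subsector[i]
    eta1 <- params$detect$subsector_intercepts[[ss]] +
      sum(design[i, ] * params$detect$coefficients)
    total <- total + dbinom(as.integer(observations$detected[i]), 1,
                            plogis(eta1), log = TRUE)
    if (observations$detected[i]) {
      eta2 <- params$concentration$subsector_intercepts[[ss]] +
        sum(design[i, ] * params$concentration$coefficients)
      total <- total + dnorm(observations$log10_conc[i], eta2,
                             params$concentration$sigma_eps, log = TRUE)
    }
  }
  total
}

random_likelihood_instance <- function(seed) {
  set.seed(seed)
  J <- sample(2:5, 1)
  subsectors <- sprintf("SS%d", seq_len(J))
  P <- sample(1:4, 1)
  n <- sample(5:50, 1)
  X <- matrix(rnorm(n * P), n, P)
  detected <- runif(n) < 0.6
  obs <- data.frame(
    subsector = sample(subsectors, n, replace = TRUE),
    detected = detected,
    log10_conc = ifelse(detected, rnorm(n), NA_real_),
    stringsAsFactors = FALSE
  )
  params <- list(
    detect = list(subsector_intercepts = setNames(rnorm(J), subsectors),
                  coefficients = rnorm(P)),
    concentration = list(subsector_intercepts = setNames(rnorm(J), subsectors),
                         coefficients = rnorm(P),
                         sigma_eps = runif(1, 0.3, 2))
  )
  list(params = params, design = X, obs = obs)
}

# Raw-sample record constructor with sensible defaults.
raw_record <- function(inspection_id = "I1", substance_id = "S1",
                       sample_type = "personal", value = 1,
                       unit = "mg_per_m3", molecular_weight = NA_real_,
                       air_volume = NA_real_, industry_code = "L1101",
                       year = 2000L) {
  data.frame(inspection_id = inspection_id, substance_id = substance_id,
             sample_type = sample_type, value = value, unit = unit,
             molecular_weight = molecular_weight, air_volume = air_volume,
             industry_code = industry_code, year = year,
             stringsAsFactors = FALSE)
}

# Observation-table constructor.
obs_table <- function(inspection_id, substance_id, subsector, sector,
                      detected, log10_conc = NA_real_) {
  data.frame(inspection_id = inspection_id, substance_id = substance_id,
             sector = sector, subsector = subsector, detected = detected,
             log10_conc = log10_conc, stringsAsFactors = FALSE)
}
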