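#' Generate a synthetic substance-property table
#'
#' Draws physicochemical descriptors for `n_substances` substances from a
#' multivariate normal with a user-supplied correlation structure. The default
#' six descriptors emulate the roles of QSAR-predicted properties commonly
#' used for occupational screening (octanol-water partition coefficient,
#' boiling point, Henry's law constant, HPLC retention time, OH rate constant
#' and soil adsorption coefficient), on realistic location/scale so that
#' downstream centering and scaling is exercised. A `molecular_weight` column
#' (g/mol) is included for unit re-expression of raw samples; it is not a
#' model predictor.
#'
#' @param n_substances Number of substances (>= 1).
#' @param n_properties Number of descriptor columns.
#' @param property_correlation Correlation matrix (symmetric positive
#'   definite, unit diagonal) of the descriptors. Default: identity.
#' @param property_names Column names; defaults to the six standard
#'   abbreviations when `n_properties == 6`, otherwise `p1, p2, ...`.
#' @param property_means,property_sds Location and scale per descriptor.
#' @param seed Integer seed.
#' @return A data.frame with `substance_id`, `molecular_weight` and one
#'   column per descriptor.
#' @export
generate_substances <- function(n_substances,
                                n_properties = 6L,
                                property_correlation = NULL,
                                property_names = NULL,
                                property_means = NULL,
                                property_sds = NULL,
                                seed = 1L) {
  if (!is_count(n_substances) || n_substances < 1) {
    abort("`n_substances` must be a positive integer")
  }
  if (!is_count(n_properties) || n_properties < 1) {
    abort("`n_properties` must be a positive integer")
  }
  P <- as.integer(n_properties)
  if (is.null(property_correlation)) property_correlation <- diag(P)
  R <- as.matrix(property_correlation)
  if (nrow(R) != P || ncol(R) != P || max(abs(R - t(R))) > 1e-8 ||
      max(abs(diag(R) - 1)) > 1e-8) {
    abort("`property_correlation` must be a symmetric matrix with unit diagonal")
  }
  L <- tryCatch(chol(R), error = function(e) {
    abort("`property_correlation` must be positive definite")
  })
  defaults <- list(
    names = c("log_p", "bp", "log_hl", "rt", "log_oh", "log_koc"),
    means = c(1.98, 212.3, -5.48, 8.34, -11.2, 2.19),
    sds   = c(2.0, 90.0, 2.0, 7.0, 1.0, 1.0)
  )
  nm <- property_names %||% (if (P == 6L) defaults$names else paste0("p", seq_len(P)))
  mu <- property_means %||% (if (P == 6L) defaults$means else rep(0, P))
  sd <- property_sds %||% (if (P == 6L) defaults$sds else rep(1, P))
  if (length(nm) != P || length(mu) != P || length(sd) != P) {
    abort("property names/means/sds must have length `n_properties`")
  }
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_substances * P), n_substances, P) %*% L
    X <- sweep(sweep(Z, 2, sd, `*`), 2, mu, `+`)
    colnames(X) <- nm
    out <- data.frame(
      substance_id = sprintf("SUB%05d", seq_len(n_substances)),
      molecular_weight = stats::runif(n_substances, 30, 300),
      stringsAsFactors = FALSE
    )
    cbind(out, as.data.frame(X))
  })
}

#' Hyperparameter configuration for the synthetic ground truth
#'
#' Defines the generative hyperparameters of the two hurdle stages. Subsector
#' intercepts are drawn around their sector mean from a Student-T with
#' `nu` degrees of freedom and scale `sigma0`; sector means are drawn around
#' the global location `mu` with scale `sigma01`; property coefficients are
#' i.i.d. normal with sd `coef_sd`; the concentration stage has residual sd
#' `sigma_eps` on the log10 mg/m3 scale.
#'
#' Defaults emulate compliance air-monitoring data: a global detection rate
#' around 60% (roughly 40% nondetects), detected concentrations spanning
#' several orders of magnitude, and a residual sd of 1 order of magnitude.
#'
#' @param nu Student-T degrees of freedom for both intercept levels.
#' @param detect,concentration Per-stage lists with elements `mu`, `sigma0`,
#'   `sigma01`, `coef_sd` and (concentration only) `sigma_eps`.
#' @return A list of class `synthetic_hyper_config`.
#' @export
synthetic_hyper_config <- function(nu = 3,
                                   detect = list(mu = 0.5, sigma0 = 0.5,
                                                 sigma01 = 0.75, coef_sd = 0.3),
                                   concentration = list(mu = -1, sigma0 = 0.5,
                                                        sigma01 = 0.75,
                                                        coef_sd = 0.3,
                                                        sigma_eps = 1.0)) {
  cfg <- list(nu = nu, detect = detect, concentration = concentration)
  if (!is.numeric(nu) || nu <= 0) abort("`nu` must be > 0")
  for (st in c("detect", "concentration")) {
    s <- cfg[[st]]
    for (f in c("sigma0", "sigma01", "coef_sd")) {
      if (!is.numeric(s[[f]]) || s[[f]] < 0) {
        abort(sprintf("`%s$%s` must be a nonnegative scale", st, f))
      }
    }
  }
  if (!is.numeric(concentration$sigma_eps) || concentration$sigma_eps < 0) {
    abort("`concentration$sigma_eps` must be a nonnegative scale")
  }
  structure(cfg, class = "synthetic_hyper_config")
}

#' Draw ground-truth parameters for both hurdle stages
#'
#' Samples the generative parameters of the detection and concentration
#' stages: sector means around the global location, subsector intercepts
#' around their sector mean (both Student-T), and i.i.d. normal property
#' coefficients. A zero scale collapses the corresponding level to its mean,
#' which is convenient for degenerate-limit checks.
#'
#' @param hierarchy A [hierarchy_index()].
#' @param n_predictors Width of the design matrix (main effects plus
#'   interactions) the coefficients apply to.
#' @param hyper_config A [synthetic_hyper_config()].
#' @param seed Integer seed.
#' @return A list of class `true_parameters` with per-stage components
#'   `mu`, `sector_means` (named), `subsector_intercepts` (named),
#'   `coefficients`, `sigma0`, `sigma01` and (concentration) `sigma_eps`.
#' @export
draw_true_parameters <- function(hierarchy, n_predictors,
                                 hyper_config = synthetic_hyper_config(),
                                 seed = 1L) {
  stopifnot(inherits(hierarchy, "hierarchy_index"))
  if (!is_count(n_predictors)) abort("`n_predictors` must be a count")
  if (!inherits(hyper_config, "synthetic_hyper_config")) {
    hyper_config <- do.call(synthetic_hyper_config, hyper_config)
  }
  nu <- hyper_config$nu
  draw_stage <- function(cfg) {
    sector_means <- stats::setNames(
      cfg$mu + cfg$sigma01 * stats::rt(hierarchy$n_sectors, df = nu),
      hierarchy$sector_ids
    )
    subsector_intercepts <- stats::setNames(
      sector_means[hierarchy$sector_of] +
        cfg$sigma0 * stats::rt(hierarchy$n_subsectors, df = nu),
      hierarchy$subsector_ids
    )
    list(
      mu = cfg$mu,
      sector_means = sector_means,
      subsector_intercepts = subsector_intercepts,
      coefficients = stats::rnorm(n_predictors, 0, cfg$coef_sd),
      sigma0 = cfg$sigma0,
      sigma01 = cfg$sigma01
    )
  }
  with_seed(seed, {
    detect <- draw_stage(hyper_config$detect)
    conc <- draw_stage(hyper_config$concentration)
    conc$sigma_eps <- hyper_config$concentration$sigma_eps
    structure(
      list(detect = detect, concentration = conc, nu = nu,
           hierarchy = hierarchy, n_predictors = as.integer(n_predictors)),
      class = "true_parameters"
    )
  })
}

#' Generate clean inspection-level observations from known parameters
#'
#' Simulates the hurdle data-generating process: each observation gets a
#' uniformly random subsector and substance; detection is Bernoulli with
#' probability `plogis(eta1)`; detected observations get a log10
#' concentration drawn from `Normal(eta2, sigma_eps)`. The linear predictors
#' use the subsector intercept plus the standardized property main effects
#' and all pairwise interactions.
#'
#' @param params A `true_parameters` object.
#' @param substances Substance-property table, already standardized the way
#'   the model expects (see [standardize()]).
#' @param hierarchy A [hierarchy_index()].
#' @param n_obs Number of observations.
#' @param seed Integer seed.
#' @return A data.frame with columns `inspection_id`, `substance_id`,
#'   `sector`, `subsector`, `detected` (logical) and `log10_conc`
#'   (log10 mg/m3; `NA` for nondetects).
#' @export
generate_observations <- function(params, substances, hierarchy, n_obs,
                                  seed = 1L) {
  stopifnot(inherits(params, "true_parameters"),
            inherits(hierarchy, "hierarchy_index"))
  if (is.null(substances) || nrow(substances) < 1L) {
    abort("`substances` must contain at least one row")
  }
  if (!is_count(n_obs) || n_obs < 1) abort("`n_obs` must be a positive integer")
  rows <- design_rows(substances)
  if (ncol(rows) != params$n_predictors) {
    abort("substance table implies a design width different from the truth")
  }
  with_seed(seed, {
    sub_idx <- sample.int(nrow(substances), n_obs, replace = TRUE)
    j_idx <- sample.int(hierarchy$n_subsectors, n_obs, replace = TRUE)
    subsector <- hierarchy$subsector_ids[j_idx]
    X <- rows[sub_idx, , drop = FALSE]
    eta1 <- unname(params$detect$subsector_intercepts[subsector]) +
      drop(X %*% params$detect$coefficients)
    detected <- stats::runif(n_obs) < stats::plogis(eta1)
    eta2 <- unname(params$concentration$subsector_intercepts[subsector]) +
      drop(X %*% params$concentration$coefficients)
    log10_conc <- ifelse(
      detected,
      stats::rnorm(n_obs, eta2, params$concentration$sigma_eps),
      NA_real_
    )
    data.frame(
      inspection_id = sprintf("INSP%07d", seq_len(n_obs)),
      substance_id = substances$substance_id[sub_idx],
      sector = unname(hierarchy$sector_of[subsector]),
      subsector = subsector,
      detected = detected,
      log10_conc = log10_conc,
      stringsAsFactors = FALSE
    )
  })
}

#' Corruption configuration for the raw-sample generator
#'
#' Controls how clean observations are expanded into raw sample records and
#' how many junk rows of each category are injected. Each category is dropped
#' at exactly one stage of the preprocessing pipeline, so the returned ledger
#' can be checked against the pipeline's drop log.
#'
#' @param samples_per_inspection_median Median of the shifted-geometric
#'   number of samples per inspection (the observed real-world median is 3).
#' @param unit_mix Named probabilities over `mg_per_m3`, `ppm`, `percent`,
#'   `mass_only` used to re-express individual samples (all invertible).
#' @param area_fraction Fraction of retained samples typed `area` rather than
#'   `personal`.
#' @param n_blanks,n_wipes Counts of blank / wipe rows (dropped by the
#'   sample-type filter).
#' @param n_nonconvertible Count of rows whose units cannot be converted
#'   (fibers/cc, ppm without molecular weight, mass without air volume).
#' @param n_unmappable Count of rows with industry codes absent from the
#'   concordance.
#' @param n_ambiguous Count of rows whose industry code maps to more than one
#'   subsector (the concordance gains matching ambiguous entries).
#' @param n_outliers Count of injected extreme concentration observations
#'   (z-score above `z_max` within their substance).
#' @param outlier_min_group Minimum number of clean detects a substance needs
#'   before an outlier is injected into it. With the inclusive z-score
#'   convention a single outlier can reach |z| > 4 only in groups of at least
#'   19 observations, so this must be comfortably above that.
#' @param outlier_offset Orders of magnitude added above the substance's
#'   maximum to form an outlier.
#' @param z_max Outlier threshold the injected rows are verified against.
#' @return A list of class `corruption_config`.
#' @export
corruption_config <- function(samples_per_inspection_median = 3,
                              unit_mix = c(mg_per_m3 = 0.6, ppm = 0.2,
                                           percent = 0.05, mass_only = 0.15),
                              area_fraction = 0.04,
                              n_blanks = 0L, n_wipes = 0L,
                              n_nonconvertible = 0L, n_unmappable = 0L,
                              n_ambiguous = 0L, n_outliers = 0L,
                              outlier_min_group = 25L,
                              outlier_offset = 9,
                              z_max = 4) {
  counts <- c(n_blanks = n_blanks, n_wipes = n_wipes,
              n_nonconvertible = n_nonconvertible,
              n_unmappable = n_unmappable, n_ambiguous = n_ambiguous,
              n_outliers = n_outliers)
  if (!all(vapply(counts, is_count, logical(1)))) {
    abort("injection counts must be nonnegative integers")
  }
  if (!is.numeric(samples_per_inspection_median) ||
      samples_per_inspection_median < 1) {
    abort("`samples_per_inspection_median` must be >= 1")
  }
  if (area_fraction < 0 || area_fraction > 1) {
    abort("`area_fraction` must lie in [0, 1]")
  }
  nm <- c("mg_per_m3", "ppm", "percent", "mass_only")
  if (!setequal(names(unit_mix), nm) || any(unit_mix < 0) ||
      abs(sum(unit_mix) - 1) > 1e-8) {
    abort("`unit_mix` must be probabilities over mg_per_m3/ppm/percent/mass_only")
  }
  structure(
    list(samples_per_inspection_median = samples_per_inspection_median,
         unit_mix = unit_mix[nm], area_fraction = area_fraction,
         n_blanks = as.integer(n_blanks), n_wipes = as.integer(n_wipes),
         n_nonconvertible = as.integer(n_nonconvertible),
         n_unmappable = as.integer(n_unmappable),
         n_ambiguous = as.integer(n_ambiguous),
         n_outliers = as.integer(n_outliers),
         outlier_min_group = as.integer(outlier_min_group),
         outlier_offset = outlier_offset, z_max = z_max),
    class = "corruption_config"
  )
}

# molar volume (L/mol) of an ideal gas at 25 C and 1 atm; the standard
# industrial-hygiene convention for ppm <-> mg/m3 conversion
MOLAR_VOLUME_L <- 24.45

#' Expand clean observations into corrupted raw sample records
#'
#' Inverts the preprocessing pipeline: each clean inspection-level
#' observation becomes one or more raw samples whose maximum converted value
#' equals the clean value (extra samples are strictly smaller), individual
#' samples are re-expressed in ppm, percent or mass units (all invertible via
#' molecular weight / sampled air volume), and junk rows are injected per the
#' corruption configuration. Running the preprocessing pipeline on the output
#' recovers the clean table and a drop log matching the returned ledger.
#'
#' @param clean Clean observation table from [generate_observations()].
#' @param substances Substance table providing `molecular_weight`.
#' @param config A [corruption_config()].
#' @param seed Integer seed.
#' @param concordance_prefix Prefix for legacy industry codes (see
#'   [build_concordance()]).
#' @return A list with `records` (raw sample table), `ledger` (data.frame of
#'   injected counts per category) and `concordance` (mapping table under
#'   which the clean rows are uniquely mappable and the injected junk is not).
#' @export
generate_raw_samples <- function(clean, substances,
                                 config = corruption_config(), seed = 1L,
                                 concordance_prefix = "L") {
  stopifnot(inherits(config, "corruption_config"))
  required <- c("inspection_id", "substance_id", "sector", "subsector",
                "detected", "log10_conc")
  if (!all(required %in% names(clean))) {
    abort("`clean` must be an inspection-observation table")
  }
  mw_of <- stats::setNames(substances$molecular_weight, substances$substance_id)
  if (anyNA(mw_of[unique(clean$substance_id)])) {
    abort("every substance in `clean` needs a molecular weight")
  }
  sector_of <- stats::setNames(clean$sector, clean$subsector)
  concordance <- data.frame(
    old_code = paste0(concordance_prefix, names(sector_of)[!duplicated(names(sector_of))]),
    sector = unname(sector_of[!duplicated(names(sector_of))]),
    subsector = names(sector_of)[!duplicated(names(sector_of))],
    stringsAsFactors = FALSE
  )

  p_geom <- 1 - 0.5^(1 / config$samples_per_inspection_median)
  units <- names(config$unit_mix)

  with_seed(seed, {
    n <- nrow(clean)
    n_samples <- 1L + stats::rgeom(n, p_geom)
    idx <- rep.int(seq_len(n), n_samples)
    total <- length(idx)
    # per-sample mg/m3 values: the first sample of each observation carries
    # the maximum; the rest are strictly smaller so unit round-trip noise
    # (one ulp) cannot change the per-inspection max
    first <- !duplicated(idx)
    mg_max <- ifelse(clean$detected, 10^clean$log10_conc, 0)[idx]
    frac <- stats::runif(total, 0.05, 0.95)
    mg <- ifelse(first, mg_max, mg_max * frac)
    unit <- sample(units, total, replace = TRUE, prob = config$unit_mix)
    mw <- unname(mw_of[clean$substance_id[idx]])
    vol <- stats::runif(total, 0.1, 2)
    value <- mg
    value[unit == "ppm"] <- mg[unit == "ppm"] * MOLAR_VOLUME_L / mw[unit == "ppm"]
    value[unit == "percent"] <-
      mg[unit == "percent"] * MOLAR_VOLUME_L / mw[unit == "percent"] / 1e4
    value[unit == "mass_only"] <- mg[unit == "mass_only"] * vol[unit == "mass_only"]
    records <- data.frame(
      inspection_id = clean$inspection_id[idx],
      substance_id = clean$substance_id[idx],
      sample_type = sample(c("personal", "area"), total, replace = TRUE,
                           prob = c(1 - config$area_fraction, config$area_fraction)),
      value = value,
      unit = unit,
      molecular_weight = ifelse(unit %in% c("ppm", "percent"), mw, NA_real_),
      air_volume = ifelse(unit == "mass_only", vol, NA_real_),
      industry_code = paste0(concordance_prefix, clean$subsector[idx]),
      year = sample(1984:2018, total, replace = TRUE),
      stringsAsFactors = FALSE
    )

    junk_row <- function(i, type, unit, value, mw, volume, code) {
      data.frame(
        inspection_id = sprintf("JUNK%05d", i),
        substance_id = sample(substances$substance_id, 1L),
        sample_type = type, value = value, unit = unit,
        molecular_weight = mw, air_volume = volume, industry_code = code,
        year = sample(1984:2018, 1L), stringsAsFactors = FALSE
      )
    }
    valid_code <- concordance$old_code[1L]
    junk <- list()
    i_junk <- 0L
    add_junk <- function(type, unit, value, mw, volume, code) {
      i_junk <<- i_junk + 1L
      junk[[length(junk) + 1L]] <<-
        junk_row(i_junk, type, unit, value, mw, volume, code)
    }
    for (b in seq_len(config$n_blanks)) {
      add_junk("blank", "mg_per_m3", stats::runif(1, 0, 0.1), NA_real_,
               NA_real_, valid_code)
    }
    for (w in seq_len(config$n_wipes)) {
      add_junk("wipe", "mg_per_m3", stats::runif(1, 0, 5), NA_real_,
               NA_real_, valid_code)
    }
    nonconv_kinds <- rep_len(c("fibers_per_cc", "ppm_no_mw", "mass_no_volume"),
                             config$n_nonconvertible)
    for (kind in nonconv_kinds) {
      if (kind == "fibers_per_cc") {
        add_junk("personal", "fibers_per_cc", stats::runif(1, 0.1, 10),
                 NA_real_, NA_real_, valid_code)
      } else if (kind == "ppm_no_mw") {
        add_junk("personal", "ppm", stats::runif(1, 0.1, 10), NA_real_,
                 NA_real_, valid_code)
      } else {
        add_junk("personal", "mass_only", stats::runif(1, 0.1, 10), NA_real_,
                 NA_real_, valid_code)
      }
    }
    for (u in seq_len(config$n_unmappable)) {
      add_junk("personal", "mg_per_m3", stats::runif(1, 0.1, 10), NA_real_,
               NA_real_, sprintf("UNK%03d", u))
    }
    if (config$n_ambiguous > 0L) {
      if (nrow(concordance) < 2L) {
        abort("ambiguous codes need a hierarchy with at least two subsectors")
      }
      for (a in seq_len(config$n_ambiguous)) {
        code <- sprintf("AMB%03d", a)
        pick <- sample.int(nrow(concordance), 2L)
        concordance <- rbind(concordance, data.frame(
          old_code = code, sector = concordance$sector[pick],
          subsector = concordance$subsector[pick], stringsAsFactors = FALSE
        ))
        add_junk("personal", "mg_per_m3", stats::runif(1, 0.1, 10), NA_real_,
                 NA_real_, code)
      }
    }

    outliers <- NULL
    if (config$n_outliers > 0L) {
      det <- clean[clean$detected, ]
      counts <- table(det$substance_id)
      eligible <- names(counts)[counts >= config$outlier_min_group]
      if (length(eligible) < config$n_outliers) {
        abort(sprintf(
          "only %d substances have >= %d detects; cannot inject %d outliers",
          length(eligible), config$outlier_min_group, config$n_outliers))
      }
      targets <- sample(eligible, config$n_outliers)
      out_rows <- lapply(seq_along(targets), function(t) {
        sid <- targets[t]
        vals <- det$log10_conc[det$substance_id == sid]
        # grow the offset until the injected point clears the z threshold
        # with margin; |z| saturates at n/sqrt(n+1), which outlier_min_group
        # keeps safely above z_max
        offset <- config$outlier_offset
        repeat {
          extreme <- max(vals) + offset
          z <- abs(extreme - mean(c(vals, extreme))) /
            stats::sd(c(vals, extreme))
          if (z > config$z_max * 1.05 || offset > 250) break
          offset <- offset * 2
        }
        if (z <= config$z_max) {
          abort("injected outlier cannot exceed the z threshold; the substance group is too small")
        }
        row <- det[det$substance_id == sid, ][1L, ]
        data.frame(
          inspection_id = sprintf("OUTL%04d", t),
          substance_id = sid, sample_type = "personal",
          value = 10^extreme, unit = "mg_per_m3",
          molecular_weight = NA_real_, air_volume = NA_real_,
          industry_code = paste0(concordance_prefix, row$subsector),
          year = sample(1984:2018, 1L), stringsAsFactors = FALSE
        )
      })
      outliers <- do.call(rbind, out_rows)
    }

    records <- rbind(records, do.call(rbind, c(junk, list(outliers))))
    records <- records[sample.int(nrow(records)), ]
    rownames(records) <- NULL
    ledger <- data.frame(
      category = c("blank", "wipe", "non_convertible", "unmappable",
                   "ambiguous_code", "outlier"),
      count = c(config$n_blanks, config$n_wipes, config$n_nonconvertible,
                config$n_unmappable, config$n_ambiguous, config$n_outliers),
      stringsAsFactors = FALSE
    )
    list(records = records, ledger = ledger, concordance = concordance)
  })
}
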