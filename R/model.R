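#' Configuration for fitting the hierarchical hurdle model
#'
#' Priors follow the weakly-informative conventions for hierarchical GLMs on
#' standardized predictors: subsector intercepts are Student-T around their
#' sector mean, sector means Student-T around a global location, property
#' coefficients Student-T(3, 0, 2.5), the global location Normal(0, 5) on the
#' logit (detection) stage and Normal(0, 10) on the concentration stage, and
#' all scale parameters (both T scales and the residual sd) half-Cauchy.
#'
#' Two inference backends produce joint posterior draws: `"laplace"` (the
#' default), a full-rank Gaussian approximation centred at the posterior mode
#' of the exact hierarchical posterior, and `"mcmc"`, a JAGS sampler used as
#' the reference method. Both are deterministic given `seed`.
#'
#' @param nu Degrees of freedom of the hierarchical Student-T levels.
#' @param coef_df,coef_scale Student-T prior on the property coefficients.
#' @param intercept_prior_sd Named vector: Normal prior sd of the global
#'   location, per stage.
#' @param hc_scale Half-Cauchy scale for sigma0, sigma01 and sigma_eps.
#' @param method `"laplace"` or `"mcmc"`.
#' @param n_draws Number of posterior draws (>= 1).
#' @param seed Integer seed for draw generation / the sampler.
#' @param mcmc List of sampler settings: `n_adapt`, `n_burnin`, `thin`.
#' @param optim_maxit Iteration cap for the mode search.
#' @return A list of class `model_config`.
#' @export
model_config <- function(nu = 3, coef_df = 3, coef_scale = 2.5,
                         intercept_prior_sd = c(detect = 5, concentration = 10),
                         hc_scale = 2.5,
                         method = c("laplace", "mcmc"),
                         n_draws = 2000L, seed = 1L,
                         mcmc = list(n_adapt = 500L, n_burnin = 1000L, thin = 1L),
                         optim_maxit = 2000L) {
  method <- match.arg(method)
  if (!is.numeric(nu) || nu <= 0) abort("`nu` must be > 0")
  for (v in c(coef_scale, hc_scale, intercept_prior_sd)) {
    if (!is.numeric(v) || any(v <= 0)) abort("prior scales must be > 0")
  }
  if (!is_count(n_draws) || n_draws < 1) abort("`n_draws` must be >= 1")
  structure(
    list(nu = nu, coef_df = coef_df, coef_scale = coef_scale,
         intercept_prior_sd = intercept_prior_sd, hc_scale = hc_scale,
         method = method, n_draws = as.integer(n_draws),
         seed = as.integer(seed), mcmc = mcmc,
         optim_maxit = as.integer(optim_maxit)),
    class = "model_config"
  )
}

# location-scale Student-T log density and d/dx
dt_ls <- function(x, df, loc, scale) {
  stats::dt((x - loc) / scale, df = df, log = TRUE) - log(scale)
}
dt_ls_dx <- function(x, df, loc, scale) {
  z <- (x - loc) / scale
  -(df + 1) * z / ((df + z^2) * scale)
}
# half-Cauchy log density of sigma = exp(ls), including the log-scale
# Jacobian, and its derivative wrt ls
half_cauchy_lp <- function(ls, scale) {
  s <- exp(ls)
  log(2 / (pi * scale)) - log1p((s / scale)^2) + ls
}
half_cauchy_dlp <- function(ls, scale) {
  r2 <- (exp(ls) / scale)^2
  1 - 2 * r2 / (1 + r2)
}

# assemble per-stage fitting data; errors mirror the data contracts
stage_data <- function(stage, design, observations, hierarchy) {
  stopifnot(inherits(hierarchy, "hierarchy_index"))
  if (nrow(design) != nrow(observations)) {
    abort("design matrix and observations must have the same number of rows")
  }
  j <- match(observations$subsector, hierarchy$subsector_ids)
  if (anyNA(j)) {
    abort(sprintf("subsector(s) absent from hierarchy: %s",
                  paste(unique(observations$subsector[is.na(j)]), collapse = ", ")))
  }
  if (stage == "detect") {
    y <- as.numeric(observations$detected)
    X <- design
  } else {
    det <- observations$detected
    if (!any(det)) abort("concentration stage requires at least one detect")
    y <- observations$log10_conc[det]
    X <- design[det, , drop = FALSE]
    j <- j[det]
  }
  k_of_j <- match(unname(hierarchy$sector_of), hierarchy$sector_ids)
  list(y = y, X = X, j = j, k_of_j = k_of_j,
       J = hierarchy$n_subsectors, K = hierarchy$n_sectors, P = ncol(design))
}

# negative log posterior and gradient over the packed parameter vector
# (mu, s[1:K], b[1:J], beta[1:P], log sigma0, log sigma01[, log sigma_eps])
stage_posterior <- function(sd, stage, config) {
  J <- sd$J; K <- sd$K; P <- sd$P
  i_mu <- 1L
  i_s <- 1L + seq_len(K)
  i_b <- 1L + K + seq_len(J)
  i_beta <- 1L + K + J + seq_len(P)
  i_ls0 <- 1L + K + J + P + 1L
  i_ls01 <- i_ls0 + 1L
  i_lse <- if (stage == "concentration") i_ls01 + 1L else NA_integer_
  nu <- config$nu
  sd_mu <- unname(config$intercept_prior_sd[[
    if (stage == "detect") "detect" else "concentration"]])

  unpack <- function(par) {
    out <- list(mu = par[i_mu], s = par[i_s], b = par[i_b],
                beta = par[i_beta], sigma0 = exp(par[i_ls0]),
                sigma01 = exp(par[i_ls01]))
    if (stage == "concentration") out$sigma_eps <- exp(par[i_lse])
    out
  }

  nlp <- function(par) {
    p <- unpack(par)
    eta <- p$b[sd$j] + drop(sd$X %*% p$beta)
    ll <- if (stage == "detect") {
      sum(stats::plogis(ifelse(sd$y > 0.5, eta, -eta), log.p = TRUE))
    } else {
      sum(stats::dnorm(sd$y, eta, p$sigma_eps, log = TRUE))
    }
    lp <- ll +
      sum(dt_ls(p$b, nu, p$s[sd$k_of_j], p$sigma0)) +
      sum(dt_ls(p$s, nu, p$mu, p$sigma01)) +
      stats::dnorm(p$mu, 0, sd_mu, log = TRUE) +
      sum(dt_ls(p$beta, config$coef_df, 0, config$coef_scale)) +
      half_cauchy_lp(par[i_ls0], config$hc_scale) +
      half_cauchy_lp(par[i_ls01], config$hc_scale)
    if (stage == "concentration") {
      lp <- lp + half_cauchy_lp(par[i_lse], config$hc_scale)
    }
    -lp
  }

  grad <- function(par) {
    p <- unpack(par)
    eta <- p$b[sd$j] + drop(sd$X %*% p$beta)
    r <- if (stage == "detect") {
      sd$y - stats::plogis(eta)
    } else {
      (sd$y - eta) / p$sigma_eps^2
    }
    g <- numeric(length(par))
    db <- numeric(J)
    agg <- rowsum(r, sd$j)
    db[as.integer(rownames(agg))] <- agg
    # likelihood terms
    g[i_b] <- db
    g[i_beta] <- drop(crossprod(sd$X, r))
    # hierarchical prior on b
    zb <- dt_ls_dx(p$b, nu, p$s[sd$k_of_j], p$sigma0)
    g[i_b] <- g[i_b] + zb
    ds <- numeric(K)
    aggs <- rowsum(-zb, sd$k_of_j)
    ds[as.integer(rownames(aggs))] <- aggs
    zb_std <- (p$b - p$s[sd$k_of_j]) / p$sigma0
    g[i_ls0] <- sum(-1 + (nu + 1) * zb_std^2 / (nu + zb_std^2)) +
      half_cauchy_dlp(par[i_ls0], config$hc_scale)
    # prior on s
    zs <- dt_ls_dx(p$s, nu, p$mu, p$sigma01)
    g[i_s] <- ds + zs
    g[i_mu] <- -sum(zs) - p$mu / sd_mu^2
    zs_std <- (p$s - p$mu) / p$sigma01
    g[i_ls01] <- sum(-1 + (nu + 1) * zs_std^2 / (nu + zs_std^2)) +
      half_cauchy_dlp(par[i_ls01], config$hc_scale)
    # prior on beta
    g[i_beta] <- g[i_beta] +
      dt_ls_dx(p$beta, config$coef_df, 0, config$coef_scale)
    if (stage == "concentration") {
      g[i_lse] <- sum(-1 + ((sd$y - eta) / p$sigma_eps)^2) +
        half_cauchy_dlp(par[i_lse], config$hc_scale)
    }
    -g
  }

  list(nlp = nlp, grad = grad, unpack = unpack,
       index = list(mu = i_mu, sectors = i_s, subsectors = i_b,
                    coefficients = i_beta, log_scales = c(i_ls0, i_ls01, i_lse)))
}

#' Hurdle model log-likelihood at a parameter point
#'
#' Sums, over observations, the Bernoulli log-likelihood of the detection
#' flags under `plogis(eta1)` and, for detected observations only, the
#' Gaussian log-likelihood of the log10 concentration around `eta2` with
#' residual sd `sigma_eps`. Both linear predictors are the observation's
#' subsector intercept plus the design-matrix row times the stage
#' coefficients.
#'
#' @param params List with components `detect` (list `subsector_intercepts`
#'   named by subsector, `coefficients`) and `concentration` (same plus
#'   `sigma_eps > 0`).
#' @param design Observation-aligned design matrix.
#' @param observations Observation table with `subsector`, `detected`,
#'   `log10_conc`.
#' @return The total log-likelihood (scalar).
#' @export
hurdle_log_likelihood <- function(params, design, observations) {
  se <- params$concentration$sigma_eps
  if (!is.numeric(se) || se <= 0) abort("`sigma_eps` must be > 0")
  b1 <- params$detect$subsector_intercepts[observations$subsector]
  b2 <- params$concentration$subsector_intercepts[observations$subsector]
  if (anyNA(b1) || anyNA(b2)) {
    abort("missing subsector intercept for some observations")
  }
  eta1 <- unname(b1) + drop(design %*% params$detect$coefficients)
  ll <- sum(stats::plogis(ifelse(observations$detected, eta1, -eta1),
                          log.p = TRUE))
  det <- observations$detected
  if (any(det)) {
    eta2 <- unname(b2)[det] +
      drop(design[det, , drop = FALSE] %*% params$concentration$coefficients)
    ll <- ll + sum(stats::dnorm(observations$log10_conc[det], eta2, se,
                                log = TRUE))
  }
  ll
}

new_posterior_draws <- function(stage, draws, hierarchy, coef_names, method,
                                seed, mode = NULL) {
  K <- hierarchy$n_sectors; J <- hierarchy$n_subsectors
  P <- length(coef_names)
  scales <- c("sigma0", "sigma01", if (stage == "concentration") "sigma_eps")
  colnames(draws) <- c("mu",
                       paste0("sector[", hierarchy$sector_ids, "]"),
                       paste0("subsector[", hierarchy$subsector_ids, "]"),
                       coef_names, scales)
  if (any(!is.finite(draws))) abort("non-finite posterior draws")
  structure(
    list(stage = stage,
         link = if (stage == "detect") "logit" else "identity",
         draws = draws,
         index = list(mu = 1L, sectors = 1L + seq_len(K),
                      subsectors = 1L + K + seq_len(J),
                      coefficients = 1L + K + J + seq_len(P),
                      scales = 1L + K + J + P + seq_along(scales)),
         coef_names = coef_names, hierarchy = hierarchy,
         method = method, seed = seed, mode = mode),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %s stage (%s link): %d draws x %d parameters [%s]\n",
              x$stage, x$link, nrow(x$draws), ncol(x$draws), x$method))
  invisible(x)
}

fit_stage_laplace <- function(sd, stage, hierarchy, config) {
  post <- stage_posterior(sd, stage, config)
  d <- 1L + sd$K + sd$J + sd$P + 2L + (stage == "concentration")
  init <- numeric(d)
  if (stage == "detect") {
    p0 <- min(max(mean(sd$y), 0.02), 0.98)
    init[post$index$mu] <- stats::qlogis(p0)
  } else {
    init[post$index$mu] <- mean(sd$y)
  }
  init[post$index$sectors] <- init[post$index$mu]
  init[post$index$subsectors] <- init[post$index$mu]
  init[post$index$log_scales[1:2]] <- log(0.5)
  if (stage == "concentration") {
    init[post$index$log_scales[3]] <- log(max(stats::sd(sd$y), 0.1))
  }
  opt <- stats::optim(init, post$nlp, post$grad, method = "BFGS",
                      control = list(maxit = config$optim_maxit,
                                     reltol = 1e-12))
  H <- stats::optimHess(opt$par, post$nlp, post$grad)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values) * 1e-10)
  A <- ev$vectors %*% diag(1 / sqrt(lam), length(lam))
  draws <- with_seed(config$seed, {
    Z <- matrix(stats::rnorm(config$n_draws * d), config$n_draws, d)
    Z %*% t(A) + matrix(opt$par, config$n_draws, d, byrow = TRUE)
  })
  ls <- post$index$log_scales[!is.na(post$index$log_scales)]
  draws[, ls] <- exp(draws[, ls])
  new_posterior_draws(stage, draws, hierarchy, colnames(sd$X),
                      method = "laplace", seed = config$seed, mode = opt$par)
}

jags_model_string <- function(stage, with_likelihood) {
  lik <- if (!with_likelihood) "" else if (stage == "detect") "
  for (i in 1:n) {
    logit(p[i]) <- b[jj[i]] + inprod(X[i,], beta)
    y[i] ~ dbern(p[i])
  }" else "
  for (i in 1:n) {
    eta[i] <- b[jj[i]] + inprod(X[i,], beta)
    y[i] ~ dnorm(eta[i], pow(sigma_eps, -2))
  }"
  sig_eps <- if (stage == "concentration") "
  sigma_eps ~ dt(0, pow(hc_scale, -2), 1) T(0,)" else ""
  paste0("model {", lik, "
  for (j in 1:J) { b[j] ~ dt(s[k_of_j[j]], pow(sigma0, -2), nu) }
  for (k in 1:K) { s[k] ~ dt(mu, pow(sigma01, -2), nu) }
  mu ~ dnorm(0, pow(sd_mu, -2))
  for (m in 1:P) { beta[m] ~ dt(0, pow(coef_scale, -2), coef_df) }
  sigma0 ~ dt(0, pow(hc_scale, -2), 1) T(0,)
  sigma01 ~ dt(0, pow(hc_scale, -2), 1) T(0,)", sig_eps, "
}")
}

fit_stage_mcmc <- function(sd, stage, hierarchy, config) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    abort("method 'mcmc' requires the rjags package")
  }
  n <- length(sd$y)
  data <- list(J = sd$J, K = sd$K, P = sd$P, k_of_j = sd$k_of_j,
               nu = config$nu, coef_df = config$coef_df,
               coef_scale = config$coef_scale, hc_scale = config$hc_scale,
               sd_mu = unname(config$intercept_prior_sd[[
                 if (stage == "detect") "detect" else "concentration"]]))
  if (n > 0L) {
    data$n <- n; data$y <- sd$y; data$X <- sd$X; data$jj <- sd$j
  }
  ms <- jags_model_string(stage, with_likelihood = n > 0L)
  jm <- rjags::jags.model(
    textConnection(ms), data = data, n.chains = 1L, quiet = TRUE,
    n.adapt = config$mcmc$n_adapt %||% 500L,
    inits = list(.RNG.name = "base::Wichmann-Hill",
                 .RNG.seed = config$seed)
  )
  stats::update(jm, config$mcmc$n_burnin %||% 1000L, progress.bar = "none")
  vars <- c("mu", "s", "b", "beta", "sigma0", "sigma01",
            if (stage == "concentration") "sigma_eps")
  thin <- config$mcmc$thin %||% 1L
  samp <- rjags::coda.samples(jm, vars, n.iter = config$n_draws * thin,
                              thin = thin, progress.bar = "none")
  m <- as.matrix(samp[[1L]])
  pick <- function(stub, len) {
    if (len == 1L && stub %in% colnames(m)) return(m[, stub, drop = FALSE])
    m[, paste0(stub, "[", seq_len(len), "]"), drop = FALSE]
  }
  draws <- cbind(pick("mu", 1L), pick("s", sd$K), pick("b", sd$J),
                 pick("beta", sd$P), pick("sigma0", 1L), pick("sigma01", 1L))
  if (stage == "concentration") draws <- cbind(draws, pick("sigma_eps", 1L))
  new_posterior_draws(stage, unname(draws), hierarchy, colnames(sd$X),
                      method = "mcmc", seed = config$seed)
}

#' Fit one stage of the hurdle model
#'
#' The detection stage is a hierarchical logistic regression on all
#' observations' binary detect/nondetect response; the concentration stage
#' is a hierarchical linear regression on the detected observations' log10
#' concentrations. Both share the prior structure described in
#' [model_config()].
#'
#' @param stage `"detect"` or `"concentration"`.
#' @param design Observation-aligned design matrix (standardized mains +
#'   interactions).
#' @param observations Observation table (`subsector`, `detected`,
#'   `log10_conc`).
#' @param hierarchy A [hierarchy_index()] covering every observed subsector.
#' @param config A [model_config()].
#' @return A `posterior_draws` object.
#' @export
fit_stage <- function(stage = c("detect", "concentration"), design,
                      observations, hierarchy, config = model_config()) {
  stage <- match.arg(stage)
  sd <- stage_data(stage, design, observations, hierarchy)
  if (config$method == "laplace") {
    if (length(sd$y) == 0L) abort("laplace fitting requires observations")
    fit_stage_laplace(sd, stage, hierarchy, config)
  } else {
    fit_stage_mcmc(sd, stage, hierarchy, config)
  }
}

#' Fit the two-stage hierarchical hurdle model
#'
#' Fits the detection stage on all rows and the concentration stage on the
#' detected subset, and bundles the posterior draws with the standardization
#' parameters and retained property list needed to predict for new
#' substance-by-workplace pairs.
#'
#' @inheritParams fit_stage
#' @param standardization Optional standardization parameter table (from
#'   [standardize()]); stored for prediction-time reuse.
#' @param properties Character vector of retained property names; defaults
#'   to the design matrix's `main_columns` attribute.
#' @return An object of class `hurdle_model`.
#' @export
fit_hurdle <- function(design, observations, hierarchy,
                       config = model_config(), standardization = NULL,
                       properties = NULL) {
  detect <- fit_stage("detect", design, observations, hierarchy, config)
  conc_config <- config
  conc_config$seed <- derive_seed(config$seed, "concentration-stage")
  concentration <- fit_stage("concentration", design, observations, hierarchy,
                             conc_config)
  structure(
    list(detect = detect, concentration = concentration,
         standardization = standardization,
         properties = properties %||% attr(design, "main_columns"),
         hierarchy = hierarchy, config = config),
    class = "hurdle_model"
  )
}

#' @export
print.hurdle_model <- function(x, ...) {
  cat(sprintf(
    "<hurdle_model> %d subsectors / %d sectors, %d predictors, %d draws (%s)\n",
    x$hierarchy$n_subsectors, x$hierarchy$n_sectors,
    length(x$detect$coef_names), nrow(x$detect$draws), x$detect$method))
  invisible(x)
}

#' Persist a fitted hurdle model to a directory
#'
#' Writes each stage's draws as a columnar CSV at full double precision (so
#' a load round-trips bit-identically) plus a YAML metadata file carrying the
#' hierarchy, column names, configuration and standardization parameters.
#'
#' @param model A `hurdle_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hurdle_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (stage in c("detect", "concentration")) {
    pd <- model[[stage]]
    df <- as.data.frame(pd$draws, check.names = FALSE)
    write_csv_full_precision(df, file.path(dir, paste0(stage, "_draws.csv")))
  }
  meta <- list(
    hierarchy = as.list(model$hierarchy$sector_of),
    properties = model$properties,
    coef_names = model$detect$coef_names,
    methods = list(detect = model$detect$method,
                   concentration = model$concentration$method),
    seeds = list(detect = model$detect$seed,
                 concentration = model$concentration$seed),
    config = unclass(model$config)[c("nu", "coef_df", "coef_scale",
                                     "hc_scale", "method", "n_draws", "seed")]
  )
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  if (!is.null(model$standardization)) {
    write_csv_full_precision(model$standardization,
                             file.path(dir, "standardization.csv"))
  }
  invisible(dir)
}

#' Load a hurdle model written by [write_hurdle_model()]
#'
#' @param dir Directory containing `detect_draws.csv`,
#'   `concentration_draws.csv` and `metadata.yaml`.
#' @return A `hurdle_model` with bit-identical draw matrices.
#' @export
read_hurdle_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  hierarchy <- hierarchy_index(unlist(meta$hierarchy))
  read_stage <- function(stage) {
    df <- utils::read.csv(file.path(dir, paste0(stage, "_draws.csv")),
                          check.names = FALSE)
    new_posterior_draws(stage, as.matrix(df), hierarchy,
                        coef_names = unlist(meta$coef_names),
                        method = meta$methods[[stage]],
                        seed = meta$seeds[[stage]])
  }
  std_path <- file.path(dir, "standardization.csv")
  std <- if (file.exists(std_path)) {
    utils::read.csv(std_path, stringsAsFactors = FALSE)
  }
  cfg <- do.call(model_config, meta$config)
  structure(
    list(detect = read_stage("detect"),
         concentration = read_stage("concentration"),
         standardization = std, properties = unlist(meta$properties),
         hierarchy = hierarchy, config = cfg),
    class = "hurdle_model"
  )
}
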