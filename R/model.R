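#' Prior configuration for the multilevel Poisson-lognormal model
#'
#' Weakly-informative defaults: inverse-gamma(0.001, 0.001) on the
#' observation-level lognormal variance, inverse-Wishart(identity, dim + 1)
#' on each random-effect / fixed-effect covariance matrix, half-Cauchy
#' (scale 4) hyperpriors on the per-component scales tau of the prior-mean
#' vectors, and Normal(0, tau^2) on the prior means themselves.
#'
#' @param ig_shape,ig_rate inverse-gamma hyperparameters for `sigma2_s`.
#' @param iw_df_offset inverse-Wishart degrees of freedom are
#'   `dim + iw_df_offset` (default 1, the weakly-informative convention);
#'   scale matrix is the identity.
#' @param tau_scale half-Cauchy scale for the tau hyper-scales.
#' @param re_means `"zero"` (default): random-effect rows are MVN(0, Sigma),
#'   identifiable against the fixed intercept/slopes. `"hierarchical"`:
#'   the prior means rho_h (estuary) and rho_v (program) are estimated with
#'   their own Normal/half-Cauchy layers.
#' @param beta_fixed_prior `NULL` (default) places the hierarchical
#'   MVN(rho_m, Sigma3) prior on beta; alternatively a
#'   `list(mean =, sd =)` of independent Normal priors (recycled to length
#'   9), used for reduced/benchmark fits where the hyper layer is not
#'   wanted.
#' @return object of class `prior_config`.
#' @export
prior_config <- function(ig_shape = 0.001, ig_rate = 0.001,
                         iw_df_offset = 1, tau_scale = 4,
                         re_means = c("zero", "hierarchical"),
                         beta_fixed_prior = NULL) {
  re_means <- match.arg(re_means)
  stopifnot(ig_shape > 0, ig_rate > 0, tau_scale > 0, iw_df_offset >= 1)
  if (!is.null(beta_fixed_prior)) {
    beta_fixed_prior$mean <- rep_len(beta_fixed_prior$mean, 9)
    beta_fixed_prior$sd <- rep_len(beta_fixed_prior$sd, 9)
    stopifnot(all(beta_fixed_prior$sd > 0))
  }
  structure(list(ig_shape = ig_shape, ig_rate = ig_rate,
                 iw_df_offset = iw_df_offset, tau_scale = tau_scale,
                 re_means = re_means, beta_fixed_prior = beta_fixed_prior),
            class = "prior_config")
}

#' Construct a full parameter state for the richness model
#'
#' Holds every symbol of the generative model: fixed effects `beta`
#' (intercept, salinity, temperature, then the six LULC covariates in
#' [lulc_groups()] order), crossed random intercept/slope matrices
#' `alpha_est` (J x 3) and `alpha_prog` (K x 3), the observation-level
#' lognormal variance `sigma2_s`, prior-mean vectors `rho_m/rho_h/rho_v`,
#' covariances `Sigma1` (estuary effects), `Sigma2` (program effects),
#' `Sigma3` (fixed effects), hyper-scales `tau_m/tau_h/tau_v`, and
#' optionally the per-row latent `log_lambda`.
#'
#' @param beta numeric length 9.
#' @param alpha_est J x 3 matrix (intercept, salinity slope, temperature
#'   slope per estuary).
#' @param alpha_prog K x 3 matrix per trawl program.
#' @param sigma2_s observation-level variance, > 0.
#' @param Sigma1,Sigma2,Sigma3 covariance matrices (3, 3, 9).
#' @param rho_m,rho_h,rho_v prior mean vectors (9, 3, 3).
#' @param tau_m,tau_h,tau_v positive hyper-scale vectors (9, 3, 3).
#' @param log_lambda optional per-row latent log expected counts.
#' @return object of class `model_params`.
#' @export
model_params <- function(beta = numeric(9),
                         alpha_est = matrix(0, 1, 3),
                         alpha_prog = matrix(0, 1, 3),
                         sigma2_s = 1,
                         Sigma1 = diag(3), Sigma2 = diag(3),
                         Sigma3 = diag(9),
                         rho_m = numeric(9), rho_h = numeric(3),
                         rho_v = numeric(3),
                         tau_m = rep(1, 9), tau_h = rep(1, 3),
                         tau_v = rep(1, 3),
                         log_lambda = NULL) {
  stopifnot(length(beta) == 9, ncol(alpha_est) == 3, ncol(alpha_prog) == 3,
            length(sigma2_s) == 1)
  structure(list(beta = as.numeric(beta),
                 alpha_est = alpha_est, alpha_prog = alpha_prog,
                 sigma2_s = sigma2_s,
                 Sigma1 = Sigma1, Sigma2 = Sigma2, Sigma3 = Sigma3,
                 rho_m = rho_m, rho_h = rho_h, rho_v = rho_v,
                 tau_m = tau_m, tau_h = tau_h, tau_v = tau_v,
                 log_lambda = log_lambda),
            class = "model_params")
}

#' Linear predictor of the richness model
#'
#' `g = beta0 + sum_i beta_i X_i + alpha0_j + alpha1_j X1 + alpha2_j X2
#'  + alpha0_k + alpha1_k X1 + alpha2_k X2`, where X3-X8 are the row's
#' estuary-level LULC covariates. Vectorised over the rows of `data`.
#'
#' @param params a [model_params()].
#' @param data a [model_data()] (or any list with `j`, `k`, `x1`, `x2`,
#'   `estuary_x`).
#' @param rows optional row subset.
#' @return numeric vector of linear-predictor values.
#' @export
linear_predictor <- function(params, data, rows = NULL) {
  j <- data$j; k <- data$k; x1 <- data$x1; x2 <- data$x2
  if (!is.null(rows)) {
    j <- j[rows]; k <- k[rows]; x1 <- x1[rows]; x2 <- x2[rows]
  }
  if (any(j < 1 | j > nrow(params$alpha_est)) ||
      any(k < 1 | k > nrow(params$alpha_prog))) {
    stop("estuary/program index out of range", call. = FALSE)
  }
  b <- params$beta
  fe <- b[1] + b[2] * x1 + b[3] * x2 +
    as.numeric(data$estuary_x[j, , drop = FALSE] %*% b[4:9])
  ae <- params$alpha_est[j, , drop = FALSE]
  ap <- params$alpha_prog[k, , drop = FALSE]
  fe + ae[, 1] + ae[, 2] * x1 + ae[, 3] * x2 +
    ap[, 1] + ap[, 2] * x1 + ap[, 3] * x2
}

#' Simulate richness counts from the generative model
#'
#' `log lambda ~ Normal(g, sigma2_s)`, `Y ~ Poisson(lambda)`, with `g` from
#' [linear_predictor()]. `sigma2_s = 0` degenerates to `Y ~ Poisson(exp(g))`.
#'
#' @param params a [model_params()].
#' @param data_design a [model_data()]-like design (counts in `y`, if any,
#'   are ignored).
#' @param seed integer seed; the draw is reproducible given it.
#' @return list with `y` (counts), `log_lambda`, `g`.
#' @export
simulate_counts <- function(params, data_design, seed) {
  stopifnot(params$sigma2_s >= 0)
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  g <- linear_predictor(params, data_design)
  ll <- if (params$sigma2_s > 0) {
    stats::rnorm(length(g), g, sqrt(params$sigma2_s))
  } else g
  y <- stats::rpois(length(g), exp(ll))
  list(y = y, log_lambda = ll, g = g)
}

#' Log joint density of data and parameters
#'
#' Sums, on the log scale: the Poisson likelihood of the counts given
#' `lambda = exp(log_lambda)`; the Normal density of `log_lambda` around
#' the linear predictor with variance `sigma2_s`; the inverse-gamma prior
#' on `sigma2_s`; MVN priors on each estuary and program random-effect row
#' and on `beta`; inverse-Wishart priors on the covariances; Normal(0, tau)
#' priors on the prior-mean vectors; and half-Cauchy priors on the tau
#' scales. Parameters outside their support yield `-Inf` rather than an
#' error. Layers switched off by the `prior_config` (zero-mean random
#' effects, fixed independent beta prior) contribute nothing.
#'
#' @param params a [model_params()] with `log_lambda` set.
#' @param data a [model_data()].
#' @param priors a [prior_config()].
#' @return scalar log density (possibly `-Inf`).
#' @export
log_joint <- function(params, data, priors = prior_config()) {
  p <- params
  if (!is.finite(p$sigma2_s) || p$sigma2_s <= 0) return(-Inf)
  if (any(c(p$tau_m, p$tau_h, p$tau_v) <= 0)) return(-Inf)
  if (is.null(p$log_lambda)) stop("params$log_lambda is required",
                                  call. = FALSE)
  g <- linear_predictor(p, data)
  lp <- sum(stats::dpois(data$y, exp(p$log_lambda), log = TRUE)) +
    sum(stats::dnorm(p$log_lambda, g, sqrt(p$sigma2_s), log = TRUE)) +
    dinvgamma_log(p$sigma2_s, priors$ig_shape, priors$ig_rate)

  hier <- priors$re_means == "hierarchical"
  mu_h <- if (hier) p$rho_h else numeric(3)
  mu_v <- if (hier) p$rho_v else numeric(3)
  for (j in seq_len(nrow(p$alpha_est))) {
    lp <- lp + dmvnorm_log(p$alpha_est[j, ], mu_h, p$Sigma1)
  }
  for (k in seq_len(nrow(p$alpha_prog))) {
    lp <- lp + dmvnorm_log(p$alpha_prog[k, ], mu_v, p$Sigma2)
  }
  lp <- lp + dinvwishart_log(p$Sigma1, diag(3), 3 + priors$iw_df_offset) +
    dinvwishart_log(p$Sigma2, diag(3), 3 + priors$iw_df_offset)
  if (hier) {
    lp <- lp + sum(stats::dnorm(p$rho_h, 0, p$tau_h, log = TRUE)) +
      sum(dhalfcauchy_log(p$tau_h, priors$tau_scale)) +
      sum(stats::dnorm(p$rho_v, 0, p$tau_v, log = TRUE)) +
      sum(dhalfcauchy_log(p$tau_v, priors$tau_scale))
  }
  if (is.null(priors$beta_fixed_prior)) {
    lp <- lp + dmvnorm_log(p$beta, p$rho_m, p$Sigma3) +
      dinvwishart_log(p$Sigma3, diag(9), 9 + priors$iw_df_offset) +
      sum(stats::dnorm(p$rho_m, 0, p$tau_m, log = TRUE)) +
      sum(dhalfcauchy_log(p$tau_m, priors$tau_scale))
  } else {
    lp <- lp + sum(stats::dnorm(p$beta, priors$beta_fixed_prior$mean,
                                priors$beta_fixed_prior$sd, log = TRUE))
  }
  lp
}
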