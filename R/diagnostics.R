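#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF: with m chains of length n, `W` the mean
#' within-chain variance and `B/n` the between-chain variance of the chain
#' means, `var+ = (n-1)/n W + B/n` and `Rhat = sqrt(var+/W)`. The split-chain
#' variant (each chain halved before the computation) is available by flag.
#'
#' @param chains list of equal-length numeric vectors (one per chain), or a
#'   matrix with one column per chain.
#' @param split halve each chain first (detects within-chain trends).
#' @return scalar R-hat.
#' @export
gelman_rubin <- function(chains, split = FALSE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(i) chains[, i])
  if (length(chains) < 2) stop("need >= 2 chains", call. = FALSE)
  n <- unique(vapply(chains, length, 1L))
  if (length(n) != 1) stop("chains must have equal length", call. = FALSE)
  if (split) {
    h <- floor(n / 2)
    chains <- unlist(lapply(chains, function(ch) {
      list(ch[seq_len(h)], ch[(length(ch) - h + 1):length(ch)])
    }), recursive = FALSE)
    n <- h
  }
  if (n < 2) stop("chains must have length >= 2", call. = FALSE)
  m <- length(chains)
  means <- vapply(chains, mean, 1)
  vars <- vapply(chains, stats::var, 1)
  W <- mean(vars)
  if (W == 0) stop("degenerate chains: zero within-chain variance",
                   call. = FALSE)
  B_over_n <- stats::var(means)           # = B/n
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

#' Per-parameter convergence report for a fit
#'
#' @param draws a [fit_richness()] result.
#' @param threshold pass rule: all monitored R-hat below this (default 1.10).
#' @param split use split-chain R-hat.
#' @return list with `rhat` (named vector), `max_rhat`, `nmin`
#'   (Raftery-Lewis minimum chain length at the default quantile settings),
#'   `threshold`, `pass`.
#' @export
convergence_report <- function(draws, threshold = 1.10, split = FALSE) {
  pars <- draws$meta$monitor
  rhat <- vapply(pars, function(p) {
    ch <- lapply(draws$chains, function(m) m[, p])
    tryCatch(gelman_rubin(ch, split = split), error = function(e) NA_real_)
  }, 1)
  rhat <- rhat[!is.na(rhat)]                 # constant (clamped) params drop
  list(rhat = rhat, max_rhat = max(rhat), nmin = raftery_lewis_nmin(),
       threshold = threshold, pass = max(rhat) < threshold)
}

#' Raftery-Lewis minimum chain length
#'
#' Independence-chain minimum of the Raftery-Lewis run-length diagnostic:
#' the number of draws needed to estimate the posterior quantile `q` to
#' within `+/- r` with probability `s`,
#' `Nmin = ceiling(q (1 - q) (z_{(1+s)/2} / r)^2)`. The defaults (2.5%
#' quantile, accuracy 0.005, probability 0.95) give 3746.
#'
#' @param q posterior quantile of interest in (0, 1).
#' @param r target accuracy, > 0.
#' @param s target probability in (0, 1).
#' @return integer minimum number of draws.
#' @export
raftery_lewis_nmin <- function(q = 0.025, r = 0.005, s = 0.95) {
  if (!(q > 0 && q < 1) || r <= 0 || !(s > 0 && s < 1)) {
    stop("require 0 < q < 1, r > 0, 0 < s < 1", call. = FALSE)
  }
  z <- stats::qnorm((1 + s) / 2)
  as.integer(ceiling(q * (1 - q) * (z / r)^2))
}

# chi-square and Freeman-Tukey discrepancies between counts and means
discrepancy_fun <- function(name = c("chisq", "freeman-tukey")) {
  name <- match.arg(name)
  switch(name,
         "chisq" = function(y, lambda) sum((y - lambda)^2 / lambda),
         "freeman-tukey" = function(y, lambda)
           sum((sqrt(y) - sqrt(lambda))^2))
}

#' Posterior predictive check (Bayesian p-value)
#'
#' For each posterior draw, data are replicated from `Poisson(lambda)` and
#' a discrepancy `T` is evaluated at the replicated and the observed
#' counts; the Bayesian p-value is the proportion of draws with
#' `T(y_new, theta) >= T(y, theta)` (ties count). Values between 0.1 and
#' 0.9 indicate no evidence of lack of fit.
#'
#' @param draws a [fit_richness()] result with stored latent draws.
#' @param data a [model_data()]; defaults to the fitted data.
#' @param discrepancy `"chisq"` (default) or `"freeman-tukey"`.
#' @param max_draws thin to at most this many posterior draws.
#' @param seed seed for the replicate draws (default derived from the fit).
#' @return object of class `ppc_result`: `bayes_p`, `discrepancy`, and the
#'   per-draw `T_rep` / `T_obs` pairs.
#' @export
posterior_predictive_p <- function(draws, data = draws$meta$data,
                                   discrepancy = c("chisq", "freeman-tukey"),
                                   max_draws = 1000,
                                   seed = draws$meta$seed + 1L) {
  discrepancy <- match.arg(discrepancy)
  lam <- exp(lambda_matrix(draws))
  if (any(lam <= 0) || any(!is.finite(lam))) {
    stop("non-positive or non-finite lambda draw", call. = FALSE)
  }
  ppc_core(lam, data$y, discrepancy, max_draws, seed)
}

ppc_core <- function(lam, y, discrepancy, max_draws, seed) {
  Tfun <- discrepancy_fun(discrepancy)
  idx <- if (nrow(lam) > max_draws) {
    round(seq(1, nrow(lam), length.out = max_draws))
  } else seq_len(nrow(lam))
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  T_rep <- numeric(length(idx)); T_obs <- numeric(length(idx))
  for (i in seq_along(idx)) {
    l <- lam[idx[i], ]
    y_new <- stats::rpois(length(l), l)
    T_rep[i] <- Tfun(y_new, l)
    T_obs[i] <- Tfun(y, l)
  }
  structure(list(bayes_p = mean(T_rep >= T_obs), discrepancy = discrepancy,
                 T_rep = T_rep, T_obs = T_obs),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("posterior predictive check (%s): Bayes p = %.3f\n",
              x$discrepancy, x$bayes_p))
  cat(if (x$bayes_p > 0.1 && x$bayes_p < 0.9)
    "  within (0.1, 0.9): no evidence of lack of fit\n"
    else "  outside (0.1, 0.9): evidence of misfit\n")
  invisible(x)
}

#' Hold-out validation via the posterior predictive distribution
#'
#' For each posterior draw, hold-out counts are replicated from the full
#' Poisson-lognormal predictive (linear predictor from the drawn `beta` and
#' random effects, fresh lognormal layer, Poisson draw) and both observed
#' and replicated counts are scored against the draw's marginal moments
#' (`mu = exp(g + sigma2/2)`, `v = mu + mu^2 (exp(sigma2) - 1)` for the
#' chi-square discrepancy). Referring both to the same moments keeps the
#' Bayesian p-value calibrated for rows whose latent rates were never
#' conditioned on. Rows from estuaries or programs unseen in
#' fitting get random effects drawn fresh from the drawn covariance (and
#' prior-mean, under the hierarchical mode) per posterior draw; a message
#' reports how many such groups occurred. If the hold-out rows are
#' literally the fitted rows, the stored latent draws are reused so that
#' the result coincides with [posterior_predictive_p()].
#'
#' @param draws a [fit_richness()] result.
#' @param holdout_data a [model_data()] of hold-out rows.
#' @param discrepancy,max_draws,seed as in [posterior_predictive_p()].
#' @return a `ppc_result`.
#' @export
validate_holdout <- function(draws, holdout_data,
                             discrepancy = c("chisq", "freeman-tukey"),
                             max_draws = 1000,
                             seed = draws$meta$seed + 1L) {
  discrepancy <- match.arg(discrepancy)
  if (is.null(holdout_data) || length(holdout_data$y) == 0) {
    stop("empty hold-out set", call. = FALSE)
  }
  fit_data <- draws$meta$data
  if (identical(holdout_data[c("y", "j", "k", "x1", "x2")],
                fit_data[c("y", "j", "k", "x1", "x2")])) {
    return(posterior_predictive_p(draws, holdout_data, discrepancy,
                                  max_draws, seed))
  }
  m <- as.matrix(draws)
  if (nrow(m) > max_draws) {
    m <- m[round(seq(1, nrow(m), length.out = max_draws)), , drop = FALSE]
  }
  nd <- nrow(m)
  hj <- holdout_data$j; hk <- holdout_data$k
  J_fit <- fit_data$J; K_fit <- fit_data$K
  # rows whose estuary/program was not seen in fitting (NA or beyond range)
  # are pooled into one fresh group each
  hj[is.na(hj)] <- J_fit + 1L
  hk[is.na(hk)] <- K_fit + 1L
  holdout_data$j <- hj
  holdout_data$k <- hk
  new_j <- sort(unique(hj[hj > J_fit]))
  new_k <- sort(unique(hk[hk > K_fit]))
  if (length(new_j) || length(new_k)) {
    message(length(new_j), " unseen estuaries and ", length(new_k),
            " unseen programs in hold-out: random effects drawn from the ",
            "fitted covariance posterior")
  }
  # estuary-level covariates for unseen estuaries default to the grand mean
  # (zero on the centered scale)
  if (length(new_j)) {
    holdout_data$estuary_x <- rbind(
      holdout_data$estuary_x,
      matrix(0, max(new_j) - nrow(holdout_data$estuary_x), 6))
  }
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)
  hier <- draws$meta$priors$re_means == "hierarchical"
  n <- length(holdout_data$y)
  y <- holdout_data$y
  Tfun <- discrepancy_fun(discrepancy)
  T_rep <- numeric(nd); T_obs <- numeric(nd)
  for (d in seq_len(nd)) {
    p <- draw_to_params(m[d, ], J_fit, K_fit)
    # fresh effects for unseen groups
    if (length(new_j) || length(new_k)) {
      mu_h <- if (hier) p$rho_h else numeric(3)
      mu_v <- if (hier) p$rho_v else numeric(3)
      if (length(new_j)) {
        extra <- t(vapply(new_j, function(z) rmvnorm1(mu_h, p$Sigma1),
                          numeric(3)))
        p$alpha_est <- rbind(p$alpha_est, extra)
      }
      if (length(new_k)) {
        extra <- t(vapply(new_k, function(z) rmvnorm1(mu_v, p$Sigma2),
                          numeric(3)))
        p$alpha_prog <- rbind(p$alpha_prog, extra)
      }
    }
    g <- linear_predictor(p, holdout_data)
    s2 <- p$sigma2_s
    # marginal Poisson-lognormal moments given the structural parameters:
    # both the observed and the replicated counts are referred to the same
    # moments, so the check is calibrated for genuinely new rows
    mu <- exp(g + s2 / 2)
    v <- mu + mu^2 * (exp(s2) - 1)
    y_new <- stats::rpois(n, exp(stats::rnorm(n, g, sqrt(s2))))
    if (discrepancy == "chisq") {
      T_rep[d] <- sum((y_new - mu)^2 / v)
      T_obs[d] <- sum((y - mu)^2 / v)
    } else {
      T_rep[d] <- Tfun(y_new, mu)
      T_obs[d] <- Tfun(y, mu)
    }
  }
  structure(list(bayes_p = mean(T_rep >= T_obs), discrepancy = discrepancy,
                 T_rep = T_rep, T_obs = T_obs),
            class = "ppc_result")
}

# reconstruct a model_params from one stored draw row
draw_to_params <- function(row, J, K) {
  model_params(
    beta = row[sprintf("beta[%d]", 0:8)],
    alpha_est = matrix(row[sprintf("alpha_est[%d,%d]",
                                   rep(seq_len(J), 3), rep(0:2, each = J))],
                       J, 3),
    alpha_prog = matrix(row[sprintf("alpha_prog[%d,%d]",
                                    rep(seq_len(K), 3), rep(0:2, each = K))],
                        K, 3),
    sigma2_s = row[["sigma2_s"]],
    Sigma1 = matrix(row[sprintf("Sigma1[%d,%d]", rep(1:3, 3),
                                rep(1:3, each = 3))], 3, 3),
    Sigma2 = matrix(row[sprintf("Sigma2[%d,%d]", rep(1:3, 3),
                                rep(1:3, each = 3))], 3, 3),
    rho_m = row[sprintf("rho_m[%d]", 0:8)],
    rho_h = row[sprintf("rho_h[%d]", 0:2)],
    rho_v = row[sprintf("rho_v[%d]", 0:2)])
}
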