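test_that("linear predictor equals the term-by-term sum", {
  md <- toy_model_data(n = 12, J = 3, K = 2)
  p0 <- random_params(3, 2)
  p0$beta[] <- 0; p0$alpha_est[] <- 0; p0$alpha_prog[] <- 0
  expect_equal(linear_predictor(p0, md), rep(0, 12))
  p0$beta[1] <- 1
  expect_equal(linear_predictor(p0, md), rep(1, 12))

  # randomized oracle: independent scalar loop over every term
  p <- random_params(3, 2, seed = 8)
  g <- linear_predictor(p, md)
  for (i in seq_len(12)) {
    jj <- md$j[i]; kk <- md$k[i]
    expected <- p$beta[1] + p$beta[2] * md$x1[i] + p$beta[3] * md$x2[i]
    for (m in 1:6) expected <- expected + p$beta[3 + m] * md$estuary_x[jj, m]
    expected <- expected + p$alpha_est[jj, 1] +
      p$alpha_est[jj, 2] * md$x1[i] + p$alpha_est[jj, 3] * md$x2[i] +
      p$alpha_prog[kk, 1] + p$alpha_prog[kk, 2] * md$x1[i] +
      p$alpha_prog[kk, 3] * md$x2[i]
    expect_equal(g[i], unname(expected), tolerance = 1e-12)
  }
  bad <- md; bad$j[1] <- 9L
  expect_error(linear_predictor(p, bad), "out of range")
})

test_that("simulated counts have Poisson-lognormal moments", {
  n <- 10000
  des <- list(j = rep(1L, n), k = rep(1L, n), x1 = numeric(n),
              x2 = numeric(n), estuary_x = matrix(0, 1, 6))
  p <- model_params(beta = c(log(4), rep(0, 8)), sigma2_s = 0)
  sim <- simulate_counts(p, des, seed = 42)
  se <- sqrt(4 / n)
  expect_lt(abs(mean(sim$y) - 4), 3 * se)

  # lognormal layer: E[Y] = exp(g + sigma2/2), Var > mean
  p2 <- model_params(beta = c(log(4), rep(0, 8)), sigma2_s = 0.5)
  sim2 <- simulate_counts(p2, des, seed = 43)
  mu <- 4 * exp(0.25)
  var_y <- mu + mu^2 * (exp(0.5) - 1)
  expect_lt(abs(mean(sim2$y) - mu), 3 * sqrt(var_y / n))
  expect_gt(var(sim2$y), mean(sim2$y))

  # determinism
  expect_identical(simulate_counts(p2, des, seed = 7)$y,
                   simulate_counts(p2, des, seed = 7)$y)
})

# --- independent density implementations for the log-joint oracle ---------
oracle_dmvnorm <- function(x, m, S) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) + determinant(S)$modulus[1] +
            t(x - m) %*% solve(S) %*% (x - m))[1]
}
oracle_dinvgamma <- function(x, a, b) a * log(b) - lgamma(a) -
  (a + 1) * log(x) - b / x
oracle_dhalfcauchy <- function(x, s) log(2) - log(pi * s) -
  log(1 + (x / s)^2)
oracle_dinvwish <- function(X, Psi, nu) {
  d <- nrow(X)
  lg <- d * (d - 1) / 4 * log(pi) +
    sum(lgamma(nu / 2 + (1 - seq_len(d)) / 2))
  nu / 2 * determinant(Psi)$modulus[1] - nu * d / 2 * log(2) - lg -
    (nu + d + 1) / 2 * determinant(X)$modulus[1] -
    0.5 * sum(diag(Psi %*% solve(X)))
}

oracle_log_joint <- function(p, md, priors) {
  g <- numeric(length(md$y))
  for (i in seq_along(md$y)) {
    jj <- md$j[i]; kk <- md$k[i]
    g[i] <- p$beta[1] + p$beta[2] * md$x1[i] + p$beta[3] * md$x2[i] +
      sum(p$beta[4:9] * md$estuary_x[jj, ]) +
      p$alpha_est[jj, 1] + p$alpha_est[jj, 2] * md$x1[i] +
      p$alpha_est[jj, 3] * md$x2[i] +
      p$alpha_prog[kk, 1] + p$alpha_prog[kk, 2] * md$x1[i] +
      p$alpha_prog[kk, 3] * md$x2[i]
  }
  lp <- sum(md$y * p$log_lambda - exp(p$log_lambda) - lfactorial(md$y)) +
    sum(-0.5 * log(2 * pi * p$sigma2_s) -
          (p$log_lambda - g)^2 / (2 * p$sigma2_s)) +
    oracle_dinvgamma(p$sigma2_s, priors$ig_shape, priors$ig_rate)
  hier <- priors$re_means == "hierarchical"
  mu_h <- if (hier) p$rho_h else numeric(3)
  mu_v <- if (hier) p$rho_v else numeric(3)
  for (jj in seq_len(nrow(p$alpha_est))) {
    lp <- lp + oracle_dmvnorm(p$alpha_est[jj, ], mu_h, p$Sigma1)
  }
  for (kk in seq_len(nrow(p$alpha_prog))) {
    lp <- lp + oracle_dmvnorm(p$alpha_prog[kk, ], mu_v, p$Sigma2)
  }
  lp <- lp + oracle_dinvwish(p$Sigma1, diag(3), 3 + priors$iw_df_offset) +
    oracle_dinvwish(p$Sigma2, diag(3), 3 + priors$iw_df_offset)
  if (hier) {
    lp <- lp + sum(-0.5 * log(2 * pi * p$tau_h^2) -
                     p$rho_h^2 / (2 * p$tau_h^2)) +
      sum(sapply(p$tau_h, oracle_dhalfcauchy, s = priors$tau_scale)) +
      sum(-0.5 * log(2 * pi * p$tau_v^2) - p$rho_v^2 / (2 * p$tau_v^2)) +
      sum(sapply(p$tau_v, oracle_dhalfcauchy, s = priors$tau_scale))
  }
  if (is.null(priors$beta_fixed_prior)) {
    lp <- lp + oracle_dmvnorm(p$beta, p$rho_m, p$Sigma3) +
      oracle_dinvwish(p$Sigma3, diag(9), 9 + priors$iw_df_offset) +
      sum(-0.5 * log(2 * pi * p$tau_m^2) - p$rho_m^2 / (2 * p$tau_m^2)) +
      sum(sapply(p$tau_m, oracle_dhalfcauchy, s = priors$tau_scale))
  } else {
    bp <- priors$beta_fixed_prior
    lp <- lp + sum(-0.5 * log(2 * pi * bp$sd^2) -
                     (p$beta - bp$mean)^2 / (2 * bp$sd^2))
  }
  lp
}

test_that("log joint matches a term-by-term independent oracle", {
  md <- toy_model_data(n = 6, J = 2, K = 2, seed = 3)
  p <- random_params(2, 2, seed = 12)
  set.seed(13)
  p$log_lambda <- rnorm(6, 1, 0.5)

  for (pr in list(prior_config(),
                  prior_config(re_means = "hierarchical"),
                  prior_config(beta_fixed_prior = list(mean = 0, sd = 10)))) {
    expect_equal(log_joint(p, md, pr), oracle_log_joint(p, md, pr),
                 tolerance = 1e-8)
  }
})

test_that("log joint support and additivity", {
  md <- toy_model_data(n = 6, J = 2, K = 2, seed = 3)
  p <- random_params(2, 2, seed = 12)
  set.seed(14)
  p$log_lambda <- rnorm(6, 1, 0.5)
  expect_true(is.finite(log_joint(p, md)))
  bad <- p; bad$sigma2_s <- -0.2
  expect_identical(log_joint(bad, md), -Inf)
  bad2 <- p; bad2$tau_m[3] <- 0
  expect_identical(log_joint(bad2, md), -Inf)

  # changing one count changes only its Poisson term
  md2 <- md; md2$y[2] <- md$y[2] + 5L
  delta <- log_joint(p, md2) - log_joint(p, md)
  lam2 <- exp(p$log_lambda[2])
  expect_equal(delta, dpois(md2$y[2], lam2, log = TRUE) -
                 dpois(md$y[2], lam2, log = TRUE), tolerance = 1e-10)
})

test_that("prior-predictive draws give finite counts", {
  set.seed(31)
  des <- toy_model_data(n = 50, J = 3, K = 2, seed = 44)
  for (r in 1:20) {
    tau <- abs(rcauchy(9, 0, 4)) + 1e-3
    p <- model_params(
      beta = rnorm(9, 0, pmin(tau, 3)),       # weakly-informative regime
      alpha_est = matrix(rnorm(9, 0, 0.5), 3, 3),
      alpha_prog = matrix(rnorm(6, 0, 0.5), 2, 3),
      sigma2_s = min(1 / rgamma(1, 1, 1), 4))
    sim <- simulate_counts(p, des, seed = 100 + r)
    expect_true(all(is.finite(sim$y)))
    expect_true(all(sim$y >= 0))
  }
})
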