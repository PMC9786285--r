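#' Fit the multilevel Poisson-lognormal richness model by MCMC
#'
#' A Metropolis-within-Gibbs sampler targeting the posterior of the
#' crossed-random-effects Poisson-lognormal model (see [log_joint()]).
#' The per-row latent `log lambda` is updated by adaptive random-walk
#' Metropolis (adaptation during warmup only); every other block is a
#' conjugate Gibbs draw (Gaussian for `beta` and the random-effect rows,
#' inverse-gamma for `sigma2_s`, inverse-Wishart for the covariances,
#' Gaussian for the prior means), except the heavy-tailed tau hyper-scales,
#' which use slice sampling on the log scale.
#'
#' When `n_iter` is `NULL` the post-warmup length per chain is
#' `max(1000, ceiling(Nmin / n_chains))` with `Nmin` the Raftery-Lewis
#' independence-chain minimum for estimating the 2.5% posterior quantile to
#' accuracy 0.005 with probability 0.95 (see [raftery_lewis_nmin()]),
#' mirroring the auto-run behaviour of the original JAGS workflow.
#'
#' After sampling, the Gelman-Rubin statistic is computed for the monitored
#' parameters; `converged` is `FALSE` (with a warning) if any exceeds 1.10.
#'
#' @param data a [model_data()].
#' @param priors a [prior_config()].
#' @param n_chains number of chains (>= 2).
#' @param warmup adaptation iterations per chain, discarded.
#' @param n_iter post-warmup iterations per chain (`NULL`: Raftery-Lewis).
#' @param thin keep every `thin`-th draw.
#' @param seed integer seed; chains get deterministic sub-seeds.
#' @param control list: `clamp_alpha` (fix all random effects at zero;
#'   for reduced/benchmark fits), `store_lambda` (store latent draws,
#'   default TRUE; needed for posterior predictive checks),
#'   `monitor_extra` (additional stored parameter names to include in the
#'   convergence set).
#' @return object of class `richness_draws`: per-chain draw matrices, the
#'   latent `log lambda` draws, sampler metadata, and a convergence report.
#' @export
fit_richness <- function(data, priors = prior_config(), n_chains = 4,
                         warmup = 1000, n_iter = NULL, thin = 1, seed,
                         control = list()) {
  stopifnot(inherits(data, "model_data") || is.list(data))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_chains < 2) stop("n_chains must be >= 2", call. = FALSE)
  ctl <- utils::modifyList(list(clamp_alpha = FALSE, store_lambda = TRUE,
                                monitor_extra = character(0)), control)
  if (is.null(n_iter)) {
    n_iter <- max(1000L, ceiling(raftery_lewis_nmin() / n_chains))
  }
  restore <- local_rng(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, n_chains)
  restore()

  chains <- vector("list", n_chains)
  lambdas <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    res <- run_chain(data, priors, warmup, n_iter, thin, chain_seeds[c], ctl)
    chains[[c]] <- res$draws
    lambdas[[c]] <- res$lambda
  }

  monitor <- c(sprintf("beta[%d]", 0:8), "sigma2_s")
  if (!ctl$clamp_alpha) {
    monitor <- c(monitor, sprintf("Sigma1[%d,%d]", 1:3, 1:3),
                 sprintf("Sigma2[%d,%d]", 1:3, 1:3))
  }
  monitor <- unique(c(monitor, ctl$monitor_extra))
  monitor <- intersect(monitor, colnames(chains[[1]]))

  out <- structure(
    list(chains = chains,
         lambda = if (ctl$store_lambda) lambdas else NULL,
         meta = list(seed = seed, chain_seeds = chain_seeds,
                     warmup = warmup, n_iter = n_iter, thin = thin,
                     n_chains = n_chains, monitor = monitor,
                     priors = priors, control = ctl, data = data)),
    class = "richness_draws")
  conv <- tryCatch(convergence_report(out), error = function(e) NULL)
  out$convergence <- conv
  if (!is.null(conv) && !conv$pass) {
    warning("fit flagged as non-converged: max R-hat = ",
            round(conv$max_rhat, 3), call. = FALSE)
  }
  out
}

# one MCMC chain; all heavy lifting is vectorised over rows
run_chain <- function(data, priors, warmup, n_iter, thin, seed, ctl) {
  restore <- local_rng(seed)
  on.exit(restore(), add = TRUE)

  y <- data$y; n <- length(y)
  J <- data$J; K <- data$K
  j <- data$j; k <- data$k; x1 <- data$x1; x2 <- data$x2
  hier <- priors$re_means == "hierarchical"
  fixed_beta <- !is.null(priors$beta_fixed_prior)

  # constant design structures: the fixed-effect design W and, unless the
  # random effects are clamped, the combined design U = [W | estuary | prog]
  # whose coefficient vector (beta, alpha_est, alpha_prog) is updated in one
  # joint conjugate Gaussian block -- separate blocks mix far too slowly
  # because the intercept, estuary effects and estuary-level covariates are
  # strongly confounded at small J
  W <- cbind(1, x1, x2, data$estuary_x[j, , drop = FALSE])
  WtW <- crossprod(W)
  Z <- cbind(1, x1, x2)
  if (!ctl$clamp_alpha) {
    U <- matrix(0, n, 9 + 3 * J + 3 * K)
    U[, 1:9] <- W
    for (col in 1:3) {
      U[cbind(seq_len(n), 9 + (col - 1) * J + j)] <- Z[, col]
      U[cbind(seq_len(n), 9 + 3 * J + (col - 1) * K + k)] <- Z[, col]
    }
    UtU <- crossprod(U)
    Ut <- t(U)
    est_cols <- lapply(seq_len(J), function(jj) 9 + (0:2) * J + jj)
    prog_cols <- lapply(seq_len(K), function(kk) 9 + 3 * J + (0:2) * K + kk)
  }

  # initial state
  ell <- log(y + 0.5)
  beta <- as.numeric(solve(WtW + diag(9), crossprod(W, ell)))
  alpha_est <- matrix(0, J, 3)
  alpha_prog <- matrix(0, K, 3)
  sigma2 <- 0.5
  Sigma1 <- diag(3); Sigma2 <- diag(3); Sigma3 <- diag(9)
  rho_m <- numeric(9); rho_h <- numeric(3); rho_v <- numeric(3)
  tau_m <- rep(1, 9); tau_h <- rep(1, 3); tau_v <- rep(1, 3)
  lstep <- rep(log(0.5), n)              # per-row MH log step sizes

  re_contrib <- function() {
    ae <- alpha_est[j, , drop = FALSE]; ap <- alpha_prog[k, , drop = FALSE]
    ae[, 1] + ae[, 2] * x1 + ae[, 3] * x2 +
      ap[, 1] + ap[, 2] * x1 + ap[, 3] * x2
  }

  par_names <- c(sprintf("beta[%d]", 0:8), "sigma2_s",
                 sprintf("alpha_est[%d,%d]", rep(seq_len(J), 3),
                         rep(0:2, each = J)),
                 sprintf("alpha_prog[%d,%d]", rep(seq_len(K), 3),
                         rep(0:2, each = K)),
                 sprintf("Sigma1[%d,%d]", rep(1:3, 3), rep(1:3, each = 3)),
                 sprintf("Sigma2[%d,%d]", rep(1:3, 3), rep(1:3, each = 3)),
                 sprintf("rho_m[%d]", 0:8), sprintf("tau_m[%d]", 0:8),
                 sprintf("rho_h[%d]", 0:2), sprintf("rho_v[%d]", 0:2))
  n_keep <- floor(n_iter / thin)
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  lam <- if (ctl$store_lambda) matrix(NA_real_, n_keep, n) else NULL

  total <- warmup + n_iter
  kept <- 0L
  for (it in seq_len(total)) {
    gg <- as.numeric(W %*% beta) + re_contrib()

    # --- latent log-lambda: vectorised adaptive random-walk MH (2 sweeps)
    for (sweep in 1:2) {
      step <- exp(lstep)
      prop <- ell + stats::rnorm(n, 0, step)
      lr <- y * (prop - ell) - (exp(prop) - exp(ell)) -
        ((prop - gg)^2 - (ell - gg)^2) / (2 * sigma2)
      acc <- log(stats::runif(n)) < lr
      ell[acc] <- prop[acc]
      if (it <= warmup) {
        lstep <- lstep + (as.numeric(acc) - 0.44) / sqrt(it)
        lstep <- pmin(pmax(lstep, log(1e-3)), log(10))
      }
    }

    # --- fixed-effect prior precision / shift
    if (fixed_beta) {
      P0 <- diag(1 / priors$beta_fixed_prior$sd^2)
      b0 <- priors$beta_fixed_prior$mean / priors$beta_fixed_prior$sd^2
    } else {
      P0 <- chol2inv(chol(Sigma3))
      b0 <- as.numeric(P0 %*% rho_m)
    }

    if (ctl$clamp_alpha) {
      # beta alone (random effects fixed at zero)
      beta <- rmvnorm_canonical(WtW / sigma2 + P0,
                                crossprod(W, ell) / sigma2 + b0)
    } else {
      # --- joint (beta, alpha_est, alpha_prog) conjugate Gaussian block
      S1inv <- chol2inv(chol(Sigma1))
      S2inv <- chol2inv(chol(Sigma2))
      mu_h <- if (hier) rho_h else numeric(3)
      mu_v <- if (hier) rho_v else numeric(3)
      p_all <- 9 + 3 * J + 3 * K
      Pprior <- matrix(0, p_all, p_all)
      bprior <- numeric(p_all)
      Pprior[1:9, 1:9] <- P0
      bprior[1:9] <- b0
      for (jj in seq_len(J)) {
        Pprior[est_cols[[jj]], est_cols[[jj]]] <- S1inv
        bprior[est_cols[[jj]]] <- S1inv %*% mu_h
      }
      for (kk in seq_len(K)) {
        Pprior[prog_cols[[kk]], prog_cols[[kk]]] <- S2inv
        bprior[prog_cols[[kk]]] <- S2inv %*% mu_v
      }
      theta <- rmvnorm_canonical(UtU / sigma2 + Pprior,
                                 as.numeric(Ut %*% ell) / sigma2 + bprior)
      beta <- theta[1:9]
      alpha_est <- matrix(theta[9 + seq_len(3 * J)], J, 3)
      alpha_prog <- matrix(theta[9 + 3 * J + seq_len(3 * K)], K, 3)
      # --- random-effect covariances (conjugate inverse-Wishart)
      dfo <- priors$iw_df_offset
      Sigma1 <- rinvwishart1(3 + dfo + J,
                             diag(3) + crossprod(sweep(alpha_est, 2, mu_h)))
      Sigma2 <- rinvwishart1(3 + dfo + K,
                             diag(3) + crossprod(sweep(alpha_prog, 2, mu_v)))
      if (hier) {
        # prior means of the random-effect rows, then their tau scales
        S1inv <- chol2inv(chol(Sigma1))
        rho_h <- rmvnorm_canonical(J * S1inv + diag(1 / tau_h^2),
                                   as.numeric(S1inv %*% colSums(alpha_est)))
        S2inv <- chol2inv(chol(Sigma2))
        rho_v <- rmvnorm_canonical(K * S2inv + diag(1 / tau_v^2),
                                   as.numeric(S2inv %*% colSums(alpha_prog)))
        tau_h <- update_tau(rho_h, tau_h, priors$tau_scale)
        tau_v <- update_tau(rho_v, tau_v, priors$tau_scale)
      }
    }

    # --- observation-level variance
    gg <- as.numeric(W %*% beta) + re_contrib()
    sigma2 <- 1 / stats::rgamma(1, priors$ig_shape + n / 2,
                                priors$ig_rate + 0.5 * sum((ell - gg)^2))

    if (!fixed_beta) {
      # --- fixed-effect hyper layer
      Sigma3 <- rinvwishart1(9 + priors$iw_df_offset + 1,
                             diag(9) + tcrossprod(beta - rho_m))
      S3inv <- chol2inv(chol(Sigma3))
      rho_m <- rmvnorm_canonical(S3inv + diag(1 / tau_m^2),
                                 as.numeric(S3inv %*% beta))
      tau_m <- update_tau(rho_m, tau_m, priors$tau_scale)
    }

    if (it > warmup && (it - warmup) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(beta, sigma2, as.numeric(alpha_est),
                         as.numeric(alpha_prog),
                         as.numeric(Sigma1), as.numeric(Sigma2),
                         rho_m, tau_m, rho_h, rho_v)
      if (!is.null(lam)) lam[kept, ] <- ell
    }
  }
  list(draws = draws, lambda = lam)
}

# slice-sample each tau component on the log scale:
# p(tau | rho) ~ N(rho | 0, tau^2) x half-Cauchy(tau | scale)
update_tau <- function(rho, tau, scale) {
  for (i in seq_along(tau)) {
    lf <- function(lt) {
      t <- exp(lt)
      stats::dnorm(rho[i], 0, t, log = TRUE) +
        dhalfcauchy_log(t, scale) + lt     # Jacobian of log transform
    }
    tau[i] <- exp(slice_sample1(log(tau[i]), lf))
  }
  tau
}

#' @export
print.richness_draws <- function(x, ...) {
  cat("Poisson-lognormal richness model posterior draws\n")
  cat(sprintf("  chains: %d, post-warmup draws/chain: %d (warmup %d, thin %d)\n",
              x$meta$n_chains, nrow(x$chains[[1]]), x$meta$warmup,
              x$meta$thin))
  cat(sprintf("  parameters stored: %d, monitored for convergence: %d\n",
              ncol(x$chains[[1]]), length(x$meta$monitor)))
  if (!is.null(x$convergence)) {
    cat(sprintf("  max R-hat (monitored): %.3f [%s]\n",
                x$convergence$max_rhat,
                if (x$convergence$pass) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Pooled posterior draws as a matrix
#'
#' @param x a `richness_draws` object.
#' @param pars optional parameter-name subset.
#' @param ... unused.
#' @return draws x parameters matrix, chains stacked in order.
#' @export
as.matrix.richness_draws <- function(x, pars = NULL, ...) {
  m <- do.call(rbind, x$chains)
  if (!is.null(pars)) m <- m[, pars, drop = FALSE]
  m
}

#' Pooled latent log-lambda draws
#' @param x a `richness_draws` object.
#' @return draws x rows matrix of latent log expected counts.
#' @export
lambda_matrix <- function(x) {
  if (is.null(x$lambda)) stop("latent draws were not stored ",
                              "(control$store_lambda = FALSE)", call. = FALSE)
  do.call(rbind, x$lambda)
}
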