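# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# a small synthetic study with a fitted model and a hold-out split;
# used by the diagnostics and postprocess tests
small_fit_fixture <- function() {
  if (is.null(.fixtures$fit)) {
    study <- generate_study(synthetic_config(
      J = 8, K = 3, trawls_per_estuary = 60, precip_years = 3, seed = 301))
    qc <- qc_filter(study$trawls)
    sub <- subsample_trawls(qc$kept, 40, seed = 302)
    prep <- transform_covariates(sub$fitted, study$runoff_cov,
                                 holdout = sub$holdout)
    md <- model_data(prep, "pelagic")
    fit <- suppressWarnings(
      fit_richness(md, n_chains = 2, warmup = 300, n_iter = 400, seed = 303))
    .fixtures$study <- study
    .fixtures$prep <- prep
    .fixtures$fit <- fit
  }
  .fixtures
}

# hand-built trawl records for the preparation tests
toy_trawls <- function() {
  samples <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    estuary_id = c("A", "A", "A", "B", "B", "B"),
    program_id = c("p1", "p1", "p2", "p1", "p2", "p2"),
    date = "2000-06-01",
    salinity_ppt = c(10, 20, 0, 15, -0.1, 12),
    temperature_c = c(20, 4.9, 25, 30, 20, 36),
    stringsAsFactors = FALSE)
  counts <- data.frame(
    sample_id = c("s1", "s1", "s1", "s3", "s3", "s4"),
    taxon = c("Anchoa mitchilli", "Brevoortia patronus",
              "Litopenaeus setiferus", "Anchoa mitchilli", "Unknown sp.",
              "Caranx hippos"),
    count = c(10L, 5L, 2L, 3L, 1L, 7L),
    stringsAsFactors = FALSE)
  trawl_records(samples, counts)
}

# a minimal hand-constructed model_data (valid by construction)
toy_model_data <- function(n = 8, J = 2, K = 2, seed = 11) {
  set.seed(seed)
  structure(list(
    y = rpois(n, 4),
    j = rep_len(seq_len(J), n), k = rep_len(seq_len(K), n),
    x1 = rnorm(n), x2 = rnorm(n),
    estuary_x = matrix(rnorm(J * 6), J, 6,
                       dimnames = list(NULL, lulc_groups())),
    J = J, K = K, group = "pelagic"), class = "model_data")
}

random_params <- function(J, K, seed = 5) {
  set.seed(seed)
  model_params(beta = rnorm(9, 0, 0.5),
               alpha_est = matrix(rnorm(J * 3, 0, 0.3), J, 3),
               alpha_prog = matrix(rnorm(K * 3, 0, 0.3), K, 3),
               sigma2_s = 0.4,
               Sigma1 = crossprod(matrix(rnorm(9), 3)) / 3 + diag(3) * 0.1,
               Sigma2 = crossprod(matrix(rnorm(9), 3)) / 3 + diag(3) * 0.1,
               Sigma3 = crossprod(matrix(rnorm(81), 9)) / 9 + diag(9) * 0.1,
               rho_m = rnorm(9, 0, 0.2), rho_h = rnorm(3, 0, 0.2),
               rho_v = rnorm(3, 0, 0.2),
               tau_m = runif(9, 0.5, 2), tau_h = runif(3, 0.5, 2),
               tau_v = runif(3, 0.5, 2))
}
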