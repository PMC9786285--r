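#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic study world at desk scale: J estuaries sampled by
#' K trawl programs (defaults 10 and 3; the real survey spans 33 estuaries
#' and 7 programs), estuary-specific salinity/temperature distributions,
#' log-scale dispersion of watershed LULC composition, a multi-year daily
#' precipitation record, and true generative parameters at the effect
#' magnitudes reported for the LULC covariates (medians within roughly
#' [-0.5, 0.9]).
#'
#' @param J number of estuaries.
#' @param K number of trawl programs.
#' @param trawls_per_estuary trawl events per estuary (spread across
#'   programs).
#' @param beta true fixed effects (intercept, salinity, temperature, six
#'   LULC covariates in [lulc_groups()] order).
#' @param sigma2_s true observation-level lognormal variance.
#' @param sd_est,sd_prog random intercept/slope standard deviations
#'   (length 3) for estuaries and programs.
#' @param salinity_mean_range,salinity_sd estuary mean salinity drawn
#'   uniformly from the range (ppt); within-estuary SD.
#' @param temperature_mean_range,temperature_sd same for temperature (C).
#' @param lulc_dispersion log-normal SD of class areas across estuaries.
#' @param precip_years complete years of daily precipitation.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(J = 10, K = 3, trawls_per_estuary = 50,
                             beta = c(1.5, 0.3, 0.2,
                                      -0.49, 0.45, 0.79, 0.30, 0.86, -0.42),
                             sigma2_s = 0.1,
                             sd_est = c(0.2, 0.1, 0.1),
                             sd_prog = c(0.2, 0.1, 0.1),
                             salinity_mean_range = c(5, 30),
                             salinity_sd = 4,
                             temperature_mean_range = c(18, 28),
                             temperature_sd = 4,
                             lulc_dispersion = 1,
                             precip_years = 30,
                             seed = 1) {
  stopifnot(J >= 2, K >= 1, trawls_per_estuary >= 1, length(beta) == 9,
            sigma2_s >= 0, precip_years >= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate synthetic watershed landscapes and precipitation
#'
#' Per estuary, class areas for the six LULC groups x four soil groups are
#' drawn log-normally around group-specific typical shares of a nominal
#' watershed, giving the log-scale spread of runoff covariates across
#' estuaries that the model needs. Daily precipitation follows a seasonal
#' wet-day/gamma-amount process (wet-day probability 0.30, seasonal mean
#' depth peaking in summer), a reasonable stand-in for a Gulf-coast daily
#' record.
#'
#' @param config a [synthetic_config()].
#' @return list with `compositions` (list of [watershed_composition()]) and
#'   `precips` (list of [precip_series()]).
#' @export
generate_landscape <- function(config) {
  restore <- local_rng(config$seed)
  on.exit(restore(), add = TRUE)
  groups <- lulc_groups()
  # typical share of a 1000 km2 watershed by group (before dispersion)
  base_km2 <- c(developed = 60, cropland = 100, forest = 300,
                palustrine_wetland = 80, estuarine_wetland = 40, barren = 10)
  soil_w <- c(A = 0.15, B = 0.35, C = 0.30, D = 0.20)
  # representative C-CAP code per group (any member code works)
  code_of <- c(developed = 2L, cropland = 6L, forest = 9L,
               palustrine_wetland = 14L, estuarine_wetland = 17L,
               barren = 20L)
  comps <- vector("list", config$J)
  precips <- vector("list", config$J)
  dates <- seq(as.Date("1981-01-01"),
               by = "day", length.out = 365 * config$precip_years +
                 sum(seq(1981, 1981 + config$precip_years - 1) %% 4 == 0))
  dates <- dates[as.integer(format(dates, "%Y")) <
                   1981 + config$precip_years]
  doy <- as.integer(format(dates, "%j"))
  # one regional daily record shared by every watershed (a single coastal
  # climate driver): cross-estuary covariate spread comes from composition
  wet <- stats::rbinom(length(dates), 1, 0.30)
  seasonal_mean <- 9 + 5 * sin(2 * pi * (doy - 105) / 365.25)   # mm, wet day
  amount <- stats::rgamma(length(dates), shape = 0.7,
                          scale = seasonal_mean / 0.7)
  regional_mm <- wet * amount
  for (e in seq_len(config$J)) {
    id <- sprintf("E%02d", e)
    area_km2 <- base_km2 *
      exp(stats::rnorm(6, -config$lulc_dispersion^2 / 2,
                       config$lulc_dispersion))
    rows <- expand.grid(group = groups, soil = soil_groups(),
                        stringsAsFactors = FALSE)
    rows$area_m2 <- area_km2[rows$group] * soil_w[rows$soil] * 1e6
    total_km2 <- sum(rows$area_m2) / 1e6 * 1.1   # 10% unclassified remainder
    comps[[e]] <- watershed_composition(
      id, code_of[rows$group], rows$soil, rows$area_m2, total_km2)
    precips[[e]] <- precip_series(id, dates, regional_mm)
  }
  list(compositions = comps, precips = precips)
}

#' Generate a synthetic trawl survey with known ground truth
#'
#' Draws per-trawl salinity and temperature from estuary-specific
#' distributions (truncated to the QC window so the synthetic survey passes
#' [qc_filter()] losslessly), applies the model's covariate transforms,
#' simulates functional-group richness from the generative model with the
#' configured true parameters, and expands each richness value into a
#' per-taxon presence list (uniform without-replacement draw from the
#' group's taxa; counts are 1 + Poisson noise). Richness draws exceeding
#' the taxa available in a group are redrawn (and counted in the truth
#' ledger).
#'
#' @param config a [synthetic_config()].
#' @param runoff_cov J x 6 matrix from [runoff_covariates()] on the
#'   generated landscape.
#' @param fg_table the taxon-to-group table used for the expansion.
#' @return list: `trawls` (a [trawl_records()]), `truth` (true parameters,
#'   transformed design, per-row latent state and resample count).
#' @export
generate_survey <- function(config, runoff_cov,
                            fg_table = read_fg_table()) {
  stopifnot(nrow(runoff_cov) == config$J)
  restore <- local_rng(config$seed + 1L)
  on.exit(restore(), add = TRUE)
  J <- config$J; K <- config$K; npe <- config$trawls_per_estuary
  n <- J * npe
  est <- rep(rownames(runoff_cov), each = npe)
  prog <- sprintf("P%d", sample.int(K, n, replace = TRUE))
  sal_mu <- stats::runif(J, config$salinity_mean_range[1],
                         config$salinity_mean_range[2])
  tmp_mu <- stats::runif(J, config$temperature_mean_range[1],
                         config$temperature_mean_range[2])
  ei <- rep(seq_len(J), each = npe)
  sal <- rtrunc_norm(n, sal_mu[ei], config$salinity_sd, 0, 60)
  tmp <- rtrunc_norm(n, tmp_mu[ei], config$temperature_sd, 5, 35)

  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    estuary_id = est, program_id = prog,
    date = as.character(as.Date("2000-01-01") + (seq_len(n) %% 3650)),
    salinity_ppt = round(sal, 2), temperature_c = round(tmp, 2),
    stringsAsFactors = FALSE)

  # transformed design exactly as the preparation stage will compute it
  log_sal <- log(samples$salinity_ppt + 1e-6)
  log_tmp <- log(samples$temperature_c)
  x1 <- log_sal - as.numeric(tapply(log_sal, est, mean)[est])
  x2 <- log_tmp - as.numeric(tapply(log_tmp, est, mean)[est])
  lx <- log(runoff_cov + 1)
  ex <- sweep(lx, 2, colMeans(lx))
  prog_levels <- sort(unique(prog))
  design <- list(j = ei, k = match(prog, prog_levels), x1 = x1, x2 = x2,
                 estuary_x = ex, J = J, K = length(prog_levels))

  true_alpha_est <- cbind(stats::rnorm(J, 0, config$sd_est[1]),
                          stats::rnorm(J, 0, config$sd_est[2]),
                          stats::rnorm(J, 0, config$sd_est[3]))
  true_alpha_prog <- cbind(stats::rnorm(K, 0, config$sd_prog[1]),
                           stats::rnorm(K, 0, config$sd_prog[2]),
                           stats::rnorm(K, 0, config$sd_prog[3]))
  # programs present in the realised survey only
  true_alpha_prog <- true_alpha_prog[match(prog_levels,
                                           sprintf("P%d", seq_len(K))), ,
                                     drop = FALSE]
  params <- model_params(beta = config$beta, alpha_est = true_alpha_est,
                         alpha_prog = true_alpha_prog,
                         sigma2_s = config$sigma2_s)

  counts <- vector("list", 3)
  names(counts) <- functional_groups()
  richness <- matrix(0L, n, 3, dimnames = list(NULL, functional_groups()))
  resampled <- 0L
  for (g in functional_groups()) {
    taxa <- fg_table$taxon[fg_table$functional_group == g]
    sim <- simulate_counts(params, design,
                           seed = config$seed + 2L + match(g, names(counts)))
    yv <- sim$y
    over <- yv > length(taxa)
    while (any(over)) {        # cannot observe more taxa than exist
      resampled <- resampled + sum(over)
      redo <- simulate_counts(params, list(
        j = design$j[over], k = design$k[over], x1 = design$x1[over],
        x2 = design$x2[over], estuary_x = ex),
        seed = config$seed + 97L + resampled)
      yv[over] <- redo$y
      over <- yv > length(taxa)
    }
    richness[, g] <- yv
    rows_with <- which(yv > 0)
    if (length(rows_with)) {
      picked <- lapply(rows_with, function(i) sample(taxa, yv[i]))
      counts[[g]] <- data.frame(
        sample_id = rep(samples$sample_id[rows_with],
                        lengths(picked)),
        taxon = unlist(picked),
        count = 1L + stats::rpois(sum(lengths(picked)), 2),
        stringsAsFactors = FALSE)
    }
  }
  count_df <- do.call(rbind, counts[!vapply(counts, is.null, TRUE)])
  if (is.null(count_df)) {
    count_df <- data.frame(sample_id = character(0), taxon = character(0),
                           count = integer(0))
  }
  rownames(count_df) <- NULL
  list(trawls = trawl_records(samples, count_df),
       truth = list(params = params, design = design, richness = richness,
                    runoff_cov = runoff_cov, resampled = resampled,
                    config = config))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  mean <- rep_len(mean, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a complete synthetic study (landscape + runoff + survey)
#'
#' Convenience wrapper chaining [generate_landscape()],
#' [runoff_covariates()] and [generate_survey()].
#'
#' @param config a [synthetic_config()].
#' @param cn curve-number table.
#' @return list: `landscape`, `runoff_cov`, `trawls`, `truth`.
#' @export
generate_study <- function(config = synthetic_config(),
                           cn = default_cn_table()) {
  land <- generate_landscape(config)
  rc <- runoff_covariates(land$compositions, land$precips, cn)
  surv <- generate_survey(config, rc)
  list(landscape = land, runoff_cov = rc, trawls = surv$trawls,
       truth = surv$truth)
}
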