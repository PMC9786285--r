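#' Posterior credible-interval table for the LULC covariates
#'
#' Empirical 2.5th/50th/97.5th percentiles (linear interpolation between
#' order statistics, `stats::quantile` type 7) of each LULC coefficient
#' beta3..beta8 across pooled post-warmup draws.
#'
#' @param draws a [fit_richness()] result, or a draws matrix with `beta[m]`
#'   columns.
#' @param percentiles percent points to report.
#' @return data.frame: `covariate`, one column per percentile (`p2.5`,
#'   `p50`, `p97.5` by default).
#' @export
credible_table <- function(draws, percentiles = c(2.5, 50, 97.5)) {
  m <- if (inherits(draws, "richness_draws")) as.matrix(draws) else draws
  if (nrow(m) == 0) stop("no draws", call. = FALSE)
  cov_names <- lulc_groups()
  out <- data.frame(covariate = cov_names, stringsAsFactors = FALSE)
  qs <- sapply(seq_along(cov_names), function(i) {
    stats::quantile(m[, sprintf("beta[%d]", i + 2)], percentiles / 100,
                    names = FALSE, type = 7)
  })
  qs <- matrix(qs, nrow = length(percentiles))
  for (p in seq_along(percentiles)) {
    out[[paste0("p", percentiles[p])]] <- qs[p, ]
  }
  out
}

#' Proportional change in expected richness over an observed covariate range
#'
#' For each LULC covariate m, `exp(median(beta_m) * (x_max - x_min)) - 1`:
#' the proportional change in expected richness as the covariate moves from
#' its lowest to its highest observed value on the transformed (log,
#' grand-mean-centered) scale. The posterior-median point summary is
#' reported; the full per-draw distribution of the change is attached.
#'
#' @param draws a [fit_richness()] result or draws matrix.
#' @param covariate_range either a 2-column matrix / data.frame of
#'   `(x_min, x_max)` per covariate (rows in [lulc_groups()] order), or the
#'   prepared `estuary_x` matrix, whose column ranges are used.
#' @return data.frame: `covariate`, `delta_x`, `prop_change`; attribute
#'   `draws` holds the per-draw changes.
#' @export
proportional_change <- function(draws, covariate_range) {
  m <- if (inherits(draws, "richness_draws")) as.matrix(draws) else draws
  cr <- as.matrix(covariate_range)
  if (ncol(cr) == 6 || nrow(cr) != 6) cr <- t(apply(cr, 2, range))
  if (any(cr[, 2] < cr[, 1])) stop("x_max < x_min", call. = FALSE)
  dx <- cr[, 2] - cr[, 1]
  cov_names <- lulc_groups()
  med <- vapply(seq_along(cov_names), function(i) {
    stats::median(m[, sprintf("beta[%d]", i + 2)])
  }, 1)
  per_draw <- sapply(seq_along(cov_names), function(i) {
    expm1(m[, sprintf("beta[%d]", i + 2)] * dx[i])
  })
  colnames(per_draw) <- cov_names
  structure(
    data.frame(covariate = cov_names, delta_x = unname(dx),
               prop_change = expm1(med * dx), stringsAsFactors = FALSE),
    draws = per_draw)
}

#' Expected-richness prediction curve for one LULC covariate
#'
#' Expected richness at grid value x with all other covariates at their
#' grand mean (0 on the centered scale) and random effects at zero:
#' `lambda*(x) = exp(beta0 + beta_m x + sigma2_s / 2)` per draw (the
#' `+sigma2_s/2` term is the lognormal-mean correction; disable it with
#' `lognormal_mean = FALSE` for the conditional-median curve). The mean
#' curve and pointwise 90% and 95% credible bands of `lambda*` across draws
#' are returned; the bands reflect coefficient (mean-curve) uncertainty,
#' not observation-level scatter.
#'
#' @param draws a [fit_richness()] result or draws matrix.
#' @param covariate one of [lulc_groups()].
#' @param grid numeric grid on the transformed covariate scale (e.g.
#'   `seq(min, max, length.out = 50)` over the observed range).
#' @param lognormal_mean include the `+sigma2_s/2` correction.
#' @return data.frame of class `prediction_curve`: `x`, `mean`, `lo95`,
#'   `lo90`, `hi90`, `hi95`.
#' @export
prediction_curve <- function(draws, covariate, grid, lognormal_mean = TRUE) {
  m <- if (inherits(draws, "richness_draws")) as.matrix(draws) else draws
  i <- match(covariate, lulc_groups())
  if (is.na(i)) stop("unknown covariate: ", covariate, call. = FALSE)
  b0 <- m[, "beta[0]"]
  bm <- m[, sprintf("beta[%d]", i + 2)]
  corr <- if (lognormal_mean) m[, "sigma2_s"] / 2 else 0
  out <- t(vapply(grid, function(x) {
    lam <- exp(b0 + bm * x + corr)
    c(mean = mean(lam),
      stats::quantile(lam, c(0.025, 0.05, 0.95, 0.975), names = FALSE))
  }, numeric(5)))
  colnames(out) <- c("mean", "lo95", "lo90", "hi90", "hi95")
  structure(data.frame(x = grid, out),
            class = c("prediction_curve", "data.frame"),
            covariate = covariate)
}

#' Write posterior summary products to CSV
#'
#' Emits the credible-interval table, the proportional-change table and one
#' prediction-curve CSV per LULC covariate into `out_dir`.
#'
#' @param draws a [fit_richness()] result.
#' @param prepared the [transform_covariates()] result used for fitting
#'   (supplies observed covariate ranges).
#' @param out_dir output directory (created if needed).
#' @param grid_n grid resolution for the curves.
#' @return invisibly, the list of written file paths.
#' @export
summarize_posterior <- function(draws, prepared, out_dir, grid_n = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  ct <- credible_table(draws)
  f <- file.path(out_dir, "credible_intervals.csv")
  utils::write.csv(ct, f, row.names = FALSE); files <- c(files, f)
  pc <- proportional_change(draws, prepared$estuary_x)
  f <- file.path(out_dir, "proportional_change.csv")
  utils::write.csv(pc, f, row.names = FALSE); files <- c(files, f)
  for (g in lulc_groups()) {
    rng <- range(prepared$estuary_x[, g])
    cur <- prediction_curve(draws, g, seq(rng[1], rng[2],
                                          length.out = grid_n))
    f <- file.path(out_dir, sprintf("curve_%s.csv", g))
    utils::write.csv(cur, f, row.names = FALSE); files <- c(files, f)
  }
  invisible(files)
}
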