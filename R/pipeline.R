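#' Default pipeline configuration
#'
#' A single structured configuration drives the whole pipeline
#' (simulate -> runoff -> prepare -> fit -> check -> summarize). It can be
#' written to / read from JSON; CLI flags override config keys.
#'
#' @param out_dir output directory.
#' @param seed top-level seed; every random stage derives its seed from it.
#' @param stages stages to run, in canonical order.
#' @param simulate arguments for [synthetic_config()] (used only when the
#'   simulate stage is enabled).
#' @param inputs input file paths for runs on real data: `trawls_csv`,
#'   `counts_csv` (optional), `composition_csv`, `watershed_csv` (optional),
#'   `precip_csv`, `cn_table_csv` (optional), `fg_table_csv` (optional).
#' @param prepare list: `n_per_estuary` (default 150), `center_by`, QC
#'   bounds `t_min`/`t_max`.
#' @param fit list: `groups`, `n_chains`, `warmup`, `n_iter`, `thin`.
#' @param check list: `discrepancy`, `max_draws`.
#' @return config list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            stages = c("simulate", "runoff", "prepare",
                                       "fit", "check", "summarize"),
                            simulate = list(), inputs = list(),
                            prepare = list(), fit = list(), check = list()) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 simulate = simulate, inputs = inputs, prepare = prepare,
                 fit = fit, check = check),
            class = "run_config")
}

validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    class(config) <- "run_config"
  }
  stopifnot(!is.null(config$out_dir))
  if (is.null(config$seed)) config$seed <- 1
  known <- c("simulate", "runoff", "prepare", "fit", "check", "summarize")
  if (is.null(config$stages)) config$stages <- known
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  config$stages <- known[known %in% config$stages]   # canonical order
  # referenced input files must exist before anything runs
  if (!"simulate" %in% config$stages) {
    need <- c("trawls_csv", "composition_csv", "precip_csv")
    for (f in need) {
      if (any(c("runoff", "prepare") %in% config$stages) &&
          is.null(config$inputs[[f]])) {
        stop("config$inputs$", f, " is required when not simulating",
             call. = FALSE)
      }
    }
  }
  for (f in unlist(config$inputs)) {
    if (!file.exists(f)) stop("input file does not exist: ", f,
                              call. = FALSE)
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, carrying intermediate objects in
#' memory and persisting each stage's outputs (CSV/JSON) plus a manifest
#' entry (stage, outputs, md5 hashes, seed, package version) under
#' `out_dir`. A stage failure stops the run; downstream stages are not
#' executed. Re-running with unchanged inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()] list or path to a JSON config.
#' @return the manifest (also written to `manifest.json`), invisibly the
#'   full state environment as attribute `state`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  manifest <- list()
  for (stage in config$stages) {
    outputs <- switch(stage,
                      simulate = stage_simulate(config, st),
                      runoff = stage_runoff(config, st),
                      prepare = stage_prepare(config, st),
                      fit = stage_fit(config, st),
                      check = stage_check(config, st),
                      summarize = stage_summarize(config, st))
    manifest[[stage]] <- list(
      stage = stage, outputs = outputs,
      md5 = as.list(tools::md5sum(outputs)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("estuarich")))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(manifest, state = st)
}

stage_simulate <- function(config, st) {
  args <- config$simulate
  args$seed <- config$seed
  cfg <- do.call(synthetic_config, args)
  land <- generate_landscape(cfg)
  rc <- runoff_covariates(land$compositions, land$precips)
  surv <- generate_survey(cfg, rc)
  st$landscape <- land
  st$trawls <- surv$trawls
  st$truth <- surv$truth
  d <- config$out_dir
  comp_df <- do.call(rbind, lapply(land$compositions, function(cp) {
    data.frame(estuary_id = cp$estuary_id, cp$rows,
               watershed_area_km2 = cp$watershed_area_km2)
  }))
  pr_df <- do.call(rbind, lapply(land$precips, function(p) {
    data.frame(estuary_id = p$estuary_id, date = as.character(p$date),
               precip_mm = p$precip_mm)
  }))
  files <- c(file.path(d, "samples.csv"), file.path(d, "counts.csv"),
             file.path(d, "composition.csv"), file.path(d, "precip.csv"),
             file.path(d, "truth.json"))
  utils::write.csv(surv$trawls$samples, files[1], row.names = FALSE)
  utils::write.csv(surv$trawls$counts, files[2], row.names = FALSE)
  utils::write.csv(comp_df, files[3], row.names = FALSE)
  utils::write.csv(pr_df, files[4], row.names = FALSE)
  tp <- surv$truth$params
  jsonlite::write_json(
    list(beta = tp$beta, sigma2_s = tp$sigma2_s,
         alpha_est = tp$alpha_est, alpha_prog = tp$alpha_prog,
         resampled = surv$truth$resampled,
         config = args[setdiff(names(args), "beta")]),
    files[5], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files
}

stage_runoff <- function(config, st) {
  if (is.null(st$landscape)) {
    comps <- read_composition(config$inputs$composition_csv,
                              config$inputs$watershed_csv)
    precips <- read_precip(config$inputs$precip_csv)
  } else {
    comps <- st$landscape$compositions
    precips <- st$landscape$precips
  }
  cn <- if (!is.null(config$inputs$cn_table_csv)) {
    read_cn_table(config$inputs$cn_table_csv)
  } else default_cn_table()
  st$runoff_cov <- runoff_covariates(comps, precips, cn)
  f <- file.path(config$out_dir, "runoff_covariates.csv")
  utils::write.csv(data.frame(estuary_id = rownames(st$runoff_cov),
                              st$runoff_cov, check.names = FALSE),
                   f, row.names = FALSE)
  f
}

stage_prepare <- function(config, st) {
  prep_cfg <- utils::modifyList(
    list(n_per_estuary = 150, center_by = "estuary", t_min = 5, t_max = 35),
    if (is.null(config$prepare)) list() else config$prepare)
  trawls <- if (!is.null(st$trawls)) st$trawls else {
    read_trawls(config$inputs$trawls_csv, config$inputs$counts_csv)
  }
  if (is.null(st$runoff_cov)) {
    rc <- utils::read.csv(file.path(config$out_dir,
                                    "runoff_covariates.csv"),
                          check.names = FALSE)
    st$runoff_cov <- as.matrix(rc[, lulc_groups()])
    rownames(st$runoff_cov) <- rc$estuary_id
  }
  fg <- if (!is.null(config$inputs$fg_table_csv)) {
    read_fg_table(config$inputs$fg_table_csv)
  } else read_fg_table()
  qc <- qc_filter(trawls, prep_cfg$t_min, prep_cfg$t_max)
  sub <- subsample_trawls(qc$kept, prep_cfg$n_per_estuary,
                          seed = config$seed + 11L)
  ks <- distribution_check(sub$fitted, qc$kept)
  st$prepared <- transform_covariates(sub$fitted, st$runoff_cov, fg,
                                      center_by = prep_cfg$center_by,
                                      holdout = sub$holdout)
  d <- config$out_dir
  files <- c(file.path(d, "prepared_rows.csv"),
             file.path(d, "holdout_rows.csv"),
             file.path(d, "estuary_x.csv"),
             file.path(d, "qc_removed.csv"),
             file.path(d, "distribution_check.csv"))
  utils::write.csv(st$prepared$rows, files[1], row.names = FALSE)
  hr <- st$prepared$holdout_rows
  if (is.null(hr)) hr <- st$prepared$rows[0, ]
  utils::write.csv(hr, files[2], row.names = FALSE)
  utils::write.csv(data.frame(estuary_id = rownames(st$prepared$estuary_x),
                              st$prepared$estuary_x, check.names = FALSE),
                   files[3], row.names = FALSE)
  utils::write.csv(qc$removed, files[4], row.names = FALSE)
  utils::write.csv(ks, files[5], row.names = FALSE)
  files
}

stage_fit <- function(config, st) {
  fit_cfg <- utils::modifyList(
    list(groups = functional_groups(), n_chains = 4, warmup = 1000,
         n_iter = NULL, thin = 1),
    if (is.null(config$fit)) list() else config$fit)
  if (is.null(st$prepared)) stop("fit stage requires the prepare stage",
                                 call. = FALSE)
  st$fits <- list()
  files <- character(0)
  for (g in fit_cfg$groups) {
    md <- model_data(st$prepared, g)
    fit <- fit_richness(md, n_chains = fit_cfg$n_chains,
                        warmup = fit_cfg$warmup, n_iter = fit_cfg$n_iter,
                        thin = fit_cfg$thin,
                        seed = config$seed + 100L + match(g,
                                                          functional_groups()))
    st$fits[[g]] <- fit
    f <- file.path(config$out_dir, sprintf("draws_%s.csv", g))
    utils::write.csv(as.matrix(fit), f, row.names = FALSE)
    cf <- file.path(config$out_dir, sprintf("convergence_%s.json", g))
    jsonlite::write_json(
      list(group = g, max_rhat = fit$convergence$max_rhat,
           pass = fit$convergence$pass, nmin = fit$convergence$nmin,
           rhat = as.list(fit$convergence$rhat)),
      cf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f, cf)
  }
  files
}

stage_check <- function(config, st) {
  chk <- utils::modifyList(
    list(discrepancy = "chisq", max_draws = 500),
    if (is.null(config$check)) list() else config$check)
  if (is.null(st$fits)) stop("check stage requires the fit stage",
                             call. = FALSE)
  report <- lapply(names(st$fits), function(g) {
    fit <- st$fits[[g]]
    ppc <- posterior_predictive_p(fit, discrepancy = chk$discrepancy,
                                  max_draws = chk$max_draws)
    hold <- tryCatch({
      hd <- model_data(st$prepared, g, holdout = TRUE)
      validate_holdout(fit, hd, discrepancy = chk$discrepancy,
                       max_draws = chk$max_draws)$bayes_p
    }, error = function(e) NA_real_)
    list(group = g, discrepancy = chk$discrepancy,
         bayes_p = ppc$bayes_p, bayes_p_holdout = hold,
         max_rhat = fit$convergence$max_rhat,
         converged = fit$convergence$pass)
  })
  f <- file.path(config$out_dir, "check_report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  f
}

stage_summarize <- function(config, st) {
  if (is.null(st$fits)) stop("summarize stage requires the fit stage",
                             call. = FALSE)
  files <- character(0)
  for (g in names(st$fits)) {
    out <- summarize_posterior(st$fits[[g]], st$prepared,
                               file.path(config$out_dir,
                                         paste0("summary_", g)))
    files <- c(files, out)
  }
  files
}

#' Command-line entry point
#'
#' Subcommands `run-all`, `simulate`, `runoff`, `prepare`, `fit`, `check`,
#' `summarize`; each takes `--config FILE` (JSON) plus overrides
#' `--out-dir`, `--seed`. `run-all` executes every stage; a single-stage
#' subcommand runs the pipeline through that stage's prerequisites.
#' Installed at `inst/cli/estuarich` for use as
#' `Rscript .../cli/estuarich run-all --config cfg.json`.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly.
#' @export
estuarich_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: estuarich <run-all|simulate|runoff|prepare|fit|check|",
        "summarize> [--config F] [--out-dir D] [--seed N]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  config <- if (!is.null(opts$config)) validate_config(opts$config) else
    pipeline_config(out_dir = if (!is.null(opts[["out-dir"]]))
      opts[["out-dir"]] else "estuarich_out")
  if (!is.null(opts[["out-dir"]])) config$out_dir <- opts[["out-dir"]]
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  stage_order <- c("simulate", "runoff", "prepare", "fit", "check",
                   "summarize")
  if (cmd == "run-all") {
    config$stages <- stage_order
  } else if (cmd %in% stage_order) {
    config$stages <- intersect(config$stages,
                               stage_order[seq_len(match(cmd, stage_order))])
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  run_pipeline(config)
  invisible(0L)
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3)
      opts[[key]] <- if (i < length(args) && !startsWith(args[i + 1], "--")) {
        i <- i + 1; args[i]
      } else TRUE
    }
    i <- i + 1
  }
  opts
}
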