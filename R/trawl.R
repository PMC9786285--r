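#' Load the packaged taxon-to-functional-group table
#'
#' The packaged table assigns each trawl-observed taxon (species, genus or
#' family level entries, treated as distinct taxa exactly as tabulated) to
#' one of three functional groups: 23 pelagic, 27 forage finfish and 27
#' shrimp taxa. A user table with the same columns may be supplied anywhere
#' a `fg_table` is accepted.
#'
#' @param file optional CSV with columns `taxon`, `functional_group`;
#'   defaults to the packaged asset.
#' @return data.frame of class `fg_table`.
#' @export
read_fg_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "functional_groups.csv",
                        package = "estuarich", mustWork = TRUE)
  }
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("taxon", "functional_group") %in% names(tab))) {
    stop("FG table needs columns taxon, functional_group", call. = FALSE)
  }
  if (anyDuplicated(tab$taxon)) {
    stop("each taxon must map to exactly one functional group", call. = FALSE)
  }
  bad <- setdiff(unique(tab$functional_group), functional_groups())
  if (length(bad)) stop("unknown functional group(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(tab) <- c("fg_table", "data.frame")
  tab
}

#' The three modelled functional groups
#' @return character vector `c("pelagic", "forage_finfish", "shrimp")`.
#' @export
functional_groups <- function() c("pelagic", "forage_finfish", "shrimp")

#' Construct a set of trawl records
#'
#' A trawl-record set couples a sample table (one row per trawl event, with
#' mean salinity in ppt and water temperature in degrees C) with a long
#' count table (sample_id, taxon, count).
#'
#' @param samples data.frame with columns `sample_id`, `estuary_id`,
#'   `program_id`, `date`, `salinity_ppt`, `temperature_c`.
#' @param counts data.frame with columns `sample_id`, `taxon`, `count`.
#' @return object of class `trawl_records`.
#' @export
trawl_records <- function(samples, counts) {
  need_s <- c("sample_id", "estuary_id", "program_id", "date",
              "salinity_ppt", "temperature_c")
  if (!all(need_s %in% names(samples))) {
    stop("samples need columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  need_c <- c("sample_id", "taxon", "count")
  if (!all(need_c %in% names(counts))) {
    stop("counts need columns ", paste(need_c, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  if (any(counts$count < 0 | counts$count != round(counts$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  orphan <- setdiff(counts$sample_id, samples$sample_id)
  if (length(orphan)) stop("counts reference unknown sample ids",
                           call. = FALSE)
  structure(list(samples = samples, counts = counts),
            class = "trawl_records")
}

#' Read trawl survey data from CSV
#'
#' Two dialects are accepted. Long format: `file` holds the sample table and
#' `counts_file` the (sample_id, taxon, count) triples. Wide format
#' (`counts_file = NULL`): every column of `file` beyond the six sample
#' columns is taken as a taxon, cells as counts.
#'
#' @param file sample (or wide) CSV path.
#' @param counts_file optional long-format counts CSV path.
#' @return a [trawl_records()] object.
#' @export
read_trawls <- function(file, counts_file = NULL) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("sample_id", "estuary_id", "program_id", "date",
                 "salinity_ppt", "temperature_c")
  if (!is.null(counts_file)) {
    counts <- utils::read.csv(counts_file, stringsAsFactors = FALSE)
    return(trawl_records(raw[, meta_cols], counts))
  }
  taxa <- setdiff(names(raw), meta_cols)
  long <- do.call(rbind, lapply(taxa, function(tx) {
    cnt <- raw[[tx]]
    keep <- !is.na(cnt) & cnt > 0
    if (!any(keep)) return(NULL)
    data.frame(sample_id = raw$sample_id[keep], taxon = tx,
               count = cnt[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(long)) {
    long <- data.frame(sample_id = character(0), taxon = character(0),
                       count = integer(0))
  }
  trawl_records(raw[, meta_cols], long)
}

#' Quality-control filter for trawl samples
#'
#' Keeps samples with water temperature in `[t_min, t_max]` (defaults 5 and
#' 35 degrees C) and non-negative salinity. Samples with missing salinity or
#' temperature are removed, since both feed the model's sample-level
#' covariates. The removal reason is recorded per dropped sample.
#'
#' @param trawls a [trawl_records()] object.
#' @param t_min,t_max temperature bounds, degrees C.
#' @return list with elements `kept` (a `trawl_records`), `removed`
#'   (data.frame of dropped samples with a `reason` column).
#' @export
qc_filter <- function(trawls, t_min = 5, t_max = 35) {
  s <- trawls$samples
  reason <- rep(NA_character_, nrow(s))
  reason[is.na(s$salinity_ppt) | is.na(s$temperature_c)] <- "missing_value"
  ok_t <- !is.na(s$temperature_c) & s$temperature_c >= t_min &
    s$temperature_c <= t_max
  reason[is.na(reason) & !ok_t] <- "temperature_out_of_range"
  reason[is.na(reason) & s$salinity_ppt < 0] <- "negative_salinity"
  keep <- is.na(reason)
  kept <- trawl_records(
    s[keep, , drop = FALSE],
    trawls$counts[trawls$counts$sample_id %in% s$sample_id[keep], ,
                  drop = FALSE])
  removed <- s[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  list(kept = kept, removed = removed)
}

#' Functional-group richness per trawl sample
#'
#' Richness of group g in a sample is the number of distinct taxa with
#' count > 0 that the FG table maps to g. Taxa absent from the table are
#' ignored; their names are attached as attribute `unmapped_taxa`.
#'
#' @param trawls a [trawl_records()] object (post-QC).
#' @param fg_table a [read_fg_table()] table.
#' @return data.frame: `sample_id` plus one richness column per functional
#'   group, in [functional_groups()] order, one row per sample (including
#'   samples with no mapped taxa, which get zeros).
#' @export
fg_richness <- function(trawls, fg_table = read_fg_table()) {
  cnt <- trawls$counts
  cnt <- cnt[cnt$count > 0, , drop = FALSE]
  grp <- fg_table$functional_group[match(cnt$taxon, fg_table$taxon)]
  unmapped <- sort(unique(cnt$taxon[is.na(grp)]))
  cnt <- cnt[!is.na(grp), , drop = FALSE]
  grp <- grp[!is.na(grp)]
  # distinct taxa only
  key <- !duplicated(paste(cnt$sample_id, cnt$taxon))
  cnt <- cnt[key, , drop = FALSE]
  grp <- grp[key]

  ids <- trawls$samples$sample_id
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (g in functional_groups()) {
    tb <- table(factor(cnt$sample_id[grp == g], levels = ids))
    out[[g]] <- as.integer(tb)
  }
  attr(out, "unmapped_taxa") <- unmapped
  out
}

#' Subsample trawl events per estuary
#'
#' Estuaries with more than `n_per_estuary` QC-passing trawl events
#' contribute a uniform without-replacement sample of that size to the
#' fitting set; smaller estuaries contribute all their events. Everything
#' else goes to the hold-out set. Reproducible given `seed`.
#'
#' @param trawls a [trawl_records()] object.
#' @param n_per_estuary fitting-set cap per estuary (default 150).
#' @param seed integer RNG seed (required).
#' @return list with `fitted` and `holdout` (both `trawl_records`) and
#'   `seed`.
#' @export
subsample_trawls <- function(trawls, n_per_estuary = 150, seed) {
  if (missing(seed)) stop("seed is required for reproducibility",
                          call. = FALSE)
  s <- trawls$samples
  keep <- logical(nrow(s))
  rng <- local_rng(seed)
  for (est in sort(unique(as.character(s$estuary_id)))) {
    idx <- which(as.character(s$estuary_id) == est)
    if (length(idx) > n_per_estuary) {
      keep[sample(idx, n_per_estuary)] <- TRUE
    } else {
      keep[idx] <- TRUE
    }
  }
  rng()
  subset_records <- function(mask) {
    trawl_records(
      s[mask, , drop = FALSE],
      trawls$counts[trawls$counts$sample_id %in% s$sample_id[mask], ,
                    drop = FALSE])
  }
  list(fitted = subset_records(keep), holdout = subset_records(!keep),
       seed = seed)
}

# set.seed scoped to the caller: returns a restore function
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Compare covariate distributions between a subsample and the full set
#'
#' Advisory check that the fitting subset preserves the distributions of the
#' full QC-passing data: per variable, the two-sample Kolmogorov-Smirnov
#' distance (sup-norm between empirical CDFs), plus optional side-by-side
#' histograms. No automatic rejection is performed.
#'
#' @param fitted,all_records `trawl_records` objects.
#' @param variables sample-table columns to compare.
#' @param plot_file optional PNG path for the histogram panel.
#' @return data.frame with columns `variable`, `ks_distance`.
#' @export
distribution_check <- function(fitted, all_records,
                               variables = c("salinity_ppt", "temperature_c"),
                               plot_file = NULL) {
  stopifnot(nrow(fitted$samples) > 0, nrow(all_records$samples) > 0)
  ks <- vapply(variables, function(v) {
    ks_distance(fitted$samples[[v]], all_records$samples[[v]])
  }, numeric(1))
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 480 * length(variables), height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    old <- graphics::par(mfrow = c(1, length(variables)))
    on.exit(graphics::par(old), add = TRUE)
    for (v in variables) {
      graphics::hist(all_records$samples[[v]], col = "grey80", main = v,
                     xlab = v, freq = FALSE)
      graphics::hist(fitted$samples[[v]], col = grDevices::rgb(0, 0, 1, .4),
                     add = TRUE, freq = FALSE)
    }
  }
  data.frame(variable = variables, ks_distance = unname(ks),
             stringsAsFactors = FALSE)
}

# two-sample KS statistic: sup |F1 - F2| over the pooled support
ks_distance <- function(x, y) {
  x <- sort(x[!is.na(x)]); y <- sort(y[!is.na(y)])
  pts <- sort(unique(c(x, y)))
  f1 <- findInterval(pts, x) / length(x)
  f2 <- findInterval(pts, y) / length(y)
  max(abs(f1 - f2))
}

#' Apply the model's covariate transforms
#'
#' Sample-level covariates (salinity, temperature) are log-transformed and
#' group-mean-centered; estuary-level runoff covariates are log-transformed
#' and grand-mean-centered across estuaries. Small offsets delta guard the
#' log at zero (default 1e-6 ppt for salinity, 0 for temperature which QC
#' keeps >= 5, and 1 m3/km2 for runoff volumes). Centering means are
#' recorded so transformed values can be mapped back.
#'
#' @param trawls QC-passed `trawl_records` used for fitting.
#' @param estuary_covariates J x 6 matrix from [runoff_covariates()]
#'   (rownames = estuary ids).
#' @param fg_table FG table for the richness response.
#' @param center_by grouping for sample-level centering: `"estuary"`
#'   (default; the grouping whose random slopes the covariates feed) or
#'   `"program"`.
#' @param holdout optional `trawl_records` given the same transforms (using
#'   the fitting set's centering means).
#' @param delta named offsets for the log transform.
#' @return object of class `prepared_dataset`: `rows` (j, k, estuary_id,
#'   program_id, X1, X2, and one richness column per FG), `estuary_x`
#'   (J x 6 transformed matrix), `holdout_rows`, `levels` (estuary/program
#'   level tables), `centering` (means used, for back-transformation).
#' @export
transform_covariates <- function(trawls, estuary_covariates,
                                 fg_table = read_fg_table(),
                                 center_by = c("estuary", "program"),
                                 holdout = NULL,
                                 delta = c(salinity = 1e-6, temperature = 0,
                                           runoff = 1)) {
  center_by <- match.arg(center_by)
  s <- trawls$samples
  if (any(s$salinity_ppt < 0) || any(s$temperature_c <= 0)) {
    stop("covariate transform requires salinity >= 0 and temperature > 0 ",
         "(run qc_filter first)", call. = FALSE)
  }
  est_levels <- rownames(estuary_covariates)
  if (is.null(est_levels)) stop("estuary_covariates needs rownames",
                                call. = FALSE)
  miss <- setdiff(unique(as.character(s$estuary_id)), est_levels)
  if (length(miss)) stop("no covariates for estuaries: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  prog_levels <- sort(unique(as.character(s$program_id)))

  log_sal <- log(s$salinity_ppt + delta[["salinity"]])
  log_tmp <- log(s$temperature_c + delta[["temperature"]])
  grp <- if (center_by == "estuary") as.character(s$estuary_id) else
    as.character(s$program_id)
  mean_sal <- tapply(log_sal, grp, mean)
  mean_tmp <- tapply(log_tmp, grp, mean)

  rich <- fg_richness(trawls, fg_table)
  rows <- data.frame(
    sample_id = s$sample_id,
    estuary_id = as.character(s$estuary_id),
    program_id = as.character(s$program_id),
    j = match(as.character(s$estuary_id), est_levels),
    k = match(as.character(s$program_id), prog_levels),
    X1 = log_sal - as.numeric(mean_sal[grp]),
    X2 = log_tmp - as.numeric(mean_tmp[grp]),
    stringsAsFactors = FALSE)
  for (g in functional_groups()) rows[[g]] <- rich[[g]]

  lx <- log(estuary_covariates + delta[["runoff"]])
  if (any(apply(estuary_covariates, 2, function(v) all(v == 0)))) {
    stop("degenerate covariate: an LULC runoff column is all zero",
         call. = FALSE)
  }
  grand <- colMeans(lx)
  ex <- sweep(lx, 2, grand)

  holdout_rows <- NULL
  if (!is.null(holdout) && nrow(holdout$samples)) {
    hs <- holdout$samples
    hg <- if (center_by == "estuary") as.character(hs$estuary_id) else
      as.character(hs$program_id)
    known <- hg %in% names(mean_sal)
    if (!all(known)) {
      message(sum(!known), " hold-out rows from centering groups unseen in ",
              "fitting were centered on the fitting-set grand mean")
    }
    ms <- ifelse(known, mean_sal[hg], mean(log_sal))
    mt <- ifelse(known, mean_tmp[hg], mean(log_tmp))
    hrich <- fg_richness(holdout, fg_table)
    holdout_rows <- data.frame(
      sample_id = hs$sample_id,
      estuary_id = as.character(hs$estuary_id),
      program_id = as.character(hs$program_id),
      j = match(as.character(hs$estuary_id), est_levels),
      k = match(as.character(hs$program_id), prog_levels),
      X1 = log(hs$salinity_ppt + delta[["salinity"]]) - ms,
      X2 = log(hs$temperature_c + delta[["temperature"]]) - mt,
      stringsAsFactors = FALSE)
    for (g in functional_groups()) holdout_rows[[g]] <- hrich[[g]]
  }

  structure(
    list(rows = rows, estuary_x = ex, holdout_rows = holdout_rows,
         levels = list(estuary = est_levels, program = prog_levels),
         centering = list(center_by = center_by, delta = delta,
                          sample_means = list(salinity = mean_sal,
                                              temperature = mean_tmp),
                          estuary_grand_means = grand)),
    class = "prepared_dataset")
}

#' Extract fitting-ready model data for one functional group
#'
#' @param prepared a [transform_covariates()] result.
#' @param group one of [functional_groups()].
#' @param holdout use the hold-out rows instead of the fitting rows.
#' @return object of class `model_data`: list with `y`, `j`, `k`, `x1`,
#'   `x2`, `estuary_x` (J x 6), `J`, `K`, `group`.
#' @export
model_data <- function(prepared, group = functional_groups(),
                       holdout = FALSE) {
  group <- match.arg(group)
  rows <- if (holdout) prepared$holdout_rows else prepared$rows
  if (is.null(rows) || !nrow(rows)) stop("no rows available", call. = FALSE)
  structure(
    list(y = as.integer(rows[[group]]), j = rows$j, k = rows$k,
         x1 = rows$X1, x2 = rows$X2,
         estuary_x = prepared$estuary_x,
         J = length(prepared$levels$estuary),
         K = length(prepared$levels$program),
         group = group),
    class = "model_data")
}
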