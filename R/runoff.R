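#' Potential maximum retention from a curve number
#'
#' The SCS/NRCS curve-number method's storage parameter,
#' `S = 1000/CN - 10` (inches). CN = 100 means no infiltration (S = 0);
#' lower CN means higher retention capacity.
#'
#' @param curve_number dimensionless CN in (0, 100].
#' @return retention S in inches.
#' @export
potential_retention <- function(curve_number) {
  if (any(!is.finite(curve_number) | curve_number <= 0 | curve_number > 100)) {
    stop("curve_number must lie in (0, 100]", call. = FALSE)
  }
  1000 / curve_number - 10
}

#' Event runoff depth from daily precipitation (curve-number method)
#'
#' Standard TR-55 event equation with initial abstraction `Ia = 0.2 S`:
#' runoff is zero when `P <= Ia`, otherwise `(P - Ia)^2 / (P - Ia + S)`.
#' All depths in inches. Vectorised over `precip_depth` and `curve_number`
#' (recycled against each other).
#'
#' @param precip_depth event (daily) precipitation depth, inches, >= 0.
#' @param curve_number dimensionless CN in (0, 100].
#' @return runoff depth in inches, guaranteed in `[0, P]`.
#' @examples
#' event_runoff(2.0, 75)   # 0.38095...
#' @export
event_runoff <- function(precip_depth, curve_number) {
  if (any(!is.finite(precip_depth) | precip_depth < 0)) {
    stop("precip_depth must be non-negative", call. = FALSE)
  }
  s <- potential_retention(curve_number)
  n <- max(length(precip_depth), length(s))
  p <- rep_len(precip_depth, n)
  s <- rep_len(s, n)
  ia <- 0.2 * s
  q <- numeric(n)
  run <- p > ia
  q[run] <- (p[run] - ia[run])^2 / (p[run] - ia[run] + s[run])
  q
}

MM_PER_INCH <- 25.4

#' Read watershed composition and precipitation inputs
#'
#' `read_composition()` expects columns `estuary_id`, `ccap_code`,
#' `soil_group`, `area_m2` plus (either in the same file or via
#' `watershed_file`) `watershed_area_km2` per estuary.
#' `read_precip()` expects `estuary_id`, `date` (ISO-8601), `precip_mm`.
#'
#' @param file CSV path.
#' @param watershed_file optional CSV path with `estuary_id`,
#'   `watershed_area_km2`; if `NULL`, `file` must carry the column itself.
#' @return `read_composition()`: a list of `watershed_composition` objects,
#'   one per estuary. `read_precip()`: a list of `precip_series` objects.
#' @export
read_composition <- function(file, watershed_file = NULL) {
  comp <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("estuary_id", "ccap_code", "soil_group", "area_m2")
  if (!all(need %in% names(comp))) {
    stop("composition CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(watershed_file)) {
    ws <- utils::read.csv(watershed_file, stringsAsFactors = FALSE)
  } else if ("watershed_area_km2" %in% names(comp)) {
    ws <- unique(comp[, c("estuary_id", "watershed_area_km2")])
  } else {
    stop("watershed areas missing: supply watershed_file or a ",
         "watershed_area_km2 column", call. = FALSE)
  }
  lapply(split(comp, comp$estuary_id), function(d) {
    id <- d$estuary_id[1]
    area <- ws$watershed_area_km2[match(id, ws$estuary_id)]
    watershed_composition(id, d$ccap_code, d$soil_group, d$area_m2, area)
  })
}

#' Construct a watershed composition
#'
#' @param estuary_id identifier.
#' @param ccap_code integer C-CAP codes per row.
#' @param soil_group hydrologic soil group A-D per row.
#' @param area_m2 class area per row, square metres.
#' @param watershed_area_km2 total watershed area, square kilometres.
#' @return object of class `watershed_composition`.
#' @export
watershed_composition <- function(estuary_id, ccap_code, soil_group, area_m2,
                                  watershed_area_km2) {
  if (any(area_m2 < 0)) stop("areas must be >= 0", call. = FALSE)
  if (!is.finite(watershed_area_km2) || watershed_area_km2 <= 0) {
    stop("watershed_area_km2 must be > 0", call. = FALSE)
  }
  if (sum(area_m2) > watershed_area_km2 * 1e6 * (1 + 1e-9)) {
    stop("class areas exceed the watershed area", call. = FALSE)
  }
  if (!all(soil_group %in% soil_groups())) {
    stop("soil_group must be one of A, B, C, D", call. = FALSE)
  }
  structure(
    list(estuary_id = estuary_id,
         rows = data.frame(ccap_code = as.integer(ccap_code),
                           soil_group = as.character(soil_group),
                           area_m2 = as.numeric(area_m2),
                           stringsAsFactors = FALSE),
         watershed_area_km2 = watershed_area_km2),
    class = "watershed_composition")
}

#' @rdname read_composition
#' @export
read_precip <- function(file) {
  pr <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("estuary_id", "date", "precip_mm")
  if (!all(need %in% names(pr))) {
    stop("precip CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(pr, pr$estuary_id), function(d) {
    precip_series(d$estuary_id[1], as.Date(d$date), d$precip_mm)
  })
}

#' Construct a daily precipitation series
#'
#' @param estuary_id identifier.
#' @param date vector of `Date`s (daily resolution).
#' @param precip_mm daily depths, mm, >= 0.
#' @return object of class `precip_series`.
#' @export
precip_series <- function(estuary_id, date, precip_mm) {
  if (any(!is.finite(precip_mm) | precip_mm < 0)) {
    stop("precipitation depths must be non-negative", call. = FALSE)
  }
  date <- as.Date(date)
  if (anyDuplicated(date)) stop("duplicate dates in precip series",
                                call. = FALSE)
  structure(list(estuary_id = estuary_id, date = date,
                 precip_mm = as.numeric(precip_mm)),
            class = "precip_series")
}

# Days belonging to complete calendar years (365 ordinary / 366 leap).
# Leap days count as ordinary days; incomplete years are dropped from the
# "mean annual" average.
complete_year_mask <- function(date) {
  yr <- as.integer(format(date, "%Y"))
  n_by_year <- table(yr)
  need <- ifelse(as.integer(names(n_by_year)) %% 4 == 0 &
                   (as.integer(names(n_by_year)) %% 100 != 0 |
                      as.integer(names(n_by_year)) %% 400 == 0), 366L, 365L)
  complete <- as.integer(names(n_by_year))[as.integer(n_by_year) >= need]
  list(mask = yr %in% complete, n_years = length(complete))
}

#' Mean annual runoff volume per LULC group, normalized by watershed area
#'
#' For every LULC group the daily curve-number runoff depth is evaluated per
#' (group, soil) stratum, multiplied by the stratum area, summed over soils
#' and days of each complete calendar year, converted to cubic metres,
#' averaged over years, and divided by the watershed area. The result is the
#' vector of LULC runoff-influence covariates (before log transform and
#' centering), in m3/km2/yr. C-CAP codes outside the six modelled groups
#' are excluded by construction.
#'
#' @param comp a [watershed_composition()].
#' @param precip a [precip_series()] for the same watershed.
#' @param cn a CN table from [read_cn_table()] / [default_cn_table()].
#' @return object of class `runoff_by_class`: named numeric vector over
#'   [lulc_groups()], with attributes `estuary_id` and `watershed_area_km2`.
#' @export
annual_runoff_by_class <- function(comp, precip, cn = default_cn_table()) {
  stopifnot(inherits(comp, "watershed_composition"),
            inherits(precip, "precip_series"))
  cyc <- complete_year_mask(precip$date)
  if (cyc$n_years < 1L) {
    stop("precipitation series must cover at least one complete year",
         call. = FALSE)
  }
  p_in <- precip$precip_mm[cyc$mask] / MM_PER_INCH

  rows <- comp$rows
  rows$lulc_group <- aggregate_ccap(rows$ccap_code)
  rows <- rows[!is.na(rows$lulc_group) & rows$area_m2 > 0, , drop = FALSE]

  vols <- stats::setNames(numeric(length(lulc_groups())), lulc_groups())
  if (nrow(rows)) {
    # collapse to (group, soil) strata: runoff is additive over area
    agg <- stats::aggregate(area_m2 ~ lulc_group + soil_group, data = rows,
                            FUN = sum)
    agg$cn <- cn_lookup(cn, agg$lulc_group, agg$soil_group)
    for (g in unique(agg$lulc_group)) {
      sub <- agg[agg$lulc_group == g, , drop = FALSE]
      v <- 0
      for (r in seq_len(nrow(sub))) {
        q_in <- event_runoff(p_in, sub$cn[r])           # inches per day
        v <- v + sum(q_in) * (MM_PER_INCH / 1000) * sub$area_m2[r]  # m3
      }
      vols[g] <- v / cyc$n_years
    }
  }
  structure(vols / comp$watershed_area_km2,
            estuary_id = comp$estuary_id,
            watershed_area_km2 = comp$watershed_area_km2,
            class = c("runoff_by_class", "numeric"))
}

#' Runoff covariate matrix across estuaries
#'
#' Applies [annual_runoff_by_class()] to matched lists of compositions and
#' precipitation series and stacks the results into the J x 6 estuary
#' covariate matrix (rows named by estuary).
#'
#' @param comps list of `watershed_composition` objects.
#' @param precips list of `precip_series` objects, matched by `estuary_id`.
#' @param cn curve-number table.
#' @return numeric matrix, estuaries x [lulc_groups()].
#' @export
runoff_covariates <- function(comps, precips, cn = default_cn_table()) {
  pids <- vapply(precips, function(p) as.character(p$estuary_id), "")
  out <- t(vapply(comps, function(cp) {
    i <- match(as.character(cp$estuary_id), pids)
    if (is.na(i)) stop("no precipitation series for estuary ",
                       cp$estuary_id, call. = FALSE)
    as.numeric(annual_runoff_by_class(cp, precips[[i]], cn))
  }, numeric(6)))
  colnames(out) <- lulc_groups()
  rownames(out) <- vapply(comps, function(cp) as.character(cp$estuary_id), "")
  out
}
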