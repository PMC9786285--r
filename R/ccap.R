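#' Aggregate a C-CAP land-cover code into a modelled LULC group
#'
#' Maps integer NOAA C-CAP 2001 regional land-cover codes onto the six
#' aggregated land-use/land-cover (LULC) groups used as estuary-level
#' covariates: developed (codes 2-5), cropland (6), forest (9-11),
#' palustrine wetland (13-15), estuarine wetland (16-18) and barren (20).
#' Codes outside the mapping (water, grassland, pasture, ice, ...) are
#' deliberately dropped: they return `NA` and contribute nothing to the
#' runoff covariates.
#'
#' @param ccap_code integer vector of C-CAP class codes.
#' @return character vector of LULC group names, `NA` where the code is not
#'   part of any modelled group.
#' @examples
#' aggregate_ccap(c(2, 6, 14, 8))
#' @export
aggregate_ccap <- function(ccap_code) {
  if (length(ccap_code) == 0L) return(character(0))
  if (any(!is.finite(ccap_code) | ccap_code != round(ccap_code))) {
    stop("ccap_code must be a vector of integers", call. = FALSE)
  }
  out <- rep(NA_character_, length(ccap_code))
  out[ccap_code %in% 2:5]   <- "developed"
  out[ccap_code == 6]       <- "cropland"
  out[ccap_code %in% 9:11]  <- "forest"
  out[ccap_code %in% 13:15] <- "palustrine_wetland"
  out[ccap_code %in% 16:18] <- "estuarine_wetland"
  out[ccap_code == 20]      <- "barren"
  out
}

#' The six modelled LULC groups, in covariate order
#'
#' Order matches the estuary-level covariate slots X3-X8 of the richness
#' model: developed, cropland, forest, palustrine wetland, estuarine
#' wetland, barren.
#'
#' @return character vector of length 6.
#' @export
lulc_groups <- function() {
  c("developed", "cropland", "forest",
    "palustrine_wetland", "estuarine_wetland", "barren")
}

#' Hydrologic soil groups
#' @return character vector `c("A","B","C","D")`.
#' @export
soil_groups <- function() c("A", "B", "C", "D")

#' Load and validate a curve-number lookup table
#'
#' A curve-number (CN) table keys the dimensionless SCS/NRCS runoff
#' parameter by (LULC group, hydrologic soil group). The packaged default
#' (see [default_cn_table()]) is patterned on the values distributed with
#' NOAA's nonpoint-source screening tooling, with one deliberate override:
#' both wetland groups carry CN = 100 (no infiltration) for every soil
#' group, so that wetland runoff influence is comparable across estuaries
#' instead of being identically zero.
#'
#' @param file path to a CSV with columns `lulc_group`, `soil_group`, `cn`.
#' @return data.frame with class `cn_table`, one row per (group, soil) pair.
#' @export
read_cn_table <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_cn_table(tab)
}

#' @rdname read_cn_table
#' @export
default_cn_table <- function() {
  read_cn_table(system.file("extdata", "curve_numbers.csv",
                            package = "estuarich", mustWork = TRUE))
}

#' @rdname read_cn_table
#' @param tab data.frame to validate.
#' @export
validate_cn_table <- function(tab) {
  need <- c("lulc_group", "soil_group", "cn")
  if (!all(need %in% names(tab))) {
    stop("CN table must have columns lulc_group, soil_group, cn",
         call. = FALSE)
  }
  full <- expand.grid(lulc_group = lulc_groups(), soil_group = soil_groups(),
                      stringsAsFactors = FALSE)
  key <- paste(tab$lulc_group, tab$soil_group)
  missing <- setdiff(paste(full$lulc_group, full$soil_group), key)
  if (length(missing)) {
    stop("CN table missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(key)) stop("duplicate (group, soil) rows in CN table",
                               call. = FALSE)
  if (any(tab$cn < 30 | tab$cn > 100)) {
    stop("curve numbers must lie in [30, 100]", call. = FALSE)
  }
  wet <- tab$lulc_group %in% c("palustrine_wetland", "estuarine_wetland")
  if (any(tab$cn[wet] != 100)) {
    stop("wetland groups must carry CN = 100 for every soil group",
         call. = FALSE)
  }
  class(tab) <- c("cn_table", "data.frame")
  tab
}

#' Look up curve numbers for (group, soil) pairs
#'
#' @param cn_table a validated CN table.
#' @param group,soil vectors of LULC groups and soil groups (recycled).
#' @return numeric vector of curve numbers.
#' @export
cn_lookup <- function(cn_table, group, soil) {
  key <- paste(cn_table$lulc_group, cn_table$soil_group)
  idx <- match(paste(group, soil), key)
  if (anyNA(idx)) {
    bad <- unique(paste(group, soil)[is.na(idx)])
    stop("no curve number for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cn_table$cn[idx]
}
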