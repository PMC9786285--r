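test_that("packaged functional-group table matches the transcribed list", {
  fg <- read_fg_table()
  expect_s3_class(fg, "fg_table")
  tab <- table(fg$functional_group)
  expect_equal(as.integer(tab[["pelagic"]]), 23L)
  expect_equal(as.integer(tab[["forage_finfish"]]), 27L)
  expect_equal(as.integer(tab[["shrimp"]]), 27L)
  expect_false(anyDuplicated(fg$taxon) > 0)
  # spot checks across ranks: species, genus, family entries
  expect_equal(fg$functional_group[fg$taxon == "Anchoa mitchilli"],
               "forage_finfish")
  expect_equal(fg$functional_group[fg$taxon == "Litopenaeus setiferus"],
               "shrimp")
  expect_equal(fg$functional_group[fg$taxon == "Penaeidae"], "shrimp")
  expect_equal(fg$functional_group[fg$taxon == "Caranx hippos"], "pelagic")
})

test_that("QC keeps 5-35 C and non-negative salinity, logs reasons", {
  tr <- toy_trawls()
  out <- qc_filter(tr)
  expect_setequal(out$kept$samples$sample_id, c("s1", "s3", "s4"))
  expect_equal(nrow(out$kept$samples) + nrow(out$removed),
               nrow(tr$samples))
  reasons <- setNames(out$removed$reason, out$removed$sample_id)
  expect_equal(reasons[["s2"]], "temperature_out_of_range")   # T = 4.9
  expect_equal(reasons[["s5"]], "negative_salinity")          # sal = -0.1
  expect_equal(reasons[["s6"]], "temperature_out_of_range")   # T = 36
  # boundary: salinity 0 and T in [5, 35] pass (s3: sal 0, T 25)
  expect_true("s3" %in% out$kept$samples$sample_id)
  # idempotence
  again <- qc_filter(out$kept)
  expect_identical(again$kept$samples, out$kept$samples)
  expect_equal(nrow(again$removed), 0)
  # missing values are removed and flagged
  tr$samples$temperature_c[1] <- NA
  expect_equal(qc_filter(tr)$removed$reason[
    qc_filter(tr)$removed$sample_id == "s1"], "missing_value")
})

test_that("FG richness counts distinct mapped taxa with count > 0", {
  tr <- toy_trawls()
  r <- fg_richness(tr)
  row1 <- r[r$sample_id == "s1", ]
  expect_equal(row1$forage_finfish, 2L)   # Anchoa mitchilli + B. patronus
  expect_equal(row1$shrimp, 1L)           # L. setiferus
  expect_equal(row1$pelagic, 0L)
  # unmapped taxa are ignored and reported
  row3 <- r[r$sample_id == "s3", ]
  expect_equal(row3$forage_finfish, 1L)
  expect_equal(attr(r, "unmapped_taxa"), "Unknown sp.")
  # samples without counts get zeros
  row2 <- r[r$sample_id == "s2", ]
  expect_equal(row2$pelagic + row2$forage_finfish + row2$shrimp, 0L)

  # zero-count listings and duplicates do not inflate richness
  tr2 <- trawl_records(
    tr$samples,
    data.frame(sample_id = c("s1", "s1", "s1"),
               taxon = c("Anchoa mitchilli", "Anchoa mitchilli",
                         "Caranx hippos"),
               count = c(3L, 8L, 0L), stringsAsFactors = FALSE))
  r2 <- fg_richness(tr2)
  expect_equal(r2[r2$sample_id == "s1", "forage_finfish"], 1L)
  expect_equal(r2[r2$sample_id == "s1", "pelagic"], 0L)
})

test_that("richness is bounded by the group's taxon count", {
  fg <- read_fg_table()
  study <- generate_study(synthetic_config(J = 4, K = 2,
                                           trawls_per_estuary = 30,
                                           precip_years = 1, seed = 77))
  r <- fg_richness(study$trawls, fg)
  expect_true(all(r$pelagic <= 23))
  expect_true(all(r$forage_finfish <= 27))
  expect_true(all(r$shrimp <= 27))
})

test_that("subsampling caps per-estuary contributions and is reproducible", {
  mk <- function(n, est) data.frame(
    sample_id = paste0(est, seq_len(n)), estuary_id = est, program_id = "p",
    date = "2001-01-01", salinity_ppt = 10, temperature_c = 20,
    stringsAsFactors = FALSE)
  s <- rbind(mk(140, "A"), mk(500, "B"))
  tr <- trawl_records(s, data.frame(sample_id = character(0),
                                    taxon = character(0),
                                    count = integer(0)))
  out <- subsample_trawls(tr, 150, seed = 10)
  fit_est <- table(out$fitted$samples$estuary_id)
  expect_equal(as.integer(fit_est[["A"]]), 140L)  # <= cap: all kept
  expect_equal(as.integer(fit_est[["B"]]), 150L)
  expect_equal(sum(out$holdout$samples$estuary_id == "B"), 350L)
  expect_equal(sum(out$holdout$samples$estuary_id == "A"), 0L)
  # partition: disjoint and exhaustive
  expect_length(intersect(out$fitted$samples$sample_id,
                          out$holdout$samples$sample_id), 0)
  expect_setequal(c(out$fitted$samples$sample_id,
                    out$holdout$samples$sample_id), s$sample_id)
  # determinism
  out2 <- subsample_trawls(tr, 150, seed = 10)
  expect_identical(out$fitted$samples$sample_id,
                   out2$fitted$samples$sample_id)
  expect_error(subsample_trawls(tr, 150), "seed")
})

test_that("KS distance matches a brute-force ECDF sweep", {
  # brute force: evaluate both ECDFs at every pooled point
  brute_ks <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(p) abs(mean(x <= p) - mean(y <= p)), 1))
  }
  set.seed(21)
  x <- runif(80)
  y <- x[1:40]
  mk <- function(v) trawl_records(
    data.frame(sample_id = as.character(seq_along(v)), estuary_id = "A",
               program_id = "p", date = "2001-01-01", salinity_ppt = v,
               temperature_c = 20, stringsAsFactors = FALSE),
    data.frame(sample_id = character(0), taxon = character(0),
               count = integer(0)))
  got <- distribution_check(mk(y), mk(x), variables = "salinity_ppt")
  expect_equal(got$ks_distance, brute_ks(y, x), tolerance = 1e-12)
  # identical sets: distance 0; disjoint supports: distance 1
  expect_equal(distribution_check(mk(x), mk(x),
                                  "salinity_ppt")$ks_distance, 0)
  expect_equal(distribution_check(mk(x), mk(x + 10),
                                  "salinity_ppt")$ks_distance, 1)
})

test_that("covariate transforms center logs as specified", {
  # estuary-level values {1, e, e^2} with zero offset -> {-1, 0, 1}
  s <- data.frame(
    sample_id = as.character(1:3), estuary_id = c("A", "B", "C"),
    program_id = "p", date = "2001-01-01",
    salinity_ppt = c(10, 10, 10), temperature_c = c(20, 20, 20),
    stringsAsFactors = FALSE)
  tr <- trawl_records(s, data.frame(sample_id = character(0),
                                    taxon = character(0),
                                    count = integer(0)))
  ex <- matrix(rep(c(1, exp(1), exp(2)), 6), nrow = 3,
               dimnames = list(c("A", "B", "C"), lulc_groups()))
  prep <- transform_covariates(tr, ex,
                               delta = c(salinity = 1e-6, temperature = 0,
                                         runoff = 0))
  expect_equal(unname(prep$estuary_x[, "forest"]), c(-1, 0, 1))

  # sample-level columns center to zero within each estuary
  fx <- small_fit_fixture()
  rows <- fx$prep$rows
  for (est in unique(rows$estuary_id)) {
    expect_equal(mean(rows$X1[rows$estuary_id == est]), 0, tolerance = 1e-12)
    expect_equal(mean(rows$X2[rows$estuary_id == est]), 0, tolerance = 1e-12)
  }
  # estuary columns center to zero across estuaries
  expect_equal(unname(colMeans(fx$prep$estuary_x)), rep(0, 6),
               tolerance = 1e-12)

  # un-centering recovers log(value + delta) exactly
  cent <- fx$prep$centering
  back <- rows$X1 + as.numeric(cent$sample_means$salinity[rows$estuary_id])
  expect_equal(back, log(fx$prep$rows$sample_id |>
                           match(fx$study$trawls$samples$sample_id) |>
                           (\(i) fx$study$trawls$samples$salinity_ppt[i])() +
                           1e-6),
               tolerance = 1e-12)
})

test_that("degenerate covariates and single-estuary input behave", {
  s <- data.frame(
    sample_id = "1", estuary_id = "A", program_id = "p",
    date = "2001-01-01", salinity_ppt = 10, temperature_c = 20,
    stringsAsFactors = FALSE)
  tr <- trawl_records(s, data.frame(sample_id = character(0),
                                    taxon = character(0),
                                    count = integer(0)))
  ex1 <- matrix(5, 1, 6, dimnames = list("A", lulc_groups()))
  prep <- transform_covariates(tr, ex1)
  expect_equal(unname(as.numeric(prep$estuary_x)), rep(0, 6))
  ex0 <- ex1; ex0[, "barren"] <- 0
  expect_error(transform_covariates(tr, ex0), "degenerate|all zero")
})

test_that("trawl CSV readers accept wide and long dialects", {
  d <- withr::local_tempdir()
  wide <- data.frame(sample_id = c("a", "b"), estuary_id = "E",
                     program_id = "p", date = "2001-01-01",
                     salinity_ppt = c(1, 2), temperature_c = c(20, 21),
                     check.names = FALSE, stringsAsFactors = FALSE)
  wide[["Anchoa mitchilli"]] <- c(3L, 0L)
  wide[["Caranx hippos"]] <- c(0L, 2L)
  wf <- file.path(d, "wide.csv")
  write.csv(wide, wf, row.names = FALSE)
  tr <- read_trawls(wf)
  expect_equal(nrow(tr$samples), 2)
  expect_equal(nrow(tr$counts), 2)      # zero cells dropped
  expect_setequal(tr$counts$taxon, c("Anchoa mitchilli", "Caranx hippos"))

  sf <- file.path(d, "samples.csv"); cf <- file.path(d, "counts.csv")
  write.csv(wide[, 1:6], sf, row.names = FALSE)
  write.csv(data.frame(sample_id = "a", taxon = "Anchoa mitchilli",
                       count = 3L), cf, row.names = FALSE)
  tr2 <- read_trawls(sf, cf)
  expect_equal(tr2$counts$count, 3L)
  # orphan counts are rejected
  write.csv(data.frame(sample_id = "zz", taxon = "x", count = 1L), cf,
            row.names = FALSE)
  expect_error(read_trawls(sf, cf), "unknown sample ids")
})
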