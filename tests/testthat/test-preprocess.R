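test_that("only personal and area samples survive the type filter", {
  records <- rbind(
    raw_record("I1", sample_type = "personal"),
    raw_record("I2", sample_type = "area"),
    raw_record("I3", sample_type = "blank"),
    raw_record("I4", sample_type = "wipe")
  )
  out <- filter_sample_types(records)
  expect_equal(out$records$sample_type, c("personal", "area"))
  expect_equal(out$drop_log$rows_dropped, 2L)

  all_personal <- rbind(raw_record("I1"), raw_record("I2"))
  expect_equal(filter_sample_types(all_personal)$records, all_personal)
  empty <- filter_sample_types(records[0, ])
  expect_equal(nrow(empty$records), 0L)
  expect_equal(empty$drop_log$rows_dropped, 0L)
})

test_that("unit conversion applies the standard industrial-hygiene rules", {
  records <- rbind(
    raw_record("I1", value = 1, unit = "mg_per_m3"),
    raw_record("I2", value = 10, unit = "ppm", molecular_weight = 48.9),
    raw_record("I3", value = 5, unit = "fibers_per_cc"),
    raw_record("I4", value = 0, unit = "mg_per_m3"),
    raw_record("I5", value = 2, unit = "mass_only", air_volume = 0.5),
    raw_record("I6", value = 1e-3, unit = "percent", molecular_weight = 24.45),
    raw_record("I7", value = 3, unit = "ppm"),              # no MW
    raw_record("I8", value = 3, unit = "mass_only")         # no volume
  )
  out <- convert_units(records)
  kept <- out$records
  expect_equal(kept$inspection_id, c("I1", "I2", "I4", "I5", "I6"))
  # 1 mg/m3 -> log10(1) = 0
  expect_equal(kept$log10_conc[kept$inspection_id == "I1"], 0)
  # 10 ppm at MW 48.9 -> 10 * 48.9 / 24.45 = 20 mg/m3
  expect_equal(kept$log10_conc[kept$inspection_id == "I2"], log10(20))
  # value 0 is a nondetect marker
  expect_false(kept$detected[kept$inspection_id == "I4"])
  expect_true(is.na(kept$log10_conc[kept$inspection_id == "I4"]))
  # mass-only with volume: 2 mg in 0.5 m3 -> 4 mg/m3
  expect_equal(kept$log10_conc[kept$inspection_id == "I5"], log10(4))
  # percent -> ppm * 1e4 first: 1e-3 % at MW 24.45 -> 10 ppm -> 10 mg/m3
  expect_equal(kept$log10_conc[kept$inspection_id == "I6"], 1)
  expect_equal(out$drop_log$rows_dropped, 3L)
  expect_setequal(out$dropped$inspection_id, c("I3", "I7", "I8"))

  expect_error(convert_units(raw_record(value = -1)), "nonnegative")
})

test_that("industry codes must map to exactly one sector and subsector", {
  cc <- data.frame(
    old_code = c("A", "B", "B"),
    sector = c("11", "12", "12"),
    subsector = c("1101", "1201", "1202"),
    stringsAsFactors = FALSE
  )
  records <- rbind(
    raw_record("I1", industry_code = "A"),
    raw_record("I2", industry_code = "B"),   # ambiguous
    raw_record("I3", industry_code = "C")    # absent
  )
  out <- map_naics(records, cc)
  expect_equal(out$records$inspection_id, "I1")
  expect_equal(out$records$sector, "11")
  expect_equal(out$records$subsector, "1101")
  drops <- setNames(out$drop_log$rows_dropped, out$drop_log$reason)
  expect_equal(drops[["unmapped"]], 1L)
  expect_equal(drops[["ambiguous"]], 1L)
  expect_error(map_naics(records, cc[, 1:2]), "columns")
})

test_that("aggregation keeps the worst case per inspection and substance", {
  base <- rbind(
    raw_record("I1", "S1", value = 0.2),
    raw_record("I1", "S1", value = 1.5),
    raw_record("I1", "S1", value = 0.9),
    raw_record("I2", "S1", value = 2),
    raw_record("I3", "S1", value = 0),
    raw_record("I3", "S1", value = 0)
  )
  conv <- convert_units(base)$records
  conv$sector <- "11"
  conv$subsector <- "1101"
  agg <- aggregate_by_inspection(conv)
  expect_equal(nrow(agg), 3L)
  expect_equal(agg$log10_conc[agg$inspection_id == "I1"], log10(1.5))
  expect_equal(agg$log10_conc[agg$inspection_id == "I2"], log10(2))
  # a group of nondetects aggregates to a nondetect
  expect_false(agg$detected[agg$inspection_id == "I3"])
  # one inspection sampling two substances yields two observations
  two <- convert_units(rbind(raw_record("I9", "S1", value = 1),
                             raw_record("I9", "S2", value = 2)))$records
  two$sector <- "11"; two$subsector <- "1101"
  expect_equal(nrow(aggregate_by_inspection(two)), 2L)
})

test_that("outlier removal drops |z| > 4 within substance, with guards", {
  mk <- function(values, substance = "S1") {
    obs_table(sprintf("I%d", seq_along(values)), substance, "1101", "11",
              detected = TRUE, log10_conc = values)
  }
  # 19 values at 0 and one at 10: z = 9.5 / 2.2361 = 4.249 > 4
  spread <- mk(c(rep(0, 19), 10))
  out <- remove_outliers(spread)
  expect_equal(out$drop_log$rows_dropped, 1L)
  expect_equal(out$dropped$log10_conc, 10)

  # two detects can never be flagged (guard on tiny groups)
  expect_equal(remove_outliers(mk(c(0, 100)))$drop_log$rows_dropped, 0L)
  # identical values: sd = 0 guard
  expect_equal(remove_outliers(mk(rep(2, 30)))$drop_log$rows_dropped, 0L)
  # z-scores are computed within substance, not across
  mixed <- rbind(mk(rep(0, 20), "S1"), mk(rep(10, 20), "S2"))
  expect_equal(remove_outliers(mixed)$drop_log$rows_dropped, 0L)
  # nondetects are never dropped by the z rule
  nd <- obs_table("I1", "S1", "1101", "11", detected = FALSE)
  expect_equal(nrow(remove_outliers(rbind(mk(c(rep(0, 19), 10)), nd))$observations),
               20L)
})

test_that("subsectors below the detect floor are dropped entirely", {
  mk <- function(subsector, n_det, n_nondet) {
    rbind(
      obs_table(sprintf("%s-D%d", subsector, seq_len(n_det)), "S1",
                subsector, "11", TRUE, 0),
      if (n_nondet > 0) {
        obs_table(sprintf("%s-N%d", subsector, seq_len(n_nondet)), "S1",
                  subsector, "11", FALSE)
      }
    )
  }
  obs <- rbind(mk("1101", 9, 50), mk("1102", 10, 5))
  out <- filter_sparse_subsectors(obs, min_detects = 10)
  # 9 detects: all 59 rows (detects and nondetects) go
  expect_equal(out$drop_log$rows_dropped, 59L)
  # exactly 10 detects: kept
  expect_setequal(unique(out$observations$subsector), "1102")
  expect_equal(nrow(filter_sparse_subsectors(obs[0, ])$observations), 0L)
})

test_that("train/test split is substance-disjoint and seed-deterministic", {
  obs <- obs_table(sprintf("I%d", 1:120), rep(sprintf("S%02d", 1:60), 2),
                   "1101", "11", TRUE, 0)
  sp <- split_by_substance(obs, test_fraction = 0.1, seed = 3)
  expect_length(sp$test_substances, 6L)
  expect_length(intersect(unique(sp$train$substance_id),
                          unique(sp$test$substance_id)), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(obs))
  sp2 <- split_by_substance(obs, test_fraction = 0.1, seed = 3)
  expect_identical(sp$test_substances, sp2$test_substances)
  expect_equal(nrow(split_by_substance(obs, 0, seed = 1)$test), 0L)
  expect_error(split_by_substance(obs, 1), "\\[0, 1\\)")
})

test_that("the drop log conserves rows at every stage", {
  fx <- roundtrip_fixture()
  out <- preprocess_samples(fx$raw$records, fx$raw$concordance,
                            properties = fx$substances)
  expect_equal(sum(out$drop_log$rows_dropped) + nrow(out$observations),
               nrow(fx$raw$records))
})

test_that("preprocessing is idempotent on already-clean observations", {
  fx <- roundtrip_fixture()
  obs <- preprocess_samples(fx$raw$records, fx$raw$concordance)$observations
  again <- remove_outliers(obs)
  expect_equal(again$drop_log$rows_dropped, 0L)
  again2 <- filter_sparse_subsectors(again$observations)
  expect_equal(again2$drop_log$rows_dropped, 0L)
  expect_equal(again2$observations, obs)
})
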