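SAMPLE_TYPES <- c("personal", "area", "blank", "wipe", "bulk", "other")
UNIT_LEVELS <- c("mg_per_m3", "ppm", "percent", "mass_only", "fibers_per_cc",
                 "other")

drop_entry <- function(stage, reason, rows_dropped) {
  data.frame(stage = stage, reason = reason,
             rows_dropped = as.integer(rows_dropped),
             stringsAsFactors = FALSE)
}

#' Keep only personal and area air samples
#'
#' Blanks and samples of other types (dermal wipes, bulk substance samples,
#' ...) are removed; personal and area samples are treated identically
#' downstream.
#'
#' @param records Raw sample table with a `sample_type` column.
#' @return List with `records` (retained rows) and `drop_log` (one-row
#'   data.frame: stage, reason, rows_dropped).
#' @export
filter_sample_types <- function(records) {
  keep <- records$sample_type %in% c("personal", "area")
  list(records = records[keep, , drop = FALSE],
       drop_log = drop_entry("sample_type_filter", "not_personal_or_area",
                             sum(!keep)))
}

#' Convert raw sample values to log10 mg/m3
#'
#' Applies the standard industrial-hygiene conversions: ppm values become
#' `value * MW / 24.45` mg/m3 (molar volume 24.45 L/mol at 25 C, 1 atm),
#' percent is 10^4 ppm, and mass-only results are divided by the sampled air
#' volume. A reported value of zero marks a nondetect (no concentration).
#' Rows that cannot be converted (fibers/cc, ppm or percent without a
#' molecular weight, mass without an air volume, unknown units) are dropped
#' with reason `non_convertible`.
#'
#' @param records Raw sample table with `value`, `unit`, `molecular_weight`,
#'   `air_volume` columns.
#' @return List with `records` (convertible rows plus logical `detected` and
#'   numeric `log10_conc` columns), `dropped` (the removed rows) and
#'   `drop_log`.
#' @export
convert_units <- function(records) {
  if (any(records$value < 0, na.rm = TRUE) || anyNA(records$value)) {
    abort("sample values must be nonnegative and non-missing")
  }
  unit <- records$unit
  if (!all(unit %in% UNIT_LEVELS)) {
    abort(sprintf("unknown unit(s): %s",
                  paste(setdiff(unique(unit), UNIT_LEVELS), collapse = ", ")))
  }
  needs_mw <- unit %in% c("ppm", "percent")
  convertible <- !(
    unit %in% c("fibers_per_cc", "other") |
      (needs_mw & is.na(records$molecular_weight)) |
      (unit == "mass_only" & is.na(records$air_volume))
  )
  kept <- records[convertible, , drop = FALSE]
  mg <- kept$value
  u <- kept$unit
  mg[u == "ppm"] <- kept$value[u == "ppm"] * kept$molecular_weight[u == "ppm"] /
    MOLAR_VOLUME_L
  mg[u == "percent"] <- kept$value[u == "percent"] * 1e4 *
    kept$molecular_weight[u == "percent"] / MOLAR_VOLUME_L
  mg[u == "mass_only"] <- kept$value[u == "mass_only"] /
    kept$air_volume[u == "mass_only"]
  kept$detected <- mg > 0
  kept$log10_conc <- ifelse(mg > 0, log10(mg), NA_real_)
  list(records = kept,
       dropped = records[!convertible, , drop = FALSE],
       drop_log = drop_entry("unit_conversion", "non_convertible",
                             sum(!convertible)))
}

#' Map industry codes to a single sector and subsector
#'
#' Joins each record's industry code against a user-supplied concordance
#' table. Rows whose code matches exactly one (sector, subsector) pair are
#' annotated with those fields; rows matching zero or multiple entries are
#' dropped.
#'
#' @param records Sample table with an `industry_code` column.
#' @param concordance Data.frame with columns `old_code`, `sector`,
#'   `subsector` (an old code may appear on several rows).
#' @return List with `records` (annotated rows), `dropped` and `drop_log`
#'   (separate reasons `unmapped` and `ambiguous`).
#' @export
map_naics <- function(records, concordance) {
  if (!all(c("old_code", "sector", "subsector") %in% names(concordance))) {
    abort("`concordance` must have columns old_code, sector, subsector")
  }
  concordance <- unique(concordance[c("old_code", "sector", "subsector")])
  n_match <- table(concordance$old_code)
  m <- as.integer(n_match[records$industry_code])
  m[is.na(m)] <- 0L
  unique_match <- m == 1L
  single <- concordance[concordance$old_code %in%
                          names(n_match)[n_match == 1L], ]
  idx <- match(records$industry_code[unique_match], single$old_code)
  kept <- records[unique_match, , drop = FALSE]
  kept$sector <- single$sector[idx]
  kept$subsector <- single$subsector[idx]
  log <- rbind(
    drop_entry("naics_mapping", "unmapped", sum(m == 0L)),
    drop_entry("naics_mapping", "ambiguous", sum(m > 1L))
  )
  list(records = kept, dropped = records[!unique_match, , drop = FALSE],
       drop_log = log)
}

#' Aggregate samples to one observation per inspection and substance
#'
#' Takes the maximum converted concentration within each (inspection,
#' substance) group to characterize the worst-case exposure scenario. A
#' group is a detect if any of its samples is a detect; sector/subsector are
#' taken from the group's first record.
#'
#' @param records Converted, mapped sample table (with `detected`,
#'   `log10_conc`, `sector`, `subsector`).
#' @return Observation table with one row per (inspection_id, substance_id),
#'   sorted by those keys.
#' @export
aggregate_by_inspection <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(inspection_id = character(), substance_id = character(),
                      sector = character(), subsector = character(),
                      detected = logical(), log10_conc = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(records$inspection_id, records$substance_id, sep = "\r")
  ord <- order(key)
  r <- records[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  vals <- ifelse(r$detected, r$log10_conc, -Inf)
  gmax <- tapply(vals, key, max)
  gmax <- gmax[unique(key)]
  out <- data.frame(
    inspection_id = r$inspection_id[first],
    substance_id = r$substance_id[first],
    sector = r$sector[first],
    subsector = r$subsector[first],
    detected = unname(is.finite(gmax)),
    log10_conc = unname(ifelse(is.finite(gmax), gmax, NA_real_)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Remove extreme within-substance outliers
#'
#' For each substance, z-scores are computed over its detected log10
#' concentrations using that substance's mean and sample (n-1) standard
#' deviation, and rows with |z| above `z_max` are removed. Substances with
#' fewer than three detects or zero spread are exempt (with an inclusive
#' standard deviation |z| cannot exceed `(n-1)/sqrt(n)` anyway, so tiny
#' groups can never be flagged).
#'
#' @param observations Aggregated observation table.
#' @param z_max Threshold on |z| (default 4).
#' @return List with `observations`, `dropped` and `drop_log`.
#' @export
remove_outliers <- function(observations, z_max = 4) {
  drop <- rep(FALSE, nrow(observations))
  det <- which(observations$detected)
  if (length(det)) {
    for (grp in split(det, observations$substance_id[det])) {
      if (length(grp) < 3L) next
      v <- observations$log10_conc[grp]
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) next
      z <- abs(v - mean(v)) / s
      drop[grp[z > z_max]] <- TRUE
    }
  }
  list(observations = observations[!drop, , drop = FALSE],
       dropped = observations[drop, , drop = FALSE],
       drop_log = drop_entry("outlier_removal", "z_score_above_threshold",
                             sum(drop)))
}

#' Drop subsectors with too few detects
#'
#' All rows (detects and nondetects) of a subsector are removed when the
#' subsector has fewer than `min_detects` detected observations, since its
#' intercept would be driven almost entirely by the prior.
#'
#' @param observations Aggregated observation table.
#' @param min_detects Minimum number of detects a subsector must have
#'   (default 10; a subsector with exactly `min_detects` is kept).
#' @return List with `observations`, `dropped` and `drop_log`.
#' @export
filter_sparse_subsectors <- function(observations, min_detects = 10) {
  det_counts <- table(observations$subsector[observations$detected])
  counts <- as.integer(det_counts[observations$subsector])
  counts[is.na(counts)] <- 0L
  keep <- counts >= min_detects
  list(observations = observations[keep, , drop = FALSE],
       dropped = observations[!keep, , drop = FALSE],
       drop_log = drop_entry("sparse_subsector_filter",
                             "subsector_below_min_detects", sum(!keep)))
}

#' Drop observations of substances without property rows
#'
#' Substances absent from the property table (e.g., inorganics outside the
#' QSAR domain) cannot enter the regression and all their observations are
#' removed.
#'
#' @param observations Aggregated observation table.
#' @param properties Substance-property table.
#' @return List with `observations`, `dropped` and `drop_log`.
#' @export
filter_missing_properties <- function(observations, properties) {
  keep <- observations$substance_id %in% properties$substance_id
  list(observations = observations[keep, , drop = FALSE],
       dropped = observations[!keep, , drop = FALSE],
       drop_log = drop_entry("property_filter", "no_property_row", sum(!keep)))
}

#' Split observations into train and test sets by substance
#'
#' Randomly selects `round(test_fraction * n_substances)` substances and
#' holds out all of their observations, so the test set contains property
#' combinations never seen during fitting.
#'
#' @param observations Aggregated observation table.
#' @param test_fraction Fraction of substances held out (in `[0, 1)`).
#' @param seed Integer seed.
#' @return List with `train`, `test` and `test_substances`.
#' @export
split_by_substance <- function(observations, test_fraction = 0.1, seed = 1L) {
  if (!is.numeric(test_fraction) || test_fraction < 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie in [0, 1)")
  }
  substances <- sort(unique(observations$substance_id))
  n_test <- round(test_fraction * length(substances))
  test_ids <- with_seed(seed, sample(substances, n_test))
  in_test <- observations$substance_id %in% test_ids
  list(train = observations[!in_test, , drop = FALSE],
       test = observations[in_test, , drop = FALSE],
       test_substances = sort(test_ids))
}

#' Run the full preprocessing pipeline on raw sample records
#'
#' Applies, in order: sample-type filtering, unit conversion to log10 mg/m3,
#' industry-code concordance mapping, per-(inspection, substance) worst-case
#' aggregation, within-substance outlier removal, sparse-subsector filtering
#' and (when a property table is supplied) removal of substances without
#' descriptors. Every removed row is accounted for in exactly one drop-log
#' entry; before aggregation the log counts raw samples, after it
#' inspection-level observations.
#'
#' @param records Raw sample table (see [generate_raw_samples()] for the
#'   schema).
#' @param concordance Industry-code concordance table.
#' @param properties Optional substance-property table.
#' @param z_max,min_detects Filter thresholds (defaults 4 and 10).
#' @return List with `observations` (clean observation table) and `drop_log`
#'   (data.frame of stage, reason, rows_dropped).
#' @export
preprocess_samples <- function(records, concordance, properties = NULL,
                               z_max = 4, min_detects = 10) {
  s1 <- filter_sample_types(records)
  s2 <- convert_units(s1$records)
  s3 <- map_naics(s2$records, concordance)
  obs <- aggregate_by_inspection(s3$records)
  s4 <- remove_outliers(obs, z_max = z_max)
  s5 <- filter_sparse_subsectors(s4$observations, min_detects = min_detects)
  log <- rbind(s1$drop_log, s2$drop_log, s3$drop_log,
               drop_entry("aggregation", "samples_collapsed_to_observations",
                          nrow(s3$records) - nrow(obs)),
               s4$drop_log, s5$drop_log)
  observations <- s5$observations
  if (!is.null(properties)) {
    s6 <- filter_missing_properties(observations, properties)
    observations <- s6$observations
    log <- rbind(log, s6$drop_log)
  }
  rownames(observations) <- NULL
  list(observations = observations, drop_log = log)
}
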