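# Builders for small in-code fixtures.

# Deterministic wide records: `months` as "YYYY-MM", constant heavy-chicken
# slaughter, per-cause counts given as a named list of vectors (recycled).
make_records <- function(months, slaughtered = 1000,
                         counts = list(contamination = 70),
                         turkey = 0, griller = 0) {
  mk <- parse_month(months)
  r <- tibble::tibble(
    year = mk$year, month = mk$month,
    slaughtered_turkey = rep_len(turkey, nrow(mk)),
    slaughtered_griller = rep_len(griller, nrow(mk)),
    slaughtered_heavy = rep_len(slaughtered, nrow(mk))
  )
  for (cc in names(counts)) r[[cc]] <- rep_len(counts[[cc]], nrow(mk))
  r
}

make_dataset <- function(...) condemnation_data(make_records(...))

all_months <- function(years) {
  unlist(lapply(years, function(y) sprintf("%04d-%02d", y, 1:12)))
}

# Random small COI series for oracle tests (values strictly positive).
random_series <- function(n_years = 3, months_per_year = 12) {
  months <- all_months(2000 + seq_len(n_years) - 1)
  months <- months[seq_len(n_years * months_per_year)]
  ds <- make_dataset(months, slaughtered = 1000,
                     counts = list(contamination = sample(10:500, length(months),
                                                          replace = TRUE)))
  coi_series(ds, "contamination")
}

# Brute-force ASI: explicit double loop over years then calendar months,
# independent of the grouped-pipeline implementation.
brute_asi <- function(series) {
  df <- as.data.frame(series)
  years <- sort(unique(df$year))
  ratios <- list()
  for (y in years) {
    sub <- df[df$year == y, ]
    ym <- sum(sub$value) / nrow(sub)
    for (i in seq_len(nrow(sub))) {
      ratios[[length(ratios) + 1]] <- data.frame(
        year = y, month = sub$month[i], ratio = sub$value[i] / ym)
    }
  }
  rat <- do.call(rbind, ratios)
  out <- numeric(0)
  for (m in sort(unique(rat$month))) {
    out[as.character(m)] <- mean(rat$ratio[rat$month == m])
  }
  out
}

# Brute-force rank-biserial: pair counting, ties worth half.
brute_rank_biserial <- function(x, y) {
  wins <- 0
  for (xi in x) for (yi in y) {
    wins <- wins + (xi > yi) + 0.5 * (xi == yi)
  }
  2 * wins / (length(x) * length(y)) - 1
}

# Flat single-cause simulation config for null-calibration tests.
flat_config <- function(n_months = 132, p = 0.005, heads = 1e5) {
  bl <- matrix(p, nrow = 4, ncol = 1,
               dimnames = list(c("dermatosis", "aerosacculitis", "septicemia",
                                 "ascitic_syndrome"), "heavy"))
  simulation_config(
    start = "2009-01", n_months = n_months,
    species_schedule = tibble::tibble(from = "2009-01", to = "2030-12",
                                      heavy = heads),
    cause_baselines = bl
  )
}
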