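# Fixture builders shared across test files. Everything is generated in
# code; herds travel through the CSV reader so fixtures also exercise I/O.

# A complete long-format records data.frame with n rows and sensible
# defaults; any column can be overridden via ...
toy_records <- function(n, ...) {
  rec <- data.frame(
    cow_id = sprintf("C%03d", seq_len(n)),
    farm_id = 1L,
    management = "organic",
    date_code = "D2",
    season = "spring_2012",
    breed_code = "HF",
    sire_breed = "HF",
    dam_breed = "HF",
    generation = "purebred",
    days_in_milk = 120,
    yield_l_day = 20,
    solids_kg_day = 1.5,
    scc_kcells_ml = 100,
    treatments_n = 0,
    concentrate_kg_day = 3,
    forage_kg_day = 5,
    oa_pct = 20,
    cla9_pct = 1,
    n3_pct = 1.5,
    epa_dpa_dha_pct = 0.2,
    c12_pct = 3.5,
    c14_pct = 11,
    c16_pct = 30,
    n6_pct = 1.6,
    n6_n3_ratio = 1.6 / 1.5,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  # by position: duplicated names must apply in call order (last wins)
  for (k in seq_along(over)) rec[[names(over)[k]]] <- over[[k]]
  rec
}

# Round-trip a records data.frame through the CSV reader.
as_herd <- function(records) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  read_herd_csv(path)
}

# Distinct per-record trait values so quintile membership is unambiguous:
# record i is the i-th best on every variable (i = n is the top cow).
# caller overrides in ... are applied last, after the graded defaults
graded_cohort <- function(n = 10, ...) {
  i <- seq_len(n)
  toy_records(n,
    yield_l_day = 10 + i,
    solids_kg_day = 0.5 + 0.1 * i,
    scc_kcells_ml = 500 - 10 * i,            # lower is better
    treatments_n = ifelse(i == n, 0, 1),    # only the top cow is untreated
    oa_pct = 15 + 0.5 * i,
    cla9_pct = 0.5 + 0.05 * i,
    n3_pct = 1 + 0.1 * i,
    epa_dpa_dha_pct = 0.1 + 0.01 * i,
    c12_pct = 5 - 0.1 * i,
    c14_pct = 13 - 0.2 * i,
    c16_pct = 35 - 0.5 * i,
    n6_pct = 2.5 - 0.1 * i,
    n6_n3_ratio = (2.5 - 0.1 * i) / (1 + 0.1 * i),
    ...
  )
}

# Generated default herd, cached per test run (generation is deterministic).
default_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_herd(default_config())
    cache
  }
})

# A small 5-farm configuration for fast end-to-end tests.
small_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$farm_roster <- cfg$farm_roster[1:5, ]
  cfg$farm_roster$n_cows <- rep(16L, 5)
  cfg
}
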