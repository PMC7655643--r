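#' @title Herd data model
#' @description
#' A herd dataset is a list of class `herd_dataset` holding `records` (one
#' data-frame row per cow x sampling date) and `farm_table` (one row per
#' farm). Records follow a fixed long-format schema; empty CSV cells are
#' missing values, never zeros.
#' @name herd_model
NULL

fa_columns <- function() {
  c("oa_pct", "cla9_pct", "n3_pct", "epa_dpa_dha_pct",
    "c12_pct", "c14_pct", "c16_pct", "n6_pct", "n6_n3_ratio")
}

production_columns <- function() {
  c("yield_l_day", "solids_kg_day", "scc_kcells_ml", "treatments_n")
}

#' Column schema of the herd CSV
#'
#' One row per cow per sampling date. Identity/management columns, then
#' production, health and feeding measurements, then the nine fatty-acid
#' variables (percent of total FA; the omega-6/omega-3 ratio is
#' dimensionless).
#'
#' @return character vector of required column names, in order.
#' @export
herd_columns <- function() {
  c("cow_id", "farm_id", "management", "date_code", "season", "breed_code",
    "sire_breed", "dam_breed", "generation", "days_in_milk",
    "yield_l_day", "solids_kg_day", "scc_kcells_ml", "treatments_n",
    "concentrate_kg_day", "forage_kg_day", fa_columns())
}

date_codes <- function() c("D1", "D2", "D3", "D4")

# Season labels for the four sampling dates (autumn 2011 through autumn 2012).
season_labels <- function() {
  c(D1 = "autumn_2011", D2 = "spring_2012", D3 = "summer_2012", D4 = "autumn_2012")
}

new_herd_dataset <- function(records, farm_table) {
  structure(list(records = records, farm_table = farm_table),
            class = "herd_dataset")
}

#' @export
print.herd_dataset <- function(x, ...) {
  r <- x$records
  cat("<herd_dataset> ", nrow(r), " records, ",
      length(unique(r$cow_id)), " cows, ",
      nrow(x$farm_table), " farms\n", sep = "")
  tab <- table(r$date_code)
  cat("  records per date: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Validate records against the model invariants. Stops with a row-numbered
# message on the first violation.
validate_herd_records <- function(records) {
  nonneg <- c("days_in_milk", production_columns(),
              "concentrate_kg_day", "forage_kg_day", fa_columns())
  for (col in intersect(nonneg, names(records))) {
    bad <- which(!is.na(records[[col]]) & records[[col]] < 0)
    if (length(bad))
      stop("negative value in column '", col, "' at row ", bad[1], call. = FALSE)
  }
  key <- paste(records$cow_id, records$date_code, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cow_id, date_code): ",
         sub("\r", " / ", key[anyDuplicated(key)]), call. = FALSE)
  if (!all(records$date_code %in% date_codes()))
    stop("date_code outside D1-D4 at row ",
         which(!records$date_code %in% date_codes())[1], call. = FALSE)
  both <- !is.na(records$yield_l_day) & !is.na(records$solids_kg_day)
  viol <- which(both & records$solids_kg_day > records$yield_l_day)
  if (length(viol))
    stop("solids_kg_day exceeds yield_l_day (fat+protein mass cannot exceed ",
         "milk mass) at row ", viol[1], call. = FALSE)
  sub <- !is.na(records$epa_dpa_dha_pct) & !is.na(records$n3_pct)
  viol <- which(sub & records$epa_dpa_dha_pct > records$n3_pct + 1e-9)
  if (length(viol))
    stop("epa_dpa_dha_pct exceeds n3_pct at row ", viol[1], call. = FALSE)
  invisible(records)
}

#' Read a herd CSV (and optional farm roster) into a herd dataset
#'
#' @param path herd CSV path; header must contain every [herd_columns()]
#'   column. Empty cells become `NA`.
#' @param farm_path optional farm roster CSV (`farm_id`, `management`,
#'   `n_cows`, `calving_pattern`, `breeds` with semicolon-separated tokens).
#'   When omitted, a minimal farm table is derived from the records.
#' @return a `herd_dataset`.
#' @export
read_herd_csv <- function(path, farm_path = NULL) {
  if (!file.exists(path)) stop("herd CSV not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
  missing_cols <- setdiff(herd_columns(), names(records))
  if (length(missing_cols))
    stop("herd CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[, herd_columns()]
  records$cow_id <- as.character(records$cow_id)
  num <- setdiff(herd_columns(),
                 c("cow_id", "management", "date_code", "season", "breed_code",
                   "sire_breed", "dam_breed", "generation"))
  for (col in num) records[[col]] <- as.numeric(records[[col]])
  validate_herd_records(records)
  if (!is.null(farm_path)) {
    farm_table <- utils::read.csv(farm_path, stringsAsFactors = FALSE,
                                  na.strings = c("", "NA"))
  } else {
    farm_table <- unique(records[, c("farm_id", "management")])
    farm_table$n_cows <- vapply(farm_table$farm_id, function(f)
      length(unique(records$cow_id[records$farm_id == f])), integer(1))
    farm_table$calving_pattern <- NA_character_
    farm_table$breeds <- vapply(farm_table$farm_id, function(f)
      paste(sort(unique(records$breed_code[records$farm_id == f])),
            collapse = ";"), character(1))
  }
  farm_table <- farm_table[order(farm_table$farm_id), , drop = FALSE]
  rownames(farm_table) <- NULL
  if (!all(records$farm_id %in% farm_table$farm_id))
    stop("record farm_id absent from farm table", call. = FALSE)
  new_herd_dataset(records, farm_table)
}

#' Write a herd dataset to CSV
#'
#' Inverse of [read_herd_csv()]: missing values become empty cells and
#' numeric values are written with enough digits to round-trip to at least
#' six significant figures.
#'
#' @param dataset a `herd_dataset`.
#' @param path herd CSV output path.
#' @param farm_path optional path for the farm roster CSV.
#' @return `path`, invisibly.
#' @export
write_herd_csv <- function(dataset, path, farm_path = NULL) {
  stopifnot(inherits(dataset, "herd_dataset"))
  rec <- dataset$records[, herd_columns()]
  old <- options(digits = 15); on.exit(options(old))
  utils::write.csv(rec, path, row.names = FALSE, na = "")
  if (!is.null(farm_path))
    utils::write.csv(dataset$farm_table, farm_path, row.names = FALSE, na = "")
  invisible(path)
}

is_complete_record <- function(records) {
  need <- c(production_columns(), fa_columns())
  stats::complete.cases(records[, need])
}

#' Keep only complete records for one sampling date
#'
#' A record is complete when yield, solids, somatic cell count, the treatment
#' count and the full nine-variable fatty-acid profile are all present —
#' the cohort eligible for scoring and ordination on that date.
#'
#' @param dataset a `herd_dataset`.
#' @param date one of `"D1"`..`"D4"`.
#' @return a `herd_dataset` with only that date's complete records (may be
#'   empty).
#' @export
filter_complete_records <- function(dataset, date) {
  stopifnot(inherits(dataset, "herd_dataset"))
  date <- match.arg(date, date_codes())
  rec <- dataset$records
  keep <- rec$date_code == date & is_complete_record(rec)
  new_herd_dataset(rec[keep, , drop = FALSE], dataset$farm_table)
}

# Complete records across all dates (the pooled scoring cohort).
all_complete_records <- function(dataset) {
  rec <- dataset$records
  rec[is_complete_record(rec), , drop = FALSE]
}

#' Apply the breed-group inclusion criteria
#'
#' A breed group enters the comparative analysis iff, on at least one
#' sampling date, it has complete records for at least `min_cows` distinct
#' cows drawn from at least `min_farms` distinct farms. Cows are counted once
#' per group per date, not once per record.
#'
#' @param dataset a `herd_dataset` (records must carry canonical breed
#'   group labels in `breed_code`).
#' @param min_cows,min_farms inclusion thresholds (defaults 6 and 3).
#' @return list with `groups` (sorted retained labels) and `dataset` (the
#'   input restricted to retained groups' records).
#' @export
apply_inclusion_criteria <- function(dataset, min_cows = 6, min_farms = 3) {
  stopifnot(inherits(dataset, "herd_dataset"))
  rec <- dataset$records
  comp <- rec[is_complete_record(rec), c("breed_code", "date_code", "cow_id", "farm_id")]
  retained <- character(0)
  for (g in unique(comp$breed_code)) {
    sub <- comp[comp$breed_code == g, ]
    ok <- vapply(unique(sub$date_code), function(d) {
      dd <- sub[sub$date_code == d, ]
      length(unique(dd$cow_id)) >= min_cows &&
        length(unique(dd$farm_id)) >= min_farms
    }, logical(1))
    if (any(ok)) retained <- c(retained, g)
  }
  retained <- sort(retained)
  keep <- dataset$records$breed_code %in% retained
  list(groups = retained,
       dataset = new_herd_dataset(dataset$records[keep, , drop = FALSE],
                                  dataset$farm_table))
}
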