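#' @title Low-input-production (LI-P) scoring
#' @description
#' Each complete cow-record is scored on thirteen variables. Production
#' (milk yield, fat+protein solids) and the nine fatty-acid variables are
#' allocated to quintile groups of (near-)equal observations scored 1-5;
#' desirable variables score 5 in the top group, undesirable ones 5 in the
#' bottom group. Somatic cell count scores 5 in the lowest quintile, and an
#' untreated indicator adds 1 for cows with no health treatments since the
#' previous sampling date. Component totals are production out of 10, health
#' out of 6 and fatty acids out of 45; two convex weightings collapse them to
#' a single score with maximum 1.
#' @name lip_score
NULL

# fatty-acid scoring directions
fa_desirable <- function() c("oa_pct", "cla9_pct", "n3_pct", "epa_dpa_dha_pct")
fa_undesirable <- function() c("c12_pct", "c14_pct", "c16_pct", "n6_pct", "n6_n3_ratio")

#' Quintile scores for one variable
#'
#' Records are sorted ascending (ties broken by the stable `keys`), the
#' ordinal rank `r` in `0..n-1` maps to group `floor(5 r / n) + 1`, so group
#' sizes differ by at most one. Desirable variables score the group number;
#' undesirable variables score `6 - group`.
#'
#' @param values numeric vector, no missing values, length >= 5.
#' @param direction `"desirable"` (high is good) or `"undesirable"`.
#' @param keys stable tie-break keys (defaults to input order).
#' @return integer scores in 1..5, aligned with `values`.
#' @examples
#' quintile_scores(c(3, 1, 4, 1, 5, 9, 2), "desirable")  # 3 1 3 1 4 5 2
#' @export
quintile_scores <- function(values, direction = c("desirable", "undesirable"),
                            keys = seq_along(values)) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < 5)
    stop("quintile allocation needs at least 5 records (got ", n, ")",
         call. = FALSE)
  if (anyNA(values))
    stop("quintile allocation requires complete values; filter upstream",
         call. = FALSE)
  stopifnot(length(keys) == n)
  ord <- order(values, keys)
  g <- as.integer(floor(5 * (seq_len(n) - 1) / n) + 1)
  scores <- integer(n)
  scores[ord] <- g
  if (direction == "undesirable") scores <- 6L - scores
  scores
}

#' Untreated indicator
#'
#' 1 if the cow received no antibiotic or alternative treatment since the
#' previous sampling date, 0 otherwise.
#'
#' @param treatments_n non-negative treatment count(s).
#' @return integer 0/1 vector.
#' @export
untreated_indicator <- function(treatments_n) {
  if (any(is.na(treatments_n)) || any(treatments_n < 0))
    stop("treatments_n must be non-negative and non-missing", call. = FALSE)
  as.integer(treatments_n == 0)
}

#' Per-record score components for a complete cohort
#'
#' @param cohort data frame of complete records (see
#'   [filter_complete_records()]); must contain `cow_id`, `date_code`,
#'   yield, solids, SCC, treatments and the nine fatty-acid variables.
#' @param scope `"pooled"` allocates quintiles over the whole cohort (one
#'   scheme per variable); `"per_date"` allocates within each sampling date.
#' @return `cohort` with appended columns: per-variable quintiles
#'   (`yield_q`, `solids_q`, `scc_q`, `<fa>_q`), `untreated_flag`,
#'   `production_score` (2-10), `health_score` (1-6), `fa_score` (9-45),
#'   `weighted_health` and `weighted_production` (both in (0, 1]).
#' @export
component_scores <- function(cohort, scope = c("pooled", "per_date")) {
  scope <- match.arg(scope)
  need <- c("cow_id", "date_code", production_columns(), fa_columns())
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!stats::complete.cases(cohort[, c(production_columns(), fa_columns())])))
    stop("cohort contains incomplete records; apply filter_complete_records ",
         "first", call. = FALSE)

  key <- paste(cohort$cow_id, cohort$date_code, sep = "|")
  score_var <- function(values, direction) {
    if (scope == "pooled") {
      quintile_scores(values, direction, keys = key)
    } else {
      out <- integer(length(values))
      for (d in unique(cohort$date_code)) {
        idx <- cohort$date_code == d
        out[idx] <- quintile_scores(values[idx], direction, keys = key[idx])
      }
      out
    }
  }

  out <- cohort
  out$yield_q <- score_var(cohort$yield_l_day, "desirable")
  out$solids_q <- score_var(cohort$solids_kg_day, "desirable")
  out$scc_q <- score_var(cohort$scc_kcells_ml, "undesirable")
  out$untreated_flag <- untreated_indicator(cohort$treatments_n)
  for (v in fa_desirable())
    out[[paste0(v, "_q")]] <- score_var(cohort[[v]], "desirable")
  for (v in fa_undesirable())
    out[[paste0(v, "_q")]] <- score_var(cohort[[v]], "undesirable")

  out$production_score <- out$yield_q + out$solids_q
  out$health_score <- out$scc_q + out$untreated_flag
  out$fa_score <- Reduce(`+`, lapply(paste0(c(fa_desirable(), fa_undesirable()),
                                            "_q"), function(c) out[[c]]))
  w <- weighted_composites(out$production_score, out$health_score, out$fa_score)
  out$weighted_health <- w$weighted_health
  out$weighted_production <- w$weighted_production
  out
}

#' Weighted composite scores
#'
#' Collapses the three components to a single score out of 1 under two
#' weightings: the health-emphasis composite
#' `0.3 (production/10) + 0.5 (health/6) + 0.2 (FA/45)` and the
#' production-emphasis composite
#' `0.6 (production/10) + 0.3 (health/6) + 0.1 (FA/45)`.
#'
#' @param production production component, 2-10.
#' @param health health component, 1-6.
#' @param fa fatty-acid component, 9-45.
#' @return list with numeric vectors `weighted_health` and
#'   `weighted_production`.
#' @export
weighted_composites <- function(production, health, fa) {
  if (any(production < 2 | production > 10))
    stop("production component out of bounds [2, 10]", call. = FALSE)
  if (any(health < 1 | health > 6))
    stop("health component out of bounds [1, 6]", call. = FALSE)
  if (any(fa < 9 | fa > 45))
    stop("fatty-acid component out of bounds [9, 45]", call. = FALSE)
  list(
    weighted_health = 0.3 * production / 10 + 0.5 * health / 6 + 0.2 * fa / 45,
    weighted_production = 0.6 * production / 10 + 0.3 * health / 6 + 0.1 * fa / 45
  )
}

#' Rank breed groups on a composite score
#'
#' Breeds are ordered by mean composite rounded to two decimals (the
#' reporting precision), descending. Among equal rounded means the lower
#' standard deviation ranks first; any remaining ties break alphabetically.
#'
#' @param breed character vector of breed-group labels, one per record.
#' @param score numeric composite per record.
#' @return data frame with `breed`, `n`, `mean`, `sd`, `rank` (1 = best),
#'   ordered by rank.
#' @export
rank_breeds <- function(breed, score) {
  stopifnot(length(breed) == length(score))
  if (!length(breed)) stop("no records to rank", call. = FALSE)
  if (anyNA(score)) stop("composite scores must be complete", call. = FALSE)
  groups <- sort(unique(breed))
  n <- vapply(groups, function(g) sum(breed == g), integer(1))
  if (any(n < 2))
    stop("each breed group needs >= 2 records to rank (violated by ",
         paste(groups[n < 2], collapse = ", "), ")", call. = FALSE)
  m <- vapply(groups, function(g) mean(score[breed == g]), numeric(1))
  s <- vapply(groups, function(g) stats::sd(score[breed == g]), numeric(1))
  ord <- order(-round(m, 2), s, groups)
  rank <- integer(length(groups))
  rank[ord] <- seq_along(groups)
  out <- data.frame(breed = groups, n = n, mean = m, sd = s, rank = rank,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$rank), ]
}

#' Score a herd dataset
#'
#' Convenience wrapper: keeps complete records (all dates), computes
#' component and composite scores, and optionally summarises per-breed
#' rankings under both weightings.
#'
#' @param dataset a `herd_dataset`.
#' @param scope quintile population scope, `"pooled"` (default) or
#'   `"per_date"`.
#' @return list with `scores` (per-record data frame) and `rankings`
#'   (list of two [rank_breeds()] tables: `weighted_health`,
#'   `weighted_production`).
#' @export
score_herd <- function(dataset, scope = c("pooled", "per_date")) {
  stopifnot(inherits(dataset, "herd_dataset"))
  scope <- match.arg(scope)
  cohort <- all_complete_records(dataset)
  if (!nrow(cohort))
    stop("no complete records to score (empty cohort)", call. = FALSE)
  scores <- component_scores(cohort, scope)
  list(
    scores = scores,
    rankings = list(
      weighted_health = rank_breeds(scores$breed_code, scores$weighted_health),
      weighted_production = rank_breeds(scores$breed_code,
                                        scores$weighted_production))
  )
}
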