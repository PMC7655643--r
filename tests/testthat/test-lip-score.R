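# independent quintile oracle: split n sorted positions into five contiguous
# groups whose sizes come from the cut points ceil(k*n/5), then assign by
# walking the sorted order
oracle_quintiles <- function(values, keys = seq_along(values)) {
  n <- length(values)
  sizes <- diff(ceiling((0:5) * n / 5))
  groups <- rep(1:5, times = sizes)
  out <- integer(n)
  out[order(values, keys)] <- groups
  out
}

test_that("quintile allocation matches the rank rule and its oracle", {
  expect_identical(quintile_scores(1:5, "desirable"), 1:5)
  expect_identical(quintile_scores(1:5, "undesirable"), 5:1)
  expect_identical(quintile_scores(c(3, 1, 4, 1, 5, 9, 2), "desirable"),
                   c(3L, 1L, 3L, 1L, 4L, 5L, 2L))

  set.seed(20)
  for (n in 5:12) {
    for (rep in 1:20) {
      v <- sample(round(rnorm(n, 50, 20), 1))   # duplicates likely
      expect_identical(quintile_scores(v, "desirable"), oracle_quintiles(v))
    }
  }
  expect_error(quintile_scores(1:4, "desirable"), "at least 5")
  expect_error(quintile_scores(c(1, NA, 3, 4, 5), "desirable"), "complete")
})

test_that("quintile group sizes differ by at most one", {
  set.seed(21)
  for (n in c(5, 7, 23, 50, 101, 299)) {
    sc <- quintile_scores(rnorm(n), "desirable")
    expect_lte(diff(range(table(sc))), 1)
    expect_identical(sort(unique(sc)), 1:5)
  }
})

test_that("undesirable scoring is the mirror of desirable scoring", {
  set.seed(22)
  for (rep in 1:10) {
    v <- rnorm(40)
    expect_identical(quintile_scores(v, "undesirable"),
                     6L - quintile_scores(v, "desirable"))
  }
})

test_that("quintiles are invariant to strictly increasing transforms", {
  set.seed(23)
  v <- rexp(60) + 0.1
  base <- quintile_scores(v, "desirable")
  expect_identical(quintile_scores(3 * v + 7, "desirable"), base)
  expect_identical(quintile_scores(log(v), "desirable"), base)
})

test_that("untreated indicator is 1 only for zero treatments", {
  expect_identical(untreated_indicator(0), 1L)
  expect_identical(untreated_indicator(1), 0L)
  expect_identical(untreated_indicator(7), 0L)
  expect_error(untreated_indicator(-1), "non-negative")
})

test_that("component scores reach their published maxima for the best cow", {
  sc <- component_scores(graded_cohort(10))
  top <- which(sc$cow_id == "C010")
  expect_identical(sc$production_score[top], 10L)
  expect_identical(sc$health_score[top], 6L)
  expect_identical(sc$fa_score[top], 45L)
  expect_equal(sc$weighted_health[top], 1)
  expect_equal(sc$weighted_production[top], 1)
})

test_that("a middle-quintile record on all nine FA variables scores 27", {
  sc <- component_scores(graded_cohort(5))
  mid <- which(sc$cow_id == "C003")
  expect_identical(sc$fa_score[mid], 27L)
})

test_that("weighted composites follow the 30/50/20 and 60/30/10 formulas", {
  w <- weighted_composites(10, 6, 45)
  expect_equal(w$weighted_health, 1)
  expect_equal(w$weighted_production, 1)
  w <- weighted_composites(2, 1, 9)
  expect_equal(w$weighted_health, 0.3 * 0.2 + 0.5 / 6 + 0.2 * 0.2)
  expect_equal(w$weighted_production, 0.19)
  w <- weighted_composites(6, 4, 27)
  expect_equal(w$weighted_health, 0.3 * 0.6 + 0.5 * 4 / 6 + 0.2 * 0.6)
  expect_equal(w$weighted_production, 0.62)
  expect_error(weighted_composites(11, 6, 45), "production")
  expect_error(weighted_composites(10, 0, 45), "health")
})

test_that("composites stay inside their attainable bounds on random cohorts", {
  set.seed(24)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    cohort <- graded_cohort(n)
    perm <- sample(n)
    cohort$yield_l_day <- cohort$yield_l_day[perm]
    cohort$scc_kcells_ml <- sample(cohort$scc_kcells_ml)
    cohort$treatments_n <- rpois(n, 0.4)
    sc <- component_scores(cohort)
    lo_h <- 0.3 * 0.2 + 0.5 * 1 / 6 + 0.2 * 0.2
    lo_p <- 0.6 * 0.2 + 0.3 * 1 / 6 + 0.1 * 0.2
    expect_true(all(sc$weighted_health >= lo_h - 1e-12 &
                      sc$weighted_health <= 1 + 1e-12))
    expect_true(all(sc$weighted_production >= lo_p - 1e-12 &
                      sc$weighted_production <= 1 + 1e-12))
  }
})

test_that("raising one cow's yield never lowers its production score", {
  set.seed(25)
  cohort <- graded_cohort(20)
  cohort$yield_l_day <- sample(cohort$yield_l_day)
  base <- component_scores(cohort)
  for (bump in c(0.5, 3, 10)) {
    up <- cohort
    up$yield_l_day[7] <- up$yield_l_day[7] + bump
    sc <- component_scores(up)
    expect_gte(sc$production_score[7], base$production_score[7])
  }
})

test_that("pooled and per-date scopes allocate quintiles differently", {
  cohort <- rbind(graded_cohort(10),
                  graded_cohort(10, date_code = "D3", cow_id = sprintf("X%02d", 1:10),
                                yield_l_day = 100 + 1:10))
  pooled <- component_scores(cohort, scope = "pooled")
  per_date <- component_scores(cohort, scope = "per_date")
  # pooled: every D3 yield beats every D2 yield, so quintiles separate
  expect_lte(max(pooled$yield_q[pooled$date_code == "D2"]),
             min(pooled$yield_q[pooled$date_code == "D3"]))
  expect_lt(max(pooled$yield_q[pooled$date_code == "D2"]), 5)
  # per-date: each date uses its own quintile scheme, so both dates span 1..5
  expect_identical(sort(unique(per_date$yield_q[per_date$date_code == "D3"])), 1:5)
})

test_that("breed ranking uses rounded means with the SD tie-break", {
  # equal rounded means: lower SD wins
  set.seed(26)
  a <- c(0.60 + 0.136 * scale(rnorm(50))[, 1])
  b <- c(0.60 + 0.167 * scale(rnorm(50))[, 1])
  r <- rank_breeds(rep(c("NZFX", "AYRX"), each = 50), c(a, b))
  expect_identical(r$breed[r$rank == 1], "NZFX")
  expect_identical(r$breed[r$rank == 2], "AYRX")

  r1 <- rank_breeds(rep("ONLY", 3), c(0.5, 0.6, 0.7))
  expect_identical(r1$rank, 1L)

  r3 <- rank_breeds(rep(c("A", "B", "C"), each = 2),
                    c(0.61, 0.61, 0.50, 0.50, 0.59, 0.59))
  expect_identical(r3$rank[match(c("A", "B", "C"), r3$breed)], c(1L, 3L, 2L))

  expect_error(rank_breeds(c("A", "A", "B"), c(1, 2, 3)), ">= 2 records")
})
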