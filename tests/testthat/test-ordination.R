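test_that("standardization gives zero mean and unit sample SD", {
  z <- standardize(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  # idempotent on already-standardized data
  expect_equal(standardize(z), z, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("a single varying direction gives PC1 variance fraction 1", {
  x <- standardize(cbind(v1 = 1:10, v2 = 2 * (1:10) + 5))
  res <- pca_ordination(x)
  expect_equal(res$variance_fraction[1], 1)
})

test_that("two variables with correlation 0.8 give PC1 fraction 0.9", {
  set.seed(30)
  n <- 200
  x <- scale(rnorm(n))[, 1]
  e <- residuals(lm(rnorm(n) ~ x))
  y <- 0.8 * x + sqrt(1 - 0.8^2) * scale(e)[, 1]
  m <- standardize(cbind(x = x, y = y))
  expect_equal(cor(m)[1, 2], 0.8, tolerance = 1e-10)
  res <- pca_ordination(m)
  expect_equal(res$variance_fraction[1], 0.9, tolerance = 1e-10)
})

test_that("PCA agrees with an eigendecomposition oracle to 1e-10", {
  set.seed(31)
  x <- standardize(matrix(rnorm(50 * 13), 50, 13,
                          dimnames = list(NULL, paste0("v", 1:13))))
  res <- pca_ordination(x)
  ev <- eigen(cor(x), symmetric = TRUE)$values
  expect_equal(res$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(res$variance_fraction, ev / sum(ev), tolerance = 1e-10)
  # eigenvalue sum equals the trace of the correlation matrix
  expect_equal(sum(res$eigenvalues), 13, tolerance = 1e-8)
  # loadings orthonormal; largest-magnitude entry of each vector positive
  expect_equal(crossprod(res$loadings), diag(13), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:13)
    expect_gt(res$loadings[which.max(abs(res$loadings[, j])), j], 0)
  # scores: zero mean, variance along component i equals lambda_i
  expect_equal(colMeans(res$scores), rep(0, 13), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(apply(res$scores, 2, var), ev, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA variance fractions match vegan's unconstrained ordination", {
  skip_if_not_installed("vegan")
  set.seed(32)
  x <- standardize(matrix(rnorm(40 * 6), 40, 6,
                          dimnames = list(NULL, paste0("v", 1:6))))
  res <- pca_ordination(x)
  rda <- vegan::rda(x)
  expect_equal(res$variance_fraction,
               unname(rda$CA$eig / sum(rda$CA$eig)), tolerance = 1e-8)
})

test_that("record order does not affect scores", {
  set.seed(33)
  x <- standardize(matrix(rnorm(30 * 5), 30, 5,
                          dimnames = list(NULL, paste0("v", 1:5))))
  res <- pca_ordination(x)
  perm <- sample(30)
  res_p <- pca_ordination(x[perm, ])
  expect_equal(res_p$scores, res$scores[perm, ], tolerance = 1e-10)
  expect_error(pca_ordination(x[1:2, ]), "at least 3")
})

test_that("the ordination report covers all four dates and writes figures", {
  herd <- apply_inclusion_criteria(default_herd())$dataset
  outdir <- tempfile("figs_")
  rep4 <- ordination_report(herd, outdir = outdir)
  expect_identical(names(rep4$results), c("D1", "D2", "D3", "D4"))
  expect_identical(nrow(rep4$variance), 4L)
  expect_true(all(rep4$variance$PC1_frac >= rep4$variance$PC2_frac))
  expect_true(file.exists(file.path(outdir, "variance.tsv")))
  expect_true(file.exists(file.path(outdir, "scores_D1.pdf")))
  expect_true(file.exists(file.path(outdir, "loadings_D4.pdf")))
  unlink(outdir, recursive = TRUE)

  # a date with too few complete records is skipped with a warning
  few <- toy_records(8, date_code = rep(c("D1", "D2"), c(2, 6)),
                     yield_l_day = rnorm(8, 20),
                     scc_kcells_ml = rexp(8, 1 / 100),
                     oa_pct = rnorm(8, 20), c16_pct = rnorm(8, 30),
                     c14_pct = rnorm(8, 11), c12_pct = rnorm(8, 3.5),
                     n6_pct = rnorm(8, 1.6, 0.2), n3_pct = rnorm(8, 1.5, 0.2),
                     cla9_pct = rnorm(8, 1, 0.2),
                     epa_dpa_dha_pct = rnorm(8, 0.2, 0.03),
                     solids_kg_day = rnorm(8, 1.5, 0.2),
                     treatments_n = rpois(8, 1))
  few$n6_n3_ratio <- few$n6_pct / few$n3_pct
  warns <- capture_warnings(res <- ordination_report(as_herd(few)))
  expect_true(any(grepl("D1", warns)))      # D1, D3, D4 all under-populated
  expect_identical(names(res$results), "D2")
})

test_that("strong farm effects cluster records by farm in PC space", {
  cfg <- small_config(seed = 41L)
  cfg$missingness[] <- 0
  boost <- c("yield_l_day", "solids_kg_day", "oa_pct", "c16_pct", "n3_pct")
  cfg$variance_components$farm_sd <-
    ifelse(cfg$variance_components$trait %in% boost,
           5 * cfg$variance_components$farm_sd,
           cfg$variance_components$farm_sd)
  herd <- generate_herd(cfg)
  res <- ordination_report(herd)$results$D2
  xy <- res$scores[, 1:2]
  farm <- res$ids$farm_id
  centroid <- apply(xy, 2, function(c) tapply(c, farm, mean))
  within <- mean(sqrt(rowSums((xy - centroid[as.character(farm), ])^2)))
  grand <- colMeans(xy)
  between <- mean(sqrt(colSums((t(centroid) - grand)^2)))
  expect_lt(within / between, 3)   # farm centroids are separated
  # and farm explains a sizable share of PC1
  expect_gt(summary(lm(xy[, 1] ~ factor(farm)))$r.squared, 0.3)
})

test_that("correlated FA blocks produce opposed loadings", {
  cfg <- small_config(seed = 42L)
  cfg$missingness[] <- 0
  tr <- c("n3_pct", "epa_dpa_dha_pct", "c12_pct", "c14_pct", "c16_pct")
  R <- matrix(-0.4, 5, 5)
  R[1:2, 1:2] <- 0.6
  R[3:5, 3:5] <- 0.6
  diag(R) <- 1
  expect_true(all(eigen(R, only.values = TRUE)$values > 0))
  cfg$correlation_spec <- list(traits = tr, R = R)
  herd <- generate_herd(cfg)
  res <- ordination_report(herd)$results$D2
  ld <- res$loadings[, 1]
  names(ld) <- res$variables
  expect_gt(ld["n3_pct"] * ld["epa_dpa_dha_pct"], 0)
  expect_gt(ld["c12_pct"] * ld["c14_pct"], 0)
  expect_lt(ld["n3_pct"] * ld["c16_pct"], 0)
})
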