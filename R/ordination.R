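#' @title Standardized PCA ordination
#' @description
#' Per-date principal components analysis of the thirteen LI-P variables
#' (yield, solids, SCC, treatments and nine fatty-acid variables). Because
#' the variables carry different units, each is standardized to mean zero
#' and unit sample SD, so the PCA operates on the correlation matrix. Record
#' scores visualise farm-to-farm structure; loadings show which traits
#' co-occur.
#' @name ordination
NULL

ordination_variables <- function() {
  c(production_columns(), fa_columns())
}

#' Standardize a records-by-variables matrix
#'
#' Centers each column to mean zero and scales it to unit sample standard
#' deviation (n-1 denominator).
#'
#' @param x numeric matrix or data frame; every column needs at least two
#'   distinct values.
#' @return standardized numeric matrix.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("standardize() needs a numeric matrix", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  bad <- which(!is.finite(sds) | sds == 0)
  if (length(bad))
    stop("cannot standardize constant/degenerate column(s): ",
         paste(colnames(x)[bad] %||% bad, collapse = ", "), call. = FALSE)
  scale(x, center = TRUE, scale = sds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal components of standardized data
#'
#' Components are the eigenvectors of the correlation matrix, ordered by
#' decreasing eigenvalue; the variance fraction of component i is
#' `lambda_i / sum(lambda)`. Signs are fixed deterministically by making the
#' largest-magnitude entry of each loading vector positive.
#'
#' @param x standardized records-by-variables matrix (>= 3 records).
#' @param date_code optional sampling-date label carried into the result.
#' @param ids optional data frame of record identifiers (e.g. cow_id,
#'   farm_id) bound to the scores.
#' @return object of class `ordination_result`: list with `date_code`,
#'   `variables`, `loadings` (variables x components, orthonormal columns),
#'   `scores` (records x components), `eigenvalues`, `variance_fraction`.
#' @export
pca_ordination <- function(x, date_code = NA_character_, ids = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 3)
    stop("PCA needs at least 3 records (got ", nrow(x), ")", call. = FALSE)
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  load <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev^2
  res <- list(date_code = date_code,
              variables = colnames(x),
              loadings = load,
              scores = scores,
              ids = ids,
              eigenvalues = ev,
              variance_fraction = ev / sum(ev))
  class(res) <- "ordination_result"
  res
}

#' @export
print.ordination_result <- function(x, ...) {
  vf <- round(100 * x$variance_fraction[1:min(2, length(x$variance_fraction))])
  cat("<ordination_result> ", if (!is.na(x$date_code)) paste0(x$date_code, ": "),
      nrow(x$scores), " records x ", length(x$variables), " variables; ",
      "PC1 ", vf[1], "%", if (length(vf) > 1) paste0(", PC2 ", vf[2], "%"),
      "\n", sep = "")
  invisible(x)
}

#' Per-date ordination report
#'
#' For each sampling date with at least three complete records: standardizes
#' the thirteen LI-P variables, runs the PCA, and (optionally) writes a
#' record-score scatter coloured by farm plus a variable-loading plot.
#' Dates with fewer than three complete records are skipped with a warning.
#'
#' @param dataset a `herd_dataset`.
#' @param outdir optional directory for plots (`scores_<date>.pdf`,
#'   `loadings_<date>.pdf`) and a `variance.tsv` table.
#' @param treatments `"count"` enters raw treatment counts into the PCA;
#'   `"binary"` uses the untreated indicator instead.
#' @return list with `results` (named list of `ordination_result` per date)
#'   and `variance` (data frame: date, PC1_frac, PC2_frac).
#' @export
ordination_report <- function(dataset, outdir = NULL,
                              treatments = c("count", "binary")) {
  stopifnot(inherits(dataset, "herd_dataset"))
  treatments <- match.arg(treatments)
  results <- list()
  for (d in date_codes()) {
    sub <- filter_complete_records(dataset, d)$records
    if (nrow(sub) < 3) {
      warning("date ", d, " has fewer than 3 complete records; skipped",
              call. = FALSE)
      next
    }
    m <- sub[, ordination_variables()]
    if (treatments == "binary")
      m$treatments_n <- as.numeric(untreated_indicator(sub$treatments_n))
    z <- standardize(m)
    results[[d]] <- pca_ordination(
      z, date_code = d,
      ids = sub[, c("cow_id", "farm_id", "breed_code")])
  }
  variance <- data.frame(
    date = names(results),
    PC1_frac = vapply(results, function(r) r$variance_fraction[1], numeric(1)),
    PC2_frac = vapply(results, function(r) r$variance_fraction[2], numeric(1)),
    row.names = NULL)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (d in names(results)) plot_ordination(results[[d]], outdir)
    utils::write.table(variance, file.path(outdir, "variance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(results = results, variance = variance)
}

# Write the two figure families for one date: record scores coloured by farm
# and variable loadings, on the PC1/PC2 plane.
plot_ordination <- function(res, outdir) {
  vf <- round(100 * res$variance_fraction[1:2])
  labs_xy <- ggplot2::labs(
    x = sprintf("PC1 (%d%%)", vf[1]), y = sprintf("PC2 (%d%%)", vf[2]),
    title = sprintf("LI-P ordination, %s", res$date_code))
  sc <- data.frame(PC1 = res$scores[, 1], PC2 = res$scores[, 2],
                   farm = factor(res$ids$farm_id))
  p1 <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                         colour = .data$farm)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    labs_xy + ggplot2::theme_minimal() +
    ggplot2::guides(colour = ggplot2::guide_legend(title = "Farm ID", ncol = 2))
  ld <- data.frame(variable = res$variables,
                   PC1 = res$loadings[, 1], PC2 = res$loadings[, 2])
  p2 <- ggplot2::ggplot(ld, ggplot2::aes(.data$PC1, .data$PC2,
                                         label = .data$variable)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                       yend = .data$PC2),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "grey40") +
    ggplot2::geom_text(size = 3, vjust = -0.4) +
    labs_xy + ggplot2::theme_minimal()
  for (spec in list(list(p = p1, f = "scores"), list(p = p2, f = "loadings"))) {
    path <- file.path(outdir, sprintf("%s_%s.pdf", spec$f, res$date_code))
    grDevices::pdf(path, width = 7, height = 5)
    print(spec$p)
    grDevices::dev.off()
  }
  invisible(res)
}
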