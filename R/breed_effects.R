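#' @title Breed comparison
#' @description
#' Descriptive per-breed summaries (mean, SD and median per variable) and a
#' restricted-maximum-likelihood linear mixed model comparing breeds with
#' farm and season as crossed random intercepts. Only the omnibus breed test
#' is reported: with eight groups, post-hoc pairwise testing would inflate
#' the family-wise false-positive rate, so none is performed.
#' @name breed_effects
NULL

summary_variables <- function() {
  c("days_in_milk", "concentrate_kg_day", "forage_kg_day",
    production_columns(), fa_columns())
}

#' Per-breed descriptive summaries
#'
#' Mean, SD and median of every LI-P and feeding variable for each breed
#' group, computed over complete records. Somatic cell counts are heavily
#' right-skewed, which is why the median is carried alongside the mean.
#'
#' @param dataset a `herd_dataset` (typically after
#'   [apply_inclusion_criteria()]).
#' @param variables variables to summarise (default [summary_variables()]).
#' @return data frame with columns `breed`, `n`, `variable`, `mean`, `sd`,
#'   `median`.
#' @export
summarize_breeds <- function(dataset, variables = summary_variables()) {
  stopifnot(inherits(dataset, "herd_dataset"))
  rec <- all_complete_records(dataset)
  out <- list()
  for (g in sort(unique(rec$breed_code))) {
    sub <- rec[rec$breed_code == g, ]
    for (v in variables) {
      vals <- sub[[v]][!is.na(sub[[v]])]
      out[[length(out) + 1L]] <- data.frame(
        breed = g, n = nrow(sub), variable = v,
        mean = mean(vals), sd = stats::sd(vals), median = stats::median(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Significance label for a p-value
#'
#' The conventional star map: `***` for p < 0.001, `**` for p < 0.01, `*`
#' for p < 0.05, `t` (tendency) for p < 0.1, `ns` otherwise.
#'
#' @param p probability in `[0, 1]`.
#' @return character label.
#' @export
star_label <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]", call. = FALSE)
  vapply(p, function(pi) {
    if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else if (pi < 0.1) "t"
    else "ns"
  }, character(1))
}

#' Mixed-model breed comparison for one response
#'
#' Fits `response ~ breed + (1 | farm) + (1 | season)` by REML over complete
#' records. Farms are observed on all four sampling dates, so repeated
#' measures within farm (and date) violate independence; the crossed random
#' intercepts absorb that structure. The omnibus breed test is a
#' Satterthwaite-approximated F test; a random-effect variance estimated at
#' the zero boundary is reported as 0 with a warning, not an error.
#'
#' @param dataset a `herd_dataset` with >= 2 breed groups, >= 2 farms and
#'   >= 2 seasons among its complete records.
#' @param response column name of the response variable.
#' @return object of class `breed_effects_result`: list with `response`,
#'   `fixed` (fixed-effect coefficient table), `group_means` (model-implied
#'   per-breed means), `varcomp` (named variances: farm, season, residual),
#'   `F`, `df`, `p`, `stars`, `n`, and the fitted `model`.
#' @export
fit_breed_model <- function(dataset, response) {
  stopifnot(inherits(dataset, "herd_dataset"))
  rec <- all_complete_records(dataset)
  if (!response %in% names(rec))
    stop("unknown response variable: ", response, call. = FALSE)
  df <- data.frame(y = rec[[response]],
                   breed = factor(rec$breed_code),
                   farm = factor(rec$farm_id),
                   season = factor(rec$season))
  df <- df[stats::complete.cases(df), ]
  if (nlevels(droplevels(df$breed)) < 2 || nlevels(droplevels(df$farm)) < 2 ||
      nlevels(droplevels(df$season)) < 2)
    stop("need >= 2 breed groups, >= 2 farms and >= 2 seasons", call. = FALSE)
  df <- droplevels(df)

  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(y ~ breed + (1 | farm) + (1 | season),
                                    data = df, REML = TRUE)),
    error = function(e) stop("mixed model failed to converge for '", response,
                             "': ", conditionMessage(e), call. = FALSE))
  if (lme4::isSingular(fit, tol = 1e-5))
    warning("singular fit for '", response,
            "': a random-effect variance is estimated as 0", call. = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"

  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  fixed <- as.data.frame(summary(fit)$coefficients)
  beta <- lme4::fixef(fit)
  gm <- beta[1] + c(0, beta[-1])
  names(gm) <- levels(df$breed)

  structure(list(response = response, fixed = fixed, group_means = gm,
                 varcomp = varcomp,
                 F = Fv, df = unlist(an[1, c("NumDF", "DenDF")]), p = p,
                 stars = star_label(p), n = nrow(df), model = fit),
            class = "breed_effects_result")
}

#' @export
print.breed_effects_result <- function(x, ...) {
  cat("<breed_effects_result> ", x$response, ": F(",
      round(x$df[1]), ", ", round(x$df[2], 1), ") = ", round(x$F, 3),
      ", p = ", signif(x$p, 3), " [", x$stars, "]\n", sep = "")
  cat("  variance components: ",
      paste(names(x$varcomp), signif(x$varcomp, 4), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Breed-effects table across responses
#'
#' Runs [fit_breed_model()] for each modelled LI-P variable and combines the
#' per-breed mean +/- SD cells with the omnibus significance star. Feeding
#' variables (concentrate, conserved forage) are summarised but not
#' modelled: rations are set per farm per date, not per cow, so the model
#' assumptions do not hold and no p-value is reported for them.
#'
#' @param dataset a `herd_dataset` (after inclusion filtering).
#' @param responses variables to model; defaults to the LI-P variable list.
#' @return list with `summary` (the [summarize_breeds()] table), `tests`
#'   (data frame: variable, F, p, stars; feeding rows carry `NA`), and
#'   `models` (named list of `breed_effects_result`).
#' @export
breed_effects_table <- function(dataset,
                                responses = c("days_in_milk",
                                              production_columns(),
                                              fa_columns())) {
  summary <- summarize_breeds(dataset)
  models <- list()
  tests <- list()
  for (v in summary_variables()) {
    if (v %in% responses) {
      m <- withCallingHandlers(fit_breed_model(dataset, v),
                               warning = function(w) invokeRestart("muffleWarning"))
      models[[v]] <- m
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v, F = m$F, p = m$p, stars = m$stars,
        stringsAsFactors = FALSE)
    } else {
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v, F = NA_real_, p = NA_real_, stars = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(summary = summary, tests = do.call(rbind, tests), models = models)
}
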