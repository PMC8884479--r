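#' Exploratory regressions of clinical scores on altered connectivity
#'
#' For every (feature, scale) combination, fits within the patient group the
#' ordinary least-squares model `scale ~ feature + covariates` and reports
#' the feature slope with its two-sided p-value. Following the exploratory
#' convention for such follow-up regressions, no multiplicity correction is
#' applied; this is recorded in the result's metadata. Features should be
#' restricted to those flagged significant in the group contrast.
#'
#' @param features_tbl Feature table (`subject_id` + feature columns).
#' @param phenotypes Phenotype tibble with `subject_id`, `group`, the
#'   covariates and the clinical scale columns.
#' @param scales Clinical scale column names (default the five standard
#'   scales: `updrs3`, `mmse`, `moca`, `hama`, `hamd`).
#' @param features Feature columns to regress; typically the significant
#'   features of an [fc_level_analysis()] result.
#' @param covariates Covariate columns (default age, sex, education).
#' @param group,patient_level Column and level selecting the patient group
#'   (defaults `"group"`, `"PD"`).
#' @param min_n Minimum usable subjects before a result is flagged low-n
#'   (default 10).
#' @return An `fc_clinreg` tibble: `feature`, `scale`, `slope`, `se`, `t`,
#'   `p`, `n`, `note` (`"low n"` when under `min_n`). Attribute
#'   `multiplicity` records that p-values are uncorrected.
#' @export
clinical_regression <- function(features_tbl, phenotypes,
                                scales = c("updrs3", "mmse", "moca", "hama", "hamd"),
                                features = NULL,
                                covariates = c("age", "sex", "education"),
                                group = "group", patient_level = "PD",
                                min_n = 10) {
  if (is.null(features)) features <- setdiff(names(features_tbl), "subject_id")
  scales <- intersect(scales, names(phenotypes))
  if (length(scales) == 0) abort("None of the requested scales are present.")
  data <- dplyr::inner_join(features_tbl, phenotypes, by = "subject_id")
  data <- data[data[[group]] == patient_level, , drop = FALSE]
  if (nrow(data) == 0) abort("No subjects in the patient group.")

  grid <- tidyr::expand_grid(feature = features, scale = scales)
  out <- purrr::pmap(grid, function(feature, scale) {
    d <- data[, c(feature, scale, covariates)]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    n_use <- nrow(d)
    if (n_use < length(covariates) + 3) {
      return(tibble(feature = feature, scale = scale, slope = NA_real_,
                    se = NA_real_, t = NA_real_, p = NA_real_, n = n_use,
                    note = "insufficient n"))
    }
    if (sd(d[[scale]]) < 1e-12) {
      abort(paste0("Scale '", scale, "' is constant in the patient group."))
    }
    x <- cbind(intercept = 1, feature = d[[feature]],
               as.matrix(d[, covariates, drop = FALSE]))
    fit <- lm.fit(x, d[[scale]])
    df <- n_use - fit$rank
    sigma2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(x)))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    slope <- fit$coefficients[["feature"]]
    tval <- slope / se
    tibble(feature = feature, scale = scale, slope = slope, se = se,
           t = tval, p = 2 * pt(-abs(tval), df), n = n_use,
           note = if (n_use < min_n) "low n" else NA_character_)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "multiplicity") <- "uncorrected (exploratory)"
  class(out) <- c("fc_clinreg", class(out))
  out
}

#' Two-sample t-test from summary statistics
#'
#' Computes the two-sample t-test directly from per-group means, standard
#' deviations and sizes, as needed to reproduce cohort-description tables
#' that print only summaries. Welch's unequal-variance form is the default;
#' the pooled-variance form is available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return Tibble with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' ttest_from_summary(62.34, 11.41, 47, 61.32, 5.60, 50)  # p ~ 0.582
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) abort("Each group needs n >= 2.")
  if (sd1 <= 0 || sd2 <= 0) abort("Standard deviations must be positive.")
  if (variant == "welch") {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean1 - mean2) / se
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohort description table
#'
#' Summarises a phenotype table per group: mean (SD) for continuous
#' variables with a Welch t-test p-value where both groups have data, and
#' counts for `sex`. Variables absent from the table are skipped with a
#' warning.
#'
#' @param phenotypes Phenotype tibble with a `group` column.
#' @param variables Continuous variables to summarise (defaults to the
#'   standard demographic and clinical set).
#' @param group Group column name.
#' @return Tibble with one row per variable: `variable`, per-group `mean`,
#'   `sd`, `n` and the Welch `p` (NA where only one group has data; sex
#'   reported as male/female counts in the `label` columns).
#' @export
describe_cohort <- function(phenotypes,
                            variables = c("age", "education", "duration_months",
                                          "hy_stage", "updrs3", "mmse", "moca",
                                          "hama", "hamd"),
                            group = "group") {
  if (!group %in% names(phenotypes)) abort("Phenotypes need a group column.")
  lev <- sort(unique(as.character(phenotypes[[group]])), decreasing = TRUE)
  if (length(lev) != 2) abort("describe_cohort() expects exactly 2 groups.")
  present <- intersect(variables, names(phenotypes))
  absent <- setdiff(variables, names(phenotypes))
  if (length(absent) > 0) {
    warn(paste0("Variable(s) absent and omitted: ", paste(absent, collapse = ", ")))
  }
  rows <- purrr::map(present, function(v) {
    s <- purrr::map(lev, function(g) {
      x <- phenotypes[[v]][phenotypes[[group]] == g]
      x <- x[!is.na(x)]
      list(mean = if (length(x) > 0) mean(x) else NA_real_,
           sd = if (length(x) > 1) sd(x) else NA_real_, n = length(x))
    })
    p <- if (s[[1]]$n >= 2 && s[[2]]$n >= 2 && s[[1]]$sd > 0 && s[[2]]$sd > 0) {
      ttest_from_summary(s[[1]]$mean, s[[1]]$sd, s[[1]]$n,
                         s[[2]]$mean, s[[2]]$sd, s[[2]]$n)$p
    } else NA_real_
    tibble(variable = v,
           mean_1 = s[[1]]$mean, sd_1 = s[[1]]$sd, n_1 = s[[1]]$n,
           mean_2 = s[[2]]$mean, sd_2 = s[[2]]$sd, n_2 = s[[2]]$n,
           p = p)
  })
  out <- dplyr::bind_rows(rows)
  names(out) <- sub("_1$", paste0("_", lev[1]), names(out))
  names(out) <- sub("_2$", paste0("_", lev[2]), names(out))
  if ("sex" %in% names(phenotypes)) {
    cnt <- table(phenotypes[[group]], phenotypes$sex)
    attr(out, "sex_counts") <- cnt
  }
  attr(out, "groups") <- lev
  out
}
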