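# Core GLM machinery for group contrasts.
#
# All features at one level share the same design (intercept, group
# indicator, covariates), so the per-feature t statistics come from one
# QR residualisation: with g and Y both residualised against the nuisance
# design, the group-coefficient t is the partial-correlation t between
# them with df = n - q - 1 (q = nuisance columns). With no covariates this
# reduces exactly to the pooled two-sample t.

prepare_design <- function(data, features, group = "group",
                           covariates = c("age", "sex", "education"),
                           positive = "PD") {
  if (!group %in% names(data)) abort(paste0("Column '", group, "' not found."))
  gvals <- data[[group]]
  lev <- unique(as.character(gvals))
  if (length(lev) != 2) abort("Group contrast needs exactly 2 groups.")
  if (!positive %in% lev) positive <- sort(lev)[1]
  g <- as.numeric(as.character(gvals) == positive)
  if (min(table(g)) < 3) abort("Need at least 3 subjects per group.")
  covariates <- covariates %||% character()
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0) {
    abort(paste0("Covariate(s) not found: ", paste(missing_cov, collapse = ", ")))
  }
  z <- if (length(covariates) > 0) {
    as.matrix(dplyr::select(data, dplyr::all_of(covariates)))
  } else NULL
  if (!is.null(z) && anyNA(z)) {
    abort("Covariates must be non-missing for every subject in a contrast.")
  }
  y <- as.matrix(dplyr::select(data, dplyr::all_of(features)))
  x0 <- cbind(intercept = rep(1, length(g)), z)
  q0 <- qr(x0)
  if (q0$rank < ncol(x0)) {
    abort("Covariate design is rank deficient; drop collinear covariates.")
  }
  g_res <- qr.resid(q0, g)
  if (sum(g_res^2) < 1e-12) {
    abort("Group indicator is confounded with the covariates (no residual group variation).")
  }
  list(y = y, g = g, g_res = g_res, q0 = q0, n = length(g),
       df = length(g) - ncol(x0) - 1, positive = positive,
       negative = setdiff(lev, positive), features = features)
}

contrast_t <- function(des) {
  y_res <- qr.resid(des$q0, des$y)
  gss <- sum(des$g_res^2)
  beta <- as.numeric(crossprod(des$g_res, y_res)) / gss
  rss <- pmax(unname(colSums(y_res^2)) - beta^2 * gss, 0)
  sigma2 <- rss / des$df
  note <- ifelse(sigma2 < 1e-24, "zero residual variance", NA_character_)
  t <- ifelse(is.na(note), beta / sqrt(sigma2 / gss), NA_real_)
  list(estimate = beta, t = t, rss = rss, note = note, y_res = y_res, gss = gss)
}

#' Covariate-adjusted group contrast for a table of features
#'
#' Fits, for every feature column, the general linear model
#' `feature ~ group + covariates` by ordinary least squares and reports the
#' group-coefficient t statistic with its two-sided parametric p-value. With
#' no covariates this reduces exactly to the pooled-variance two-sample
#' t-test. The group effect direction is reported as `"PD<HC"` / `"PD>HC"`
#' style labels built from the actual group levels.
#'
#' @param data Data frame holding the feature columns plus `group` and the
#'   covariate columns (e.g. a feature table joined to phenotypes).
#' @param features Character vector of feature column names; defaults to all
#'   columns except `group`, the covariates and `subject_id`.
#' @param group Name of the two-level group column (default `"group"`).
#' @param covariates Covariate column names (default age, sex, education);
#'   `NULL` for none.
#' @param positive Group level coded 1 (default `"PD"`); the estimate is
#'   `positive - other`, adjusted for covariates.
#' @return Tibble with one row per feature: `feature`, `estimate`, `t`,
#'   `df`, `p`, `direction`, `note` (`"zero residual variance"` for
#'   degenerate features, else `NA`).
#' @export
glm_group_contrast <- function(data, features = NULL, group = "group",
                               covariates = c("age", "sex", "education"),
                               positive = "PD") {
  if (is.null(features)) {
    features <- setdiff(names(data), c(group, covariates, "subject_id"))
  }
  des <- prepare_design(data, features, group, covariates, positive)
  ct <- contrast_t(des)
  p <- 2 * pt(-abs(ct$t), des$df)
  tibble(feature = features,
         estimate = ct$estimate,
         t = ct$t, df = des$df, p = p,
         direction = ifelse(ct$estimate < 0,
                            paste0(des$positive, "<", des$negative),
                            paste0(des$positive, ">", des$negative)),
         note = ct$note)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment of a vector of p-values with rejection flags at a
#' target FDR level.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, carried
#'   through).
#' @param q Target FDR level (default 0.05).
#' @return Tibble with columns `p`, `q` (BH-adjusted values, monotone) and
#'   `reject` (`q <=` threshold). Empty input gives an empty tibble.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(tibble(p = numeric(), q = numeric(), reject = logical()))
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  qv <- p.adjust(p, method = "BH")
  rej <- !is.na(qv) & qv <= q
  tibble(p = p, q = qv, reject = rej)
}

#' Freedman-Lane permutation p-values for a group contrast
#'
#' Builds an empirical null for every feature's group-coefficient t by the
#' Freedman-Lane scheme: the group indicator and the features are both
#' residualised against the covariates, the residualised indicator is
#' permuted `B` times (and re-residualised), and the partial-correlation t
#' is recomputed. The permutation p-value is
#' `(1 + #permutations with |t*| >= |t_obs|) / (B + 1)`, so its minimum is
#' `1/(B+1)`. A max-T family-wise p-value (comparing each observed |t| with
#' the permutation distribution of the maximum |t| across features) is
#' reported alongside, and BH-FDR is applied to the per-feature permutation
#' p-values.
#'
#' @inheritParams glm_group_contrast
#' @param B Number of permutations (>= 100; default 5000).
#' @param seed Mandatory integer seed for the permutation stream.
#' @param q Target FDR level for the significance flag (default 0.05).
#' @param scheme `"freedman_lane"` (default) or `"raw"` (permute raw group
#'   labels, ignoring covariates in the permutation step).
#' @param chunk Permutations processed per block (memory control for the
#'   4005-feature edge level).
#' @return Tibble with one row per feature: `feature`, `estimate`, `t`,
#'   `df`, `p_param`, `p_perm`, `p_maxT`, `q_perm` (BH on `p_perm`),
#'   `significant` (`q_perm <= q`), `direction`, `note`. Attributes `B`,
#'   `seed`, `q`, `scheme` record the run.
#' @export
permutation_correction <- function(data, features = NULL, group = "group",
                                   covariates = c("age", "sex", "education"),
                                   B = 5000, seed, q = 0.05,
                                   positive = "PD",
                                   scheme = c("freedman_lane", "raw"),
                                   chunk = 500) {
  scheme <- match.arg(scheme)
  if (missing(seed) || is.null(seed)) {
    abort("A seed is mandatory for permutation inference.")
  }
  if (B < 100) abort("B must be at least 100 permutations.")
  if (is.null(features)) {
    features <- setdiff(names(data), c(group, covariates, "subject_id"))
  }
  des <- prepare_design(data, features, group, covariates, positive)
  obs <- contrast_t(des)
  abs_t <- abs(obs$t)
  m <- length(features)
  n <- des$n
  yss <- colSums(obs$y_res^2)

  count_ge <- numeric(m)
  max_ge <- numeric(m)
  withr::with_seed(seed, {
    done <- 0
    while (done < B) {
      nb <- min(chunk, B - done)
      perm_base <- if (scheme == "freedman_lane") des$g_res else des$g
      gmat <- vapply(seq_len(nb), function(b) perm_base[sample.int(n)],
                     numeric(n))
      gmat <- qr.resid(des$q0, gmat)
      gss_b <- colSums(gmat^2)
      num <- crossprod(gmat, obs$y_res)             # nb x m
      beta <- num / gss_b
      rss <- pmax(rep(yss, each = nb) - beta^2 * gss_b, 0)
      tperm <- abs(beta) / sqrt(rss / des$df / gss_b)
      tperm[!is.finite(tperm)] <- 0
      count_ge <- count_ge +
        unname(colSums(sweep(tperm, 2, abs_t, ">="), na.rm = TRUE))
      row_max <- apply(tperm, 1, max)
      max_ge <- max_ge + vapply(abs_t, function(a) sum(row_max >= a),
                                numeric(1))
      done <- done + nb
    }
  })
  p_perm <- (1 + count_ge) / (B + 1)
  p_perm[is.na(abs_t)] <- NA_real_
  p_maxT <- (1 + max_ge) / (B + 1)
  p_maxT[is.na(abs_t)] <- NA_real_
  fdr <- bh_fdr(p_perm, q)
  out <- tibble(feature = features,
                estimate = obs$estimate,
                t = obs$t, df = des$df,
                p_param = 2 * pt(-abs_t, des$df),
                p_perm = p_perm, p_maxT = p_maxT,
                q_perm = fdr$q,
                significant = fdr$reject,
                direction = ifelse(obs$estimate < 0,
                                   paste0(des$positive, "<", des$negative),
                                   paste0(des$positive, ">", des$negative)),
                note = obs$note)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "q") <- q
  attr(out, "scheme") <- scheme
  out
}

#' Full group analysis of one feature level
#'
#' Joins a feature table to phenotypes, runs the covariate-adjusted GLM
#' contrast with Freedman-Lane permutation and BH-FDR (see
#' [permutation_correction()]), and returns an `fc_contrast` object carrying
#' the level metadata. This is the per-level statistical unit of the
#' three-level analysis: the multiplicity family is the level's own feature
#' set (90 integrity, 36 network, 4005 edge features).
#'
#' @param features_tbl Feature table with `subject_id` first (one element of
#'   [build_feature_tables()]'s output).
#' @param phenotypes Phenotype tibble with `subject_id`, `group` and the
#'   covariate columns.
#' @param level Label stored with the result (e.g. `"network"`).
#' @inheritParams permutation_correction
#' @return An `fc_contrast` tibble (see [permutation_correction()] for
#'   columns) with attributes `level`, `B`, `seed`, `q`, `scheme`.
#' @export
fc_level_analysis <- function(features_tbl, phenotypes, level = "features",
                              covariates = c("age", "sex", "education"),
                              B = 5000, seed, q = 0.05, positive = "PD",
                              scheme = c("freedman_lane", "raw")) {
  features <- setdiff(names(features_tbl), "subject_id")
  data <- dplyr::inner_join(features_tbl, phenotypes, by = "subject_id")
  if (nrow(data) < nrow(features_tbl)) {
    warn("Some subjects in the feature table have no phenotype row and were dropped.")
  }
  keep <- !vapply(features, function(f) anyNA(data[[f]]), logical(1))
  if (any(!keep)) {
    inform(paste0(sum(!keep), " feature(s) with missing values excluded from the ",
                  level, "-level contrast."))
  }
  out <- permutation_correction(data, features[keep], group = "group",
                                covariates = covariates, B = B, seed = seed,
                                q = q, positive = positive, scheme = scheme)
  attr(out, "level") <- level
  class(out) <- c("fc_contrast", class(out))
  out
}
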