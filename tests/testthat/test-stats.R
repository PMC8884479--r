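make_contrast_data <- function(n_per_group, effect = 0, seed = 1,
                               n_features = 3) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    g <- rep(c("PD", "HC"), each = n_per_group)
    d <- tibble::tibble(
      subject_id = paste0("s", seq_len(n)), group = g,
      age = rnorm(n, 60, 8), sex = rep(c(0, 1), length.out = n),
      education = rnorm(n, 10, 3))
    for (j in seq_len(n_features)) {
      d[[paste0("f", j)]] <- rnorm(n) + ifelse(g == "PD", effect, 0)
    }
    d
  })
}

test_that("with no covariates the GLM t equals the pooled two-sample t", {
  d <- make_contrast_data(6, effect = 0.8, seed = 21, n_features = 2)
  got <- glm_group_contrast(d, features = c("f1", "f2"), covariates = NULL)
  for (f in c("f1", "f2")) {
    x <- d[[f]][d$group == "PD"]; y <- d[[f]][d$group == "HC"]
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
           (length(x) + length(y) - 2)
    t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    expect_equal(got$t[got$feature == f], t_oracle, tolerance = 1e-10)
  }
  expect_equal(unique(got$df), 10)
})

test_that("degenerate and confounded designs are flagged, not silently fit", {
  d <- make_contrast_data(6, seed = 22)
  d$f1 <- 5
  got <- glm_group_contrast(d, features = "f1")
  expect_equal(got$note, "zero residual variance")
  expect_true(is.na(got$t))

  # covariate perfectly confounded with group
  d2 <- make_contrast_data(6, seed = 23)
  d2$age <- ifelse(d2$group == "PD", 1, 0)
  expect_error(glm_group_contrast(d2, features = "f1", covariates = "age"),
               "confounded")
  expect_error(glm_group_contrast(d2[c(1:2, 7:8), ], features = "f1"),
               "3 subjects")
})

test_that("a pure-noise covariate barely moves the planted-effect t", {
  d <- make_contrast_data(100, effect = 0.5, seed = 24, n_features = 1)
  d$noise_cov <- withr::with_seed(25, rnorm(200))
  t_without <- glm_group_contrast(d, features = "f1", covariates = NULL)$t
  t_with <- glm_group_contrast(d, features = "f1", covariates = "noise_cov")$t
  expect_lt(abs(t_with - t_without), 0.2)
})

test_that("the contrast is invariant to affine rescaling of covariates", {
  d <- make_contrast_data(20, effect = 0.4, seed = 26)
  base <- glm_group_contrast(d, features = c("f1", "f2", "f3"))
  d2 <- dplyr::mutate(d, age = (age - 50) / 10, education = education * 3 + 1)
  rescaled <- glm_group_contrast(d2, features = c("f1", "f2", "f3"))
  expect_equal(base$t, rescaled$t, tolerance = 1e-10)
  expect_equal(base$p, rescaled$p, tolerance = 1e-10)
})

test_that("BH step-up follows the hand-checked examples and is monotone", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$reject))  # p(i) <= i/4 * 0.05 for all i
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.04))

  none <- bh_fdr(rep(1, 5), q = 0.05)
  expect_false(any(none$reject))

  empty <- bh_fdr(numeric(0))
  expect_equal(nrow(empty), 0)

  withr::with_seed(27, {
    p <- runif(50)^2
    strict <- bh_fdr(p, q = 0.01)$reject
    loose <- bh_fdr(p, q = 0.05)$reject
    expect_true(all(which(strict) %in% which(loose)))
  })
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("permutation p-values are deterministic, bounded, and match a naive oracle", {
  d <- make_contrast_data(8, effect = 0, seed = 28, n_features = 2)
  a <- permutation_correction(d, features = c("f1", "f2"), B = 300, seed = 5)
  b <- permutation_correction(d, features = c("f1", "f2"), B = 300, seed = 5)
  expect_identical(a$p_perm, b$p_perm)
  expect_error(permutation_correction(d, features = "f1", B = 300), "seed")
  expect_error(permutation_correction(d, features = "f1", B = 50, seed = 1),
               "at least 100")

  # planted huge effect attains the permutation floor 1/(B+1)
  d2 <- make_contrast_data(10, effect = 10, seed = 29, n_features = 1)
  huge <- permutation_correction(d2, features = "f1", B = 500, seed = 6)
  expect_equal(huge$p_perm, 1 / 501)

  # naive Freedman-Lane oracle: same permutation stream, t refit by lm()
  feats <- c("f1", "f2")
  covs <- c("age", "sex", "education")
  B <- 200
  got <- permutation_correction(d, features = feats, covariates = covs,
                                B = B, seed = 7, chunk = B)
  g <- as.numeric(d$group == "PD")
  Z <- as.matrix(d[, covs])
  q0 <- qr(cbind(1, Z))
  g_res <- qr.resid(q0, g)
  t_of <- function(gstar, y) {
    fit <- lm(y ~ gstar + Z)
    summary(fit)$coefficients["gstar", "t value"]
  }
  obs_t <- vapply(feats, function(f) t_of(g_res, d[[f]]), numeric(1))
  expect_equal(unname(obs_t), got$t, tolerance = 1e-8)
  perm_t <- withr::with_seed(7, {
    gmat <- vapply(seq_len(B), function(b) g_res[sample.int(length(g))],
                   numeric(length(g)))
    apply(gmat, 2, function(gs) vapply(feats, function(f) t_of(gs, d[[f]]),
                                       numeric(1)))
  })
  p_oracle <- vapply(seq_along(feats), function(j) {
    (1 + sum(abs(perm_t[j, ]) >= abs(obs_t[j]))) / (B + 1)
  }, numeric(1))
  expect_equal(got$p_perm, p_oracle, tolerance = 1e-12)
  expect_true(all(got$p_maxT >= got$p_perm - 1e-12))
})

test_that("permutation and parametric p agree for Gaussian features", {
  d <- make_contrast_data(100, effect = 0, seed = 30, n_features = 30)
  got <- permutation_correction(d, features = paste0("f", 1:30),
                                B = 2000, seed = 8)
  expect_lt(median(abs(got$p_perm - got$p_param)), 0.02)
})

test_that("clinical regression recovers exact and planted slopes", {
  withr::with_seed(31, {
    n <- 47
    ph <- tibble::tibble(
      subject_id = paste0("p", 1:n), group = "PD",
      age = rnorm(n, 62, 10), sex = rbinom(n, 1, 0.4),
      education = rnorm(n, 10, 3))
    feat <- tibble::tibble(subject_id = ph$subject_id, fc1 = rnorm(n, 0.4, 0.1))
    # scale exactly 2 x feature: slope 2, p ~ 0
    ph$moca <- 2 * feat$fc1
    exact <- clinical_regression(feat, ph, scales = "moca", features = "fc1")
    expect_equal(exact$slope, 2, tolerance = 1e-8)
    expect_lt(exact$p, 1e-12)

    # constant scale errors
    ph$hama <- 7
    expect_error(clinical_regression(feat, ph, scales = "hama"), "constant")
  })

  # planted slope recovered within 3 SE (covariate effects present)
  withr::with_seed(32, {
    n <- 100
    ph <- tibble::tibble(
      subject_id = paste0("p", 1:n), group = "PD",
      age = rnorm(n, 62, 10), sex = rbinom(n, 1, 0.4),
      education = rnorm(n, 10, 3))
    feat <- tibble::tibble(subject_id = ph$subject_id, fc1 = rnorm(n, 0.4, 0.1))
    ph$moca <- 20 + 1.5 * feat$fc1 - 0.1 * ph$age + 0.3 * ph$education + rnorm(n, 0, 0.5)
    got <- clinical_regression(feat, ph, scales = "moca", features = "fc1")
    expect_lt(abs(got$slope - 1.5) / got$se, 3)
  })

  # low-n flag
  withr::with_seed(33, {
    ph <- tibble::tibble(subject_id = paste0("p", 1:8), group = "PD",
                         age = rnorm(8, 60, 5), sex = rep(0:1, 4),
                         education = rnorm(8, 10, 2),
                         moca = rnorm(8, 20, 3))
    feat <- tibble::tibble(subject_id = ph$subject_id, fc1 = rnorm(8))
    got <- clinical_regression(feat, ph, scales = "moca", features = "fc1")
    expect_equal(got$note, "low n")
  })
})

test_that("null clinical slopes have ~95% CI coverage of zero", {
  covered <- withr::with_seed(34, {
    vapply(1:100, function(rep) {
      n <- 200
      ph <- tibble::tibble(
        subject_id = paste0("p", 1:n), group = "PD",
        age = rnorm(n, 62, 10), sex = rbinom(n, 1, 0.4),
        education = rnorm(n, 10, 3),
        moca = rnorm(n, 22, 3))
      feat <- tibble::tibble(subject_id = ph$subject_id, fc1 = rnorm(n, 0.4, 0.1))
      got <- clinical_regression(feat, ph, scales = "moca", features = "fc1")
      crit <- qt(0.975, n - 5)
      abs(got$slope) <= crit * got$se
    }, logical(1))
  })
  expect_gte(mean(covered), 0.89)
  expect_lte(mean(covered), 1.00)
})

test_that("summary-statistic t-tests reproduce raw-data Welch results", {
  withr::with_seed(35, {
    x <- rnorm(30, 5, 2); y <- rnorm(40, 4, 3)
    ours <- ttest_from_summary(mean(x), sd(x), 30, mean(y), sd(y), 40)
    ref <- t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
    pool <- ttest_from_summary(mean(x), sd(x), 30, mean(y), sd(y), 40,
                               variant = "pooled")
    refp <- t.test(x, y, var.equal = TRUE)
    expect_equal(pool$p, refp$p.value, tolerance = 1e-10)
  })
  same <- ttest_from_summary(10, 2, 20, 10, 2, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(ttest_from_summary(1, 0, 10, 2, 1, 10), "positive")
})

test_that("describe_cohort summarises per group with Welch p-values", {
  ph <- tibble::tibble(
    subject_id = paste0("s", 1:97),
    group = c(rep("PD", 47), rep("HC", 50)),
    age = c(exact_summary_values(47, 62.34, 11.41, seed = 36),
            exact_summary_values(50, 61.32, 5.60, seed = 37)),
    education = c(exact_summary_values(47, 9.83, 3.44, seed = 38),
                  exact_summary_values(50, 10.92, 3.18, seed = 39)),
    sex = rep(c(0, 1), length.out = 97),
    updrs3 = c(exact_summary_values(47, 25.28, 12.03, seed = 40), rep(NA, 50)))
  expect_warning(out <- describe_cohort(ph), "omitted")
  age_row <- out[out$variable == "age", ]
  expect_equal(round(age_row$p, 3), 0.582)
  expect_equal(age_row$mean_PD, 62.34, tolerance = 1e-10)
  edu_row <- out[out$variable == "education", ]
  expect_equal(round(edu_row$p, 3), 0.109)
  expect_true(is.na(out$p[out$variable == "updrs3"]))  # PD-only variable

  # identical group summaries give t = 0, p = 1
  ph2 <- ph
  ph2$age <- c(exact_summary_values(47, 60, 5, seed = 41),
               exact_summary_values(50, 60, 5, seed = 42))
  out2 <- describe_cohort(ph2, variables = "age")
  expect_equal(out2$p, 1, tolerance = 1e-10)
})
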