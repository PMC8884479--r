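test_that("correlation matrix matches hand-evaluated Pearson formulas", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1, 2, 3, 5), e = c(1, 1, 2, 2))
  ts <- fc_timeseries(m, "s", tr = 1, stage = "cleaned")
  r <- correlation_matrix(ts)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["d", "e"], oracle_pearson(m[, "d"], m[, "e"]), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(r)))
  expect_equal(unname(diag(r)), rep(1, 5))

  m2 <- cbind(m, f = rep(7, 4))
  expect_error(correlation_matrix(fc_timeseries(m2, "s", 1, stage = "cleaned")),
               "Zero-variance")
  expect_error(correlation_matrix(fc_timeseries(m, "s", 1, stage = "raw")),
               "cleaned")
})

test_that("Fisher z transform follows the closed form and clips |r| = 1", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.5
  r[1, 3] <- r[3, 1] <- 0
  r[2, 3] <- r[3, 2] <- 1
  z <- fisher_z(r)
  expect_equal(z[1, 3], 0)
  expect_equal(z[1, 2], 0.5 * log(3), tolerance = 1e-12)  # atanh(0.5)
  expect_true(is.finite(z[2, 3]))
  expect_equal(z[2, 3], atanh(0.999999))
  expect_equal(unname(diag(z)), rep(0, 3))
})

test_that("exponential conversion is the documented monotone map", {
  r <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(exponential_conversion(r)[1, 2], 1)
  r[1, 2] <- r[2, 1] <- -1
  expect_equal(exponential_conversion(r)[1, 2], exp(-2), tolerance = 1e-12)
  withr::with_seed(6, {
    ra <- runif(50, -1, 1); rb <- ra + runif(50, 0.001, 0.5)
    expect_true(all(exp(ra - 1) < exp(pmin(rb, 1) - 1)))
  })
  expect_error(exponential_conversion(r, "no_such"), "Unknown conversion")
})

test_that("nodal integrity is the off-diagonal mean of the conversion", {
  conv <- matrix(0.7, 4, 4); diag(conv) <- 0
  expect_equal(unname(nodal_integrity(conv)), rep(0.7, 4))

  conv3 <- matrix(0, 3, 3)
  conv3[1, 2] <- conv3[2, 1] <- 0.2
  conv3[1, 3] <- conv3[3, 1] <- 0.4
  conv3[2, 3] <- conv3[3, 2] <- 0.6
  expect_equal(unname(nodal_integrity(conv3)), c(0.3, 0.4, 0.5))

  withr::with_seed(7, {
    cm <- random_cor(6, seed = 70)
    conv <- exponential_conversion(cm)
    eta <- nodal_integrity(conv)
    perm <- sample(6)
    expect_equal(unname(nodal_integrity(conv[perm, perm])), unname(eta[perm]))
  })
})

test_that("elementwise increase of one r increases exactly the two incident etas", {
  cm <- random_cor(5, seed = 8)
  eta0 <- nodal_integrity(exponential_conversion(cm))
  cm2 <- cm
  cm2[2, 4] <- cm2[4, 2] <- cm[2, 4] + 0.1
  eta1 <- nodal_integrity(exponential_conversion(cm2))
  expect_gt(eta1[2], eta0[2])
  expect_gt(eta1[4], eta0[4])
  expect_equal(eta1[-c(2, 4)], eta0[-c(2, 4)], tolerance = 1e-12)
})

test_that("network averaging matches hand enumeration on the 2-network toy", {
  parc <- toy_parcellation(4, c("VSN", "VSN", "SMN", "SMN"))
  z <- matrix(0.1, 4, 4); diag(z) <- 0
  z[1, 2] <- z[2, 1] <- 0.6
  z[3, 4] <- z[4, 3] <- 0.2
  out <- network_fc(z, parc)
  vals <- setNames(out$value, out$feature)
  expect_equal(vals[["intra_VSN"]], 0.6)
  expect_equal(vals[["intra_SMN"]], 0.2)
  expect_equal(vals[["inter_VSN_SMN"]], 0.1)

  zk <- matrix(0.37, 4, 4); diag(zk) <- 0
  outk <- network_fc(zk, parc)
  expect_equal(outk$value, rep(0.37, 3))

  # singleton network at the intra level is flagged missing, not 0
  parc3 <- toy_parcellation(3, c("VSN", "VSN", "SMN"))
  out3 <- network_fc(z[1:3, 1:3], parc3)
  expect_true(is.na(out3$value[out3$feature == "intra_SMN"]))
})

test_that("vectorised network averaging equals the double-loop oracle", {
  for (seed in 1:20) {
    parc <- toy_parcellation(10, c("VSN", "SMN", "DGN"))
    zm <- fisher_z(random_cor(10, seed = seed))
    got <- network_fc(zm, parc)
    oracle <- oracle_network_fc(zm, parc)
    expect_equal(setNames(got$value, got$feature), oracle, tolerance = 1e-12)
  }
})

test_that("block means aggregate back to the grand off-diagonal mean", {
  parc <- toy_parcellation(9, c("VSN", "SMN", "LBN"))
  zm <- fisher_z(random_cor(9, seed = 31))
  out <- network_fc(zm, parc)
  grand <- sum(out$value * out$n_pairs) / sum(out$n_pairs)
  expect_equal(grand, mean(zm[upper.tri(zm)]), tolerance = 1e-12)
})

test_that("edge flattening is the row-major upper triangle and round-trips", {
  z3 <- matrix(0, 3, 3)
  z3[1, 2] <- z3[2, 1] <- 0.1
  z3[1, 3] <- z3[3, 1] <- 0.2
  z3[2, 3] <- z3[3, 2] <- 0.3
  e <- edge_features(z3)
  expect_equal(names(e), c("1_2", "1_3", "2_3"))
  expect_equal(unname(e), c(0.1, 0.2, 0.3))

  z4 <- fisher_z(random_cor(4, seed = 9))
  expect_equal(names(edge_features(z4)), c("1_2", "1_3", "1_4", "2_3", "2_4", "3_4"))

  zm <- fisher_z(random_cor(7, seed = 10))
  e7 <- edge_features(zm)
  expect_equal(e7, oracle_edges(zm), tolerance = 1e-15)
  back <- edges_to_matrix(e7, 7)
  expect_equal(edge_features(back), e7)
  zm0 <- zm; diag(zm0) <- 0
  expect_equal(unname(back), unname(zm0), ignore_attr = TRUE)
})

test_that("feature tables have the documented shapes and ordering", {
  parc <- aal90_parcellation()
  withr::with_seed(12, {
    ts <- lapply(1:2, function(i) toy_cleaned_ts(40, 90, seed = 100 + i,
                                                 subject_id = paste0("s", i)))
    ph <- tibble::tibble(subject_id = c("s1", "s2"), group = c("PD", "HC"))
    coh <- fc_cohort(ts, ph)
    ft <- build_feature_tables(coh, parc)
    expect_equal(dim(ft$integrity), c(2, 91))
    expect_equal(dim(ft$network), c(2, 37))
    expect_equal(dim(ft$edge), c(2, 4006))
    expect_equal(names(ft$network)[2:9], paste0("intra_", RSN_ORDER))

    single <- build_feature_tables(fc_cohort(ts[1], ph[1, ]), parc)
    expect_equal(nrow(single$integrity), 1)
    expect_equal(unlist(single$edge[1, -1]),
                 unlist(ft$edge[1, -1]))

    # subject order permutation permutes rows only
    coh_rev <- fc_cohort(rev(ts), ph)
    ft_rev <- build_feature_tables(coh_rev, parc)
    expect_equal(ft_rev$network[2:1, ], ft$network)
  })
})

test_that("zero-variance ROIs propagate as flagged missing features", {
  parc <- toy_parcellation(6, c("VSN", "VSN", "VSN", "SMN", "SMN", "DGN"))
  withr::with_seed(13, {
    good <- toy_cleaned_ts(50, 6, seed = 14, subject_id = "good")
    bad <- toy_cleaned_ts(50, 6, seed = 15, subject_id = "bad")
    bad$data[, 2] <- 0  # node 2 is in VSN
    ph <- tibble::tibble(subject_id = c("good", "bad"), group = c("HC", "PD"))
    expect_message(
      ft <- build_feature_tables(fc_cohort(list(good, bad), ph), parc),
      "Zero-variance")
    expect_equal(names(attr(ft, "missing_report")), "bad")
    expect_false(anyNA(ft$integrity[1, -1]))
    expect_true(all(is.na(ft$integrity[2, -1])))
    # VSN-dependent network features are missing; SMN-DGN untouched
    expect_true(is.na(ft$network$intra_VSN[2]))
    expect_false(is.na(ft$network$inter_SMN_DGN[2]))
    # edges touching node 2 are missing, others present
    expect_true(is.na(ft$edge$`2_5`[2]))
    expect_false(is.na(ft$edge$`1_5`[2]))
  })
})
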