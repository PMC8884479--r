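#' Specification of a synthetic two-group resting-state cohort
#'
#' Describes the generative model for a seeded synthetic cohort with the
#' statistical structure the three-level analysis assumes: each group's
#' regional BOLD series are stationary Gaussian signals with a
#' network-modular correlation structure (`rho_within` inside each
#' resting-state network, `rho_between` elsewhere), and the patient group's
#' target correlations are reduced by `deltas` on selected blocks.
#' Demographic covariates and clinical scores are drawn per group, with
#' scores linearly linked to the subject's own network-level Fisher-z
#' connectivity (so score-connectivity regressions have a planted truth).
#'
#' Defaults mirror a typical early-Parkinson's case-control study: 47
#' patients and 50 controls, 373 retained time points at TR = 0.8 s,
#' connectivity reductions concentrated in the visual, somatomotor, limbic
#' and deep gray matter networks, MoCA linked to DGN connectivity and
#' anxiety/depression scores to somatomotor-limbic-deep blocks.
#'
#' @param n_pd,n_hc Group sizes (defaults 47 and 50).
#' @param n_time Time points per subject (default 373).
#' @param tr Repetition time in seconds (default 0.8).
#' @param rho_within Baseline correlation inside a network (default 0.4).
#' @param rho_between Baseline correlation between networks (default 0.15).
#' @param deltas Named numeric vector of target-correlation reductions
#'   applied to the patient group: names are a network label (intra block,
#'   e.g. `"SMN"`) or `"A_B"` (inter block). Default plants the
#'   visual/somatomotor/limbic/deep-gray pattern.
#' @param covariates List with per-group age and education mean/sd and male
#'   proportion; see the default for the shape.
#' @param scores Score models: named list per scale with `intercept`,
#'   `weights` (named by network feature, e.g. `"intra_DGN"`), `sd`, and
#'   optional `groups` restricting the scale to some groups.
#' @param ar1 Optional AR(1) temporal autocorrelation coefficient in
#'   `[0, 1)` (default 0; autocorrelation inflates correlation variance and
#'   is provided for sensitivity analyses).
#' @return An object of class `fc_cohort_spec`.
#' @export
cohort_spec <- function(n_pd = 47, n_hc = 50, n_time = 373, tr = 0.8,
                        rho_within = 0.4, rho_between = 0.15,
                        deltas = c(VSN = 0.15, SMN = 0.15, LBN = 0.15,
                                   DGN = 0.15, VAN = 0.10, VAN_DGN = 0.10),
                        covariates = list(
                          age = list(PD = c(62.34, 11.41), HC = c(61.32, 5.60)),
                          education = list(PD = c(9.83, 3.44), HC = c(10.92, 3.18)),
                          male_prop = c(PD = 18 / 47, HC = 19 / 50)),
                        scores = default_score_models(),
                        ar1 = 0) {
  if (!(rho_between >= 0 && rho_between <= rho_within && rho_within < 1)) {
    abort("Need 0 <= rho_between <= rho_within < 1.")
  }
  deltas <- unlist(deltas) %||% numeric(0)  # accept YAML-style named lists
  if (length(deltas) > 0 && is.null(names(deltas))) {
    abort("deltas must be named by network or network-pair.")
  }
  if (any(abs(rho_within - deltas) >= 1) || any(abs(rho_between - deltas) >= 1)) {
    abort("deltas must keep target correlations inside (-1, 1).")
  }
  if (ar1 < 0 || ar1 >= 1) abort("ar1 must lie in [0, 1).")
  if (n_time < 3) abort("n_time must be at least 3.")
  structure(list(n_pd = n_pd, n_hc = n_hc, n_time = n_time, tr = tr,
                 rho_within = rho_within, rho_between = rho_between,
                 deltas = deltas, covariates = covariates, scores = scores,
                 ar1 = ar1),
            class = "fc_cohort_spec")
}

#' Default clinical score models for the synthetic cohort
#'
#' Weights link each scale to the subject's Fisher-z network connectivity
#' deviations from the control-group target: cognition (MoCA, MMSE)
#' positively to deep-gray connectivity, anxiety (HAMA) and depression
#' (HAMD) negatively to somatomotor/limbic-or-attention/deep blocks, so
#' reduced patient connectivity yields lower cognition and higher
#' anxiety/depression scores. Intercepts are the control-group means of a
#' typical cohort-description table; motor severity (UPDRS-III) is patient
#' only and unlinked to connectivity.
#'
#' @return Named list of score model definitions (see [cohort_spec()]).
#' @export
default_score_models <- function() {
  list(
    updrs3 = list(intercept = 25.28, weights = NULL, sd = 12.03, groups = "PD"),
    mmse = list(intercept = 25.58, weights = c(intra_DGN = 6), sd = 2.5),
    moca = list(intercept = 23.56,
                weights = c(intra_DGN = 25, inter_VAN_DGN = 15), sd = 3.3),
    hama = list(intercept = 4.68,
                weights = c(intra_SMN = -13, intra_LBN = -13, intra_DGN = -13),
                sd = 3.9),
    hamd = list(intercept = 4.84,
                weights = c(intra_SMN = -13, intra_VAN = -13, intra_DGN = -13),
                sd = 3.2))
}

delta_blocks <- function(deltas, nets) {
  if (length(deltas) == 0) return(list())
  purrr::imap(as.list(deltas), function(d, key) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1]]
    bad <- setdiff(parts, nets)
    if (length(bad) > 0 || !(length(parts) %in% 1:2)) {
      abort(paste0("Unknown network in delta '", key, "'."))
    }
    list(nets = parts, delta = d)
  })
}

#' Target correlation matrix for one group
#'
#' Builds the block-structured target: `rho_within` inside every network
#' block, `rho_between` elsewhere, unit diagonal; for the patient group the
#' spec's `deltas` are subtracted from their blocks. If the result is not
#' positive semidefinite it is repaired by eigenvalue clipping with the
#' diagonal re-normalised to 1; the largest entry change is recorded in the
#' `repair_distance` attribute and a repair beyond 0.05 is an error.
#'
#' @param spec An `fc_cohort_spec`.
#' @param parc An `fc_parcellation`.
#' @param group `"PD"` (deltas applied) or `"HC"`.
#' @return N x N target correlation matrix with attribute
#'   `repair_distance`.
#' @export
build_group_covariance <- function(spec, parc, group = c("HC", "PD")) {
  group <- match.arg(group)
  n <- nrow(parc)
  net <- parc$network
  same <- outer(net, net, "==")
  sigma <- matrix(spec$rho_between, n, n)
  sigma[same] <- spec$rho_within
  if (group == "PD") {
    for (blk in delta_blocks(spec$deltas, unique(net))) {
      if (length(blk$nets) == 1) {
        idx <- net == blk$nets
        sel <- outer(idx, idx, "&")
      } else {
        ia <- net == blk$nets[1]; ib <- net == blk$nets[2]
        sel <- outer(ia, ib, "&") | outer(ib, ia, "&")
      }
      sigma[sel] <- sigma[sel] - blk$delta
    }
  }
  diag(sigma) <- 1
  ev <- eigen(sigma, symmetric = TRUE)
  repair <- 0
  if (min(ev$values) < -1e-10) {
    lam <- pmax(ev$values, 1e-8)
    fixed <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(diag(fixed))
    fixed <- fixed / tcrossprod(d)
    repair <- max(abs(fixed - sigma))
    if (repair > 0.05) {
      abort(sprintf(
        "Requested deltas give an irreparably non-PSD target (repair %.3f > 0.05).",
        repair))
    }
    inform(sprintf("Target correlation repaired to PSD (max change %.4f).", repair))
    sigma <- fixed
  }
  attr(sigma, "repair_distance") <- repair
  sigma
}

sym_sqrt <- function(sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Simulate a seeded synthetic cohort
#'
#' Draws every subject's T x N series as correlated Gaussian noise with the
#' group's target correlation (independent normals mixed through the
#' symmetric matrix square root; optional AR(1) innovations), then samples
#' demographic covariates and clinical scores per the cohort spec. Scores are
#' linear in the subject's own empirical network-level Fisher-z
#' connectivity, centred on the control-group target values, so planted
#' score-connectivity links are recoverable by regression. Output is
#' bit-reproducible for a given seed.
#'
#' The simulator emits series at stage `"cleaned"`: it generates the
#' stationary, trend- and confound-free signal that the preprocessing chain
#' is designed to recover, so the connectivity stage can consume it
#' directly.
#'
#' @param spec An `fc_cohort_spec`.
#' @param parc An `fc_parcellation` (default the packaged AAL-90 atlas).
#' @param seed Mandatory integer seed.
#' @return An `fc_cohort`; phenotypes have columns `subject_id`, `group`,
#'   `age`, `sex` (0 female / 1 male), `education`, the five scale scores,
#'   and patient-only `duration_months`, `hy_stage`. The element `network_z`
#'   holds the subjects x network-features matrix of Fisher-z connectivity
#'   computed while generating the scores (the same quantities the network
#'   level of the analysis recomputes), convenient for simulation studies.
#' @export
simulate_cohort <- function(spec, parc = aal90_parcellation(), seed) {
  if (missing(seed) || is.null(seed)) abort("A seed is mandatory for simulation.")
  n <- nrow(parc)
  groups <- c(rep("PD", spec$n_pd), rep("HC", spec$n_hc))
  ids <- c(sprintf("PD%03d", seq_len(spec$n_pd)),
           sprintf("HC%03d", seq_len(spec$n_hc)))
  roots <- list(PD = sym_sqrt(build_group_covariance(spec, parc, "PD")),
                HC = sym_sqrt(build_group_covariance(spec, parc, "HC")))
  # control-group target z values per network feature, used as score centres
  hc_net <- network_fc(fisher_z(build_group_covariance(spec, parc, "HC")), parc)
  ref_z <- setNames(hc_net$value, hc_net$feature)

  withr::with_seed(seed, {
    ts_list <- vector("list", length(ids))
    net_z <- matrix(NA_real_, length(ids), nrow(hc_net),
                    dimnames = list(ids, hc_net$feature))
    for (s in seq_along(ids)) {
      e <- matrix(rnorm(spec$n_time * n), spec$n_time, n)
      if (spec$ar1 > 0) {
        # AR(1) innovations scaled to keep unit marginal variance
        phi <- spec$ar1
        e <- apply(e, 2, function(col) {
          as.numeric(stats::filter(col * sqrt(1 - phi^2), phi,
                                   method = "recursive"))
        })
      }
      x <- e %*% roots[[groups[s]]]
      colnames(x) <- as.character(parc$node_id)
      ts_list[[s]] <- fc_timeseries(x, subject_id = ids[s], tr = spec$tr,
                                    stage = "cleaned")
      net_z[s, ] <- network_fc(fisher_z(cor(x)), parc)$value
    }

    cov <- spec$covariates
    draw2 <- function(def, g) rnorm(1, def[[g]][1], def[[g]][2])
    age <- vapply(groups, function(g) draw2(cov$age, g), numeric(1))
    education <- vapply(groups, function(g) draw2(cov$education, g), numeric(1))
    sex <- vapply(groups, function(g) rbinom(1, 1, cov$male_prop[[g]]), numeric(1))

    ph <- tibble(subject_id = ids, group = groups, age = age, sex = sex,
                 education = pmax(education, 0))
    for (scale in names(spec$scores)) {
      mod <- spec$scores[[scale]]
      val <- rep(mod$intercept, length(ids))
      if (!is.null(mod$weights)) {
        absent <- setdiff(names(mod$weights), colnames(net_z))
        if (length(absent) > 0) {
          abort(paste0("Score model '", scale, "' references feature(s) not in ",
                       "this parcellation: ", paste(absent, collapse = ", "),
                       ". Adjust scores= in the spec (e.g. scores = list())."))
        }
        for (f in names(mod$weights)) {
          val <- val + mod$weights[[f]] * (net_z[, f] - ref_z[[f]])
        }
      }
      val <- val + rnorm(length(ids), 0, mod$sd)
      if (!is.null(mod$groups)) val[!(groups %in% mod$groups)] <- NA_real_
      ph[[scale]] <- val
    }
    ph$duration_months <- ifelse(groups == "PD",
                                 pmax(rnorm(length(ids), 16.72, 12.08), 1), NA_real_)
    ph$hy_stage <- ifelse(groups == "PD",
                          pmin(pmax(rnorm(length(ids), 1.60, 0.43), 1), 2.5),
                          NA_real_)
    out <- fc_cohort(ts_list, ph)
    out$network_z <- net_z
    out
  })
}

#' Write a small NIfTI fixture with known ground truth
#'
#' Creates a toy 4D volume plus integer label volume in which every
#' parcellation node occupies `voxels_per_roi` voxels carrying the node's
#' ground-truth series (plus optional voxel-level noise), for round-trip
#' testing of [extract_roi_timeseries()]. With zero noise, extraction
#' reproduces the ground truth exactly.
#'
#' @param parc An `fc_parcellation` (any node count).
#' @param n_time Time points (default 20).
#' @param voxels_per_roi Voxels per node (default 1).
#' @param grid_dim 3D grid dimensions (default `c(10, 10, 10)`; must hold
#'   `nodes * voxels_per_roi` voxels).
#' @param noise_sd Voxel-level Gaussian noise SD (default 0).
#' @param tr Repetition time stored in the header (default 0.8).
#' @param seed Mandatory integer seed.
#' @param dir Output directory (default `tempdir()`).
#' @return List with `volume_path`, `labels_path`, `truth` (T x N matrix),
#'   `tr`.
#' @export
make_nifti_fixture <- function(parc, n_time = 20, voxels_per_roi = 1,
                               grid_dim = c(10, 10, 10), noise_sd = 0,
                               tr = 0.8, seed, dir = tempdir()) {
  if (missing(seed) || is.null(seed)) abort("A seed is mandatory for fixtures.")
  n <- nrow(parc)
  need <- n * voxels_per_roi
  if (prod(grid_dim) < need) {
    abort(sprintf("Grid of %d voxels cannot hold %d nodes x %d voxels.",
                  prod(grid_dim), n, voxels_per_roi))
  }
  withr::with_seed(seed, {
    truth <- matrix(rnorm(n_time * n), n_time, n,
                    dimnames = list(NULL, as.character(parc$node_id)))
    labels <- array(0L, grid_dim)
    vol <- array(0, c(grid_dim, n_time))
    flat_vol <- matrix(0, prod(grid_dim), n_time)
    pos <- 1L
    for (j in seq_len(n)) {
      idx <- seq.int(pos, pos + voxels_per_roi - 1L)
      labels[idx] <- parc$node_id[j]
      noise <- if (noise_sd > 0) {
        matrix(rnorm(voxels_per_roi * n_time, 0, noise_sd),
               voxels_per_roi, n_time)
      } else 0
      flat_vol[idx, ] <- rep(truth[, j], each = voxels_per_roi) + noise
      pos <- pos + voxels_per_roi
    }
    vol[] <- flat_vol
    volume_path <- file.path(dir, "fixture_bold.nii.gz")
    labels_path <- file.path(dir, "fixture_labels.nii.gz")
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(1, 1, 1, tr)
    RNifti::writeNifti(img, volume_path)
    RNifti::writeNifti(RNifti::asNifti(labels), labels_path)
    list(volume_path = volume_path, labels_path = labels_path,
         truth = truth, tr = tr)
  })
}
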