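#' Assemble a cohort object
#'
#' Bundles a list of subject time series with a phenotype table keyed by
#' `subject_id`.
#'
#' @param timeseries List of `fc_timeseries`, one per subject.
#' @param phenotypes Tibble with at least `subject_id` and `group` columns.
#' @return An object of class `fc_cohort`.
#' @export
fc_cohort <- function(timeseries, phenotypes) {
  ids <- vapply(timeseries, function(ts) ts$subject_id, character(1))
  if (anyDuplicated(ids)) abort("Duplicate subject_ids in the cohort.")
  if (!all(c("subject_id", "group") %in% names(phenotypes))) {
    abort("Phenotypes need subject_id and group columns.")
  }
  missing_ph <- setdiff(ids, phenotypes$subject_id)
  if (length(missing_ph) > 0) {
    abort(paste0("Subjects without phenotypes: ", paste(missing_ph, collapse = ", ")))
  }
  names(timeseries) <- ids
  structure(list(timeseries = timeseries,
                 phenotypes = as_tibble(phenotypes)),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  grp <- table(x$phenotypes$group[match(names(x$timeseries), x$phenotypes$subject_id)])
  cat(sprintf("<fc_cohort> %d subjects (%s)\n", length(x$timeseries),
              paste(names(grp), grp, sep = " = ", collapse = ", ")))
  invisible(x)
}

subject_features <- function(ts, parc, integrity_conversion, network_transform,
                             clip_r) {
  cm <- correlation_matrix(ts)
  conv <- exponential_conversion(cm, integrity_conversion)
  eta <- nodal_integrity(conv)
  tm <- if (identical(network_transform, "fisher_z")) fisher_z(cm, clip_r) else {
    m <- cm; diag(m) <- 0; m          # raw r with diagonal excluded
  }
  list(integrity = eta,
       network = network_fc(tm, parc),
       edge = edge_features(tm))
}

#' Build the three per-level feature tables for a cohort
#'
#' For every subject, computes the Pearson correlation matrix and derives
#' the three feature families analysed in a three-level connectivity study:
#'
#' * **integrity**: the 90 nodal degrees eta (exponential conversion,
#'   default `exp(r - 1)`), one column per node name;
#' * **network**: 8 intra-network plus 28 inter-network averages of the
#'   transformed correlations (Fisher z by default), columns in canonical
#'   order;
#' * **edge**: the N(N-1)/2 transformed upper-triangle correlations
#'   (4005 columns for N = 90), named `"i_j"`.
#'
#' Subjects with flagged zero-variance ROIs get `NA` in every feature that
#' depends on an affected node, and the affected subject/node pairs are
#' recorded in the `missing_report` attribute.
#'
#' @param cohort An `fc_cohort` whose time series are at stage `"cleaned"`.
#' @param parc An `fc_parcellation` matching the series' node count.
#' @param integrity_conversion Conversion for the integrity level (see
#'   [exponential_conversion()]); default `"exp_shift"`.
#' @param network_transform `"fisher_z"` (default) or `"r"` -- the transform
#'   averaged at the network level and used at the edge level.
#' @param clip_r Clipping for the Fisher transform.
#' @return Named list of three tibbles (`integrity`, `network`, `edge`),
#'   each with `subject_id` first and one feature per remaining column, rows
#'   in cohort order. Attribute `meta` records level metadata; attribute
#'   `missing_report` lists flagged subject/ROI pairs.
#' @export
build_feature_tables <- function(cohort, parc,
                                 integrity_conversion = "exp_shift",
                                 network_transform = c("fisher_z", "r"),
                                 clip_r = 0.999999) {
  network_transform <- match.arg(network_transform)
  n <- nrow(parc)
  missing_report <- list()

  rows <- purrr::map(cohort$timeseries, function(ts) {
    if (ncol(ts$data) != n) {
      abort(sprintf("Subject %s has %d ROIs; parcellation has %d.",
                    ts$subject_id, ncol(ts$data), n))
    }
    zv <- zero_variance_rois(ts)
    if (length(zv) == 0) {
      return(subject_features(ts, parc, integrity_conversion,
                              network_transform, clip_r))
    }
    missing_report[[ts$subject_id]] <<- zv
    bad <- match(zv, colnames(ts$data))
    # correlate the surviving columns only, then place NA wherever a flagged
    # node is involved: integrity mixes every node, so it is all-NA; network
    # averages touching an affected network are NA; edges touching a flagged
    # node are NA.
    cm <- matrix(NA_real_, n, n, dimnames = list(colnames(ts$data),
                                                 colnames(ts$data)))
    keep <- setdiff(seq_len(n), bad)
    cm[keep, keep] <- cor(ts$data[, keep, drop = FALSE])
    diag(cm) <- 1
    tm <- if (identical(network_transform, "fisher_z")) {
      z <- atanh(pmin(pmax(cm, -clip_r), clip_r)); diag(z) <- 0; z
    } else { m <- cm; diag(m) <- 0; m }
    netvals <- network_fc(ifelse(is.na(tm), 0, tm), parc)
    bad_nets <- unique(parc$network[bad])
    netvals$value[netvals$net_a %in% bad_nets | netvals$net_b %in% bad_nets] <- NA_real_
    list(integrity = setNames(rep(NA_real_, n), colnames(ts$data)),
         network = netvals,
         edge = edge_features(tm))
  })

  ids <- names(cohort$timeseries)
  integrity <- dplyr::bind_cols(
    tibble(subject_id = ids),
    as_tibble(do.call(rbind, purrr::map(rows, "integrity"))))
  names(integrity)[-1] <- parc$node_name
  network <- dplyr::bind_cols(
    tibble(subject_id = ids),
    as_tibble(do.call(rbind, purrr::map(rows, function(r) {
      setNames(r$network$value, r$network$feature)
    }))))
  edge <- dplyr::bind_cols(
    tibble(subject_id = ids),
    as_tibble(do.call(rbind, purrr::map(rows, "edge"))))

  if (length(missing_report) > 0) {
    inform(paste0("Zero-variance ROIs flagged for subject(s): ",
                  paste(names(missing_report), collapse = ", "),
                  "; dependent features set to NA."))
  }
  out <- list(integrity = integrity, network = network, edge = edge)
  attr(out, "meta") <- list(
    n_nodes = n,
    integrity_conversion = if (is.character(integrity_conversion))
      integrity_conversion else "custom",
    network_transform = network_transform, clip_r = clip_r,
    feature_counts = vapply(out, function(t) ncol(t) - 1L, integer(1)))
  attr(out, "missing_report") <- missing_report
  out
}
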