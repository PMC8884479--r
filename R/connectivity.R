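#' Subject-level Pearson correlation matrix
#'
#' Correlates every pair of ROI columns of a cleaned time series, giving the
#' N x N functional-connectivity matrix (symmetric, unit diagonal). Columns
#' with zero variance make the correlation undefined and raise an error
#' naming the offending node(s).
#'
#' @param ts An `fc_timeseries` at stage `"cleaned"` with T >= 3.
#' @return N x N numeric matrix of Pearson r values, dimnames = node ids,
#'   with attribute `subject_id`.
#' @export
correlation_matrix <- function(ts) {
  if (ts$stage != "cleaned") {
    abort("correlation_matrix() expects a cleaned time series; run clean_timeseries() first.")
  }
  if (nrow(ts$data) < 3) abort("Need at least 3 time points to correlate.")
  zv <- zero_variance_rois(ts)
  if (length(zv) > 0) {
    abort(paste0("Zero-variance ROI column(s): ", paste(zv, collapse = ", "),
                 "; correlations are undefined."))
  }
  r <- cor(ts$data)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  attr(r, "subject_id") <- ts$subject_id
  r
}

#' Fisher z-transform of a correlation matrix
#'
#' Applies the variance-stabilising transform z = atanh(r) to every
#' off-diagonal entry. Correlations are clipped to `clip_r` in magnitude
#' first so that |r| = 1 maps to a finite value. The diagonal is stored as 0
#' by convention and excluded from all downstream aggregates.
#'
#' @param cm N x N correlation matrix.
#' @param clip_r Clipping threshold applied before `atanh` (default
#'   0.999999).
#' @return N x N matrix of z values with zero diagonal; attributes
#'   `subject_id` and `clip_r` are carried along.
#' @export
fisher_z <- function(cm, clip_r = 0.999999) {
  z <- atanh(pmin(pmax(cm, -clip_r), clip_r))
  diag(z) <- 0
  attr(z, "subject_id") <- attr(cm, "subject_id")
  attr(z, "clip_r") <- clip_r
  z
}

#' Exponential conversion of a correlation matrix
#'
#' Transforms every off-diagonal correlation by a strictly increasing,
#' positive, bounded map before nodal-degree averaging. The default
#' conversion is c(r) = exp(r - 1), which equals 1 at r = 1 and e^-2 at
#' r = -1. The conversion is pluggable: supply any vectorised strictly
#' increasing function.
#'
#' @param cm N x N correlation matrix.
#' @param conversion Either the name `"exp_shift"` (the default map
#'   `exp(r - 1)`) or a function of `r`.
#' @return N x N converted matrix (diagonal stored as 0, excluded from
#'   aggregates), attribute `conversion_name` recording the choice.
#' @export
exponential_conversion <- function(cm, conversion = "exp_shift") {
  if (is.character(conversion)) {
    conv_name <- conversion
    fn <- switch(conversion,
                 exp_shift = function(r) exp(r - 1),
                 abort(paste0("Unknown conversion '", conversion, "'.")))
  } else if (is.function(conversion)) {
    conv_name <- "custom"
    fn <- conversion
  } else {
    abort("conversion must be a name or a function.")
  }
  out <- fn(cm)
  diag(out) <- 0
  attr(out, "subject_id") <- attr(cm, "subject_id")
  attr(out, "conversion_name") <- conv_name
  out
}

#' Nodal connectivity degree (integrity level)
#'
#' The integrity-level feature of node i is the mean converted connectivity
#' of i to every other node: eta_i = mean_{j != i} c(r_ij). Using the mean
#' rather than the sum keeps eta scale-free in the node count; group
#' contrasts are unaffected by this affine choice.
#'
#' @param conv N x N converted connectivity matrix (see
#'   [exponential_conversion()]); the diagonal is ignored.
#' @return Named numeric vector eta of length N, attribute
#'   `conversion_name` carried along.
#' @export
nodal_integrity <- function(conv) {
  n <- ncol(conv)
  if (n < 2) abort("Nodal integrity needs at least 2 nodes.")
  m <- conv
  diag(m) <- 0
  eta <- rowSums(m) / (n - 1)
  names(eta) <- colnames(conv) %||% as.character(seq_len(n))
  attr(eta, "conversion_name") <- attr(conv, "conversion_name")
  eta
}

#' Intra- and inter-network connectivity averages (network level)
#'
#' Averages the transformed correlations over all ROI pairs within each
#' network (intra) and over all pairs spanning each of the 28 network pairs
#' (inter). A singleton network has no intra pairs; its intra value is
#' returned as `NA` (flagged missing, never 0).
#'
#' @param zm N x N transformed connectivity matrix with zero diagonal
#'   (typically Fisher z, see [fisher_z()]).
#' @param parc An `fc_parcellation` whose node count matches `zm`.
#' @return Tibble with columns `feature` (e.g. `"intra_SMN"`,
#'   `"inter_VSN_SMN"`), `type` (`"intra"`/`"inter"`), `net_a`, `net_b`,
#'   `n_pairs`, `value`, in canonical order: the intra features in
#'   [RSN_ORDER], then the network pairs.
#' @export
network_fc <- function(zm, parc) {
  n <- ncol(zm)
  if (nrow(parc) != n) {
    abort(sprintf("Parcellation has %d nodes but the matrix is %d x %d.",
                  nrow(parc), n, n))
  }
  blocks <- network_blocks(parc)
  nets <- blocks$networks
  # membership indicator (N x K) gives all block sums in one product
  m <- vapply(nets, function(k) as.numeric(parc$network == k), numeric(n))
  block_sums <- t(m) %*% zm %*% m
  sizes <- colSums(m)

  intra <- tibble(
    feature = paste0("intra_", nets),
    type = "intra", net_a = nets, net_b = nets,
    n_pairs = sizes * (sizes - 1) / 2,
    # zm diagonal is 0, block sum counts each unordered pair twice
    value = unname(ifelse(unname(sizes) >= 2,
                          unname(diag(block_sums)) / unname(sizes * (sizes - 1)),
                          NA_real_)))
  pr <- blocks$pairs
  ia <- match(pr$net_a, nets); ib <- match(pr$net_b, nets)
  inter <- tibble(
    feature = paste0("inter_", pr$pair),
    type = "inter", net_a = pr$net_a, net_b = pr$net_b,
    n_pairs = sizes[ia] * sizes[ib],
    value = unname(block_sums[cbind(ia, ib)] / (sizes[ia] * sizes[ib])))
  dplyr::bind_rows(intra, inter)
}

#' Edge-level feature vector
#'
#' Flattens the strict upper triangle (i < j) of a transformed connectivity
#' matrix in row-major order: (1,2), (1,3), ..., (1,N), (2,3), ... Features
#' are named `"i_j"` using 1-based node ids with i < j; an N-node matrix
#' yields N(N-1)/2 features (4005 for N = 90).
#'
#' @param zm N x N symmetric transformed connectivity matrix.
#' @return Named numeric vector of length N(N-1)/2.
#' @export
edge_features <- function(zm) {
  n <- ncol(zm)
  tm <- t(zm)
  keep <- lower.tri(tm)
  # tm[a, b] with a > b is zm[b, a]; column-major over tm's lower triangle
  # enumerates zm's upper triangle in row-major order.
  v <- tm[keep]
  i <- col(tm)[keep]
  j <- row(tm)[keep]
  names(v) <- paste(i, j, sep = "_")
  v
}

#' Rebuild a symmetric matrix from an edge-feature vector
#'
#' Inverse of [edge_features()]: places each `"i_j"` value at positions
#' (i, j) and (j, i) of an N x N matrix with zero diagonal.
#'
#' @param edges Named vector as produced by [edge_features()].
#' @param n Node count N.
#' @return N x N symmetric matrix with zero diagonal.
#' @export
edges_to_matrix <- function(edges, n) {
  if (length(edges) != n * (n - 1) / 2) {
    abort("Edge vector length does not match n(n-1)/2.")
  }
  idx <- do.call(rbind, strsplit(names(edges), "_", fixed = TRUE))
  i <- as.integer(idx[, 1]); j <- as.integer(idx[, 2])
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- edges
  m[cbind(j, i)] <- edges
  m
}
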