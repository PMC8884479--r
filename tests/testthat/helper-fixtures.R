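# Fixtures are built in code; nothing is stored on disk.

# A toy parcellation with arbitrary node count; networks assigned round-robin
# from the canonical order.
toy_parcellation <- function(n_nodes = 6, networks = c("VSN", "SMN")) {
  tbl <- tibble::tibble(
    node_id = seq_len(n_nodes),
    node_name = paste0("R", seq_len(n_nodes), rep(c("_L", "_R"), length.out = n_nodes)),
    hemisphere = rep(c("left", "right"), length.out = n_nodes),
    network = rep(networks, length.out = n_nodes))
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path, progress = FALSE)
  load_parcellation(path, n_nodes = NULL)
}

# Random symmetric correlation-like matrix with unit diagonal.
random_cor <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * (n + 2)), n + 2, n)
    r <- cor(x)
    dimnames(r) <- list(as.character(1:n), as.character(1:n))
    r
  })
}

# A cleaned fc_timeseries with given dimensions.
toy_cleaned_ts <- function(n_time, n_roi, seed, subject_id = "s1", tr = 0.8) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_time * n_roi), n_time, n_roi,
                dimnames = list(NULL, as.character(seq_len(n_roi))))
    fc_timeseries(m, subject_id = subject_id, tr = tr, stage = "cleaned")
  })
}

# Phenotypes with exact group summary statistics: values are shifted/scaled
# so each group's sample mean and SD match the requested targets exactly.
exact_summary_values <- function(n, mean, sd, seed) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    (x - base::mean(x)) / stats::sd(x) * sd + mean
  })
}

# Network-level feature table straight from a simulated cohort's stored
# Fisher-z matrix (same quantities build_feature_tables() recomputes).
network_feature_tbl <- function(cohort) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(cohort$network_z)),
    tibble::as_tibble(cohort$network_z))
}

# Brute-force double-loop oracles -----------------------------------------

oracle_integrity <- function(conv) {
  n <- ncol(conv)
  vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(j) conv[i, j], numeric(1)))
  }, numeric(1))
}

oracle_network_fc <- function(zm, parc) {
  nets <- RSN_ORDER[RSN_ORDER %in% unique(parc$network)]
  intra <- vapply(nets, function(a) {
    ids <- parc$node_id[parc$network == a]
    if (length(ids) < 2) return(NA_real_)
    vals <- c()
    for (i in ids) for (j in ids) if (i < j) vals <- c(vals, zm[i, j])
    mean(vals)
  }, numeric(1))
  inter <- c()
  inter_names <- c()
  for (ai in seq_along(nets)) for (bi in seq_along(nets)) {
    if (ai < bi) {
      ia <- parc$node_id[parc$network == nets[ai]]
      ib <- parc$node_id[parc$network == nets[bi]]
      vals <- c()
      for (i in ia) for (j in ib) vals <- c(vals, zm[i, j])
      inter <- c(inter, mean(vals))
      inter_names <- c(inter_names, paste0("inter_", nets[ai], "_", nets[bi]))
    }
  }
  c(stats::setNames(intra, paste0("intra_", nets)),
    stats::setNames(inter, inter_names))
}

oracle_edges <- function(zm) {
  n <- ncol(zm)
  v <- c(); nm <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) { v <- c(v, zm[i, j]); nm <- c(nm, paste0(i, "_", j)) }
  }
  stats::setNames(v, nm)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}
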