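#' Load and validate a node-to-network parcellation table
#'
#' Reads a tab-separated parcellation table with columns `node_id`,
#' `node_name`, `hemisphere` and `network`, validates it, and returns it as a
#' tibble ordered by `node_id`. The default atlas shipped with the package
#' ([aal90_parcellation()]) assigns the 90 AAL cortical and subcortical
#' regions (45 per hemisphere, cerebellum excluded) to seven cortical
#' resting-state networks plus the deep gray matter network (DGN): the
#' bilateral caudate, putamen, pallidum and thalamus.
#'
#' @param path Path to a TSV file with columns `node_id`, `node_name`,
#'   `hemisphere`, `network`.
#' @param n_nodes Expected number of nodes. Defaults to 90 (the AAL-90
#'   parcellation). Set to `NULL` to accept any node count, e.g. for toy
#'   atlases in tests; all other validation still applies.
#' @return A tibble with class `fc_parcellation` and columns `node_id`
#'   (integer, contiguous from 1), `node_name`, `hemisphere`
#'   (`"left"`/`"right"`), `network` (one of [RSN_ORDER]).
#' @seealso [aal90_parcellation()], [network_blocks()]
#' @export
#' @examples
#' parc <- aal90_parcellation()
#' dplyr::count(parc, network)
load_parcellation <- function(path, n_nodes = 90) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("node_id", "node_name", "hemisphere", "network")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("Parcellation table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- dplyr::arrange(dplyr::select(tbl, dplyr::all_of(required)),
                        .data$node_id)
  tbl$node_id <- as.integer(tbl$node_id)
  validate_parcellation(tbl, n_nodes = n_nodes)
  class(tbl) <- c("fc_parcellation", class(tbl))
  tbl
}

#' The packaged AAL-90 parcellation with 8-network assignment
#'
#' Returns the default parcellation table: the 90 AAL regions grouped into
#' the seven cortical resting-state networks of the Yeo clustering
#' convention plus the deep gray matter network. The per-region network
#' assignment is a reconstruction following that convention -- the exact
#' mapping used by any given study is a configuration choice, and users can
#' supply their own table through [load_parcellation()].
#'
#' @return An `fc_parcellation` tibble with 90 rows.
#' @export
aal90_parcellation <- function() {
  load_parcellation(system.file("extdata", "aal90_networks.tsv",
                                package = "rsfcnet", mustWork = TRUE))
}

validate_parcellation <- function(tbl, n_nodes = 90) {
  if (anyNA(tbl)) abort("Parcellation table contains missing values.")
  if (anyDuplicated(tbl$node_id)) {
    abort("Parcellation table has duplicate node_ids.")
  }
  n <- nrow(tbl)
  if (!identical(tbl$node_id, seq_len(n))) {
    abort("node_ids must be contiguous 1..N.")
  }
  if (!is.null(n_nodes) && n != n_nodes) {
    abort(paste0("Expected ", n_nodes, " nodes, found ", n,
                 ". Use n_nodes = NULL for non-standard atlases."))
  }
  bad_hemi <- setdiff(unique(tbl$hemisphere), c("left", "right"))
  if (length(bad_hemi) > 0) {
    abort(paste0("Unknown hemisphere label(s): ",
                 paste(bad_hemi, collapse = ", ")))
  }
  bad_net <- setdiff(unique(tbl$network), RSN_ORDER)
  if (length(bad_net) > 0) {
    abort(paste0("Unknown network label(s): ",
                 paste(bad_net, collapse = ", "),
                 ". Allowed: ", paste(RSN_ORDER, collapse = ", ")))
  }
  # full-size atlas invariants
  if (n == 90) {
    hemi_n <- table(tbl$hemisphere)
    if (!all(hemi_n == 45)) {
      abort("A 90-node parcellation must have 45 nodes per hemisphere.")
    }
    if (length(unique(tbl$network)) != 8) {
      abort("A 90-node parcellation must use all 8 network labels.")
    }
    dgn <- tolower(tbl$node_name[tbl$network == "DGN"])
    dgn_expected <- c("caudate", "putamen", "pallidum", "thalamus")
    dgn_stem <- sub("_(l|r)$", "", dgn)
    if (length(dgn) != 8 || !setequal(unique(dgn_stem), dgn_expected)) {
      abort(paste0("DGN must be exactly the bilateral caudate, putamen, ",
                   "pallidum and thalamus (8 nodes)."))
    }
  }
  invisible(tbl)
}

#' Network membership blocks and the canonical network-pair list
#'
#' Decomposes a parcellation into per-network node-id sets and enumerates the
#' unordered network pairs in canonical order. For K networks the pair list
#' has K(K-1)/2 entries, ordered by the fixed label order [RSN_ORDER] (first
#' by the earlier network, then the later), so feature indexing at the
#' network level is deterministic.
#'
#' @param parc An `fc_parcellation` tibble (see [load_parcellation()]).
#' @return A list with elements
#'   * `nodes`: named list mapping each network label to its integer node ids;
#'   * `pairs`: tibble with columns `net_a`, `net_b`, `pair`
#'     (`"A_B"` label) in canonical order;
#'   * `networks`: the networks present, in canonical order.
#' @export
#' @examples
#' blocks <- network_blocks(aal90_parcellation())
#' nrow(blocks$pairs)  # 28
network_blocks <- function(parc) {
  nets <- RSN_ORDER[RSN_ORDER %in% unique(parc$network)]
  nodes <- lapply(setNames(nets, nets),
                  function(k) parc$node_id[parc$network == k])
  if (length(nets) >= 2) {
    idx <- utils::combn(seq_along(nets), 2)
    pairs <- tibble(net_a = nets[idx[1, ]], net_b = nets[idx[2, ]])
  } else {
    pairs <- tibble(net_a = character(), net_b = character())
  }
  pairs$pair <- paste(pairs$net_a, pairs$net_b, sep = "_")
  list(nodes = nodes, pairs = pairs, networks = nets)
}
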