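#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a group-contrast result
#'
#' Returns the per-feature contrast table as a plain tibble.
#'
#' @param x An `fc_contrast`.
#' @param ... Unused.
#' @return A tibble, one row per feature.
#' @export
tidy.fc_contrast <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "fc_contrast")
  out
}

#' One-row summary of a group-contrast result
#'
#' @param x An `fc_contrast`.
#' @param ... Unused.
#' @return Tibble with `level`, `n_features`, `n_significant`, `B`, `q`,
#'   `seed`, `scheme`.
#' @export
glance.fc_contrast <- function(x, ...) {
  tibble(level = attr(x, "level") %||% NA_character_,
         n_features = nrow(x),
         n_significant = sum(x$significant, na.rm = TRUE),
         B = attr(x, "B"), q = attr(x, "q"),
         seed = attr(x, "seed"), scheme = attr(x, "scheme"))
}

#' Tidy a clinical-regression result
#'
#' @param x An `fc_clinreg`.
#' @param ... Unused.
#' @return A tibble, one row per (feature, scale) pair.
#' @export
tidy.fc_clinreg <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "fc_clinreg")
  out
}

#' One-row summary of a clinical-regression result
#'
#' @param x An `fc_clinreg`.
#' @param ... Unused.
#' @return Tibble with counts of pairs tested and nominally significant.
#' @export
glance.fc_clinreg <- function(x, ...) {
  tibble(n_pairs = nrow(x),
         n_nominal = sum(x$p < 0.05, na.rm = TRUE),
         multiplicity = attr(x, "multiplicity") %||% "uncorrected (exploratory)")
}
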