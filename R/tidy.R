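#' Broom-style accessors for pepdepth results
#'
#' `tidy()` on a processed dataset returns its frequency matrix; `glance()`
#' returns the one-row cleaning statistics. On a distinguishing analysis,
#' `tidy()` returns the per-member CI table and `glance()` a one-row
#' summary of how many tied-frequency groups the deeper dataset resolves.
#'
#' @param x A `pd_dataset` or `pd_distinguish` object.
#' @param ... Unused.
#' @return A tibble.
#' @name pepdepth-tidiers
NULL

#' @rdname pepdepth-tidiers
#' @method tidy pd_dataset
#' @export
tidy.pd_dataset <- function(x, ...) {
  as_tibble(x$freq_matrix)
}

#' @rdname pepdepth-tidiers
#' @method glance pd_dataset
#' @export
glance.pd_dataset <- function(x, ...) {
  x$stats
}

#' @rdname pepdepth-tidiers
#' @method tidy pd_distinguish
#' @export
tidy.pd_distinguish <- function(x, ...) {
  x$members
}

#' @rdname pepdepth-tidiers
#' @method glance pd_distinguish
#' @export
glance.pd_distinguish <- function(x, ...) {
  tibble(
    n_groups = nrow(x$groups),
    n_members = nrow(x$members),
    n_significant = sum(x$groups$significant),
    z = x$z,
    alpha = x$alpha
  )
}
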