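#' Tidy a clustering result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return A tibble with one row per entity: `entity`, `cluster` (`NA` =
#'   noise).
#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(entity = names(x$entities), cluster = x$labels)
}

#' @rdname tidy.cluster_result
#' @return `glance()`: a one-row tibble with `n_entities`, `n_clusters`,
#'   `n_noise`, `largest_size`.
#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_entities = length(x$labels),
    n_clusters = x$n_clusters,
    n_noise = sum(is.na(x$labels)),
    largest_size = if (nrow(x$sizes)) max(x$sizes$size) else 0L
  )
}

#' Tidy a gyration-shape result
#'
#' @param x A `gyration_shape`.
#' @param ... Unused.
#' @return A tibble with `lambda1`, `lambda2`, `lambda3` (A^2),
#'   `asphericity`, `prolateness`, `degenerate`, `n`.
#' @export
tidy.gyration_shape <- function(x, ...) {
  tibble::tibble(
    lambda1 = x$eigenvalues[1], lambda2 = x$eigenvalues[2],
    lambda3 = x$eigenvalues[3],
    asphericity = x$asphericity, prolateness = x$prolateness,
    degenerate = x$degenerate, n = x$n
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
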