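#' Gyration-tensor shape analysis
#'
#' Computes the (unweighted) gyration tensor of a point selection,
#' \deqn{S_{\alpha\beta} = \sum_{i=1}^{N} (r_{\alpha i} - r_{\alpha}^{com})
#'   (r_{\beta i} - r_{\beta}^{com}),}
#' its eigenvalues \eqn{\lambda_1 \le \lambda_2 \le \lambda_3}, and the two
#' derived shape descriptors:
#' \deqn{a = \frac{(\lambda_2-\lambda_1)^2 + (\lambda_3-\lambda_1)^2 +
#'   (\lambda_3-\lambda_2)^2}{2(\lambda_1+\lambda_2+\lambda_3)^2}}
#' \deqn{p = \frac{(2\lambda_1-\lambda_2-\lambda_3)
#'   (2\lambda_2-\lambda_1-\lambda_3)(2\lambda_3-\lambda_1-\lambda_2)}
#'   {2(\lambda_1^2+\lambda_2^2+\lambda_3^2-\lambda_1\lambda_2-
#'   \lambda_1\lambda_3-\lambda_2\lambda_3)^{3/2}}}
#' Asphericity `a` is 0 for a sphere and approaches 1 as the shape departs
#' from sphericity (a line attains exactly 1). Prolateness `p` ranges over
#' [-1, 1]: +1 for a perfectly prolate shape (\eqn{\lambda_1 = \lambda_2 <
#' \lambda_3}), -1 for a fully oblate one (\eqn{\lambda_1 < \lambda_2 =
#' \lambda_3}). For a degenerate tensor (all eigenvalues equal) `p` is 0/0
#' and is returned as 0 with `degenerate = TRUE`: a sphere is neither prolate
#' nor oblate.
#'
#' The tensor is applied unweighted (plain coordinates, no masses), for a
#' single polymer or a whole aggregate alike; `coords` is simply the bead
#' selection to analyse.
#'
#' @param coords N x 3 coordinate matrix (A), N >= 2, not all coincident.
#' @return A `gyration_shape` object: list with `tensor` (3 x 3, A^2),
#'   `eigenvalues` (ascending), `n`, `com`, `asphericity`, `prolateness`,
#'   `degenerate`.
#' @examples
#' pts <- make_shape_cloud("prolate", n = 60, seed = 1)
#' gyration_shape(pts)$prolateness
#' @export
gyration_shape <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) {
    stop("shape analysis needs at least 2 points", call. = FALSE)
  }
  com <- colMeans(coords)
  cen <- sweep(coords, 2, com)
  if (max(abs(cen)) < 1e-12) {
    stop("all points are coincident; gyration tensor undefined",
         call. = FALSE)
  }
  S <- crossprod(cen)  # sum_i (r_i - com)(r_i - com)^T
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0 & ev > -1e-9 * max(ev)] <- 0  # clip eigen round-off
  l1 <- ev[1]; l2 <- ev[2]; l3 <- ev[3]
  a <- ((l2 - l1)^2 + (l3 - l1)^2 + (l3 - l2)^2) / (2 * (l1 + l2 + l3)^2)
  denom <- l1^2 + l2^2 + l3^2 - l1 * l2 - l1 * l3 - l2 * l3
  degenerate <- denom <= 1e-12 * max(ev)^2
  p <- if (degenerate) 0 else {
    (2 * l1 - l2 - l3) * (2 * l2 - l1 - l3) * (2 * l3 - l1 - l2) /
      (2 * denom^1.5)
  }
  structure(list(tensor = S, eigenvalues = ev, n = nrow(coords), com = com,
                 asphericity = a, prolateness = p, degenerate = degenerate),
            class = "gyration_shape")
}

#' @export
print.gyration_shape <- function(x, ...) {
  cat("<gyration_shape> n=", x$n,
      sprintf(", lambda = (%.3g, %.3g, %.3g) A^2", x$eigenvalues[1],
              x$eigenvalues[2], x$eigenvalues[3]),
      sprintf(", a = %.4f, p = %.4f%s", x$asphericity, x$prolateness,
              if (x$degenerate) " (degenerate)" else ""), "\n", sep = "")
  invisible(x)
}

#' Shape time series over a trajectory
#'
#' @param trajectory A `cg_trajectory`.
#' @param select Optional predicate on the bead tibble returning a logical
#'   selection; default uses all beads of each frame.
#' @return A tibble with `time`, `asphericity`, `prolateness`, `rg`
#'   (radius of gyration, A: `sqrt(sum(eigenvalues)/n)`).
#' @export
shape_timeseries <- function(trajectory, select = NULL) {
  purrr::map_dfr(trajectory, function(fr) {
    idx <- if (is.null(select)) seq_len(nrow(fr$coords))
           else which(select(fr$beads))
    gs <- gyration_shape(fr$coords[idx, , drop = FALSE])
    tibble::tibble(time = fr$time, asphericity = gs$asphericity,
                   prolateness = gs$prolateness,
                   rg = sqrt(sum(gs$eigenvalues) / gs$n))
  })
}
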