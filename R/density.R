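#' Standard bead-group selections for density profiles
#'
#' The four groups plotted in aggregate cross-section profiles: the M1, M2
#' and M3 side chains (non-backbone beads of each monomer type) and the
#' backbone. Each selection is a predicate on a frame's bead tibble.
#'
#' @return A named list of functions `beads -> logical`.
#' @export
density_groups <- function() {
  list(
    M1_side  = function(b) b$monomer == "M1" & b$role != "backbone",
    M2_side  = function(b) b$monomer == "M2" & b$role != "backbone",
    M3_side  = function(b) b$monomer == "M3" & b$role != "backbone",
    backbone = function(b) b$role == "backbone"
  )
}

#' Cylindrical density profile across an aggregate
#'
#' For every frame in the (trailing) analysis window, a cylinder of the given
#' diameter is centred on the aggregate centre of mass and aligned along the
#' chosen axis; beads of each group whose radial (minimum-image) distance
#' from the axis is at most `diameter / 2` are histogrammed along the axis in
#' `bin`-wide bins, and the per-bin counts are averaged over frames. The
#' profile of each group sums to that group's mean in-cylinder bead count.
#'
#' @param trajectory A `cg_trajectory`, or a single `cg_frame`.
#' @param groups Named list of bead predicates; default [density_groups()].
#' @param diameter Cylinder diameter in A (default 6).
#' @param bin Bin width in A (default 0.5).
#' @param axis `"x"`, `"y"` or `"z"` (default `"x"`).
#' @param window Trailing time window in ns over which to average (default
#'   50); frames with `time >= max(time) - window` are used. Ignored when
#'   timestamps are absent or constant.
#' @return A tibble with `group`, `bin_center` (A, relative to the aggregate
#'   centre of mass) and `count` (mean beads per bin).
#' @export
cylinder_density_profile <- function(trajectory, groups = density_groups(),
                                     diameter = 6, bin = 0.5, axis = "x",
                                     window = 50) {
  if (inherits(trajectory, "cg_frame")) trajectory <- list(trajectory)
  stopifnot(length(trajectory) >= 1L, length(groups) >= 1L)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  tms <- vapply(trajectory, function(f) f$time, numeric(1))
  keep <- tms >= max(tms) - window
  trajectory <- trajectory[keep]
  box <- trajectory[[1]]$box
  L <- box[ax]
  breaks <- seq(-L / 2, L / 2 + bin, by = bin)
  centers <- breaks[-length(breaks)] + bin / 2
  radial <- setdiff(1:3, ax)
  acc <- matrix(0, length(groups), length(centers),
                dimnames = list(names(groups), NULL))
  for (fr in trajectory) {
    com <- colMeans(fr$coords)
    d <- min_image(sweep(fr$coords, 2, com), fr$box)
    inside <- sqrt(d[, radial[1]]^2 + d[, radial[2]]^2) <= diameter / 2
    for (g in names(groups)) {
      sel <- inside & groups[[g]](fr$beads)
      if (!any(sel)) next
      h <- graphics::hist(pmin(pmax(d[sel, ax], -L / 2), L / 2),
                          breaks = breaks, plot = FALSE)
      acc[g, ] <- acc[g, ] + h$counts
    }
  }
  acc <- acc / length(trajectory)
  if (all(acc == 0)) {
    warning("no beads of any group fell inside the cylinder; ",
            "returning a zero profile", call. = FALSE)
  }
  out <- tibble::tibble(
    group = rep(rownames(acc), each = length(centers)),
    bin_center = rep(centers, times = nrow(acc)),
    count = as.vector(t(acc))
  )
  structure(out, class = c("density_profile", class(out)),
            diameter = diameter, bin = bin, axis = axis)
}
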