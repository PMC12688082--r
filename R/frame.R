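#' Construct a single trajectory frame
#'
#' A `cg_frame` holds one time point: an N x 3 coordinate matrix (A), a bead
#' metadata tibble (one row per bead, including `molecule` name, `mol_id`
#' instance index and the topology columns `bead`, `type`, `size_class`,
#' `charge`, `mass`, `role`, `monomer`, `monomer_index`), an orthorhombic box
#' (length-3 vector, A) and a timestamp in ns.
#'
#' @param coords N x 3 numeric matrix, A.
#' @param beads Tibble with at least `molecule` and `mol_id`.
#' @param box Length-3 positive box vector (A).
#' @param time Time stamp in ns.
#' @return A `cg_frame`.
#' @export
cg_frame <- function(coords, beads, box, time = 0) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || (nrow(coords) && ncol(coords) != 3L)) {
    stop("coords must be an N x 3 numeric matrix", call. = FALSE)
  }
  if (nrow(coords) && any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (nrow(coords) != nrow(beads)) {
    stop("coords and beads disagree on bead count", call. = FALSE)
  }
  if (length(box) != 3L || any(box <= 0)) {
    stop("box must be a length-3 positive vector (A)", call. = FALSE)
  }
  structure(list(coords = coords, beads = tibble::as_tibble(beads),
                 box = as.numeric(box), time = time),
            class = "cg_frame")
}

#' @export
print.cg_frame <- function(x, ...) {
  cat("<cg_frame> ", nrow(x$coords), " beads, ",
      length(unique(x$beads$mol_id)), " molecules, box ",
      paste(sprintf("%.1f", x$box), collapse = " x "), " A, t = ",
      x$time, " ns\n", sep = "")
  invisible(x)
}

empty_frame <- function(box, time = 0) {
  cg_frame(matrix(numeric(), 0, 3),
           tibble::tibble(molecule = character(), mol_id = integer()),
           box, time)
}

#' Minimum-image displacement and distances
#'
#' `min_image()` wraps a displacement matrix into the primary periodic image
#' of an orthorhombic box; `pair_min_dist()` returns the minimum-image
#' distance between every row of `a` and every row of `b`.
#'
#' @param d Displacement matrix (N x 3, A).
#' @param box Length-3 box vector (A).
#' @return `min_image()`: wrapped displacement matrix. `pair_min_dist()`:
#'   an `nrow(a)` x `nrow(b)` distance matrix.
#' @export
min_image <- function(d, box) {
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' @rdname min_image
#' @param a,b Coordinate matrices (rows are beads).
#' @export
pair_min_dist <- function(a, b, box) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    out <- out + dk^2
  }
  sqrt(out)
}

#' Assemble a trajectory from frames
#'
#' @param frames List of `cg_frame` objects (time-ordered).
#' @return A `cg_trajectory` (list of frames).
#' @export
cg_trajectory <- function(frames) {
  stopifnot(all(vapply(frames, inherits, logical(1), "cg_frame")))
  structure(frames, class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  tms <- vapply(x, function(f) f$time, numeric(1))
  cat("<cg_trajectory> ", length(x), " frames, t = ",
      if (length(tms)) paste0(min(tms), "..", max(tms), " ns") else "-",
      "\n", sep = "")
  invisible(x)
}

#' Write / read GRO coordinate files
#'
#' Fixed-width GROMACS coordinate format; positions are converted A -> nm on
#' write and back on read. Molecule identity is stored in the residue
#' number/name columns (`mol_id`, `molecule`).
#'
#' @param frame A `cg_frame`.
#' @param path Optional output path.
#' @return `write_gro()`: the file lines, invisibly; `read_gro()`: a
#'   `cg_frame` (bead metadata limited to what GRO carries).
#' @export
write_gro <- function(frame, path = NULL) {
  n <- nrow(frame$coords)
  lines <- c(sprintf("cgkit frame t= %g ns", frame$time), sprintf("%5d", n))
  if (n) {
    resname <- substr(frame$beads$molecule, 1, 5)
    atname <- if ("bead" %in% names(frame$beads)) {
      substr(frame$beads$bead, 1, 5)
    } else {
      rep("BD", n)
    }
    xyz <- frame$coords * cg_units$ang_to_nm
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      frame$beads$mol_id %% 100000L, resname, atname, seq_len(n) %% 100000L,
      xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f",
    frame$box[1] * cg_units$ang_to_nm, frame$box[2] * cg_units$ang_to_nm,
    frame$box[3] * cg_units$ang_to_nm))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_gro
#' @param x Path to a GRO file or character vector of lines.
#' @export
read_gro <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  tm <- regmatches(lines[1], regexec("t=\\s*([-0-9.eE+]+)", lines[1]))[[1]]
  time <- if (length(tm) == 2L) as.numeric(tm[2]) else 0
  n <- as.integer(trimws(lines[2]))
  if (n > 0) {
    at <- lines[3:(2 + n)]
    mol_id <- as.integer(substr(at, 1, 5))
    molecule <- trimws(substr(at, 6, 10))
    bead <- trimws(substr(at, 11, 15))
    xyz <- cbind(as.numeric(substr(at, 21, 28)),
                 as.numeric(substr(at, 29, 36)),
                 as.numeric(substr(at, 37, 44))) / cg_units$ang_to_nm
  } else {
    mol_id <- integer(); molecule <- character(); bead <- character()
    xyz <- matrix(numeric(), 0, 3)
  }
  boxline <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])
  cg_frame(xyz, tibble::tibble(molecule = molecule, mol_id = mol_id,
                               bead = bead),
           boxline[1:3] / cg_units$ang_to_nm, time)
}

# Bind a topology's beads (with coordinates) into an existing frame
append_molecule <- function(frame, top, coords, mol_id = NULL) {
  b <- top$beads
  b$molecule <- top$molecule
  b$mol_id <- mol_id %||%
    (if (nrow(frame$beads)) max(frame$beads$mol_id) + 1L else 1L)
  cg_frame(rbind(frame$coords, coords),
           dplyr::bind_rows(frame$beads, b), frame$box, frame$time)
}
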