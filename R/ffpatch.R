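#' A minimal nonbonded parameter table
#'
#' Lennard-Jones parameter tables are tibbles with columns `type_a`,
#' `type_b`, `sigma` (A) and `epsilon` (kcal/mol), one row per unordered
#' type pair — the in-memory form of a GROMACS `[ nonbond_params ]` section.
#' This constructor builds a small self/cross table from per-type defaults
#' with Lorentz-Berthelot combination, sufficient as a base set for patching.
#'
#' @param types Character vector of bead type names.
#' @param sigma,epsilon Per-type values, recycled; defaults are
#'   Martini-plausible (4.7 A, 0.8 kcal/mol).
#' @return A nonbonded parameter tibble covering all unordered pairs.
#' @export
nonbond_table <- function(types, sigma = 4.7, epsilon = 0.8) {
  sigma <- rep_len(sigma, length(types))
  epsilon <- rep_len(epsilon, length(types))
  idx <- which(upper.tri(diag(length(types)), diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    type_a = types[idx[, 1]], type_b = types[idx[, 2]],
    sigma = (sigma[idx[, 1]] + sigma[idx[, 2]]) / 2,
    epsilon = sqrt(epsilon[idx[, 1]] * epsilon[idx[, 2]])
  )
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

find_pair <- function(params, a, b) {
  which(pair_key(params$type_a, params$type_b) == pair_key(a, b))
}

#' Scale protein-water interaction strength by bead duplication
#'
#' Martini protein beads are prone to spurious self-aggregation; the standard
#' remedy is to strengthen protein-water interactions. Every protein bead
#' type `X` is duplicated as `WX` with all of `X`'s self and cross LJ rows
#' copied (e.g. `TP1-TP1` duplicated as `WTP1-WTP1` and `WTP1-TP1`), and only
#' the epsilon of the new `WX`-water pair is multiplied by `factor` (default
#' 1.10, i.e. +10%). Sigma is untouched: "interaction strength" is the LJ
#' well depth. Re-applying the same scaling is a no-op.
#'
#' @param params Nonbonded parameter tibble (see [nonbond_table()]).
#' @param protein_types Character vector of protein bead types to duplicate.
#' @param factor Multiplier for epsilon(WX-W); must be > 0.
#' @param water_type Name of the water bead type (default `"W"`).
#' @return The patched parameter tibble.
#' @export
scale_protein_water <- function(params, protein_types, factor = 1.10,
                                water_type = "W") {
  if (factor <= 0) stop("scaling factor must be > 0", call. = FALSE)
  all_types <- unique(c(params$type_a, params$type_b))
  missing <- setdiff(protein_types, all_types)
  if (length(missing)) {
    stop("unknown bead type(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (x in protein_types) {
    wx <- paste0("W", x)
    if (wx %in% unique(c(params$type_a, params$type_b))) next  # idempotent
    rows_x <- params[params$type_a == x | params$type_b == x, ]
    dup <- rows_x
    dup$type_a <- ifelse(rows_x$type_a == x, wx, rows_x$type_a)
    dup$type_b <- ifelse(rows_x$type_b == x, wx, rows_x$type_b)
    # the duplicated self row X-X becomes WX-WX; also keep the WX-X cross row
    self_row <- rows_x[rows_x$type_a == x & rows_x$type_b == x, ]
    if (nrow(self_row)) {
      cross <- self_row
      cross$type_a <- wx; cross$type_b <- x
      dup <- dplyr::bind_rows(dup, cross)
    }
    wrow <- find_pair(dup, wx, water_type)
    dup$epsilon[wrow] <- dup$epsilon[wrow] * factor
    params <- dplyr::bind_rows(params, dup)
  }
  params
}

#' Specification of the Zn-sulfonamide Lennard-Jones cross term
#'
#' The specific recognition of the benzene-sulfonamide ligand by the carbonic
#' anhydrase Zn site is modelled as a single LJ cross term between the Zn
#' bead and the terminal P6 sulfonamide bead: sigma 5 A, epsilon 15 kcal/mol
#' — comparable to the 4-6 A Zn-ligand distance in bound structures and the
#' 10-12 kcal/mol binding free energy of benzene-sulfonamide analogues.
#'
#' @param bead_a,bead_b Bead type names.
#' @param sigma LJ sigma in A (> 0).
#' @param epsilon LJ epsilon in kcal/mol (> 0).
#' @return A `crossterm_spec` list.
#' @export
crossterm_spec <- function(bead_a = "ZN", bead_b = "P6",
                           sigma = 5, epsilon = 15) {
  stopifnot(sigma > 0, epsilon > 0)
  structure(list(bead_a = bead_a, bead_b = bead_b,
                 sigma = sigma, epsilon = epsilon),
            class = "crossterm_spec")
}

#' Add (or override) the Zn-ligand LJ cross term
#'
#' Inserts exactly one `[ nonbond_params ]` override row for the Zn-ligand
#' pair. Applying the identical spec twice leaves a single row unchanged;
#' a conflicting second spec for the same pair is an error.
#'
#' @param params Nonbonded parameter tibble.
#' @param spec A [crossterm_spec()]; the default is the Zn-P6 term
#'   (5 A, 15 kcal/mol).
#' @return The patched parameter tibble.
#' @export
add_zn_ligand_crossterm <- function(params, spec = crossterm_spec()) {
  all_types <- unique(c(params$type_a, params$type_b))
  for (t in c(spec$bead_a, spec$bead_b)) {
    if (!t %in% all_types) {
      stop("bead type '", t, "' is not defined in the parameter set",
           call. = FALSE)
    }
  }
  row <- find_pair(params, spec$bead_a, spec$bead_b)
  if (length(row)) {
    same <- abs(params$sigma[row] - spec$sigma) < 1e-9 &&
            abs(params$epsilon[row] - spec$epsilon) < 1e-9
    if (attr(params, "zn_override_applied", exact = TRUE) %||% FALSE) {
      if (!same) {
        stop("conflicting cross-term override for pair ",
             spec$bead_a, "-", spec$bead_b, call. = FALSE)
      }
      return(params)
    }
    params$sigma[row] <- spec$sigma
    params$epsilon[row] <- spec$epsilon
  } else {
    params <- dplyr::bind_rows(
      params,
      tibble::tibble(type_a = spec$bead_a, type_b = spec$bead_b,
                     sigma = spec$sigma, epsilon = spec$epsilon)
    )
  }
  attr(params, "zn_override_applied") <- TRUE
  params
}

#' Add Zn coordination bonds to a protein topology
#'
#' Models the carbonic anhydrase Zn coordination site: one harmonic bond of
#' length 2.4 A from the Zn bead to the side-chain bead of each coordinating
#' histidine (H93, H95, H188 in bCA-II numbering), and the Zn bead type set
#' to SD (the Martini type used for Ca2+ ions; Martini has no Zn default).
#' The force constant defaults to a stiff 50 kcal/mol/A^2 so that thermal
#' bond-length fluctuation stays far below 2.4 A. Re-application is a no-op.
#'
#' @param protein_top A `cg_topology` whose beads carry a `residue` column;
#'   the Zn bead is identified by `bead == zn_bead`.
#' @param zn_bead Name of the Zn bead (default `"ZN"`).
#' @param residue_ids Coordinating residue labels (default H93, H95, H188).
#' @param distance Coordination bond length in A (default 2.4).
#' @param kb Bond force constant, kcal/mol/A^2.
#' @return The patched `cg_topology` with exactly `length(residue_ids)` new
#'   bonds and the Zn bead typed SD, mass 65.4.
#' @export
add_zn_coordination <- function(protein_top, zn_bead = "ZN",
                                residue_ids = c("H93", "H95", "H188"),
                                distance = 2.4, kb = 50) {
  b <- protein_top$beads
  zn_idx <- which(b$bead == zn_bead)
  if (length(zn_idx) != 1L) {
    stop("protein topology must contain exactly one Zn bead named '",
         zn_bead, "'", call. = FALSE)
  }
  if (!"residue" %in% names(b)) {
    stop("protein topology beads need a 'residue' column", call. = FALSE)
  }
  his_idx <- vapply(residue_ids, function(res) {
    hit <- which(b$residue == res & b$role == "sidechain")
    if (!length(hit)) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(his_idx)) {
    stop("missing coordinating residue(s): ",
         paste(residue_ids[is.na(his_idx)], collapse = ", "), call. = FALSE)
  }
  protein_top$beads$type[zn_idx] <- "SD"
  protein_top$beads$mass[zn_idx] <- 65.4
  existing <- pair_key(protein_top$bonds$i, protein_top$bonds$j)
  for (hi in his_idx) {
    if (pair_key(zn_idx, hi) %in% existing) next  # idempotent
    protein_top$bonds <- dplyr::bind_rows(
      protein_top$bonds,
      tibble::tibble(i = as.integer(min(zn_idx, hi)),
                     j = as.integer(max(zn_idx, hi)),
                     length = distance, kb = kb)
    )
  }
  protein_top
}

#' Write / read a GROMACS-dialect nonbonded parameter section
#'
#' `write_nonbond_params()` emits a `[ nonbond_params ]` table (sigma in nm,
#' epsilon in kJ/mol, funct 1); `read_nonbond_params()` parses one back into
#' the internal A / kcal/mol tibble. Round-tripping recovers sigma and
#' epsilon to better than 1e-6 relative error.
#'
#' @param params Nonbonded parameter tibble.
#' @param path Optional output path.
#' @return `write_nonbond_params()`: file lines, invisibly;
#'   `read_nonbond_params()`: a parameter tibble.
#' @export
write_nonbond_params <- function(params, path = NULL) {
  lines <- c("[ nonbond_params ]", ";  i  j funct sigma_nm epsilon_kJ")
  for (r in seq_len(nrow(params))) {
    lines <- c(lines, sprintf("%-8s %-8s 1 %s %s",
      params$type_a[r], params$type_b[r],
      num(params$sigma[r] * cg_units$ang_to_nm),
      num(params$epsilon[r] * cg_units$kcal_to_kj)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_nonbond_params
#' @param x Path or character vector of lines.
#' @export
read_nonbond_params <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- strip_comment(lines)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*\\[", lines)]
  purrr::map_dfr(lines, function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    tibble::tibble(type_a = f[1], type_b = f[2],
                   sigma = as.numeric(f[4]) / cg_units$ang_to_nm,
                   epsilon = as.numeric(f[5]) / cg_units$kcal_to_kj)
  })
}

#' Minimal synthetic Zn-protein stand-in
#'
#' A small bead cloud shaped like the carbonic anhydrase active site: one Zn
#' bead surrounded by three labelled histidine side-chain beads (plus a few
#' backbone filler beads), so the Zn patching and placement machinery can be
#' exercised without any real protein structure. Clearly synthetic — not a
#' coarse-grained bCA-II model.
#'
#' @param n_filler Number of extra backbone filler beads.
#' @return A `cg_topology` with a `residue` bead column and accompanying
#'   `coords` attribute (N x 3 matrix, A).
#' @export
make_synthetic_zn_protein <- function(n_filler = 6) {
  his <- c("H93", "H95", "H188")
  beads <- dplyr::bind_rows(
    bead_row("ZN", "SQ5", "tiny", charge = 2, role = "ion"),
    purrr::map_dfr(his, function(h) {
      out <- bead_row(paste0("SC_", h), "TC4", "tiny", role = "sidechain")
      out
    }),
    purrr::map_dfr(seq_len(n_filler), function(i) {
      bead_row(paste0("BB", i), "P2", "regular", role = "backbone")
    })
  )
  beads$residue <- c("ZN", his, paste0("G", seq_len(n_filler)))
  beads$monomer <- "PROT"
  beads$monomer_index <- seq_len(nrow(beads))
  # Zn at origin, histidines on a tripod 2.4 A away, filler ring further out
  ang <- 2 * pi * (0:2) / 3
  his_xyz <- cbind(2.4 * cos(ang), 2.4 * sin(ang), 0)
  fil_ang <- 2 * pi * seq_len(n_filler) / n_filler
  fil_xyz <- cbind(7 * cos(fil_ang), 7 * sin(fil_ang), 3)
  coords <- rbind(c(0, 0, 0), his_xyz, fil_xyz)
  bonds <- tibble::tibble(i = integer(), j = integer(),
                          length = double(), kb = double())
  top <- new_cg_topology("SYNPROT", beads, bonds,
                         tibble::tibble(i = integer(), j = integer(),
                                        k = integer(), theta = double(),
                                        ktheta = double()))
  attr(top, "coords") <- coords
  top
}

`%||%` <- function(a, b) if (is.null(a)) b else a
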