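# Self-avoiding-walk conformation for one molecule; returns centered coords (A)
build_conformation <- function(top, rng, min_intra = 2.0, bond_default = 3.5) {
  n <- nrow(top$beads)
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- 0
  if (n == 1L) return(coords)
  parent <- rep(NA_integer_, n)
  blen <- rep(bond_default, n)
  for (r in seq_len(nrow(top$bonds))) {
    i <- top$bonds$i[r]; j <- top$bonds$j[r]
    lo <- min(i, j); hi <- max(i, j)
    if (is.na(parent[hi])) {
      parent[hi] <- lo
      L <- top$bonds$length[r]
      blen[hi] <- if (is.na(L)) bond_default else L
    }
  }
  for (k in 2:n) {
    p <- parent[k]
    if (is.na(p)) p <- k - 1L  # disconnected safety net
    for (try in 1:200) {
      u <- rng$norm(3); u <- u / sqrt(sum(u^2))
      cand <- coords[p, ] + blen[k] * u
      done <- which(!is.na(coords[, 1]))
      d2 <- colSums((t(coords[done, , drop = FALSE]) - cand)^2)
      if (all(d2 >= min_intra^2) || try == 200) { coords[k, ] <- cand; break }
    }
  }
  sweep(coords, 2, colMeans(coords))
}

random_rotation <- function(rng) {
  # QR of a Gaussian matrix gives a Haar-uniform rotation
  m <- matrix(rng$norm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Bounding-sphere prefilter + exact bead check against the frame
placement_clashes <- function(frame, cand, box, min_sep, mol_com, mol_rad) {
  if (!nrow(frame$coords)) return(FALSE)
  st <- attr(frame, "mol_summary")
  if (is.null(st)) {
    st <- frame_mol_summary(frame)
  }
  dcom <- pair_min_dist(matrix(mol_com, 1), st$com, box)[1, ]
  near <- which(dcom < mol_rad + st$rad + min_sep)
  if (!length(near)) return(FALSE)
  sel <- frame$beads$mol_id %in% st$mol_id[near]
  any(pair_min_dist(cand, frame$coords[sel, , drop = FALSE], box) < min_sep)
}

frame_mol_summary <- function(frame) {
  ids <- unique(frame$beads$mol_id)
  com <- matrix(0, length(ids), 3)
  rad <- numeric(length(ids))
  for (k in seq_along(ids)) {
    xyz <- frame$coords[frame$beads$mol_id == ids[k], , drop = FALSE]
    com[k, ] <- colMeans(xyz)
    rad[k] <- sqrt(max(rowSums(sweep(xyz, 2, com[k, ])^2)))
  }
  list(mol_id = ids, com = com, rad = rad)
}

#' Place polymer unimers at random positions in a box
#'
#' Initialises a self-assembly system: `n` chains drawn from the supplied
#' topology set in the given ratio (default 2:1:1:1 across the four standard
#' P1 sequences, largest-remainder apportionment) are given random
#' conformations, random orientations and uniform random positions, subject
#' to every intermolecular bead-bead distance being at least `min_sep` under
#' the periodic minimum image.
#'
#' @param n Number of molecules (>= 0).
#' @param topologies List of `cg_topology` objects (chain types).
#' @param box Length-3 box vector (A), or `NULL` to size the box from a
#'   default dilute concentration of one chain per (35 A)^3.
#' @param min_sep Minimum intermolecular bead separation (A), default 3.5.
#' @param ratio Numeric vector, one weight per topology (default 2:1:1:1
#'   when four topologies are supplied, else uniform).
#' @param seed Integer seed.
#' @param max_retries Placement attempts per molecule before giving up.
#' @return A `cg_frame`.
#' @export
place_unimers <- function(n, topologies, box = NULL, min_sep = 3.5,
                          ratio = NULL, seed = 1L, max_retries = 1e4) {
  stopifnot(n >= 0)
  if (is.null(box)) box <- rep(max(60, ceiling(n^(1/3)) * 35), 3)
  if (n == 0L) return(empty_frame(box))
  if (is.null(ratio)) {
    ratio <- if (length(topologies) == 4L) c(2, 1, 1, 1)
             else rep(1, length(topologies))
  }
  stopifnot(length(ratio) == length(topologies))
  # largest-remainder apportionment of n molecules over the chain types
  quota <- n * ratio / sum(ratio)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(quota - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  # feasibility bound: occupied volume must fit loosely in the box
  rng <- local_rng(seed)
  type_of <- rep(seq_along(topologies), counts)
  type_of <- type_of[rng$sample(length(type_of))]
  frame <- empty_frame(box)
  confs <- lapply(topologies, build_conformation, rng = rng)
  occ <- sum(vapply(seq_along(topologies), function(k) {
    r <- sqrt(max(rowSums(confs[[k]]^2))) + min_sep
    counts[k] * 4 / 3 * pi * r^3
  }, numeric(1)))
  if (occ > 2 * prod(box)) {
    stop("packing infeasible: ", n, " molecules cannot fit a box of ",
         paste(round(box), collapse = " x "),
         " A at min_sep ", min_sep, "; use a larger box", call. = FALSE)
  }
  for (m in seq_len(n)) {
    top <- topologies[[type_of[m]]]
    base <- confs[[type_of[m]]]
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      rot <- random_rotation(rng)
      cand <- base %*% t(rot)
      com <- rng$unif(3) * box
      cand <- sweep(cand, 2, com, "+")
      rad <- sqrt(max(rowSums(sweep(cand, 2, com)^2)))
      if (!placement_clashes(frame, cand, box, min_sep, com, rad)) {
        frame <- append_molecule(frame, top, cand)
        attr(frame, "mol_summary") <- NULL
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("failed to place molecule ", m, " after ", max_retries,
           " attempts; use a larger box", call. = FALSE)
    }
    attr(frame, "mol_summary") <- frame_mol_summary(frame)
  }
  attr(frame, "mol_summary") <- NULL
  attr(frame, "chain_type") <- type_of
  frame
}

#' Insert cargo molecules into an existing frame
#'
#' Adds `n` copies of a cargo topology (typically DiI) at random non-clashing
#' positions, preserving all existing molecules. Insertion points are drawn
#' outside the bounding sphere of the existing assembly — cargo starts in the
#' bulk, not pre-embedded.
#'
#' @param frame A `cg_frame` (e.g. a preformed aggregate).
#' @param cargo_top A `cg_topology` for the cargo molecule.
#' @param n Number of copies (>= 0).
#' @param min_sep Minimum separation to existing beads (A).
#' @param seed Integer seed.
#' @param max_retries Attempts per molecule.
#' @return The augmented `cg_frame`.
#' @export
insert_cargo <- function(frame, cargo_top, n, min_sep = 3.5, seed = 1L,
                         max_retries = 1e4) {
  stopifnot(n >= 0)
  if (n == 0L) return(frame)
  rng <- local_rng(seed)
  base <- build_conformation(cargo_top, rng)
  box <- frame$box
  agg_com <- colMeans(frame$coords)
  agg_rad <- sqrt(max(rowSums(sweep(frame$coords, 2, agg_com)^2)))
  for (m in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      rot <- random_rotation(rng)
      cand <- base %*% t(rot)
      com <- rng$unif(3) * box
      # keep the cargo outside the assembly's bounding sphere initially
      if (pair_min_dist(matrix(com, 1), matrix(agg_com, 1), box)[1, 1] <=
          agg_rad + min_sep) next
      cand <- sweep(cand, 2, com, "+")
      if (!any(pair_min_dist(cand, frame$coords, box) < min_sep)) {
        frame <- append_molecule(frame, cargo_top, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("failed to insert cargo molecule ", m, " after ", max_retries,
           " attempts; use a larger box", call. = FALSE)
    }
  }
  frame
}

#' Place binding proteins near exposed surface ligands
#'
#' Positions `n` copies of a protein so that each protein's Zn bead lies
#' within the stated distance window (default 5-10 A) of a distinct exposed
#' ligand-anchor bead (the benzene-sulfonamide bead of an M3 side chain),
#' without clashing with assembly beads. "Exposed" means the anchor bead's
#' SASA in the frame exceeds `exposure_min` (default 10 A^2).
#'
#' @param frame A `cg_frame` containing M3 ligand-anchor beads
#'   (`role == "ligand_anchor"`).
#' @param protein_top A protein `cg_topology` with a `coords` attribute
#'   (N x 3, A) giving its reference conformation, containing one Zn bead.
#' @param n Number of proteins to place.
#' @param window Zn-anchor distance window in A, default `c(5, 10)`.
#' @param min_sep Minimum protein-assembly bead separation (A).
#' @param exposure_min SASA threshold (A^2) defining an exposed anchor.
#' @param zn_bead Name of the Zn bead in `protein_top`.
#' @param seed Integer seed.
#' @param max_retries Attempts per protein.
#' @return The augmented `cg_frame`.
#' @export
place_proteins_near_ligands <- function(frame, protein_top, n,
                                        window = c(5, 10), min_sep = 3.5,
                                        exposure_min = 10, zn_bead = "ZN",
                                        seed = 1L, max_retries = 1e4) {
  stopifnot(n >= 0)
  if (n == 0L) return(frame)
  pcoords <- attr(protein_top, "coords")
  if (is.null(pcoords)) {
    stop("protein topology needs a 'coords' attribute", call. = FALSE)
  }
  zn_i <- which(protein_top$beads$bead == zn_bead)
  if (length(zn_i) != 1L) {
    stop("protein topology must contain exactly one '", zn_bead, "' bead",
         call. = FALSE)
  }
  anchors <- which(frame$beads$role == "ligand_anchor")
  if (length(anchors)) {
    sasa <- vapply(anchors, function(a) bead_sasa(frame, target = a), numeric(1))
    anchors <- anchors[sasa > exposure_min]
  }
  if (length(anchors) < n) {
    stop("only ", length(anchors), " exposed ligand anchor bead(s) ",
         "available for ", n, " protein(s)", call. = FALSE)
  }
  rng <- local_rng(seed)
  anchors <- anchors[rng$sample(length(anchors), n)]
  box <- frame$box
  agg_com <- colMeans(frame$coords)
  for (m in seq_len(n)) {
    a_xyz <- frame$coords[anchors[m], ]
    out_dir <- a_xyz - agg_com
    if (sum(out_dir^2) < 1e-12) out_dir <- c(1, 0, 0)
    out_dir <- out_dir / sqrt(sum(out_dir^2))
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      u <- rng$unif(1, window[1], window[2])
      jit <- rng$norm(3) * 0.3
      dir <- out_dir + jit; dir <- dir / sqrt(sum(dir^2))
      zn_target <- a_xyz + u * dir
      rot <- random_rotation(rng)
      cand <- sweep(pcoords, 2, pcoords[zn_i, ]) %*% t(rot)
      cand <- sweep(cand, 2, zn_target, "+")
      # the Zn bead itself sits inside the window by construction; the rest
      # of the protein must clear the assembly
      others <- cand[-zn_i, , drop = FALSE]
      if (!any(pair_min_dist(others, frame$coords, box) < min_sep)) {
        frame <- append_molecule(frame, protein_top, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("failed to place protein ", m, " after ", max_retries,
           " attempts", call. = FALSE)
    }
  }
  frame
}

#' Solvation and counter-ion bookkeeping
#'
#' The kit prepares inputs for an MD engine rather than equilibrating them,
#' so solvent is accounted for by number: the free volume of the box (total
#' minus a per-bead excluded volume) is filled with CG water beads at the
#' standard density of 8.35 beads/nm^3 (four waters per bead), and
#' counter-ions are added to neutralise the net solute charge exactly.
#'
#' @param frame A `cg_frame`.
#' @return A tibble with `n_water`, `n_cl`, `n_na`, `net_charge` (the system
#'   net charge after neutralisation, always 0).
#' @export
solvate_count <- function(frame) {
  vol <- prod(frame$box)
  bead_vol <- 54  # (4/3) pi (2.35 A)^3, regular-bead excluded volume
  free <- max(0, vol - nrow(frame$coords) * bead_vol)
  n_w <- floor(free * 8.35e-3)
  q <- if (nrow(frame$beads)) sum(frame$beads$charge) else 0
  n_cl <- max(0, round(q))
  n_na <- max(0, -round(q))
  tibble::tibble(n_water = n_w, n_cl = n_cl, n_na = n_na,
                 net_charge = q - n_cl + n_na)
}

#' Write a GROMACS system topology (TOP dialect)
#'
#' @param frame A `cg_frame`.
#' @param includes Character vector of ITP include paths to reference.
#' @param path Optional output path.
#' @param name System title.
#' @return File lines, invisibly.
#' @export
write_system_top <- function(frame, includes = character(), path = NULL,
                             name = "cgkit system") {
  inv <- dplyr::count(dplyr::distinct(frame$beads, .data$mol_id,
                                      .data$molecule), .data$molecule)
  solv <- solvate_count(frame)
  lines <- c(
    sprintf('#include "%s"', includes),
    "", "[ system ]", name, "", "[ molecules ]",
    sprintf("%-10s %6d", inv$molecule, inv$n),
    sprintf("%-10s %6d", "W", solv$n_water)
  )
  if (solv$n_cl > 0) lines <- c(lines, sprintf("%-10s %6d", "CL", solv$n_cl))
  if (solv$n_na > 0) lines <- c(lines, sprintf("%-10s %6d", "NA", solv$n_na))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Run-parameter sets for the simulation protocol
#'
#' Returns the fixed protocol settings for one of the three phases:
#' \describe{
#'   \item{minimize}{5000 steps of steepest descent.}
#'   \item{equilibrate}{200 ps with heavy beads position-restrained at
#'     0.1 kcal/mol/A^2 (41.84 kJ/mol/nm^2).}
#'   \item{production}{unrestrained dynamics.}
#' }
#' Common to all dynamics phases: 10 fs leapfrog timestep, Verlet neighbour
#' list updated every 20 steps, 1.1 nm LJ cutoff with potential shift,
#' reaction-field electrostatics with relative permittivity 15 and 1.1 nm
#' cutoff, Berendsen thermostat at 303 K (tau 0.5 ps), Parrinello-Rahman
#' barostat at 1 bar (compressibility 4.5e-5 bar^-1, tau 4.0 ps).
#'
#' @param phase One of `"minimize"`, `"equilibrate"`, `"production"`.
#' @return A `run_parameters` list.
#' @export
emit_run_parameters <- function(phase = c("production", "minimize",
                                          "equilibrate")) {
  phase <- match.arg(phase)
  rp <- list(
    phase = phase,
    integrator = if (phase == "minimize") "steep" else "md",
    nsteps = switch(phase, minimize = 5000L, equilibrate = 20000L,
                    production = 100000000L),
    timestep_fs = 10,
    nstlist = 20L,
    cutoff_scheme = "Verlet",
    vdw_cutoff_nm = 1.1,
    vdw_modifier = "Potential-shift-Verlet",
    coulomb_type = "Reaction-Field",
    coulomb_cutoff_nm = 1.1,
    epsilon_r = 15,
    tcoupl = "berendsen",
    ref_t_K = 303,
    tau_t_ps = 0.5,
    pcoupl = "parrinello-rahman",
    ref_p_bar = 1,
    compressibility_bar = 4.5e-5,
    tau_p_ps = 4.0,
    posres_fc_kcal_A2 = if (phase == "equilibrate") 0.1 else NULL
  )
  structure(rp, class = "run_parameters")
}

#' @export
print.run_parameters <- function(x, ...) {
  cat("<run_parameters> phase=", x$phase, ", dt=", x$timestep_fs,
      " fs, cutoffs=", x$vdw_cutoff_nm, " nm, eps_r=", x$epsilon_r,
      ", T=", x$ref_t_K, " K, P=", x$ref_p_bar, " bar\n", sep = "")
  invisible(x)
}

#' Write run parameters as a GROMACS MDP file
#'
#' @param rp A `run_parameters` object from [emit_run_parameters()].
#' @param path Optional output path.
#' @return File lines, invisibly.
#' @export
write_mdp <- function(rp, path = NULL) {
  lines <- c(
    sprintf("; cgkit run parameters, phase = %s", rp$phase),
    sprintf("integrator               = %s", rp$integrator),
    sprintf("nsteps                   = %d", rp$nsteps)
  )
  if (rp$integrator == "md") {
    lines <- c(lines,
      sprintf("dt                       = %g", rp$timestep_fs * cg_units$fs_to_ps))
  } else {
    lines <- c(lines, "emtol                    = 100")
  }
  lines <- c(lines,
    sprintf("cutoff-scheme            = %s", rp$cutoff_scheme),
    sprintf("nstlist                  = %d", rp$nstlist),
    sprintf("vdw-type                 = cutoff"),
    sprintf("vdw-modifier             = %s", rp$vdw_modifier),
    sprintf("rvdw                     = %g", rp$vdw_cutoff_nm),
    sprintf("coulombtype              = %s", rp$coulomb_type),
    sprintf("rcoulomb                 = %g", rp$coulomb_cutoff_nm),
    sprintf("epsilon_r                = %g", rp$epsilon_r)
  )
  if (rp$integrator == "md") {
    lines <- c(lines,
      sprintf("tcoupl                   = %s", rp$tcoupl),
      sprintf("ref_t                    = %g", rp$ref_t_K),
      sprintf("tau_t                    = %g", rp$tau_t_ps),
      "tc-grps                  = System",
      sprintf("pcoupl                   = %s", rp$pcoupl),
      sprintf("ref_p                    = %g", rp$ref_p_bar),
      sprintf("compressibility          = %g", rp$compressibility_bar),
      sprintf("tau_p                    = %g", rp$tau_p_ps)
    )
  }
  if (!is.null(rp$posres_fc_kcal_A2)) {
    lines <- c(lines,
      "define                   = -DPOSRES",
      sprintf("; position restraint fc  = %g kJ/mol/nm^2 (%g kcal/mol/A^2)",
              kcal_A2_to_kJ_nm2(rp$posres_fc_kcal_A2), rp$posres_fc_kcal_A2))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
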