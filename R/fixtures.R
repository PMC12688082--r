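# Fixtures are geometric stand-ins for the structural motifs seen in the
# assembly simulations (layered micelles, multicore aggregates, dispersed
# unimers, buried/exposed cargo, stepwise disassembly). They reuse the real
# bead typing from the topology builders so clustering entities and SASA
# radii resolve naturally, but make no claim of thermodynamic realism.

place_monomer_beads <- function(sp, u, rng, radii) {
  # returns a nrow(beads) x 3 matrix for one monomer, on direction u
  n <- nrow(sp$beads)
  out <- matrix(0, n, 3)
  jit <- function(s = 1.2) rng$norm(3) * s
  core <- radii[1]; shell <- radii[2]; surface <- radii[3]
  if (sp$label == "M1") {
    cdir <- rng$norm(3); cdir <- cdir / sqrt(sum(cdir^2))
    cr <- rng$unif(1, 0, core - 3)  # linear in r: density peaked at centre
    cc <- cdir * cr
    out[1, ] <- u * rng$unif(1, core + 1, shell - 1)   # BB in shell layer
    for (k in 2:n) out[k, ] <- cc + jit(0.8)
  } else if (sp$label == "M2") {
    out[1, ] <- u * rng$unif(1, core + 1, shell - 1)
    cdir <- rng$norm(3); cdir <- cdir / sqrt(sum(cdir^2))
    cc <- cdir * rng$unif(1, 0, shell - 1)             # mixed core + shell
    for (k in 2:n) out[k, ] <- cc + jit(0.8)
  } else {  # M3: OEG in shell, ring/anchor near surface, SUF on the surface
    out[1, ] <- u * rng$unif(1, core + 1, shell - 1)
    r_seq <- c(NA, seq(core + 1, surface - 4, length.out = n - 3),
               surface - 2, surface)
    for (k in 2:n) {
      rk <- r_seq[k]
      out[k, ] <- u * rk + if (k < n - 1) jit(0.6) else c(0, 0, 0)
    }
  }
  out
}

#' Synthetic layered micelle
#'
#' Builds one micelle with the three-layer organisation the density profiles
#' report: M1 side chains buried in a hydrophobic core, backbones in a
#' surrounding shell, M3 side chains (benzene-sulfonamide anchor and terminal
#' sulfonamide bead outermost) exposed on the surface, M2 side chains mixed
#' through core and shell. Default layer radii 15 / 22 / 27 A for a
#' 10-polymer micelle, consistent with the ~5 nm micelle scale.
#'
#' @param n_polymers Number of P1 chains.
#' @param radii Strictly increasing layer radii `c(core, shell, surface)` (A).
#' @param seed Integer seed (same seed, identical frame).
#' @param box Box vector (A); default `4 * surface` cube.
#' @param center Micelle centre (A); default box centre.
#' @param time Frame timestamp (ns).
#' @param chains Optional list of `chain_spec` objects to use instead of a
#'   seeded draw (e.g. to fix the exact M1 count per core).
#' @return A `cg_frame`.
#' @export
make_micelle <- function(n_polymers = 10, radii = c(15, 22, 27), seed = 1L,
                         box = NULL, center = NULL, time = 0, chains = NULL) {
  if (any(diff(radii) <= 0)) {
    stop("layer radii must be strictly increasing (core < shell < surface)",
         call. = FALSE)
  }
  if (is.null(box)) box <- rep(4 * radii[3], 3)
  if (is.null(center)) center <- box / 2
  rng <- local_rng(seed)
  if (is.null(chains)) chains <- generate_chain_set(n_polymers, seed = seed)
  frame <- empty_frame(box, time)
  for (ch in chains) {
    top <- build_polymer_topology(ch)
    xyz <- matrix(0, nrow(top$beads), 3)
    off <- 0L
    for (lab in ch$sequence) {
      sp <- monomer_spec(lab)
      u <- rng$norm(3); u <- u / sqrt(sum(u^2))
      xyz[off + seq_len(nrow(sp$beads)), ] <-
        place_monomer_beads(sp, u, rng, radii)
      off <- off + nrow(sp$beads)
    }
    frame <- append_molecule(frame, top, sweep(xyz, 2, center, "+"))
  }
  frame
}

#' Micelle pseudo-trajectory
#'
#' Independent micelle realisations (one per frame, seeds derived from
#' `seed`) with timestamps 1..n ns, for profile averaging.
#'
#' @param n_frames Number of frames.
#' @inheritParams make_micelle
#' @return A `cg_trajectory`.
#' @export
make_micelle_trajectory <- function(n_frames = 20, n_polymers = 10,
                                    radii = c(15, 22, 27), seed = 1L) {
  cg_trajectory(lapply(seq_len(n_frames), function(i) {
    make_micelle(n_polymers, radii, seed = seed * 1000L + i, time = i)
  }))
}

# bridge of synthetic M1 side-chain entities between two points
m1_bridge_beads <- function(from, to, rng, station_step = 2.5) {
  v <- to - from
  L <- sqrt(sum(v^2)); v <- v / L
  perp <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  perp <- perp - sum(perp * v) * v; perp <- perp / sqrt(sum(perp^2))
  perp2 <- c(v[2] * perp[3] - v[3] * perp[2],
             v[3] * perp[1] - v[1] * perp[3],
             v[1] * perp[2] - v[2] * perp[1])
  stations <- seq(0, L, by = station_step)
  xyz <- list(); ent <- integer()
  e <- 0L
  for (s in stations) {
    base <- from + s * v
    for (k in 0:2) {  # three entities per station -> every entity is core
      e <- e + 1L
      c0 <- base + 2 * (cos(2 * pi * k / 3) * perp + sin(2 * pi * k / 3) * perp2)
      pts <- sweep(matrix(rng$norm(9) * 0.5, 3, 3), 2, c0, "+")
      xyz[[e]] <- pts
      ent <- c(ent, rep(e, 3))
    }
  }
  list(coords = do.call(rbind, xyz), entity = ent)
}

#' Synthetic multicore aggregate
#'
#' Packs micelles in a row with interpenetrating hydrophilic shells (centre
#' spacing defaulting to core radius + shell radius, the partial-merging seen
#' in mature aggregates), so peptide-level clustering sees one aggregate
#' while the hydrophobic M1 cores stay separated by more than the clustering
#' eps. With `bridged = TRUE`, dense chains of synthetic M1 side-chain
#' entities connect neighbouring cores at the interfaces, merging the M1
#' clusters.
#'
#' @param n_micelles Number of micelle subunits.
#' @param core_sizes Polymers per micelle (recycled to `n_micelles`).
#' @param packing Centre-to-centre spacing (A); default `radii[1] + radii[2]`.
#' @param radii Layer radii passed to [make_micelle()].
#' @param bridged Bridge neighbouring cores with M1 side chains.
#' @param seed Integer seed.
#' @param chain_sets Optional list of chain-spec lists, one per micelle,
#'   forwarded to [make_micelle()].
#' @return A `cg_frame`.
#' @export
make_multicore_aggregate <- function(n_micelles = 6, core_sizes = 10,
                                     packing = NULL, radii = c(15, 22, 27),
                                     bridged = FALSE, seed = 1L,
                                     chain_sets = NULL) {
  if (is.null(packing)) packing <- radii[1] + radii[2]
  core_sizes <- rep_len(core_sizes, n_micelles)
  rng <- local_rng(seed + 7L)
  span <- (n_micelles - 1) * packing
  box <- c(span + 8 * radii[3], 8 * radii[3], 8 * radii[3])
  frame <- empty_frame(box)
  centers <- matrix(0, n_micelles, 3)
  for (m in seq_len(n_micelles)) {
    centers[m, ] <- c(box[1] / 2 - span / 2 + (m - 1) * packing,
                      box[2] / 2, box[3] / 2)
    sub <- make_micelle(core_sizes[m], radii, seed = seed * 100L + m,
                        box = box, center = centers[m, ],
                        chains = if (!is.null(chain_sets)) chain_sets[[m]])
    b <- sub$beads
    b$mol_id <- b$mol_id +
      (if (nrow(frame$beads)) max(frame$beads$mol_id) else 0L)
    frame <- cg_frame(rbind(frame$coords, sub$coords),
                      dplyr::bind_rows(frame$beads, b), box, frame$time)
  }
  if (bridged && n_micelles > 1) {
    for (m in seq_len(n_micelles - 1L)) {
      a <- centers[m, ]; b <- centers[m + 1L, ]
      v <- (b - a) / sqrt(sum((b - a)^2))
      br <- m1_bridge_beads(a + v * (radii[1] - 2), b - v * (radii[1] - 2), rng)
      nb <- nrow(br$coords)
      beads <- tibble::tibble(
        bead = rep(c("EST", "SC1", "SC2"), nb / 3),
        type = rep(c("P2", "C1", "C1"), nb / 3),
        size_class = rep(c("small", "regular", "regular"), nb / 3),
        charge = 0, mass = rep(c(54, 72, 72), nb / 3),
        heavy_atoms = rep(c(3L, 4L, 4L), nb / 3),
        role = "sidechain", monomer = "M1", monomer_index = br$entity,
        molecule = "M1BRIDGE",
        mol_id = max(frame$beads$mol_id) + 1L
      )
      frame <- cg_frame(rbind(frame$coords, br$coords),
                        dplyr::bind_rows(frame$beads, beads), box, frame$time)
    }
  }
  frame
}

#' Fully dispersed unimer fixture
#'
#' Compact polymer blobs on a cubic lattice with spacing large enough that
#' every intermolecular entity distance exceeds the clustering eps: the
#' no-cluster, all-noise reference state.
#'
#' @param n Number of unimers.
#' @param spacing Lattice spacing (A), default 30.
#' @param blob_radius Radius of each unimer blob (A), default 5.
#' @param seed Integer seed.
#' @return A `cg_frame`.
#' @export
make_dispersed <- function(n = 20, spacing = 30, blob_radius = 5, seed = 1L) {
  rng <- local_rng(seed)
  chains <- generate_chain_set(n, seed = seed)
  side <- ceiling(n^(1/3))
  box <- rep(side * spacing, 3)
  frame <- empty_frame(box)
  k <- 0L
  for (ch in chains) {
    top <- build_polymer_topology(ch)
    ix <- k %% side; iy <- (k %/% side) %% side; iz <- k %/% (side^2)
    cc <- (c(ix, iy, iz) + 0.5) * spacing
    nb <- nrow(top$beads)
    u <- matrix(rng$norm(3 * nb), nb, 3)
    u <- u / sqrt(rowSums(u^2)) * rng$unif(nb, 0, blob_radius)
    frame <- append_molecule(frame, top, sweep(u, 2, cc, "+"))
    k <- k + 1L
  }
  frame
}

#' Stepwise-disassembly pseudo-trajectory
#'
#' Emits frames in which whole micelle units detach from a multicore
#' aggregate one step at a time, so the largest polymer cluster follows
#' `steps` exactly (e.g. 80 -> 60 -> 40 -> 20). Detached micelles are moved
#' far from the aggregate and from each other (gaps of tens of A, well beyond
#' the 8 A clustering eps). With `protein_bound = TRUE`, one synthetic
#' Zn-protein stand-in is attached per micelle with its Zn bead placed within
#' the 5-10 A window of the micelle's terminal sulfonamide ligand bead.
#'
#' @param steps Largest-aggregate polymer counts per frame, each a multiple
#'   of `micelle_size`, non-increasing.
#' @param micelle_size Polymers per micelle unit (default 10).
#' @param radii Micelle layer radii (A).
#' @param protein_bound Attach synthetic Zn proteins at ligand sites.
#' @param seed Integer seed.
#' @return A `cg_trajectory` with one frame per step (timestamps 0, 1, ... ns).
#' @export
make_disassembly_series <- function(steps = c(80, 60, 40, 20),
                                    micelle_size = 10, radii = c(15, 22, 27),
                                    protein_bound = FALSE, seed = 1L) {
  if (any(steps %% micelle_size != 0)) {
    stop("every step must be a multiple of micelle_size", call. = FALSE)
  }
  if (any(diff(steps) > 0)) stop("steps must be non-increasing", call. = FALSE)
  n_mic <- steps[1] %/% micelle_size
  packing <- radii[1] + radii[2]
  span <- (n_mic - 1) * packing
  n_det_max <- n_mic - min(steps) %/% micelle_size
  box <- c(span + 8 * radii[3],
           200 + 100 * n_det_max,
           8 * radii[3])
  rng <- local_rng(seed)
  micelles <- lapply(seq_len(n_mic), function(m) {
    center <- c(box[1] / 2 - span / 2 + (m - 1) * packing, 100, box[3] / 2)
    make_micelle(micelle_size, radii, seed = seed * 100L + m, box = box,
                 center = center)
  })
  protein <- if (protein_bound) make_synthetic_zn_protein() else NULL
  frames <- lapply(seq_along(steps), function(t) {
    keep <- steps[t] %/% micelle_size
    frame <- empty_frame(box, time = t - 1)
    for (m in seq_len(n_mic)) {
      sub <- micelles[[m]]
      shift <- if (m <= keep) c(0, 0, 0) else c(0, 100 + 100 * (m - keep), 0)
      xyz <- sweep(sub$coords, 2, shift, "+")
      b <- sub$beads
      b$mol_id <- b$mol_id + (m - 1L) * micelle_size
      if (protein_bound) {
        # attach one protein at this micelle's outermost ligand bead
        suf <- which(b$bead == "SUF")[1]
        center <- colMeans(xyz)
        a_xyz <- xyz[suf, ]
        out_dir <- a_xyz - center; out_dir <- out_dir / sqrt(sum(out_dir^2))
        d <- rng$unif(1, 6, 9)
        zn_target <- a_xyz + d * out_dir
        pc <- attr(protein, "coords")
        zn_i <- which(protein$beads$bead == "ZN")
        pxyz <- sweep(sweep(pc, 2, pc[zn_i, ]), 2, zn_target, "+")
        pb <- protein$beads
        pb$molecule <- protein$molecule
        pb$mol_id <- n_mic * micelle_size + m
        xyz <- rbind(xyz, pxyz)
        b <- dplyr::bind_rows(b, pb)
      }
      frame <- cg_frame(rbind(frame$coords, xyz),
                        dplyr::bind_rows(frame$beads, b), box, frame$time)
    }
    # re-number molecule ids uniquely across micelles
    frame
  })
  cg_trajectory(frames)
}

#' Archetypal point clouds for shape-metric tests
#'
#' Generates coordinate sets whose gyration tensors have exactly known
#' structure:
#' \describe{
#'   \item{prolate}{symmetric shells of points on the axes with the z axis
#'     stretched by `axis_ratio`: eigenvalues exactly (s, s, c) with c > s,
#'     so prolateness is exactly +1.}
#'   \item{oblate}{z axis compressed by `axis_ratio`: eigenvalues (c, s, s)
#'     with c < s, prolateness exactly -1.}
#'   \item{line}{collinear points: two zero eigenvalues, asphericity exactly 1.}
#'   \item{sphere}{points uniform on a sphere: asphericity -> 0 as n grows.}
#' }
#'
#' @param archetype One of `"sphere"`, `"prolate"`, `"oblate"`, `"line"`.
#' @param n Approximate number of points (rounded up to a multiple of 6 for
#'   the symmetric archetypes).
#' @param axis_ratio Long/short (or short/long) axis ratio, default 3.
#' @param seed Integer seed.
#' @param scale Overall length scale (A), default 10.
#' @return An N x 3 coordinate matrix.
#' @export
make_shape_cloud <- function(archetype = c("sphere", "prolate", "oblate",
                                           "line"),
                             n = 60, axis_ratio = 3, seed = 1L, scale = 10) {
  archetype <- match.arg(archetype)
  rng <- local_rng(seed)
  if (archetype == "sphere") {
    u <- matrix(rng$norm(3 * n), n, 3)
    return(u / sqrt(rowSums(u^2)) * scale)
  }
  if (archetype == "line") {
    t <- rng$unif(n, -1, 1) * scale
    dir <- rng$norm(3); dir <- dir / sqrt(sum(dir^2))
    return(outer(t, dir))
  }
  m <- ceiling(n / 6)
  a <- rng$unif(m, 0.5, 1) * scale
  cc <- if (archetype == "prolate") a * axis_ratio else a / axis_ratio
  pts <- lapply(seq_len(m), function(i) {
    rbind(c(a[i], 0, 0), c(-a[i], 0, 0),
          c(0, a[i], 0), c(0, -a[i], 0),
          c(0, 0, cc[i]), c(0, 0, -cc[i]))
  })
  do.call(rbind, pts)
}

# simple-cubic occluder lattice within a shell around given beads
occluder_lattice <- function(around, inner = 3.0, outer = 9.5, spacing = 3.0,
                             exclude_near = NULL, exclude_dist = 5) {
  lo <- apply(around, 2, min) - outer
  hi <- apply(around, 2, max) + outer
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  colnames(grid) <- NULL
  dmin <- rep(Inf, nrow(grid))
  for (i in seq_len(nrow(around))) {
    dmin <- pmin(dmin, sqrt(rowSums(sweep(grid, 2, around[i, ])^2)))
  }
  keep <- dmin >= inner & dmin <= outer
  if (!is.null(exclude_near)) {
    dex <- rep(Inf, nrow(grid))
    for (i in seq_len(nrow(exclude_near))) {
      dex <- pmin(dex, sqrt(rowSums(sweep(grid, 2, exclude_near[i, ])^2)))
    }
    keep <- keep & dex >= exclude_dist
  }
  grid[keep, , drop = FALSE]
}

dii_reference_coords <- function() {
  # fixed DiI geometry: head in the z = 6 plane, two tails hanging along -z
  head <- rbind(
    c(-3.0, 0.0, 6.0),   # HN1
    c(-5.5, 1.5, 6.5),   # RA1
    c(-8.0, 2.5, 7.0),   # RA2
    c( 0.0, 0.0, 6.0),   # LNK
    c( 3.0, 0.0, 6.0),   # HN2
    c( 5.5, 1.5, 6.5),   # RB1
    c( 8.0, 2.5, 7.0)    # RB2
  )
  tail_a <- cbind(-2, 0, seq(-2, -12.5, length.out = 4))
  tail_b <- cbind( 2, 0, seq(-2, -12.5, length.out = 4))
  rbind(head, tail_a, tail_b)
}

#' Buried- and exposed-cargo fixtures
#'
#' `"buried"`: the whole DiI molecule is enclosed in a watertight close-packed
#' shell of M1-type beads, so the headgroup SASA drops below 1 A^2 — the
#' fully encapsulated state. `"exposed"`: only the hydrophobic tails are
#' buried in a small M1 cluster (the four-to-five-polymer remnant state) while
#' the headgroup faces solvent, so head SASA is in the hundreds of A^2 and
#' tail SASA is ~0.
#'
#' @param state `"buried"` or `"exposed"`.
#' @param seed Integer seed (jitters occluder positions reproducibly).
#' @param variant Model variant for the DiI topology.
#' @return A `cg_frame` containing one DiI molecule (head beads have
#'   `role == "head"`) plus the M1 occluder shell (`molecule == "M1SHELL"`).
#' @export
make_cargo_states <- function(state = c("buried", "exposed"), seed = 1L,
                              variant = "nonstandard") {
  state <- match.arg(state)
  rng <- local_rng(seed)
  dii <- build_dii_topology(variant)
  xyz <- dii_reference_coords()
  box <- rep(120, 3)
  center <- box / 2
  xyz <- sweep(xyz, 2, center, "+")
  frame <- empty_frame(box)
  frame <- append_molecule(frame, dii, xyz)
  head_idx <- which(dii$beads$role == "head")
  tail_idx <- which(dii$beads$role == "tail")
  occ <- if (state == "buried") {
    occluder_lattice(xyz, inner = 3.0, outer = 9.5, spacing = 2.9)
  } else {
    occluder_lattice(xyz[tail_idx, , drop = FALSE], inner = 3.0, outer = 9.5,
                     spacing = 2.9,
                     exclude_near = xyz[head_idx, , drop = FALSE],
                     exclude_dist = 5.5)
  }
  occ <- occ + matrix(rng$norm(length(occ)) * 0.15, nrow(occ), 3)
  shell <- tibble::tibble(
    bead = "SC1", type = "C1", size_class = "regular", charge = 0, mass = 72,
    heavy_atoms = 4L, role = "sidechain", monomer = "M1",
    monomer_index = seq_len(nrow(occ)), molecule = "M1SHELL",
    mol_id = max(frame$beads$mol_id) + 1L
  )
  cg_frame(rbind(frame$coords, occ), dplyr::bind_rows(frame$beads, shell),
           box, 0)
}
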