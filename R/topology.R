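new_cg_topology <- function(molecule, beads, bonds, angles, dihedrals = NULL,
                            exclusions = NULL, variant = "nonstandard") {
  if (is.null(dihedrals)) {
    dihedrals <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                                l = integer(), phi = double(), kphi = double(),
                                mult = integer())
  }
  if (is.null(exclusions)) {
    exclusions <- tibble::tibble(i = integer(), j = integer())
  }
  structure(
    list(molecule = molecule, beads = beads, bonds = bonds, angles = angles,
         dihedrals = dihedrals, exclusions = exclusions, variant = variant),
    class = "cg_topology"
  )
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("<cg_topology> ", x$molecule, " (", x$variant, "): ",
      nrow(x$beads), " beads, ", nrow(x$bonds), " bonds, ",
      nrow(x$angles), " angles, ", nrow(x$dihedrals), " dihedrals; charge ",
      sprintf("%+.1f", sum(x$beads$charge)), "\n", sep = "")
  invisible(x)
}

#' Total charge of a topology
#' @param top A `cg_topology`.
#' @return Numeric scalar, sum of bead partial charges.
#' @export
total_charge <- function(top) sum(top$beads$charge)

check_topology <- function(top) {
  n <- nrow(top$beads)
  ref <- c(top$bonds$i, top$bonds$j, top$angles$i, top$angles$j, top$angles$k,
           top$dihedrals$i, top$dihedrals$j, top$dihedrals$k, top$dihedrals$l)
  if (length(ref) && (min(ref) < 1L || max(ref) > n)) {
    stop("bonded term references a bead outside 1..", n, call. = FALSE)
  }
  invisible(top)
}

empty_parameter_slots <- function(top) {
  sum(is.na(top$bonds$length)) + sum(is.na(top$bonds$kb)) +
    sum(is.na(top$angles$theta)) + sum(is.na(top$angles$ktheta)) +
    sum(is.na(top$dihedrals$phi)) + sum(is.na(top$dihedrals$kphi))
}

#' Build the CG topology of one P1 polymer chain
#'
#' Concatenates the monomer templates along the chain sequence: backbone
#' beads (coil-type P2, since the polypeptide backbone is disordered) form a
#' linear path joined by backbone bonds; each monomer's side chain branches
#' off its backbone bead. The M3 terminal sulfonamide bead (P6) is flagged as
#' the specific protein-binding site and the TN6d ring bead as the
#' benzene-sulfonamide anchor used for protein placement.
#'
#' Bond/angle parameter slots are created empty (`NA`); fill them with
#' [assign_bonded_parameters()].
#'
#' @param chain A `chain_spec` from [generate_chain_set()].
#' @param variant `"nonstandard"` (default) or `"strict_standard"`.
#' @return A `cg_topology`. Total charge is 0 for every P1 chain.
#' @export
build_polymer_topology <- function(chain, variant = "nonstandard") {
  assert_variant(variant)
  seqn <- chain$sequence
  if (is.null(seqn)) stop("chain has no sequence", call. = FALSE)
  beads <- list(); bonds <- list(); angles <- list()
  offset <- 0L
  bb_idx <- integer(length(seqn))
  for (im in seq_along(seqn)) {
    sp <- monomer_spec(seqn[im], variant)  # errors on unknown label
    b <- sp$beads
    b$monomer <- sp$label
    b$monomer_index <- im
    beads[[im]] <- b
    bonds[[im]] <- tibble::tibble(i = sp$bonds$i + offset, j = sp$bonds$j + offset)
    angles[[im]] <- tibble::tibble(i = sp$angles$i + offset, j = sp$angles$j + offset,
                                   k = sp$angles$k + offset)
    bb_idx[im] <- sp$backbone + offset
    offset <- offset + nrow(b)
  }
  beads <- dplyr::bind_rows(beads)
  bonds <- dplyr::bind_rows(bonds)
  angles <- dplyr::bind_rows(angles)
  if (length(bb_idx) > 1L) {
    bonds <- dplyr::bind_rows(
      bonds,
      tibble::tibble(i = bb_idx[-length(bb_idx)], j = bb_idx[-1L])
    )
  }
  if (length(bb_idx) > 2L) {
    angles <- dplyr::bind_rows(
      angles,
      tibble::tibble(i = bb_idx[1:(length(bb_idx) - 2L)],
                     j = bb_idx[2:(length(bb_idx) - 1L)],
                     k = bb_idx[3:length(bb_idx)])
    )
  }
  bonds$length <- NA_real_; bonds$kb <- NA_real_
  angles$theta <- NA_real_; angles$ktheta <- NA_real_
  top <- new_cg_topology("P1", beads, bonds, angles, variant = variant)
  check_topology(top)
}

#' Build the CG topology of the carbocyanine dye DiI
#'
#' The DiI model carries its +1 formal charge as two +0.5 partial charges on
#' the two nitrogen-bearing headgroup beads, reflecting the resonant charge
#' distribution of the carbocyanine group. The headgroup (two charged SN6
#' beads, four TC5 aromatic ring beads and the conjugated TN6d methine
#' linker; seven beads in total) is flagged for SASA tracking; two equal
#' four-bead C1 alkyl tails hang off the ring nitrogens. In the
#' strict-standard variant the linker bead type is TC1 instead of TN6d (see
#' [variant_overrides()]).
#'
#' @param variant `"nonstandard"` (default) or `"strict_standard"`.
#' @return A `cg_topology` with total charge +1.
#' @export
build_dii_topology <- function(variant = "nonstandard") {
  assert_variant(variant)
  key <- paste0("DII.", variant)
  cached <- .template_cache[[key]]
  if (!is.null(cached)) return(cached)
  beads <- bead_table(
    bead = c("HN1", "RA1", "RA2", "LNK", "HN2", "RB1", "RB2",
             paste0("TA", 1:4), paste0("TB", 1:4)),
    type = c("SN6", "TC5", "TC5", "TN6d", "SN6", "TC5", "TC5", rep("C1", 8)),
    size_class = c("small", "tiny", "tiny", "tiny", "small", "tiny", "tiny",
                   rep("regular", 8)),
    charge = c(0.5, 0, 0, 0, 0.5, 0, 0, rep(0, 8)),
    role = c(rep("head", 7), rep("tail", 8))
  )
  beads <- apply_variant(beads, "DII", variant)
  beads$monomer <- "DII"
  beads$monomer_index <- 1L
  bonds <- tibble::tribble(
    ~i, ~j,
    1L, 2L,  2L, 3L,   # head ring A
    1L, 4L,  4L, 5L,   # methine bridge
    5L, 6L,  6L, 7L,   # head ring B
    1L, 8L,  8L, 9L,  9L, 10L, 10L, 11L,   # tail A
    5L, 12L, 12L, 13L, 13L, 14L, 14L, 15L  # tail B
  )
  angles <- tibble::tribble(
    ~i, ~j, ~k,
    3L, 2L, 1L,  2L, 1L, 4L,  1L, 4L, 5L,  4L, 5L, 6L,  5L, 6L, 7L,
    4L, 1L, 8L,  1L, 8L, 9L,  8L, 9L, 10L, 9L, 10L, 11L,
    4L, 5L, 12L, 5L, 12L, 13L, 12L, 13L, 14L, 13L, 14L, 15L
  )
  bonds$length <- NA_real_; bonds$kb <- NA_real_
  angles$theta <- NA_real_; angles$ktheta <- NA_real_
  # one stiff improper-style dihedral keeps the conjugated bridge planar
  dihedrals <- tibble::tibble(i = 2L, j = 1L, k = 5L, l = 6L,
                              phi = NA_real_, kphi = NA_real_, mult = 1L)
  top <- new_cg_topology("DII", beads, bonds, angles, dihedrals,
                         variant = variant)
  top <- check_topology(top)
  .template_cache[[key]] <- top
  top
}

#' Shipped default bonded-parameter table
#'
#' Bond lengths come from idealised CG geometry by size-class pair; force
#' constants follow typical Martini analog groups. The reference workflow
#' derives lengths from energy-minimised all-atom structures — supply those
#' via the `reference` argument of [assign_bonded_parameters()] to override
#' these defaults.
#'
#' @return A list with `bonds` (tibble: `class_a`, `class_b`, `length` A,
#'   `kb` kcal/mol/A^2), `angle_theta` (deg), `angle_k` (kcal/mol),
#'   `dihedral_phi` (deg), `dihedral_k` (kcal/mol), and a `version` string.
#' @export
default_bond_table <- function() {
  list(
    bonds = tibble::tribble(
      ~class_a,  ~class_b,  ~length, ~kb,
      "regular", "regular", 3.50,    2.99,
      "regular", "small",   3.30,    2.99,
      "regular", "tiny",    3.00,    2.99,
      "small",   "small",   3.10,    2.99,
      "small",   "tiny",    2.90,    2.99,
      "tiny",    "tiny",    2.80,    2.99
    ),
    angle_theta = 130, angle_k = 5.98,
    dihedral_phi = 180, dihedral_k = 1.2,
    version = "1.0"
  )
}

#' Fill empty bonded-parameter slots of a topology
#'
#' Bond lengths are taken, in order of precedence, from (1) a user-supplied
#' reference geometry — either a named distance table (`"BEADA-BEADB"` ->
#' length in A) or an N x 3 coordinate matrix aligned with the bead order,
#' from which bond distances are measured directly — or (2) the shipped
#' default table ([default_bond_table()]) keyed by the size-class pair.
#' Angle and dihedral parameters are copied from the default analog group.
#' A topology that is already fully parameterised is returned unchanged.
#'
#' @param top A `cg_topology`.
#' @param reference Optional named numeric vector of distances (A) or an
#'   N x 3 numeric coordinate matrix.
#' @return The fully parameterised `cg_topology` (no empty slots).
#' @export
assign_bonded_parameters <- function(top, reference = NULL) {
  if (empty_parameter_slots(top) == 0L) return(top)
  defs <- default_bond_table()
  ref_dist <- function(i, j) {
    if (is.null(reference)) return(NA_real_)
    if (is.matrix(reference)) {
      return(sqrt(sum((reference[i, ] - reference[j, ])^2)))
    }
    key1 <- paste0(top$beads$bead[i], "-", top$beads$bead[j])
    key2 <- paste0(top$beads$bead[j], "-", top$beads$bead[i])
    if (key1 %in% names(reference)) return(unname(reference[key1]))
    if (key2 %in% names(reference)) return(unname(reference[key2]))
    NA_real_
  }
  default_len <- function(i, j) {
    ca <- top$beads$size_class[i]; cb <- top$beads$size_class[j]
    tab <- defs$bonds
    hit <- (tab$class_a == ca & tab$class_b == cb) |
           (tab$class_a == cb & tab$class_b == ca)
    if (!any(hit)) NA_real_ else tab$length[which(hit)[1]]
  }
  missing_terms <- character()
  for (r in seq_len(nrow(top$bonds))) {
    if (is.na(top$bonds$length[r])) {
      d <- ref_dist(top$bonds$i[r], top$bonds$j[r])
      if (is.na(d)) d <- default_len(top$bonds$i[r], top$bonds$j[r])
      if (is.na(d)) {
        missing_terms <- c(missing_terms,
          paste0(top$beads$bead[top$bonds$i[r]], "-",
                 top$beads$bead[top$bonds$j[r]]))
        next
      }
      top$bonds$length[r] <- d
    }
    if (is.na(top$bonds$kb[r])) {
      tab <- defs$bonds
      ca <- top$beads$size_class[top$bonds$i[r]]
      cb <- top$beads$size_class[top$bonds$j[r]]
      hit <- (tab$class_a == ca & tab$class_b == cb) |
             (tab$class_a == cb & tab$class_b == ca)
      top$bonds$kb[r] <- if (any(hit)) tab$kb[which(hit)[1]] else defs$bonds$kb[1]
    }
  }
  if (length(missing_terms)) {
    stop("no default or reference distance for bond(s): ",
         paste(unique(missing_terms), collapse = ", "), call. = FALSE)
  }
  top$angles$theta[is.na(top$angles$theta)] <- defs$angle_theta
  top$angles$ktheta[is.na(top$angles$ktheta)] <- defs$angle_k
  if (nrow(top$dihedrals)) {
    top$dihedrals$phi[is.na(top$dihedrals$phi)] <- defs$dihedral_phi
    top$dihedrals$kphi[is.na(top$dihedrals$kphi)] <- defs$dihedral_k
  }
  top
}
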