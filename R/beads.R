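#' Martini size-class conventions used throughout cgkit
#'
#' Regular, small and tiny beads map 4, 3 and 2 heavy atoms per bead and carry
#' masses of 72, 54 and 36 u respectively. One documented exception exists:
#' the M3 backbone amide bead maps 6 heavy atoms to a single regular bead so
#' that the downstream oligoethylene-glycol segment stays intact as a
#' hydrophilic unit.
#'
#' @return A tibble with columns `size_class`, `heavy_atoms`, `mass`,
#'   `radius` (A, used as the default SASA radius: half the Martini
#'   size-class sigma).
#' @export
size_class_table <- function() {
  tibble::tibble(
    size_class  = c("regular", "small", "tiny"),
    heavy_atoms = c(4L, 3L, 2L),
    mass        = c(72, 54, 36),
    radius      = c(2.35, 2.05, 1.70)
  )
}

class_mass <- function(size_class) {
  tab <- size_class_table()
  tab$mass[match(size_class, tab$size_class)]
}

#' Bead-type override table for the two model variants
#'
#' The default ("nonstandard") model departs from strict Martini 3 typing in
#' exactly three places, each chosen to capture resonance or enhanced
#' hydrophilicity: the M3 backbone secondary amide (P3 instead of P2), the
#' benzene-sulfonamide anchor bead in M3 (TN6d instead of TC5), and the
#' conjugated methine linker of the DiI headgroup (TN6d instead of TC1).
#' The "strict_standard" variant reverts all three; everything else about the
#' two models (bead counts, connectivity, charges, bonded terms) is identical.
#'
#' @return A tibble with columns `molecule`, `bead`, `nonstandard`,
#'   `strict_standard`.
#' @export
variant_overrides <- function() {
  tibble::tribble(
    ~molecule, ~bead,  ~nonstandard, ~strict_standard,
    "M3",      "AMD",  "P3",         "P2",
    "M3",      "BSD",  "TN6d",       "TC5",
    "DII",     "LNK",  "TN6d",       "TC1"
  )
}

assert_variant <- function(variant) {
  if (!variant %in% c("nonstandard", "strict_standard")) {
    stop("unknown model variant '", variant,
         "'; use 'nonstandard' or 'strict_standard'", call. = FALSE)
  }
  variant
}

apply_variant <- function(beads, molecule, variant) {
  assert_variant(variant)
  ov <- variant_overrides()
  ov <- ov[ov$molecule == molecule, ]
  if (nrow(ov) == 0L) return(beads)
  idx <- match(ov$bead, beads$bead)
  hit <- !is.na(idx)
  beads$type[idx[hit]] <- ov[[variant]][hit]
  beads
}

bead_row <- function(bead, type, size_class, charge = 0, heavy_atoms = NULL,
                     role = "sidechain") {
  tab <- size_class_table()
  k <- match(size_class, tab$size_class)
  tibble::tibble(
    bead = bead, type = type, size_class = size_class,
    charge = charge,
    mass = tab$mass[k],
    heavy_atoms = if (is.null(heavy_atoms)) tab$heavy_atoms[k]
                  else as.integer(heavy_atoms),
    role = role
  )
}

# vectorised template constructor (one tibble per monomer, not per bead)
bead_table <- function(bead, type, size_class, charge = 0, role = "sidechain",
                       heavy_atoms = NULL) {
  tab <- size_class_table()
  k <- match(size_class, tab$size_class)
  ha <- tab$heavy_atoms[k]
  if (!is.null(heavy_atoms)) {
    ov <- !is.na(heavy_atoms)
    ha[ov] <- as.integer(heavy_atoms[ov])
  }
  tibble::tibble(
    bead = bead, type = type, size_class = size_class,
    charge = rep_len(charge, length(bead)),
    mass = tab$mass[k], heavy_atoms = ha,
    role = rep_len(role, length(bead))
  )
}

.template_cache <- new.env(parent = emptyenv())

#' Monomer bead templates for the P1 copolymer
#'
#' Returns the CG bead layout and intra-monomer bonded terms for one of the
#' three glutamic-acid-derived monomers:
#' \describe{
#'   \item{M1}{hydrophobic: backbone (P2 coil), ester linker (P2), two C1
#'     alkyl side-chain beads.}
#'   \item{M2}{hydrophilic: backbone, ester linker, two SN3a
#'     oligoethylene-glycol beads.}
#'   \item{M3}{ligand-bearing: backbone, secondary-amide linker (P3, the
#'     single six-heavy-atoms-to-one-bead exception), two SN3a OEG beads,
#'     then the split amide carbonyl (TN4a), two TC5 ring beads, the
#'     benzene-sulfonamide anchor (TN6d) and a terminal highly polar P6
#'     sulfonamide bead — the specific Zn-binding site.}
#' }
#' Bond/angle indices are local to the monomer; bead 1 is always the backbone
#' bead that the polymerised chain links through.
#'
#' @param label One of `"M1"`, `"M2"`, `"M3"`.
#' @param variant Model variant, `"nonstandard"` (default) or
#'   `"strict_standard"`; see [variant_overrides()].
#' @return A list with elements `label`, `beads` (tibble), `bonds`, `angles`
#'   (local index tibbles), `backbone` (local index of the backbone bead).
#' @export
monomer_spec <- function(label, variant = "nonstandard") {
  assert_variant(variant)
  key <- paste0(label, ".", variant)
  cached <- .template_cache[[key]]
  if (!is.null(cached)) return(cached)
  beads <- switch(label,
    M1 = bead_table(
      bead = c("BB", "EST", "SC1", "SC2"),
      type = c("P2", "P2", "C1", "C1"),
      size_class = c("regular", "small", "regular", "regular"),
      role = c("backbone", "linker", "sidechain", "sidechain")
    ),
    M2 = bead_table(
      bead = c("BB", "EST", "OE1", "OE2"),
      type = c("P2", "P2", "SN3a", "SN3a"),
      size_class = c("regular", "small", "small", "small"),
      role = c("backbone", "linker", "sidechain", "sidechain")
    ),
    M3 = bead_table(
      bead = c("BB", "AMD", "OE1", "OE2", "CAM", "BZ1", "BZ2", "BSD", "SUF"),
      type = c("P2", "P3", "SN3a", "SN3a", "TN4a", "TC5", "TC5", "TN6d", "P6"),
      size_class = c("regular", "regular", "small", "small", "tiny", "tiny",
                     "tiny", "tiny", "regular"),
      role = c("backbone", "linker", "sidechain", "sidechain", "sidechain",
               "sidechain", "sidechain", "ligand_anchor", "binding_site"),
      heavy_atoms = c(NA, 6L, NA, NA, NA, NA, NA, NA, NA)
    ),
    stop("unknown monomer label '", label, "'", call. = FALSE)
  )
  beads <- apply_variant(beads, label, variant)
  n <- nrow(beads)
  bonds <- tibble::tibble(i = seq_len(n - 1L), j = 2L:n)
  angles <- if (n >= 3L) {
    tibble::tibble(i = seq_len(n - 2L), j = 2L:(n - 1L), k = 3L:n)
  } else {
    tibble::tibble(i = integer(), j = integer(), k = integer())
  }
  out <- list(label = label, beads = beads, bonds = bonds, angles = angles,
              backbone = 1L)
  .template_cache[[key]] <- out
  out
}
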