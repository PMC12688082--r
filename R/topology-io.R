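num <- function(x) sprintf("%.10g", x)

#' Write a CG topology as a GROMACS molecule definition (ITP dialect)
#'
#' Converts internal units (A, kcal/mol) to the GROMACS convention (nm,
#' kJ/mol): bond lengths x0.1, bond force constants x418.4, angle/dihedral
#' force constants x4.184. Bead metadata that the ITP atom table has no
#' column for (size class, heavy-atom count, role, monomer assignment) is
#' carried in a structured trailing comment on each atom line so that
#' [read_topology()] recovers the full object.
#'
#' @param top A fully parameterised `cg_topology`; unparameterised terms are
#'   refused.
#' @param path Optional file path; when `NULL` the text is returned invisibly
#'   only.
#' @return Character vector of file lines, invisibly.
#' @export
write_topology <- function(top, path = NULL) {
  if (empty_parameter_slots(top) > 0L) {
    stop("topology has unparameterised bonded terms; run ",
         "assign_bonded_parameters() first", call. = FALSE)
  }
  b <- top$beads
  lines <- c(
    paste0("; cgkit molecule definition (variant=", top$variant, ")"),
    "[ moleculetype ]",
    "; name  nrexcl",
    paste0(top$molecule, "  1"),
    "",
    "[ atoms ]",
    ";  nr type resnr residue atom cgnr charge mass ; size_class heavy_atoms role monomer monomer_index"
  )
  for (r in seq_len(nrow(b))) {
    lines <- c(lines, sprintf(
      "%5d %-6s %4d %-5s %-5s %4d %10s %10s ; %s %d %s %s %d",
      r, b$type[r], b$monomer_index[r], b$monomer[r], b$bead[r], r,
      num(b$charge[r]), num(b$mass[r]),
      b$size_class[r], b$heavy_atoms[r], b$role[r], b$monomer[r],
      b$monomer_index[r]))
  }
  if (nrow(top$bonds)) {
    lines <- c(lines, "", "[ bonds ]", ";  i  j funct length_nm kb_kJ_nm2")
    for (r in seq_len(nrow(top$bonds))) {
      lines <- c(lines, sprintf("%5d %5d 1 %s %s",
        top$bonds$i[r], top$bonds$j[r],
        num(top$bonds$length[r] * cg_units$ang_to_nm),
        num(kcal_A2_to_kJ_nm2(top$bonds$kb[r]))))
    }
  }
  if (nrow(top$angles)) {
    lines <- c(lines, "", "[ angles ]", ";  i  j  k funct theta_deg k_kJ")
    for (r in seq_len(nrow(top$angles))) {
      lines <- c(lines, sprintf("%5d %5d %5d 2 %s %s",
        top$angles$i[r], top$angles$j[r], top$angles$k[r],
        num(top$angles$theta[r]),
        num(top$angles$ktheta[r] * cg_units$kcal_to_kj)))
    }
  }
  if (nrow(top$dihedrals)) {
    lines <- c(lines, "", "[ dihedrals ]", ";  i  j  k  l funct phi_deg k_kJ mult")
    for (r in seq_len(nrow(top$dihedrals))) {
      lines <- c(lines, sprintf("%5d %5d %5d %5d 1 %s %s %d",
        top$dihedrals$i[r], top$dihedrals$j[r], top$dihedrals$k[r],
        top$dihedrals$l[r], num(top$dihedrals$phi[r]),
        num(top$dihedrals$kphi[r] * cg_units$kcal_to_kj),
        top$dihedrals$mult[r]))
    }
  }
  if (nrow(top$exclusions)) {
    lines <- c(lines, "", "[ exclusions ]")
    for (r in seq_len(nrow(top$exclusions))) {
      lines <- c(lines, sprintf("%5d %5d", top$exclusions$i[r], top$exclusions$j[r]))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

strip_comment <- function(x) sub(";.*$", "", x)

itp_sections <- function(lines) {
  sec <- NA_character_
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*\\[\\s*([A-Za-z_]+)\\s*\\]", ln))[[1]]
    if (length(m) == 2L) { sec <- m[2]; out[[sec]] <- character(); next }
    if (is.na(sec)) next
    out[[sec]] <- c(out[[sec]], ln)
  }
  out
}

#' Read a cgkit-written molecule definition back into a `cg_topology`
#'
#' Inverse of [write_topology()]: parses the ITP sections, converts nm/kJ
#' back to A/kcal, and restores bead metadata from the structured atom-line
#' comments.
#'
#' @param x Path to an ITP file or a character vector of its lines.
#' @return A `cg_topology`.
#' @export
read_topology <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  variant <- "nonstandard"
  vm <- regmatches(lines[1], regexec("variant=([a-z_]+)", lines[1]))[[1]]
  if (length(vm) == 2L) variant <- vm[2]
  secs <- itp_sections(lines)
  molname <- {
    ml <- strip_comment(secs[["moleculetype"]])
    ml <- ml[nzchar(trimws(ml))][1]
    strsplit(trimws(ml), "\\s+")[[1]][1]
  }
  atom_lines <- secs[["atoms"]]
  atom_lines <- atom_lines[grepl(";", atom_lines) & nzchar(trimws(strip_comment(atom_lines)))]
  beads <- purrr::map_dfr(atom_lines, function(ln) {
    parts <- strsplit(ln, ";", fixed = TRUE)[[1]]
    f <- strsplit(trimws(parts[1]), "\\s+")[[1]]
    meta <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    tibble::tibble(
      bead = f[5], type = f[2], size_class = meta[1],
      charge = as.numeric(f[7]), mass = as.numeric(f[8]),
      heavy_atoms = as.integer(meta[2]), role = meta[3],
      monomer = meta[4], monomer_index = as.integer(meta[5])
    )
  })
  parse_num_rows <- function(sec_lines) {
    sec_lines <- strip_comment(sec_lines)
    sec_lines <- sec_lines[nzchar(trimws(sec_lines))]
    if (!length(sec_lines)) return(NULL)
    do.call(rbind, lapply(sec_lines, function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    }))
  }
  bm <- parse_num_rows(secs[["bonds"]])
  bonds <- if (is.null(bm)) {
    tibble::tibble(i = integer(), j = integer(), length = double(), kb = double())
  } else {
    tibble::tibble(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
                   length = bm[, 4] / cg_units$ang_to_nm,
                   kb = kJ_nm2_to_kcal_A2(bm[, 5]))
  }
  am <- parse_num_rows(secs[["angles"]])
  angles <- if (is.null(am)) {
    tibble::tibble(i = integer(), j = integer(), k = integer(),
                   theta = double(), ktheta = double())
  } else {
    tibble::tibble(i = as.integer(am[, 1]), j = as.integer(am[, 2]),
                   k = as.integer(am[, 3]), theta = am[, 5],
                   ktheta = am[, 6] / cg_units$kcal_to_kj)
  }
  dm <- parse_num_rows(secs[["dihedrals"]])
  dihedrals <- if (is.null(dm)) NULL else {
    tibble::tibble(i = as.integer(dm[, 1]), j = as.integer(dm[, 2]),
                   k = as.integer(dm[, 3]), l = as.integer(dm[, 4]),
                   phi = dm[, 6], kphi = dm[, 7] / cg_units$kcal_to_kj,
                   mult = as.integer(dm[, 8]))
  }
  em <- parse_num_rows(secs[["exclusions"]])
  exclusions <- if (is.null(em)) NULL else {
    tibble::tibble(i = as.integer(em[, 1]), j = as.integer(em[, 2]))
  }
  new_cg_topology(molname, beads, bonds, angles, dihedrals, exclusions,
                  variant = variant)
}
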