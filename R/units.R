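# Internal units are Angstrom and kcal/mol; GROMACS dialects use nm, kJ/mol, ps.

#' Unit conversion constants
#'
#' `cgkit` works internally in Angstrom and kcal/mol (the units the modelling
#' protocol is stated in); file writers convert to the GROMACS convention of
#' nm, kJ/mol and ps on output, and readers convert back on input.
#'
#' @format A named list with elements `kcal_to_kj` (4.184, exact),
#'   `ang_to_nm` (0.1), `fs_to_ps` (0.001).
#' @export
cg_units <- list(
  kcal_to_kj = 4.184,
  ang_to_nm  = 0.1,
  fs_to_ps   = 0.001
)

# Bond force constants: kcal/mol/A^2 -> kJ/mol/nm^2 (factor 418.4)
kcal_A2_to_kJ_nm2 <- function(x) x * cg_units$kcal_to_kj / cg_units$ang_to_nm^2
kJ_nm2_to_kcal_A2 <- function(x) x / cg_units$kcal_to_kj * cg_units$ang_to_nm^2
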