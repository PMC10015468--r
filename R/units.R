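# Length-unit conversion constants. All coordinates are stored in nanometers
# internally; file formats use their native units (gro: nm, pdb/xyz: Angstrom,
# CPMD GEOMETRY and all CPMD input sections: Bohr).

#' Unit conversion constants
#'
#' CODATA value of the Bohr radius in nanometers, and derived factors used
#' throughout the package.
#'
#' @format Named numeric constants:
#' \describe{
#'   \item{BOHR_NM}{1 Bohr in nm (0.0529177210903)}
#'   \item{NM_BOHR}{1 nm in Bohr (1 / BOHR_NM)}
#'   \item{ANG_NM}{1 Angstrom in nm (0.1)}
#' }
#' @name units
#' @keywords internal
NULL

BOHR_NM <- 0.0529177210903
NM_BOHR <- 1 / BOHR_NM
ANG_NM <- 0.1

#' Convert lengths between the units used in molecular file formats
#'
#' @param x numeric vector of lengths.
#' @param from,to one of `"nm"`, `"angstrom"`, `"bohr"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_length(1, "bohr", "nm") # 0.0529177210903
#' @export
convert_length <- function(x, from, to) {
  from <- match.arg(from, c("nm", "angstrom", "bohr"))
  to <- match.arg(to, c("nm", "angstrom", "bohr"))
  nm <- switch(from, nm = x, angstrom = x * ANG_NM, bohr = x * BOHR_NM)
  switch(to, nm = nm, angstrom = nm / ANG_NM, bohr = nm / BOHR_NM)
}
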