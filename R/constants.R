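#' Physical constants and unit conversions
#'
#' All internal coordinates and energies are in atomic units (Bohr, Hartree);
#' structure files on disk are in Angstrom and are converted at the I/O
#' boundary.
#'
#' @format A named list with elements `bohr_per_angstrom`, `hartree_ev`,
#'   `fs_per_au_time`.
#' @export
lobehf_units <- list(
  bohr_per_angstrom = 1.8897259886,
  hartree_ev        = 27.211386245988,
  fs_per_au_time    = 2.418884e-2
)

#' Convert Angstrom to Bohr
#' @param x length(s) in Angstrom.
#' @return length(s) in Bohr.
#' @export
ang2bohr <- function(x) x * lobehf_units$bohr_per_angstrom

#' Convert Bohr to Angstrom
#' @param x length(s) in Bohr.
#' @return length(s) in Angstrom.
#' @export
bohr2ang <- function(x) x / lobehf_units$bohr_per_angstrom

# element symbol -> atomic number, for the species the minimal basis and the
# bond tables cover plus common hetero atoms read from files
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53
)

element_number <- function(sym) {
  sym <- sub("^([A-Za-z])([a-z]?).*$", "\\1\\2", sym)
  sym <- paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, 2)))
  z <- .element_z[sym]
  if (anyNA(z)) {
    bad <- unique(sym[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  as.integer(unname(z))
}

element_symbol <- function(z) {
  names(.element_z)[match(z, .element_z)]
}
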