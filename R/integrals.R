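#' One-electron integral matrices
#'
#' Closed-form s-Gaussian integrals over the lobe basis.  The nuclear
#' attraction uses the same erf-based `F0` kernel as the two-electron
#' integrals; `erf = "exact"` switches both to the library error function
#' (used by the quadrature-oracle tests).
#'
#' @param basis a `lobe_basis` from [basis_for_structure()].
#' @param structure the parent [atomic_structure()] (needed for V).
#' @param erf `"approx"` (default, the six-coefficient rational
#'   approximation with saturation at erf argument 4) or `"exact"`.
#' @return `overlap_matrix`/`kinetic_matrix`: symmetric `nbf x nbf` matrix;
#'   `core_hamiltonian` returns `list(S, T, V, H)`.
#' @export
overlap_matrix <- function(basis) {
  if (basis$nbf == 0L) stop("empty basis")
  one_electron(basis, NULL)$S
}

#' @rdname overlap_matrix
#' @export
kinetic_matrix <- function(basis) {
  if (basis$nbf == 0L) stop("empty basis")
  one_electron(basis, NULL)$T
}

#' @rdname overlap_matrix
#' @param screening optional [screening_config()]: applies the smooth
#'   Coulomb cut-off weight to each nuclear-attraction contribution
#'   (between the orbital-pair centre and the nucleus).  Long-range
#'   electrostatics must be truncated consistently across the
#'   electron-electron, electron-nuclear and nuclear-nuclear terms, or the
#'   neutral-system cancellation is destroyed.
#' @export
nuclear_attraction_matrix <- function(basis, structure,
                                      erf = c("approx", "exact"),
                                      screening = NULL) {
  erf <- match.arg(erf)
  if (any(structure$Z <= 0)) stop("nucleus with non-positive charge")
  one_electron(basis, structure, exact_erf = identical(erf, "exact"),
               screening = screening)$V
}

#' @rdname overlap_matrix
#' @export
core_hamiltonian <- function(basis, structure, erf = c("approx", "exact"),
                             screening = NULL) {
  erf <- match.arg(erf)
  if (any(structure$Z <= 0)) stop("nucleus with non-positive charge")
  m <- one_electron(basis, structure, exact_erf = identical(erf, "exact"),
                    screening = screening)
  m$H <- m$T + m$V
  m
}

one_electron <- function(basis, structure, exact_erf = FALSE,
                         screening = NULL) {
  if (is.null(structure)) {
    Zn <- numeric(0); nuc <- matrix(0, 0, 3)
  } else {
    Zn <- as.numeric(structure$Z); nuc <- structure$xyz
  }
  atom_xyz <- NULL; rcl <- -1; rcu <- -1
  if (!is.null(screening) && !is.null(structure)) {
    atom_xyz <- structure$xyz[basis$atom_index, , drop = FALSE]
    rcl <- ang2bohr(screening$coulomb_lower)
    rcu <- ang2bohr(screening$coulomb_upper)
  }
  cpp_one_electron(basis$off, basis$A, basis$alpha, basis$x, basis$y, basis$z,
                   Zn, nuc, sat = 4.0, exact_erf = exact_erf,
                   atom_xyz = atom_xyz, rcl = rcl, rcu = rcu)
}

#' Dipole-moment integral matrices
#' @param basis a `lobe_basis`.
#' @return list of three symmetric matrices, `<i| r |j>` in Bohr.
#' @export
dipole_matrices <- function(basis) {
  cpp_dipole(basis$off, basis$A, basis$alpha, basis$x, basis$y, basis$z)
}

#' Rational error-function approximation
#'
#' The six-coefficient rational approximation (c0 = 0.3275911, ...) used in
#' the integral kernels, saturating to exactly 1 for `x >= 4` where
#' `1 - erf(4) ~ 1.5e-8`.
#'
#' @param x numeric, `>= 0`.
#' @return `erf(x)` approximation.
#' @export
erf_approx <- function(x) {
  cpp_erf_approx(as.numeric(x))
}

#' Screening configuration
#'
#' @param density_threshold keep orbital pairs with relevance above this
#'   (default 1e-4).
#' @param coulomb_lower,coulomb_upper smooth Coulomb cut-off radii in
#'   Angstrom (default 8 and 10): weight 1 below the lower radius, 0 above
#'   the upper.
#' @param combined_relevance_threshold keep quadruplets with
#'   `r(ij) * r(kl) / max(d, 1 Bohr)` above this (default 1e-6).
#' @param erf_saturation_x saturation threshold on the kernel argument
#'   `x = P d^2` (default 16, i.e. erf argument 4).
#' @return A `screening_config`.
#' @export
screening_config <- function(density_threshold = 1e-4,
                             coulomb_lower = 8, coulomb_upper = 10,
                             combined_relevance_threshold = 1e-6,
                             erf_saturation_x = 16) {
  stopifnot(density_threshold >= 0, combined_relevance_threshold >= 0,
            coulomb_lower > 0, coulomb_lower < coulomb_upper)
  out <- list(density_threshold = density_threshold,
              coulomb_lower = coulomb_lower, coulomb_upper = coulomb_upper,
              combined_relevance_threshold = combined_relevance_threshold,
              erf_saturation_x = erf_saturation_x)
  class(out) <- "screening_config"
  out
}

#' Screening disabled (all thresholds zero, cut-offs effectively infinite)
#' @export
no_screening <- function() {
  screening_config(density_threshold = 0, coulomb_lower = 1e7,
                   coulomb_upper = 1e7 + 1,
                   combined_relevance_threshold = 0)
}

#' Smooth Coulomb cut-off weight
#'
#' `f(x) = 1 + 2 x^3 - 3 x^2` on the interval between the lower and upper
#' cut-off radii; 1 below, 0 above, with vanishing first derivative at both
#' ends.
#'
#' @param d distance(s) in Angstrom.
#' @param config a [screening_config()].
#' @return weight(s) in `[0, 1]`.
#' @export
coulomb_weight <- function(d, config = screening_config()) {
  stopifnot(all(d >= 0))
  x <- (d - config$coulomb_lower) /
    (config$coulomb_upper - config$coulomb_lower)
  x <- pmin(pmax(x, 0), 1)
  1 + 2 * x^3 - 3 * x^2
}

#' Density relevance of orbital pairs
#'
#' The integral of the absolute value of all pairwise primitive products of
#' two orbitals, computed analytically from the absolute-value lobe
#' representation (positive anisotropic Gaussians).
#'
#' @param basis a `lobe_basis`.
#' @param i,j orbital indices (1-based); omit both to get the full matrix.
#' @return scalar `r(rho_ij) >= 0`, or the symmetric `nbf x nbf` matrix.
#' @export
density_relevance <- function(basis, i = NULL, j = NULL) {
  R <- cpp_relevance(basis$aoff, basis$aA, basis$aax, basis$aay, basis$aaz,
                     basis$aox, basis$aoy, basis$aoz)
  if (is.null(i)) R else R[i, j]
}

#' Primitive electron-repulsion integral
#'
#' `(g_a g_b | g_c g_d)` for four s-Gaussians given as
#' `c(coefficient, exponent, x, y, z)` vectors; the uniform kernel used for
#' every integral in the lobe basis.
#'
#' @param ga,gb,gc,gd numeric(5) primitive descriptions.
#' @param erf `"approx"` or `"exact"`.
#' @return the integral value (Hartree).
#' @export
eri_primitive <- function(ga, gb, gc, gd, erf = c("approx", "exact")) {
  erf <- match.arg(erf)
  prim <- rbind(ga, gb, gc, gd)
  cpp_eri_contracted(off = 0:4, A = prim[, 1], al = prim[, 2],
                     x = prim[, 3], y = prim[, 4], z = prim[, 5],
                     i = 0L, j = 1L, k = 2L, l = 3L,
                     exact_erf = identical(erf, "exact"))
}

# contracted (ij|kl) over a lobe basis (1-based indices); testing surface
eri_contracted <- function(basis, i, j, k, l, exact_erf = FALSE) {
  cpp_eri_contracted(basis$off, basis$A, basis$alpha,
                     basis$x, basis$y, basis$z,
                     i - 1L, j - 1L, k - 1L, l - 1L, exact_erf = exact_erf)
}

#' Number of unique ERIs for a basis size
#'
#' Canonical 8-fold permutational symmetry: `m (m + 1) / 2` with
#' `m = nbf (nbf + 1) / 2`.
#'
#' @param nbf number of basis functions.
#' @return count (double, exact for minimal-basis protein sizes).
#' @export
count_unique_eris <- function(nbf) {
  m <- nbf * (nbf + 1) / 2
  m * (m + 1) / 2
}

#' Build the screened ERI set
#'
#' Three-stage screening: (a) orbital pairs must both pass the
#' density-relevance threshold; (b) the distance between the pair centres
#' (arithmetic means of the two parent atom positions) must lie below the
#' upper Coulomb cut-off; (c) the combined relevance
#' `r(ij) r(kl) / max(d, 1 Bohr)` must exceed its threshold.  Surviving
#' quadruplets are evaluated through the precomputed pair tables and stored
#' with their smooth Coulomb weight.
#'
#' @param basis a `lobe_basis`.
#' @param structure the parent [atomic_structure()].
#' @param config a [screening_config()].
#' @param erf `"approx"` or `"exact"` kernel.
#' @return A `screened_eri_set`: quadruplet arrays (1-based `i,j,k,l`),
#'   `value`, `weight`, and counters `n_theoretical`, `n_unique`,
#'   `n_density_surviving`, `n_fully_surviving`.
#' @export
build_screened_eris <- function(basis, structure,
                                config = screening_config(),
                                erf = c("approx", "exact")) {
  erf <- match.arg(erf)
  nbf <- basis$nbf
  R <- density_relevance(basis)
  pairs <- which(upper.tri(R, diag = TRUE) & R > config$density_threshold,
                 arr.ind = TRUE)
  # canonical i <= j ordering (upper triangle gives row <= col)
  pi <- pairs[, 1]; pj <- pairs[, 2]
  ctr <- (structure$xyz[basis$atom_index[pi], , drop = FALSE] +
            structure$xyz[basis$atom_index[pj], , drop = FALSE]) / 2
  rel <- R[cbind(pi, pj)]
  res <- cpp_screened_eris(basis$off, basis$A, basis$alpha,
                           basis$x, basis$y, basis$z,
                           as.integer(pi - 1L), as.integer(pj - 1L),
                           ctr, rel,
                           rcl = ang2bohr(config$coulomb_lower),
                           rcu = ang2bohr(config$coulomb_upper),
                           comb_thr = config$combined_relevance_threshold,
                           sat = sqrt(config$erf_saturation_x),
                           exact_erf = identical(erf, "exact"))
  np <- length(pi)
  out <- list(i = res$i + 1L, j = res$j + 1L, k = res$k + 1L, l = res$l + 1L,
              value = res$value, weight = res$weight,
              nbf = nbf,
              n_theoretical = as.numeric(nbf)^4,
              n_unique = count_unique_eris(nbf),
              n_density_surviving = np * (np + 1) / 2,
              n_fully_surviving = length(res$value),
              config = config)
  class(out) <- "screened_eri_set"
  out
}

#' @export
print.screened_eri_set <- function(x, ...) {
  cat(sprintf(paste0("<screened_eri_set> nbf=%d\n",
                     "  theoretical %.4g | unique %.4g | density-surviving",
                     " %.4g | stored %d\n"),
              x$nbf, x$n_theoretical, x$n_unique, x$n_density_surviving,
              x$n_fully_surviving))
  invisible(x)
}

#' Binary dump of a screened ERI set (debugging aid)
#'
#' Layout per record: four little-endian int32 (1-based i,j,k,l), one
#' float64 value, one float32 weight.
#'
#' @param eris a `screened_eri_set`.
#' @param path output file.
#' @export
write_eri_dump <- function(eris, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (e in seq_along(eris$value)) {
    writeBin(as.integer(c(eris$i[e], eris$j[e], eris$k[e], eris$l[e])), con,
             size = 4L, endian = "little")
    writeBin(eris$value[e], con, size = 8L, endian = "little")
    writeBin(eris$weight[e], con, size = 4L, endian = "little")
  }
  invisible(path)
}
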