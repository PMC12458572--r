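#' SCF configuration
#'
#' @param density_rmsd_tol convergence threshold on the RMSD of successive
#'   density matrices (default 1e-6).
#' @param max_iterations iteration cap (default 200).
#' @param mixing `"diis"` (default, commutator DIIS), `"damping"` or
#'   `"none"`.
#' @param damping damping factor for `mixing = "damping"`.
#' @param diis_depth number of retained Fock matrices.
#' @param s_eigen_cutoff overlap eigenvalues below this are discarded in the
#'   symmetric orthogonalization (guards linear dependence).
#' @return An `scf_config`.
#' @export
scf_config <- function(density_rmsd_tol = 1e-6, max_iterations = 200L,
                       mixing = c("diis", "damping", "none"), damping = 0.5,
                       diis_depth = 8L, s_eigen_cutoff = 1e-7) {
  stopifnot(density_rmsd_tol > 0, max_iterations >= 1)
  mixing <- match.arg(mixing)
  out <- list(density_rmsd_tol = density_rmsd_tol,
              max_iterations = as.integer(max_iterations), mixing = mixing,
              damping = damping, diis_depth = as.integer(diis_depth),
              s_eigen_cutoff = s_eigen_cutoff)
  class(out) <- "scf_config"
  out
}

# symmetric (Loewdin) orthogonalizer X = S^{-1/2} with eigenvalue cutoff
loewdin_x <- function(S, cutoff = 1e-7) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > cutoff
  if (!any(keep)) stop("overlap matrix is singular")
  if (!all(keep))
    warning(sum(!keep), " overlap eigenvalue(s) below cutoff dropped ",
            "(basis near-linear dependence)")
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

# two-electron matrix G = J - K/2 from a screened ERI set
fock_2e <- function(eris, P) {
  cpp_fock_2e(eris$nbf, eris$i - 1L, eris$j - 1L, eris$k - 1L, eris$l - 1L,
              eris$value, eris$weight, P)
}

# nuclear repulsion, with the same smooth Coulomb cut-off weight as the
# two-electron and nuclear-attraction terms when screening is active
nuclear_repulsion <- function(structure, screening = NULL) {
  n <- n_atoms(structure)
  if (n < 2) return(0)
  e <- 0
  for (a in seq_len(n - 1)) {
    d <- sqrt(rowSums((structure$xyz[(a + 1):n, , drop = FALSE] -
                         matrix(structure$xyz[a, ], n - a, 3,
                                byrow = TRUE))^2))
    w <- if (is.null(screening)) 1 else coulomb_weight(bohr2ang(d), screening)
    e <- e + sum(w * structure$Z[a] * structure$Z[(a + 1):n] / d)
  }
  e
}

#' Restricted Hartree-Fock over screened integrals
#'
#' Core-Hamiltonian initial guess, Fock build from the screened ERI set
#' (each integral multiplied by its Coulomb weight), symmetric
#' orthogonalization, and iteration to a density-matrix RMSD below
#' tolerance, with optional DIIS acceleration.
#'
#' @param structure an [atomic_structure()]; electron count must be even
#'   (closed shell).
#' @param basis optional prebuilt `lobe_basis`.
#' @param screening a [screening_config()].
#' @param config an [scf_config()].
#' @param eris optional prebuilt `screened_eri_set` (skips screening).
#' @param charge net charge (electrons = sum(Z) - charge).
#' @param erf integral kernel flavour, `"approx"` or `"exact"`.
#' @param verbose print the SCF trace.
#' @return An `scf_result` with the converged density matrix `P`, Fock `F`,
#'   core Hamiltonian `H`, two-electron matrix `G`, MO coefficients and
#'   orbital energies (Hartree), total energy (electronic + nuclear
#'   repulsion), and convergence metadata.
#' @export
scf_solve <- function(structure, basis = NULL,
                      screening = screening_config(),
                      config = scf_config(), eris = NULL, charge = 0,
                      erf = c("approx", "exact"), verbose = FALSE) {
  erf <- match.arg(erf)
  if (is.null(basis)) basis <- basis_for_structure(structure)
  nel <- sum(structure$Z) - charge
  if (nel %% 2L)
    stop("odd electron count (", nel, "): closed-shell RHF needs an even ",
         "number of electrons")
  nocc <- nel / 2L
  if (nocc > basis$nbf) stop("more electron pairs than basis functions")

  m <- core_hamiltonian(basis, structure, erf = erf, screening = screening)
  S <- m$S; H <- m$H
  X <- loewdin_x(S, config$s_eigen_cutoff)
  if (is.null(eris)) eris <- build_screened_eris(basis, structure, screening,
                                                 erf = erf)

  solve_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    e <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    C <- X %*% e$vectors[, ord, drop = FALSE]
    list(C = C, eps = e$values[ord])
  }

  sol <- solve_fock(H)
  Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
  P <- 2 * Cocc %*% t(Cocc)

  fock_hist <- list(); err_hist <- list()
  trace <- data.frame(iteration = integer(0), energy = numeric(0),
                      rmsd = numeric(0))
  converged <- FALSE
  it <- 0L
  enuc <- nuclear_repulsion(structure, screening)
  G <- NULL; F <- NULL
  while (it < config$max_iterations) {
    it <- it + 1L
    G <- fock_2e(eris, P)
    F <- H + G
    eel <- 0.5 * sum(P * (H + F))

    if (config$mixing == "diis") {
      err <- F %*% P %*% S - S %*% P %*% F
      fock_hist[[length(fock_hist) + 1L]] <- F
      err_hist[[length(err_hist) + 1L]] <- err
      if (length(fock_hist) > config$diis_depth) {
        fock_hist <- fock_hist[-1L]; err_hist <- err_hist[-1L]
      }
      nd <- length(fock_hist)
      if (nd > 1L) {
        B <- matrix(0, nd + 1L, nd + 1L)
        for (a in seq_len(nd)) for (b in seq_len(nd))
          B[a, b] <- sum(err_hist[[a]] * err_hist[[b]])
        B[nd + 1L, seq_len(nd)] <- B[seq_len(nd), nd + 1L] <- -1
        rhs <- c(rep(0, nd), -1)
        cf <- tryCatch(solve(B, rhs)[seq_len(nd)], error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf))) {
          F <- Reduce(`+`, Map(`*`, fock_hist, cf))
        }
      }
    }

    sol <- solve_fock(F)
    Cocc <- sol$C[, seq_len(nocc), drop = FALSE]
    Pnew <- 2 * Cocc %*% t(Cocc)
    if (config$mixing == "damping" && it > 1L)
      Pnew <- config$damping * Pnew + (1 - config$damping) * P
    rmsd <- sqrt(mean((Pnew - P)^2))
    trace <- rbind(trace, data.frame(iteration = it, energy = eel + enuc,
                                     rmsd = rmsd))
    if (verbose)
      message(sprintf("iter %3d  E = %.10f Ha  dP = %.3e", it, eel + enuc,
                      rmsd))
    P <- Pnew
    if (rmsd < config$density_rmsd_tol) { converged <- TRUE; break }
  }

  # final consistent quantities at the converged density
  G <- fock_2e(eris, P)
  F <- H + G
  eel <- sum(P * (H + 0.5 * G))
  sol <- solve_fock(F)

  out <- list(P = P, F = F, H = H, G = G, S = S, X = X,
              mo_coefficients = sol$C, orbital_energies = sol$eps,
              electronic_energy = eel, nuclear_repulsion = enuc,
              total_energy = eel + enuc,
              n_electrons = nel, n_occupied = nocc,
              converged = converged, iterations = it, trace = trace,
              basis = basis, structure = structure, eris = eris)
  class(out) <- "scf_result"
  out
}

#' @export
print.scf_result <- function(x, ...) {
  cat(sprintf("<scf_result> %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  total energy      %.6f Ha (electronic %.6f + nuclear %.6f)\n",
              x$total_energy, x$electronic_energy, x$nuclear_repulsion))
  cat(sprintf("  electrons %d in %d orbitals; HOMO %.4f Ha\n",
              x$n_electrons, x$basis$nbf,
              x$orbital_energies[x$n_occupied]))
  invisible(x)
}

#' @export
summary.scf_result <- function(object, ...) {
  print(object)
  cat("  orbital energies (Ha):\n")
  eps <- object$orbital_energies
  occ <- c(rep("occ", object$n_occupied),
           rep("virt", length(eps) - object$n_occupied))
  print(data.frame(orbital = seq_along(eps), energy = round(eps, 6),
                   occupation = occ), row.names = FALSE)
  invisible(object)
}

#' @export
coef.scf_result <- function(object, ...) object$mo_coefficients

#' Atomic-energy partition of a converged SCF result
#'
#' `E_a = (1/Z_a) sum_{i in valence(a)} sum_j P_ij (H_ij + G_ij / 2)`:
#' the row sum runs over valence basis functions centred on atom `a`, the
#' column sum over all basis functions, normalized by the atomic number.
#'
#' @param scf an `scf_result` (or anything carrying `P`, `H`, `G`).
#' @param basis,structure default to those stored in `scf`.
#' @param valence_only restrict rows to valence shells (default TRUE, the
#'   element-type normalization used for structure assessment).
#' @return An `atomic_energies` object: per-atom energies (Hartree), atomic
#'   numbers and valence basis counts.
#' @export
atomic_energies <- function(scf, basis = scf$basis,
                            structure = scf$structure, valence_only = TRUE) {
  if (any(structure$Z == 0)) stop("atom with zero nuclear charge")
  W <- scf$P * (scf$H + 0.5 * scf$G)
  rows <- rowSums(W)
  keep <- if (valence_only) basis$is_valence else rep(TRUE, basis$nbf)
  e_atom <- numeric(n_atoms(structure))
  nv <- integer(n_atoms(structure))
  for (a in seq_len(n_atoms(structure))) {
    idx <- which(basis$atom_index == a & keep)
    e_atom[a] <- sum(rows[idx]) / structure$Z[a]
    nv[a] <- length(idx)
  }
  out <- list(energies = e_atom, Z = structure$Z, n_valence_bf = nv,
              valence_only = valence_only)
  class(out) <- "atomic_energies"
  out
}

#' @export
print.atomic_energies <- function(x, ...) {
  cat(sprintf("<atomic_energies> %d atoms, mean %.4f Ha (valence_only=%s)\n",
              length(x$energies), mean(x$energies), x$valence_only))
  invisible(x)
}

#' Electronic density on a regular grid
#'
#' `rho(r) = sum_ab P_ab phi_a(r) phi_b(r)` over the orbital pairs retained
#' by the density-relevance screen (the pair indicator of the total-density
#' expression); optionally valence shells only.
#'
#' @param scf an `scf_result`.
#' @param spacing grid spacing in Bohr (default 1.5, the production value;
#'   use ~0.2 for integration checks).
#' @param padding margin around the structure, Bohr.
#' @param relevance_threshold pair screen for the summation.
#' @param valence_only drop core shells from the display density.
#' @return A `density_grid`: `values` array (x outer, z inner), `origin`,
#'   `spacing`, `dims`.
#' @export
density_on_grid <- function(scf, spacing = 1.5, padding = 4,
                            relevance_threshold = scf$eris$config$density_threshold,
                            valence_only = FALSE) {
  if (spacing <= 0) stop("grid spacing must be positive")
  basis <- scf$basis
  lo <- apply(scf$structure$xyz, 2, min) - padding
  hi <- apply(scf$structure$xyz, 2, max) + padding
  dims <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 1L, 2L)
  R <- density_relevance(basis)
  keep <- which(upper.tri(R, diag = TRUE) & R > relevance_threshold,
                arr.ind = TRUE)
  if (valence_only) {
    v <- basis$is_valence
    keep <- keep[v[keep[, 1]] & v[keep[, 2]], , drop = FALSE]
  }
  vals <- if (nrow(keep) == 0L) {
    numeric(prod(dims))
  } else {
    cpp_density_grid(basis$off, basis$A, basis$alpha, basis$x, basis$y,
                     basis$z, as.integer(keep[, 1] - 1L),
                     as.integer(keep[, 2] - 1L), scf$P, lo, spacing,
                     dims)
  }
  out <- list(values = array(vals, dim = rev(dims)), origin = lo,
              spacing = spacing, dims = dims,
              n_electrons_grid = sum(vals) * spacing^3)
  class(out) <- "density_grid"
  out
}
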