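# Independent numerical oracles used across the test files.
#
# Every lobe basis function is a sum of s-Gaussians, so pair products
# factorize per Cartesian axis; the 1D factors are integrated numerically
# (stats::integrate), giving overlap/kinetic references that never touch
# the package's closed forms.  The 1/r kernels use the Gauss transform
# 1/r = (2/sqrt(pi)) Int_0^inf exp(-t^2 r^2) dt, reducing V and ERI to a
# 1D t-integral whose inner Gaussian pieces are validated by the 1D
# quadrature tests; the erf-based kernel itself is never reused.

# a minimal hand-built lobe basis: `prims` is a list of n x 5 matrices
# (coefficient, exponent, x, y, z per primitive row)
custom_basis <- function(prims, atom_index = seq_along(prims),
                         is_valence = rep(TRUE, length(prims))) {
  P <- if (length(prims)) do.call(rbind, prims) else matrix(numeric(0), 0, 5)
  out <- list(
    atom_index = atom_index,
    shell_label = rep("1s", length(prims)),
    is_valence = is_valence,
    element = rep("H", length(prims)),
    nbf = length(prims),
    off = as.integer(c(0, cumsum(vapply(prims, nrow, 1L)))),
    A = P[, 1], alpha = P[, 2], x = P[, 3], y = P[, 4], z = P[, 5],
    aoff = as.integer(c(0, cumsum(vapply(prims, nrow, 1L)))),
    aA = abs(P[, 1]), aax = P[, 2], aay = P[, 2], aaz = P[, 2],
    aox = P[, 3], aoy = P[, 4], aoz = P[, 5])
  class(out) <- "lobe_basis"
  out
}

# single normalized s-Gaussian primitive as a 1 x 5 matrix
norm_s_prim <- function(alpha, center = c(0, 0, 0)) {
  matrix(c((2 * alpha / pi)^0.75, alpha, center), 1, 5)
}

# primitive rows of orbital i of a lobe basis
prim_rows <- function(basis, i) {
  idx <- (basis$off[i] + 1L):basis$off[i + 1L]
  cbind(basis$A[idx], basis$alpha[idx], basis$x[idx], basis$y[idx],
        basis$z[idx])
}

int1d <- function(f, lo = -Inf, hi = Inf) {
  # the adaptive rule converges far beyond the requested tolerance on these
  # smooth Gaussian integrands; keep the value when it merely reports that
  # the (very tight) tolerance target ran into roundoff
  stats::integrate(f, lo, hi, rel.tol = 1e-12, abs.tol = 1e-14,
                   subdivisions = 400L, stop.on.error = FALSE)$value
}

# finite integration window for a product of two 1D Gaussians: their
# product is a Gaussian at the weighted centre with exponent a1 + a2
gauss_window <- function(pa, pb, ax) {
  c1 <- pa[2 + ax]; c2 <- pb[2 + ax]
  p <- (pa[2] * c1 + pb[2] * c2) / (pa[2] + pb[2])
  w <- 12 / sqrt(pa[2] + pb[2])
  c(p - w, p + w)
}

# numeric overlap of two primitive rows via per-axis 1D quadrature
oracle_prim_overlap <- function(pa, pb) {
  v <- pa[1] * pb[1]
  for (ax in 1:3) {
    wd <- gauss_window(pa, pb, ax)
    v <- v * int1d(function(x)
      exp(-pa[2] * (x - pa[2 + ax])^2 - pb[2] * (x - pb[2 + ax])^2),
      wd[1], wd[2])
  }
  v
}

# numeric kinetic-energy integral -1/2 <a|del^2|b> via separable 1D factors
oracle_prim_kinetic <- function(pa, pb) {
  ov <- function(ax) {
    wd <- gauss_window(pa, pb, ax)
    int1d(function(x)
      exp(-pa[2] * (x - pa[2 + ax])^2 - pb[2] * (x - pb[2 + ax])^2),
      wd[1], wd[2])
  }
  d2 <- function(ax) {
    wd <- gauss_window(pa, pb, ax)
    int1d(function(x) {
      u <- x - pb[2 + ax]
      exp(-pa[2] * (x - pa[2 + ax])^2) *
        (4 * pb[2]^2 * u^2 - 2 * pb[2]) * exp(-pb[2] * u^2)
    }, wd[1], wd[2])
  }
  o <- vapply(1:3, ov, 0); d <- vapply(1:3, d2, 0)
  -0.5 * pa[1] * pb[1] *
    (d[1] * o[2] * o[3] + o[1] * d[2] * o[3] + o[1] * o[2] * d[3])
}

oracle_matrix <- function(basis, prim_fun) {
  n <- basis$nbf
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    pi_ <- prim_rows(basis, i); pj_ <- prim_rows(basis, j)
    s <- 0
    for (a in seq_len(nrow(pi_))) for (b in seq_len(nrow(pj_)))
      s <- s + prim_fun(pi_[a, ], pj_[b, ])
    M[i, j] <- M[j, i] <- s
  }
  M
}

oracle_overlap_matrix <- function(basis) oracle_matrix(basis, oracle_prim_overlap)
oracle_kinetic_matrix <- function(basis) oracle_matrix(basis, oracle_prim_kinetic)

# nuclear attraction via the Gauss transform (1D t-integral)
oracle_prim_nuclear <- function(pa, pb, C, Z) {
  g <- pa[2] + pb[2]
  xi <- pa[2] * pb[2] / g
  R2 <- sum((pa[3:5] - pb[3:5])^2)
  P <- (pa[2] * pa[3:5] + pb[2] * pb[3:5]) / g
  pc2 <- sum((P - C)^2)
  pre <- pa[1] * pb[1] * exp(-xi * R2)
  f <- function(t) (pi / (g + t^2))^1.5 *
    exp(-g * t^2 / (g + t^2) * pc2)
  -Z * pre * 2 / sqrt(pi) *
    stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
}

oracle_nuclear_matrix <- function(basis, structure) {
  n <- basis$nbf
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    pi_ <- prim_rows(basis, i); pj_ <- prim_rows(basis, j)
    s <- 0
    for (a in seq_len(nrow(pi_))) for (b in seq_len(nrow(pj_)))
      for (k in seq_len(n_atoms(structure)))
        s <- s + oracle_prim_nuclear(pi_[a, ], pj_[b, ],
                                     structure$xyz[k, ], structure$Z[k])
    M[i, j] <- M[j, i] <- s
  }
  M
}

# primitive ERI (g_a g_b | g_c g_d) via the Gauss transform:
# both products are combined analytically, the t-integral is numeric
oracle_prim_eri <- function(pa, pb, pc, pd) {
  g1 <- pa[2] + pb[2]; g2 <- pc[2] + pd[2]
  xi1 <- pa[2] * pb[2] / g1; xi2 <- pc[2] * pd[2] / g2
  A <- (pa[2] * pa[3:5] + pb[2] * pb[3:5]) / g1
  B <- (pc[2] * pc[3:5] + pd[2] * pd[3:5]) / g2
  d2 <- sum((A - B)^2)
  pre <- pa[1] * pb[1] * pc[1] * pd[1] *
    exp(-xi1 * sum((pa[3:5] - pb[3:5])^2)) *
    exp(-xi2 * sum((pc[3:5] - pd[3:5])^2))
  f <- function(t) {
    den <- g1 * g2 + t^2 * (g1 + g2)
    (pi^2 / den)^1.5 * exp(-g1 * g2 * t^2 / den * d2)
  }
  pre * 2 / sqrt(pi) * stats::integrate(f, 0, Inf, rel.tol = 1e-12)$value
}

# contracted (ij|kl) oracle over a lobe basis
oracle_eri_contracted <- function(basis, i, j, k, l) {
  pi_ <- prim_rows(basis, i); pj_ <- prim_rows(basis, j)
  pk_ <- prim_rows(basis, k); pl_ <- prim_rows(basis, l)
  s <- 0
  for (a in seq_len(nrow(pi_))) for (b in seq_len(nrow(pj_)))
    for (c in seq_len(nrow(pk_))) for (d in seq_len(nrow(pl_)))
      s <- s + oracle_prim_eri(pi_[a, ], pj_[b, ], pk_[c, ], pl_[d, ])
  s
}

# overlap matrix of the *reference* contracted basis (Cartesian-prefactor
# p functions) by separable 1D quadrature; used to check that the lobe
# basis reproduces the reference overlaps
reference_overlap_quadrature <- function(structure, ref) {
  orbs <- list()
  for (ia in seq_len(n_atoms(structure))) {
    el <- structure$elements[ia]
    for (sh in reference_element(ref, el)) {
      ex <- sh$exponents
      mk <- function(co, pow) {
        np <- if (sum(pow) == 0) (2 * ex / pi)^0.75
              else 2 * sqrt(ex) * (2 * ex / pi)^0.75
        cn <- co * np
        # renormalize the contraction
        gs <- outer(ex, ex, "+")
        ov <- if (sum(pow) == 0) sum(outer(cn, cn) * (pi / gs)^1.5)
              else sum(outer(cn, cn) * (pi / gs)^1.5 / (2 * gs))
        list(c = cn / sqrt(ov), a = ex, pow = pow,
             center = structure$xyz[ia, ])
      }
      if (sh$type %in% c("S", "SP"))
        orbs[[length(orbs) + 1L]] <- mk(sh$coefficients[, 1], c(0, 0, 0))
      if (sh$type %in% c("P", "SP"))
        for (ax in 1:3) {
          pow <- c(0, 0, 0); pow[ax] <- 1
          orbs[[length(orbs) + 1L]] <- mk(sh$coefficients[, 2], pow)
        }
    }
  }
  n <- length(orbs)
  S <- matrix(0, n, n)
  ov1d <- function(a, b, X1, X2, p1, p2)
    int1d(function(x) (x - X1)^p1 * (x - X2)^p2 *
            exp(-a * (x - X1)^2 - b * (x - X2)^2))
  for (i in seq_len(n)) for (j in i:n) {
    oi <- orbs[[i]]; oj <- orbs[[j]]
    s <- 0
    for (k in seq_along(oi$a)) for (l in seq_along(oj$a)) {
      v <- oi$c[k] * oj$c[l]
      for (ax in 1:3)
        v <- v * ov1d(oi$a[k], oj$a[l], oi$center[ax], oj$center[ax],
                      oi$pow[ax], oj$pow[ax])
      s <- s + v
    }
    S[i, j] <- S[j, i] <- s
  }
  S
}

# 3D Riemann-sum quadrature of |phi_i| |phi_j| (density-relevance oracle)
oracle_abs_pair_integral <- function(basis, i, j, half = 8, spacing = 0.2,
                                     center = c(0, 0, 0)) {
  ax <- seq(-half, half, by = spacing)
  pts <- as.matrix(expand.grid(ax + center[1], ax + center[2],
                               ax + center[3]))
  fi <- eval_basis_function(basis, i, pts)
  fj <- eval_basis_function(basis, j, pts)
  sum(abs(fi) * abs(fj)) * spacing^3
}

# MO-basis two-electron integrals for a tiny basis (full transform)
oracle_mo_eris <- function(scf) {
  n <- scf$basis$nbf
  C <- scf$mo_coefficients
  eri <- array(0, c(n, n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n)
    eri[i, j, k, l] <- eri_contracted(scf$basis, i, j, k, l)
  mo <- eri
  for (idx in 1:4) {   # transform the leading index, then rotate axes
    mo <- apply(mo, 2:4, function(v) as.vector(t(C) %*% v))
    mo <- aperm(mo, c(2, 3, 4, 1))
  }
  mo
}

# singlet excitation oracles from a converged SCF on a tiny basis.
# CIS diagonalizes A alone; time-dependent HF (RPA) couples A and B:
#   A_ia,jb = d_ij d_ab (e_a - e_i) + 2(ia|jb) - (ij|ab)
#   B_ia,jb = 2(ia|jb) - (ib|ja)
# and w^2 are the eigenvalues of (A - B)(A + B).
oracle_singlet_AB <- function(scf) {
  mo <- oracle_mo_eris(scf)
  n <- scf$basis$nbf
  occ <- seq_len(scf$n_occupied); virt <- setdiff(1:n, occ)
  eps <- scf$orbital_energies
  pairs <- expand.grid(i = occ, a = virt)
  m <- nrow(pairs)
  A <- matrix(0, m, m); B <- matrix(0, m, m)
  for (p in 1:m) for (q in 1:m) {
    i <- pairs$i[p]; a <- pairs$a[p]; j <- pairs$i[q]; b <- pairs$a[q]
    A[p, q] <- 2 * mo[i, a, j, b] - mo[i, j, a, b]
    if (p == q) A[p, q] <- A[p, q] + eps[a] - eps[i]
    B[p, q] <- 2 * mo[i, a, j, b] - mo[i, b, j, a]
  }
  list(A = (A + t(A)) / 2, B = (B + t(B)) / 2)
}

oracle_cis_energies <- function(scf) {
  ab <- oracle_singlet_AB(scf)
  sort(eigen(ab$A, symmetric = TRUE)$values)
}

oracle_tdhf_energies <- function(scf) {
  ab <- oracle_singlet_AB(scf)
  w2 <- eigen((ab$A - ab$B) %*% (ab$A + ab$B))$values
  sort(sqrt(Re(w2)))
}

# small shared fixtures built once per test run
shared_env <- new.env()

shared_h2o_scf <- function(screened = FALSE) {
  key <- if (screened) "h2o_scr" else "h2o"
  if (is.null(shared_env[[key]])) {
    scr <- if (screened) screening_config() else no_screening()
    shared_env[[key]] <- scf_solve(make_molecule("h2o"), screening = scr)
  }
  shared_env[[key]]
}

shared_h2_scf <- function() {
  if (is.null(shared_env$h2))
    shared_env$h2 <- scf_solve(make_molecule("h2"), screening = no_screening())
  shared_env$h2
}
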