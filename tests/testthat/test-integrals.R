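# One- and two-electron integrals, the erf kernel and the screening stages.

test_that("overlap closed forms match the textbook values", {
  b <- custom_basis(list(norm_s_prim(0.7)))
  expect_equal(overlap_matrix(b)[1, 1], 1, tolerance = 1e-12)

  # two unit-coefficient s Gaussians, alpha = 1, same center: (pi/2)^{3/2}
  unit <- matrix(c(1, 1, 0, 0, 0), 1, 5)
  b2 <- custom_basis(list(unit, unit))
  expect_equal(overlap_matrix(b2)[1, 2], (pi / 2)^1.5, tolerance = 1e-12)
  expect_error(overlap_matrix(custom_basis(list())), "empty basis")
})

test_that("S and T for H2 match 1D-separable quadrature to 1e-8", {
  b <- basis_for_structure(make_molecule("h2"))
  expect_lt(max(abs(overlap_matrix(b) - oracle_overlap_matrix(b))), 1e-8)
  expect_lt(max(abs(kinetic_matrix(b) - oracle_kinetic_matrix(b))), 1e-8)
})

test_that("kinetic self-energy of a normalized s Gaussian is 3 alpha / 2", {
  for (alpha in c(0.3, 1, 4.2)) {
    b <- custom_basis(list(norm_s_prim(alpha)))
    expect_equal(kinetic_matrix(b)[1, 1], 1.5 * alpha, tolerance = 1e-12)
  }
})

test_that("T and V for H2O match the quadrature oracle", {
  st <- make_molecule("h2o")
  b <- basis_for_structure(st)
  expect_lt(max(abs(kinetic_matrix(b) - oracle_kinetic_matrix(b))), 1e-7)
  V_or <- oracle_nuclear_matrix(b, st)
  # exact-erf kernel agrees to quadrature accuracy
  expect_lt(max(abs(nuclear_attraction_matrix(b, st, erf = "exact") - V_or)),
            1e-7)
  # the production kernel deviates only by the documented accuracy of the
  # rational erf approximation (printed max error ~1.5e-7 on erf itself)
  expect_lt(max(abs(nuclear_attraction_matrix(b, st) - V_or)), 5e-6)
  bad <- st; bad$Z[1] <- 0L
  expect_error(nuclear_attraction_matrix(b, bad), "non-positive charge")
})

test_that("erf approximation matches the series oracle and saturates", {
  expect_equal(erf_approx(0), 0, tolerance = 1e-8)
  expect_identical(erf_approx(4), 1)
  expect_identical(erf_approx(1e3), 1)
  expect_error(erf_approx(-0.1), "x >= 0")
  x <- seq(0, 4, by = 1e-3)
  exact <- 2 * stats::pnorm(x * sqrt(2)) - 1
  expect_lt(max(abs(erf_approx(x) - exact)), 2e-7)
  # tail values that justify saturating the kernel at erf argument 4
  expect_equal(1 - (2 * stats::pnorm(4 * sqrt(2)) - 1), 1.5e-8,
               tolerance = 0.05)
  expect_equal(1 - (2 * stats::pnorm(5 * sqrt(2)) - 1), 1.5e-12,
               tolerance = 0.05)
})

test_that("(ss|ss) closed form: four unit Gaussians at the origin", {
  g <- c(1, 1, 0, 0, 0)
  expect_equal(eri_primitive(g, g, g, g), pi^2.5 / 4, tolerance = 1e-9)
  # F11(1/2, 3/2, 0) = 1 is the d = 0 limit used by the kernel
  expect_equal(eri_primitive(g, g, g, g, erf = "exact"), pi^2.5 / 4,
               tolerance = 1e-12)
})

test_that("distant s densities reach the point-charge limit", {
  d <- 20
  a <- norm_s_prim(0.8); b <- norm_s_prim(0.8)
  c_ <- norm_s_prim(1.3, c(d, 0, 0)); e <- norm_s_prim(1.3, c(d, 0, 0))
  v <- eri_primitive(a[1, ], b[1, ], c_[1, ], e[1, ])
  # both densities are unit charges, so (aa|cc) -> 1/d
  expect_equal(v, 1 / d, tolerance = 1e-6)
})

test_that("eri_primitive agrees with the Gauss-transform oracle", {
  set.seed(42)
  for (rep in 1:20) {
    prims <- lapply(1:4, function(i)
      c(stats::runif(1, 0.2, 2), stats::runif(1, 0.1, 3),
        stats::runif(3, -2.5, 2.5)))
    v <- eri_primitive(prims[[1]], prims[[2]], prims[[3]], prims[[4]])
    o <- oracle_prim_eri(prims[[1]], prims[[2]], prims[[3]], prims[[4]])
    expect_equal(v, o, tolerance = 1e-6)
  }
})

test_that("contracted ERIs are invariant under the 8 index permutations", {
  set.seed(11)
  prims <- lapply(1:4, function(i) {
    n <- sample(1:3, 1)
    cbind(stats::runif(n, -1, 1), stats::runif(n, 0.1, 2),
          matrix(stats::runif(3 * n, -2, 2), n, 3))
  })
  b <- custom_basis(prims)
  perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  vals <- vapply(perms, function(p)
    eri_contracted(b, p[1], p[2], p[3], p[4]), 0)
  expect_lt(max(abs(vals - vals[1])), 1e-12 * max(1, abs(vals[1])))
})

test_that("coulomb_weight interpolates smoothly between the cut-offs", {
  cfg <- screening_config()
  expect_identical(coulomb_weight(8, cfg), 1)
  expect_identical(coulomb_weight(10, cfg), 0)
  expect_equal(coulomb_weight(9, cfg), 0.5, tolerance = 1e-12)
  d <- seq(0, 12, by = 0.01)
  w <- coulomb_weight(d, cfg)
  expect_true(all(diff(w) <= 1e-12))            # non-increasing
  # first derivative vanishes at both cut-off radii
  eps <- 1e-5
  for (r in c(8, 10)) {
    slope <- (coulomb_weight(r + eps, cfg) - coulomb_weight(r - eps, cfg)) /
      (2 * eps)
    expect_lt(abs(slope), 1e-4)
  }
})

test_that("density relevance behaves like an absolute pair overlap", {
  b <- basis_for_structure(make_molecule("h2"))
  r11 <- density_relevance(b, 1, 1)
  expect_gt(r11, 0)
  # for an s orbital the self-relevance is the |coefficient| self-overlap
  def <- default_lobe_basis()
  sh <- def$elements$H[[1]]
  expect_equal(r11, s_self_overlap(abs(sh$A), sh$alpha), tolerance = 1e-10)

  far <- atomic_structure(c("H", "H"),
                          rbind(c(0, 0, 0), c(bohr2ang(50), 0, 0)))
  bf <- basis_for_structure(far)
  expect_lt(density_relevance(bf, 1, 2), 1e-10)
})

test_that("p x s relevance matches 3D quadrature of |phi_i||phi_j|", {
  st <- atomic_structure(c("C", "H"),
                         rbind(c(0, 0, 0), c(bohr2ang(2), 0, 0)))
  b <- basis_for_structure(st)
  i_px <- which(b$shell_label == "2p_x")[1]
  j_h <- which(b$atom_index == 2)[1]
  r <- density_relevance(b, i_px, j_h)
  q <- oracle_abs_pair_integral(b, i_px, j_h, half = 7, spacing = 0.1,
                                center = c(1, 0, 0))
  expect_equal(r, q, tolerance = 2e-2)
})

test_that("unique-ERI counter follows the combinatorial identity", {
  for (nbf in c(1, 2, 7, 72, 256)) {
    m <- nbf * (nbf + 1) / 2
    expect_identical(count_unique_eris(nbf), m * (m + 1) / 2)
  }
  expect_identical(count_unique_eris(256), 541089856)
})

test_that("H2 with screening disabled keeps all 6 unique ERIs", {
  st <- make_molecule("h2")
  b <- basis_for_structure(st)
  eris <- build_screened_eris(b, st, no_screening())
  expect_identical(eris$n_fully_surviving, 6L)
  expect_identical(eris$n_unique, 6)
  expect_true(all(eris$weight == 1))
  # counters are monotone
  expect_lte(eris$n_fully_surviving, eris$n_density_surviving)
  expect_lte(eris$n_density_surviving, eris$n_unique)
  expect_lte(eris$n_unique, eris$n_theoretical)
})

test_that("screened energies converge to the unscreened energy", {
  st <- make_molecule("h2o")
  b <- basis_for_structure(st)
  e_ref <- shared_h2o_scf()$total_energy
  thresholds <- c(1e-2, 1e-4, 1e-8)
  errs <- vapply(thresholds, function(thr) {
    cfg <- screening_config(density_threshold = thr, coulomb_lower = 1e6,
                            coulomb_upper = 1e6 + 1,
                            combined_relevance_threshold = 0)
    abs(scf_solve(st, basis = b, screening = cfg)$total_energy - e_ref)
  }, 0)
  expect_true(all(diff(errs) <= 1e-12))   # tighter threshold, smaller error
  expect_lt(errs[3], 1e-10)
})

test_that("ERI binary dump has the documented record layout", {
  st <- make_molecule("h2")
  eris <- build_screened_eris(basis_for_structure(st), st, no_screening())
  tmp <- withr::local_tempfile(fileext = ".bin")
  write_eri_dump(eris, tmp)
  expect_identical(file.size(tmp), 6 * 28)
  con <- file(tmp, "rb")
  on.exit(close(con))
  idx <- readBin(con, "integer", 4, size = 4, endian = "little")
  val <- readBin(con, "double", 1, size = 8, endian = "little")
  expect_identical(idx, c(eris$i[1], eris$j[1], eris$k[1], eris$l[1]))
  expect_identical(val, eris$value[1])
})
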