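# Basis parsing, lobe-expansion fitting and orbital enumeration.

ref_basis <- load_reference_basis()

test_that("reference parser handles element blocks, SP shells and errors", {
  h <- reference_element(ref_basis, "H")
  expect_length(h, 1L)
  expect_identical(h[[1]]$type, "S")
  expect_length(h[[1]]$exponents, 6L)

  cshells <- reference_element(ref_basis, "C")
  types <- vapply(cshells, `[[`, "", "type")
  expect_identical(types, c("S", "SP"))
  # SP block: shared exponents, separate s and p coefficient columns
  expect_identical(ncol(cshells[[2]]$coefficients), 2L)
  expect_length(cshells[[2]]$exponents, 6L)

  expect_error(parse_basis_reference(""), "parse error")
  expect_error(reference_element(ref_basis, "Xx"), "element not in basis")
  expect_error(parse_basis_reference("H 0\nS 2 1.00\n1.0 1.0"),
               "truncated|unterminated")
  expect_error(parse_basis_reference("H 0\nS 2 1.00\n1.0\n****"),
               "line 3")
})

test_that("s lobe fits are normalized and deterministic", {
  grid <- fit_grid(half_width = 6, spacing = 0.25)   # reduced grid: speed
  f1 <- fit_lobe_expansion(ref_basis$H[[1]], "s", grid = grid)
  expect_true(f1$converged)
  # self-overlap of the returned expansion is exactly renormalized
  expect_equal(s_self_overlap(f1$A, f1$alpha), 1, tolerance = 1e-10)
  # ... and the raw fit is itself close to normalized
  expect_lt(f1$rms, 5e-3 * sqrt(1 / pi))
  f2 <- fit_lobe_expansion(ref_basis$H[[1]], "s", grid = grid)
  expect_identical(f1$A, f2$A)
  expect_identical(f1$alpha, f2$alpha)
})

test_that("shipped basis cache shells are normalized to unit self-overlap", {
  def <- default_lobe_basis()
  for (el in names(def$elements)) {
    for (sh in def$elements[[el]]) {
      ov <- if (sh$l == "s") s_self_overlap(sh$A, sh$alpha)
            else p_self_overlap(sh$A, sh$alpha, sh$disp)
      expect_equal(ov, 1, tolerance = 1e-3,
                   label = sprintf("self-overlap %s %d%s", el, sh$n, sh$l))
    }
  }
})

test_that("fitted p shells are odd under reflection through the nodal plane", {
  def <- default_lobe_basis()
  sh <- Filter(function(s) s$l == "p", def$elements$C)[[1]]
  set.seed(7)
  pts <- matrix(stats::runif(60, -3, 3), 20, 3)
  v_plus <- eval_p_expansion(sh$A, sh$alpha, sh$disp, pts)
  v_minus <- eval_p_expansion(sh$A, sh$alpha, sh$disp,
                              cbind(-pts[, 1], pts[, 2], pts[, 3]))
  peak <- max(abs(v_plus))
  expect_lt(max(abs(v_plus + v_minus)), 1e-10 * peak)
})

test_that("carbon 2p lobe fit tracks the reference on a dense grid", {
  def <- default_lobe_basis()
  sh <- Filter(function(s) s$l == "p", def$elements$C)[[1]]
  # dense re-evaluation grid, finer than the fit grid
  ax <- seq(-6, 6, by = 0.11)
  pts <- as.matrix(expand.grid(ax, ax, 0))
  ref_v <- eval_reference_shell(ref_basis$C[[2]], "px", pts)
  fit_v <- eval_p_expansion(sh$A, sh$alpha, sh$disp, pts)
  expect_lt(sqrt(mean((fit_v - ref_v)^2)), 5e-3 * max(abs(ref_v)))
})

test_that("absolute-value lobe representation recombines to the orbital", {
  def <- default_lobe_basis()
  sh <- Filter(function(s) s$l == "p", def$elements$C)[[1]]
  ar <- sh$absrep
  ax <- seq(-6, 6, by = 0.23)
  pts <- as.matrix(expand.grid(ax, ax, 0))
  plus <- eval_abs_lobe(ar$A, ar$ax, ar$ay, ar$az, ar$x0, pts)
  minus <- eval_abs_lobe(ar$A, ar$ax, ar$ay, ar$az, ar$x0,
                         cbind(-pts[, 1], pts[, 2], pts[, 3]))
  ref_v <- eval_reference_shell(ref_basis$C[[2]], "px", pts)
  expect_lt(sqrt(mean((plus - minus - ref_v)^2)), 2e-2 * max(abs(ref_v)))
  # the two lobes are mirror images with opposite sign by construction
  expect_true(all(ar$A >= 0))
})

test_that("per-lobe absolute integral matches 3D quadrature", {
  def <- default_lobe_basis()
  sh <- Filter(function(s) s$l == "p", def$elements$C)[[1]]
  ar <- sh$absrep
  analytic <- sum(ar$A * pi^1.5 / sqrt(ar$ax * ar$ay * ar$az))
  ax <- seq(-7, 7, by = 0.1)
  pts <- as.matrix(expand.grid(ax, ax, ax))
  quad <- sum(abs(eval_abs_lobe(ar$A, ar$ax, ar$ay, ar$az, ar$x0, pts))) *
    0.1^3
  expect_equal(analytic, quad, tolerance = 1e-2)
})

test_that("basis_for_structure enumerates orbitals atom-major", {
  b <- basis_for_structure(make_molecule("h2o"))
  expect_identical(b$nbf, 7L)
  expect_identical(b$shell_label[1:5], c("1s", "2s", "2p_x", "2p_y", "2p_z"))
  expect_identical(b$atom_index, c(rep(1L, 5), 2L, 3L))
  # minimal-basis valence flags: only the heavy-atom 1s is core
  expect_identical(b$is_valence, c(FALSE, rep(TRUE, 6)))

  # beta-carotene-sized composition: 40 C x 5 + 56 H x 1 = 256 orbitals
  set.seed(1)
  big <- atomic_structure(c(rep("C", 40), rep("H", 56)),
                          matrix(stats::runif(96 * 3, 0, 30), 96, 3))
  expect_identical(basis_for_structure(big)$nbf, 256L)

  empty <- atomic_structure(character(0), matrix(numeric(0), 0, 3))
  expect_identical(basis_for_structure(empty)$nbf, 0L)

  bad <- atomic_structure(c("H", "Fe"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_error(basis_for_structure(bad), "element not in basis: Fe")
})

test_that("basis cache round-trips through JSON", {
  def <- default_lobe_basis()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_basis_cache(def, tmp)
  back <- read_basis_cache(tmp)
  expect_equal(back$elements$C, def$elements$C, tolerance = 0)
})

test_that("lobe overlap matrix of CH4 matches the reference contracted basis", {
  st <- make_molecule("ch4")
  b <- basis_for_structure(st)
  S <- overlap_matrix(b)
  S_ref <- reference_overlap_quadrature(st, ref_basis)
  # dominated by the same-atom 1s/2s overlap, where the 3-Gaussian
  # truncation of the 6-Gaussian reference shows up most
  expect_lt(max(abs(S - S_ref)), 5e-3)
})
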