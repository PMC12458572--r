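# Core generation, bond classification, capped subsystems, density merging.

water_dimer <- function(sep_ang = 3.0) {
  w1 <- make_molecule("h2o")
  w2 <- translate_structure(make_molecule("h2o"), ang2bohr(c(sep_ang, 0, 0)))
  atomic_structure(c(w1$elements, w2$elements),
                   rbind(w1$xyz, w2$xyz), units = "bohr",
                   provenance = "fixture:water_dimer")
}

test_that("k-means separates well-separated molecules and handles k = n", {
  dim_far <- local({
    w1 <- make_molecule("h2o")
    w2 <- translate_structure(make_molecule("h2o"), ang2bohr(c(20, 0, 0)))
    atomic_structure(c(w1$elements, w2$elements), rbind(w1$xyz, w2$xyz),
                     units = "bohr")
  })
  lab <- kmeans_cores(dim_far, 2, seed = 3)
  expect_identical(lab[1:3], rep(lab[1], 3))
  expect_identical(lab[4:6], rep(lab[4], 3))
  expect_false(lab[1] == lab[4])

  expect_identical(kmeans_cores(dim_far, n_atoms(dim_far)),
                   seq_len(n_atoms(dim_far)))
  expect_error(kmeans_cores(dim_far, 0), "positive")
  expect_error(kmeans_cores(dim_far, 99), "exceeds")
  # determinism under a fixed seed
  expect_identical(kmeans_cores(dim_far, 2, seed = 5),
                   kmeans_cores(dim_far, 2, seed = 5))
})

test_that("k-means clusters beat the worst of random assignments", {
  set.seed(9)
  centers <- matrix(stats::runif(12 * 3, 0, 60), 12, 3)
  pts <- centers[rep(1:12, each = 8), ] + matrix(stats::rnorm(288, 0, 1.0),
                                                 96, 3)
  st <- atomic_structure(rep("C", 96), pts)
  wss <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      m <- colMeans(st$xyz[lab == g, , drop = FALSE])
      s <- s + sum(sweep(st$xyz[lab == g, , drop = FALSE], 2, m)^2)
    }
    s
  }
  km_wss <- wss(kmeans_cores(st, 12, seed = 1))
  worst <- max(vapply(1:20, function(i) {
    set.seed(100 + i)
    wss(sample(1:12, 96, replace = TRUE))
  }, 0))
  expect_lte(km_wss, worst)
})

test_that("grid cores bin atoms into bounding-box cells", {
  line <- atomic_structure(rep("He", 3),
                           rbind(c(0, 0, 0), c(15, 0, 0), c(30, 0, 0)))
  expect_identical(grid_cores(line, 12.5), 1:3)
  # all atoms in one cell
  expect_identical(grid_cores(make_molecule("h2o"), 12.5), rep(1L, 3))
  expect_error(grid_cores(line, 0), "positive")
  # box-filling lattice: cell count is the product of per-axis counts
  g <- as.matrix(expand.grid(x = seq(0, 67.2, by = 4), y = seq(0, 78.8, by = 4),
                             z = seq(0, 86.8, by = 4)))
  box <- atomic_structure(rep("He", nrow(g)), g)
  n_cells <- length(unique(grid_cores(box, 12.5)))
  per_axis <- ceiling(c(67.2, 78.8, 86.8) / 12.5)
  expect_identical(n_cells, as.integer(prod(per_axis)))
})

test_that("bond classification follows the shipped distance table", {
  expect_identical(classify_bond("C", "C", 1.34), "double")
  expect_identical(classify_bond("C", "C", 1.54), "single")
  expect_identical(classify_bond("C", "C", 3.0), "none")
  expect_identical(classify_bond("C", "H", 1.09), "single")
  # amide C-N is a single bond for capping purposes
  expect_identical(classify_bond("N", "C", 1.35), "single")
  expect_warning(out <- classify_bond("C", "Fe", 1.5), "no bond table")
  expect_identical(out, "none")
})

test_that("fixture geometries classify as the bonds they model", {
  et <- make_molecule("ethylene")
  d_cc <- bohr2ang(sqrt(sum((et$xyz[1, ] - et$xyz[2, ])^2)))
  expect_identical(classify_bond("C", "C", d_cc), "double")
  ea <- make_molecule("ethane")
  d_cc2 <- bohr2ang(sqrt(sum((ea$xyz[1, ] - ea$xyz[2, ])^2)))
  expect_identical(classify_bond("C", "C", d_cc2), "single")
})

test_that("a water-dimer core buffers the partner without caps", {
  st <- water_dimer(3.0)
  sub <- build_subsystem(1:3, st, partition_config(buffer_cutoff = 8))
  expect_identical(sub$core_atoms, 1:3)
  expect_identical(sub$buffer_atoms, 4:6)
  expect_identical(nrow(sub$cap_atoms), 0L)
  expect_identical(n_atoms(sub$structure), 6L)
})

test_that("severed single bonds get a cap hydrogen at the table length", {
  dec <- make_chain("alkane", 10)
  # core around one chain end with a small buffer severs a C-C bond
  sub <- build_subsystem(which(seq_len(n_atoms(dec)) %in% 1:2), dec,
                         partition_config(buffer_cutoff = 3.2))
  expect_gt(nrow(sub$cap_atoms), 0)
  cap <- sub$cap_atoms[1, ]
  anchor <- dec$xyz[cap$anchor, ]
  gone <- dec$xyz[cap$replaced, ]
  capv <- c(cap$x, cap$y, cap$z) - anchor
  bondv <- gone - anchor
  # cap lies on the former bond direction at the C-H table length
  cosang <- sum(capv * bondv) / sqrt(sum(capv^2) * sum(bondv^2))
  expect_equal(cosang, 1, tolerance = 1e-10)
  expect_equal(bohr2ang(sqrt(sum(capv^2))), 1.09, tolerance = 1e-6)
  # capped subsystems keep an even electron count
  expect_identical(sub$n_electrons %% 2L, 0L)
})

test_that("a cut double bond pulls both partners in", {
  et <- make_molecule("ethylene")
  # buffer that includes C1's hydrogens but excludes the second carbon by
  # distance alone: the C=C pulls it in, its C-H bonds get capped
  sub <- build_subsystem(1L, et, partition_config(buffer_cutoff = 1.2))
  expect_true(2L %in% sub$parent_atoms)
  # no cap sits on the double bond itself
  expect_false(any(sub$cap_atoms$anchor == 1 & sub$cap_atoms$replaced == 2))
  # severed bonds are C-H only, so every cap replaces a hydrogen
  expect_true(all(et$elements[sub$cap_atoms$replaced] == "H"))
  expect_identical(sub$n_electrons %% 2L, 0L)
})

test_that("merging a single all-covering subsystem is the identity", {
  st <- water_dimer(3.0)
  sub <- build_subsystem(1:6, st, partition_config(buffer_cutoff = 8))
  scf <- scf_solve(sub$structure, screening = no_screening())
  pb <- basis_for_structure(st)
  merged <- merge_density(list(list(subsystem = sub, scf = scf)), pb)
  expect_equal(merged$P, scf$P, tolerance = 0)
  expect_identical(merged$n_uncovered, 0L)
  expect_true(isSymmetric(merged$P))
})

test_that("overlapping identical values average to themselves", {
  st <- water_dimer(3.0)
  cfg <- partition_config(buffer_cutoff = 8)
  s1 <- build_subsystem(1:3, st, cfg)
  s2 <- build_subsystem(4:6, st, cfg)
  # both subsystems contain all six atoms, so their SCFs are identical
  r1 <- scf_solve(s1$structure, screening = no_screening())
  r2 <- scf_solve(s2$structure, screening = no_screening())
  pb <- basis_for_structure(st)
  merged <- merge_density(list(list(subsystem = s1, scf = r1),
                               list(subsystem = s2, scf = r2)), pb)
  direct <- scf_solve(st, basis = pb, screening = no_screening())
  expect_equal(merged$P, direct$P, tolerance = 1e-5)
  expect_equal(sum(merged$P * direct$S), 20, tolerance = 0.2)
})

test_that("a whole-system core reproduces the direct SCF", {
  st <- make_molecule("h2o")
  run <- dnc_run(st, partition_config("grid", cell_size = 50),
                 screening = no_screening())
  direct <- scf_solve(st, screening = no_screening())
  expect_identical(length(run$subsystem_results), 1L)
  expect_equal(run$P, direct$P, tolerance = 1e-12)
  ea <- atomic_energies(direct)
  expect_equal(run$atomic_energies, ea$energies, tolerance = 1e-12)
})

test_that("divide-and-conquer recovers water-dimer atomic energies", {
  st <- water_dimer(3.0)
  run <- dnc_run(st, partition_config("kmeans", k = 2, buffer_cutoff = 8),
                 screening = no_screening())
  expect_identical(length(run$failures), 0L)
  direct <- scf_solve(st, screening = no_screening())
  ea <- atomic_energies(direct)
  expect_lt(max(abs(run$atomic_energies - ea$energies)), 1e-3)
})

test_that("subsystem runs are deterministic and order-independent", {
  dec <- make_chain("alkane", 6)
  cfg <- partition_config("grid", cell_size = 4, buffer_cutoff = 3.5)
  labels <- grid_cores(dec, cfg$cell_size)
  subs <- lapply(sort(unique(labels)), function(l)
    build_subsystem(which(labels == l), dec, cfg))
  runs1 <- lapply(subs, function(s) scf_solve(s$structure,
                                              screening = no_screening()))
  runs2 <- lapply(rev(seq_along(subs)), function(i)
    scf_solve(subs[[i]]$structure, screening = no_screening()))
  for (i in seq_along(subs))
    expect_identical(runs1[[i]]$P,
                     runs2[[length(subs) + 1L - i]]$P)
})

test_that("buffer growth converges core energies toward the full system", {
  ch <- make_chain("alkane", 8)
  direct <- atomic_energies(scf_solve(ch, screening = no_screening()))
  rms <- vapply(c(2.5, 4.5, 8.0), function(buf) {
    run <- dnc_run(ch, partition_config("grid", cell_size = 5,
                                        buffer_cutoff = buf),
                   screening = no_screening())
    sqrt(mean((run$atomic_energies - direct$energies)^2))
  }, 0)
  expect_true(all(diff(rms) <= 1e-12))
  expect_lt(rms[3] / sqrt(mean(direct$energies^2)), 0.02)
})

test_that("subsystem manifests serialize core, buffer and caps", {
  st <- water_dimer(3.0)
  sub <- build_subsystem(1:3, st, partition_config(buffer_cutoff = 8))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_subsystem_manifest(list(sub), tmp)
  man <- jsonlite::read_json(tmp, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  expect_identical(as.integer(man[[1]]$core), 1:3)
  expect_identical(as.integer(man[[1]]$buffer), 4:6)
})
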