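#' Partition configuration for divide-and-conquer runs
#'
#' @param mode `"grid"` (3D cells) or `"kmeans"` (spatial clustering).
#' @param cell_size grid cell edge in Angstrom (default 12.5).
#' @param k number of k-means clusters (required for `mode = "kmeans"`).
#' @param buffer_cutoff buffer radius around each core in Angstrom
#'   (default 8).
#' @param seed seed for the k-means initialization.
#' @return A `partition_config`.
#' @export
partition_config <- function(mode = c("grid", "kmeans"), cell_size = 12.5,
                             k = NULL, buffer_cutoff = 8, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(cell_size > 0, buffer_cutoff > 0)
  if (mode == "kmeans" && is.null(k)) stop("kmeans mode needs k")
  out <- list(mode = mode, cell_size = cell_size, k = k,
              buffer_cutoff = buffer_cutoff, seed = as.integer(seed))
  class(out) <- "partition_config"
  out
}

#' k-means core assignment
#'
#' Groups atoms into `k` spatially localized clusters that serve as the
#' core regions.  Deterministic for a fixed seed; empty clusters cannot
#' arise with Hartigan-Wong on distinct points, and ties are resolved by
#' the seeded initialization.
#'
#' @param structure an [atomic_structure()].
#' @param k number of clusters, `1 <= k <= n_atoms`.
#' @param seed RNG seed.
#' @return integer vector of cluster labels (1..k), one per atom.
#' @export
kmeans_cores <- function(structure, k, seed = 1L) {
  if (k <= 0) stop("k must be positive")
  n <- n_atoms(structure)
  if (k > n) stop("k exceeds the number of atoms")
  if (k == n) return(seq_len(n))
  xyz <- unique(structure$xyz)
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(structure$xyz, centers = min(k, nrow(xyz)),
                  nstart = 5L, iter.max = 100L))
  as.integer(km$cluster)
}

#' Grid core assignment
#'
#' Atoms are binned into cubic cells of edge `cell_size` anchored at the
#' minimum corner of the bounding box; empty cells are dropped and labels
#' renumbered consecutively.
#'
#' @param structure an [atomic_structure()].
#' @param cell_size cell edge, Angstrom.
#' @return integer vector of cell labels (1..n_cells), one per atom.
#' @export
grid_cores <- function(structure, cell_size = 12.5) {
  if (cell_size <= 0) stop("cell_size must be positive")
  cs <- ang2bohr(cell_size)
  origin <- apply(structure$xyz, 2, min)
  cell <- floor(sweep(structure$xyz, 2, origin) / cs)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  as.integer(factor(key, levels = unique(key)))
}

# covalent bond tables: single/double max distances (Angstrom) derived from
# standard covalent radii (single: Cordero; double: Pyykko) + 0.06 A band
.covalent_single <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                      P = 1.07)
.covalent_double <- c(H = NA, C = 0.67, N = 0.60, O = 0.57, S = 0.94,
                      P = 1.02)
.bond_tolerance <- 0.06
# X-H cap lengths (Angstrom)
.cap_lengths <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34, P = 1.42)

#' Load the editable bond-classification table
#'
#' Shipped as a plain-text file so the thresholds can be audited or
#' replaced; [classify_bond()] uses these values.
#'
#' @return data.frame with element pair thresholds in Angstrom.
#' @export
bond_table <- function() {
  utils::read.table(system.file("extdata", "bond-table.tsv",
                                package = "lobehf"),
                    header = TRUE, stringsAsFactors = FALSE)
}

.bond_env <- new.env(parent = emptyenv())

bond_lookup <- function() {
  if (is.null(.bond_env$tab)) {
    tab <- bond_table()
    key <- paste(tab$elem1, tab$elem2)
    .bond_env$tab <- tab
    .bond_env$single <- stats::setNames(tab$single_max, key)
    .bond_env$double <- stats::setNames(tab$double_max, key)
  }
  .bond_env
}

#' Classify a bond from an interatomic distance
#'
#' Distance-based bond character: `double` up to the double-bond threshold,
#' `single` up to the single-bond threshold, otherwise `none`.  Thresholds
#' come from the shipped covalent-radius table ([bond_table()]); an
#' uncovered element pair yields `none` with a warning.
#'
#' @param elem1,elem2 element symbols.
#' @param distance Angstrom.
#' @return `"none"`, `"single"` or `"double"`.
#' @export
classify_bond <- function(elem1, elem2, distance) {
  lk <- bond_lookup()
  key <- paste(sort(c(elem1, elem2)), collapse = " ")
  smax <- unname(lk$single[key])
  if (is.na(smax)) {
    warning("no bond table entry for ", key, "; treated as non-bonded")
    return("none")
  }
  dmax <- unname(lk$double[key])
  if (!is.na(dmax) && distance <= dmax) return("double")
  if (distance <= smax) return("single")
  "none"
}

# all covalent neighbours of atom a (indices + bond order)
covalent_neighbours <- function(structure, a, max_bond_ang = 2.6) {
  d <- sqrt(rowSums((structure$xyz -
                       matrix(structure$xyz[a, ], n_atoms(structure), 3,
                              byrow = TRUE))^2))
  d_ang <- bohr2ang(d)
  cand <- which(d_ang <= max_bond_ang & seq_along(d) != a)
  if (!length(cand)) return(data.frame(atom = integer(0), bond = character(0)))
  bond <- vapply(cand, function(b)
    suppressWarnings(classify_bond(structure$elements[a],
                                   structure$elements[b], d_ang[b])), "")
  keep <- bond != "none"
  data.frame(atom = cand[keep], bond = bond[keep],
             stringsAsFactors = FALSE)
}

#' Build one divide-and-conquer subsystem
#'
#' The buffer contains all atoms within `buffer_cutoff` of any core atom.
#' Covalent bonds crossing the outer boundary are then repaired: a severed
#' double bond pulls the outside partner in; a severed single bond replaces
#' the outside atom with a cap hydrogen placed along the former bond at the
#' standard X-H length of the inside (anchor) element.  If the resulting
#' electron count is odd, the nearest outside bonded atom is pulled in (with
#' its own repair) until parity is restored.
#'
#' @param core integer vector of core atom indices into `structure`.
#' @param structure the parent [atomic_structure()].
#' @param config a [partition_config()].
#' @return A `subsystem`: local structure (core + buffer + caps), index
#'   maps back to the parent, and cap records.
#' @export
build_subsystem <- function(core, structure, config = partition_config()) {
  n <- n_atoms(structure)
  core <- sort(unique(as.integer(core)))
  cut <- ang2bohr(config$buffer_cutoff)
  inside <- rep(FALSE, n); inside[core] <- TRUE
  for (a in core) {
    d2 <- rowSums((structure$xyz -
                     matrix(structure$xyz[a, ], n, 3, byrow = TRUE))^2)
    inside <- inside | d2 <= cut^2
  }

  caps <- data.frame(anchor = integer(0), replaced = integer(0))
  # boundary repair; double bonds can pull atoms in, so iterate to closure
  repeat {
    grew <- FALSE
    for (a in which(inside)) {
      nb <- covalent_neighbours(structure, a)
      for (r in seq_len(nrow(nb))) {
        b <- nb$atom[r]
        if (inside[b]) next
        if (nb$bond[r] == "double") {
          inside[b] <- TRUE
          grew <- TRUE
        } else if (!any(caps$anchor == a & caps$replaced == b)) {
          caps <- rbind(caps, data.frame(anchor = a, replaced = b))
        }
      }
    }
    if (!grew) break
  }
  caps <- caps[!inside[caps$replaced], , drop = FALSE]

  # even-electron repair: pull in the nearest capped-out atom until parity
  repeat {
    nel <- sum(structure$Z[inside]) + nrow(caps)
    if (nel %% 2L == 0L) break
    if (!nrow(caps))
      stop("odd electron count in subsystem and no capped bond to extend")
    dcap <- sqrt(rowSums((structure$xyz[caps$replaced, , drop = FALSE] -
                            structure$xyz[caps$anchor, , drop = FALSE])^2))
    pull <- caps$replaced[which.min(dcap)]
    inside[pull] <- TRUE
    caps <- caps[!inside[caps$replaced], , drop = FALSE]
    # the pulled atom may itself sever bonds; add its caps
    nb <- covalent_neighbours(structure, pull)
    for (r in seq_len(nrow(nb))) {
      b <- nb$atom[r]
      if (inside[b]) next
      if (nb$bond[r] == "double") inside[b] <- TRUE
      else caps <- rbind(caps, data.frame(anchor = pull, replaced = b))
    }
    caps <- caps[!inside[caps$replaced], , drop = FALSE]
  }

  local_atoms <- which(inside)
  sub <- subset_structure(structure, local_atoms)
  cap_xyz <- NULL
  if (nrow(caps)) {
    cap_xyz <- matrix(0, nrow(caps), 3)
    for (r in seq_len(nrow(caps))) {
      anchor <- structure$xyz[caps$anchor[r], ]
      gone <- structure$xyz[caps$replaced[r], ]
      v <- gone - anchor
      len <- ang2bohr(.cap_lengths[[structure$elements[caps$anchor[r]]]] %||%
                        1.09)
      cap_xyz[r, ] <- anchor + v / sqrt(sum(v^2)) * len
    }
    # a cap must not collide with a retained atom
    for (r in seq_len(nrow(caps))) {
      d <- sqrt(rowSums((sub$xyz - matrix(cap_xyz[r, ], n_atoms(sub), 3,
                                          byrow = TRUE))^2))
      if (any(bohr2ang(d) < 0.5))
        stop("cap hydrogen for bond ", caps$anchor[r], "-", caps$replaced[r],
             " overlaps an existing atom")
    }
    cap_st <- atomic_structure(rep("H", nrow(caps)), cap_xyz, units = "bohr",
                               provenance = "cap")
    sub <- atomic_structure(c(sub$elements, cap_st$elements),
                            rbind(sub$xyz, cap_st$xyz), units = "bohr",
                            provenance = "subsystem")
  } else {
    sub$provenance <- "subsystem"
  }

  out <- list(structure = sub,
              core_atoms = core,
              buffer_atoms = setdiff(local_atoms, core),
              cap_atoms = if (nrow(caps))
                data.frame(anchor = caps$anchor, replaced = caps$replaced,
                           x = cap_xyz[, 1], y = cap_xyz[, 2],
                           z = cap_xyz[, 3]) else
                             data.frame(anchor = integer(0),
                                        replaced = integer(0)),
              parent_atoms = local_atoms,   # local index -> parent index
              n_electrons = sum(sub$Z))
  class(out) <- "subsystem"
  out
}

#' @export
print.subsystem <- function(x, ...) {
  cat(sprintf("<subsystem> core %d + buffer %d + caps %d atoms (%d electrons)\n",
              length(x$core_atoms), length(x$buffer_atoms),
              nrow(x$cap_atoms), x$n_electrons))
  invisible(x)
}

#' Export subsystem definitions as a JSON manifest
#' @param subsystems list of `subsystem` objects.
#' @param path output JSON path.
#' @export
write_subsystem_manifest <- function(subsystems, path) {
  man <- lapply(subsystems, function(s) list(
    core = s$core_atoms, buffer = s$buffer_atoms,
    caps = s$cap_atoms, parent_atoms = s$parent_atoms,
    n_electrons = s$n_electrons))
  jsonlite::write_json(man, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Merge subsystem density matrices into a global density
#'
#' An element (mu, nu) whose two parent atoms are both inside a single
#' subsystem is taken from the subsystem whose core contains the atom of
#' `mu` (tie-break: lower parent atom index); if the two atoms are only
#' co-resident in several subsystems, the arithmetic mean of the candidate
#' values is used.  Cap-atom functions never map back to the parent.
#'
#' @param subsystem_results list of lists with elements `subsystem` and
#'   `scf` (an `scf_result` on the subsystem).
#' @param parent_basis the `lobe_basis` of the full structure.
#' @return list with the sparse-symmetric global `P`, a provenance matrix
#'   (0 = uncovered, 1 = single owner, 2 = averaged) and the count of
#'   uncovered elements.
#' @export
merge_density <- function(subsystem_results, parent_basis) {
  nbf <- parent_basis$nbf
  P <- matrix(0, nbf, nbf)
  acc <- matrix(0, nbf, nbf)    # accumulated values for averaging
  cnt <- matrix(0L, nbf, nbf)
  owner <- matrix(FALSE, nbf, nbf)

  for (res in subsystem_results) {
    sub <- res$subsystem; scf <- res$scf
    # map local orbitals to parent orbitals: parent atoms only (not caps)
    loc_basis <- scf$basis
    n_real <- length(sub$parent_atoms)
    loc2par <- rep(NA_integer_, loc_basis$nbf)
    for (q in seq_len(loc_basis$nbf)) {
      la <- loc_basis$atom_index[q]
      if (la <= n_real) {
        pa <- sub$parent_atoms[la]
        # orbital ordering within an atom is deterministic, so match by rank
        loc_of_atom <- which(loc_basis$atom_index == la)
        par_of_atom <- which(parent_basis$atom_index == pa)
        loc2par[q] <- par_of_atom[match(q, loc_of_atom)]
      }
    }
    core_set <- sub$core_atoms
    keep <- which(!is.na(loc2par))
    for (qi in keep) {
      for (qj in keep) {
        mu <- loc2par[qi]; nu <- loc2par[qj]
        if (mu > nu) next
        v <- scf$P[qi, qj]
        pa_mu <- parent_basis$atom_index[mu]
        owns <- pa_mu %in% core_set
        if (owns && !owner[mu, nu]) {
          P[mu, nu] <- v
          owner[mu, nu] <- TRUE
        }
        acc[mu, nu] <- acc[mu, nu] + v
        cnt[mu, nu] <- cnt[mu, nu] + 1L
      }
    }
  }
  averaged <- !owner & cnt > 0L
  P[averaged] <- acc[averaged] / cnt[averaged]
  P[lower.tri(P)] <- t(P)[lower.tri(P)]
  prov <- matrix(0L, nbf, nbf)
  prov[cnt > 0L] <- 1L
  prov[averaged & cnt > 1L] <- 2L
  prov[lower.tri(prov)] <- t(prov)[lower.tri(prov)]
  list(P = P, provenance = prov,
       n_uncovered = sum(cnt[upper.tri(cnt, diag = TRUE)] == 0L))
}

#' Divide-and-conquer Hartree-Fock run
#'
#' Generates cores (grid or k-means), builds capped subsystems, solves each
#' independently (results are order-independent), reports atomic energies
#' for core atoms only and merges the density matrices into a global
#' density over the parent basis.
#'
#' @param structure the full [atomic_structure()].
#' @param partition a [partition_config()].
#' @param screening a [screening_config()].
#' @param scf an [scf_config()].
#' @param basis_def basis-set definition for all subsystems.
#' @param verbose print progress.
#' @return A `dnc_result`: global density + provenance, per-atom energies
#'   (Hartree, core ownership), subsystem list, per-subsystem logs and the
#'   failure list.
#' @export
dnc_run <- function(structure, partition = partition_config(),
                    screening = screening_config(), scf = scf_config(),
                    basis_def = default_lobe_basis(), verbose = FALSE) {
  labels <- if (partition$mode == "grid")
    grid_cores(structure, partition$cell_size)
  else kmeans_cores(structure, partition$k, partition$seed)

  parent_basis <- basis_for_structure(structure, basis_def)
  results <- list(); failures <- list(); logs <- list()
  e_atom <- rep(NA_real_, n_atoms(structure))

  for (lab in sort(unique(labels))) {
    core <- which(labels == lab)
    sub <- build_subsystem(core, structure, partition)
    if (verbose)
      message(sprintf("subsystem %d: %d core / %d buffer / %d caps", lab,
                      length(sub$core_atoms), length(sub$buffer_atoms),
                      nrow(sub$cap_atoms)))
    res <- tryCatch(
      scf_solve(sub$structure, basis = basis_for_structure(sub$structure,
                                                           basis_def),
                screening = screening, config = scf),
      error = function(e) e)
    if (inherits(res, "error") || !res$converged) {
      failures[[length(failures) + 1L]] <- list(label = lab,
        reason = if (inherits(res, "error")) conditionMessage(res)
                 else "not converged")
      next
    }
    ea <- atomic_energies(res)
    # keep energies of core atoms only (local index of parent core atoms)
    loc_core <- match(sub$core_atoms, sub$parent_atoms)
    e_atom[sub$core_atoms] <- ea$energies[loc_core]
    logs[[length(logs) + 1L]] <- list(label = lab,
      n_core = length(sub$core_atoms), n_buffer = length(sub$buffer_atoms),
      n_caps = nrow(sub$cap_atoms), iterations = res$iterations,
      total_energy = res$total_energy,
      n_fully_surviving = res$eris$n_fully_surviving)
    results[[length(results) + 1L]] <- list(subsystem = sub, scf = res)
  }

  merged <- if (length(results)) merge_density(results, parent_basis)
            else list(P = matrix(0, parent_basis$nbf, parent_basis$nbf),
                      provenance = NULL, n_uncovered = NA)
  out <- list(P = merged$P, provenance = merged$provenance,
              n_uncovered = merged$n_uncovered,
              atomic_energies = e_atom, labels = labels,
              subsystem_results = results, logs = logs, failures = failures,
              parent_basis = parent_basis, structure = structure)
  class(out) <- "dnc_result"
  out
}

#' @export
print.dnc_result <- function(x, ...) {
  cat(sprintf("<dnc_result> %d subsystems (%d failed), %d atoms\n",
              length(x$subsystem_results) + length(x$failures),
              length(x$failures), n_atoms(x$structure)))
  invisible(x)
}
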