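#' Fit a full lobe basis-set definition
#'
#' Runs [fit_lobe_expansion()] (and, for p shells,
#' [fit_abs_lobe_representation()]) for every shell of the requested
#' elements of a reference basis.  Shells are labelled by their order of
#' appearance (first S block is 1s, an SP block contributes 2s and 2p, a
#' second SP block 3s and 3p).  A shell is flagged as valence when its
#' principal quantum number equals the element's valence shell, so in a
#' minimal basis only heavy-atom core shells are excluded from the
#' atomic-energy partition.
#'
#' @param ref a `basis_set_reference` from [parse_basis_reference()].
#' @param elements element symbols to fit (default: all in `ref`).
#' @param grid a [fit_grid()].
#' @param quiet suppress progress messages.
#' @return A `basis_set_definition`.
#' @export
fit_basis_set <- function(ref, elements = names(ref), grid = fit_grid(),
                          quiet = FALSE) {
  out <- list()
  for (el in elements) {
    shells <- reference_element(ref, el)
    fitted <- list()
    n_s <- 0L
    for (sh in shells) {
      if (sh$type %in% c("S", "SP")) {
        n_s <- n_s + 1L
        if (!quiet) message("fitting ", el, " ", n_s, "s")
        fs <- fit_lobe_expansion(sh, "s", grid = grid)
        fitted[[length(fitted) + 1L]] <- list(
          n = n_s, l = "s", A = fs$A, alpha = fs$alpha, rms = fs$rms)
      }
      if (sh$type %in% c("P", "SP")) {
        if (!quiet) message("fitting ", el, " ", n_s, "p")
        fp <- fit_lobe_expansion(sh, "p", grid = grid)
        fa <- fit_abs_lobe_representation(sh, grid = grid, lobe_fit = fp)
        fitted[[length(fitted) + 1L]] <- list(
          n = n_s, l = "p", A = fp$A, alpha = fp$alpha, disp = fp$disp,
          rms = fp$rms,
          absrep = list(A = fa$A, ax = fa$ax, ay = fa$ay, az = fa$az,
                        x0 = fa$x0, rms = fa$rms,
                        abs_integral = fa$abs_integral))
      }
    }
    out[[el]] <- fitted
  }
  structure(list(elements = out,
                 grid = list(half_width = grid$half_width,
                             spacing = grid$spacing),
                 schema_version = 1L),
            class = "basis_set_definition")
}

#' Write / read a fitted basis definition as JSON
#'
#' The cache is a documented plain-text JSON file with a schema version, so
#' fits are performed once per element and shipped with the package.
#'
#' @param basis a `basis_set_definition`.
#' @param path JSON path.
#' @export
write_basis_cache <- function(basis, path) {
  jsonlite::write_json(unclass(basis), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_basis_cache
#' @export
read_basis_cache <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(raw$schema_version) || raw$schema_version != 1L)
    stop("unsupported basis cache schema in ", path)
  raw$elements <- lapply(raw$elements, function(shells)
    lapply(shells, function(sh) {
      sh$A <- as.numeric(sh$A); sh$alpha <- as.numeric(sh$alpha)
      if (!is.null(sh$disp)) sh$disp <- as.numeric(sh$disp)
      if (!is.null(sh$absrep))
        sh$absrep <- lapply(sh$absrep, as.numeric)
      sh
    }))
  structure(raw, class = "basis_set_definition")
}

#' Load the fitted minimal lobe basis shipped with the package
#' @return A `basis_set_definition` covering H, C, N, O, P, S.
#' @export
default_lobe_basis <- function() {
  cache <- getOption("lobehf.basis_cache",
                     system.file("extdata", "lobe-basis-cache.json",
                                 package = "lobehf"))
  read_basis_cache(cache)
}

# valence shell (principal quantum number) per element covered by the basis
.valence_n <- c(H = 1L, He = 1L, C = 2L, N = 2L, O = 2L, F = 2L,
                P = 3L, S = 3L)

#' Build the orbital list for a structure
#'
#' Expands the fitted per-element shells over the atoms of a structure in a
#' deterministic atom-major order (1s, 2s, 2p_x, 2p_y, 2p_z, ...).  p shells
#' become sign-paired displaced s-Gaussian lobes along the lab axes.
#'
#' @param structure an [atomic_structure()].
#' @param basis a `basis_set_definition` (default: shipped minimal basis).
#' @return A `lobe_basis` object: per-orbital metadata plus flattened
#'   primitive arrays (signed lobes for integrals, positive anisotropic
#'   lobes for density relevance).
#' @export
basis_for_structure <- function(structure, basis = default_lobe_basis()) {
  n_at <- n_atoms(structure)
  atom_index <- integer(0); shell_label <- character(0)
  is_valence <- logical(0); element <- character(0)
  off <- 0L; A <- numeric(0); al <- numeric(0)
  cx <- numeric(0); cy <- numeric(0); cz <- numeric(0)
  aoff <- 0L; aA <- numeric(0); aax <- numeric(0); aay <- numeric(0)
  aaz <- numeric(0); aox <- numeric(0); aoy <- numeric(0); aoz <- numeric(0)
  axes <- diag(3)

  for (ia in seq_len(n_at)) {
    el <- structure$elements[ia]
    shells <- basis$elements[[el]]
    if (is.null(shells))
      stop("element not in basis: ", el, " (atom ", ia, ")")
    pos <- structure$xyz[ia, ]
    vn <- unname(.valence_n[el])
    if (is.na(vn)) vn <- max(vapply(shells, `[[`, 0L, "n"))
    for (sh in shells) {
      if (sh$l == "s") {
        atom_index <- c(atom_index, ia)
        shell_label <- c(shell_label, paste0(sh$n, "s"))
        is_valence <- c(is_valence, sh$n >= vn)
        element <- c(element, el)
        A <- c(A, sh$A); al <- c(al, sh$alpha)
        cx <- c(cx, rep(pos[1], length(sh$A)))
        cy <- c(cy, rep(pos[2], length(sh$A)))
        cz <- c(cz, rep(pos[3], length(sh$A)))
        off <- c(off, off[length(off)] + length(sh$A))
        # abs representation of an s shell: its own primitives, |A|
        aA <- c(aA, abs(sh$A))
        aax <- c(aax, sh$alpha); aay <- c(aay, sh$alpha); aaz <- c(aaz, sh$alpha)
        aox <- c(aox, rep(pos[1], length(sh$A)))
        aoy <- c(aoy, rep(pos[2], length(sh$A)))
        aoz <- c(aoz, rep(pos[3], length(sh$A)))
        aoff <- c(aoff, aoff[length(aoff)] + length(sh$A))
      } else {
        for (ax_i in 1:3) {
          e <- axes[ax_i, ]
          atom_index <- c(atom_index, ia)
          shell_label <- c(shell_label,
                           paste0(sh$n, "p_", c("x", "y", "z")[ax_i]))
          is_valence <- c(is_valence, sh$n >= vn)
          element <- c(element, el)
          npl <- length(sh$A)
          # sign-paired lobes: +A at +d, -A at -d along the axis
          A <- c(A, sh$A, -sh$A)
          al <- c(al, sh$alpha, sh$alpha)
          ctr <- rbind(t(pos + t(outer(sh$disp, e))),
                       t(pos - t(outer(sh$disp, e))))
          cx <- c(cx, ctr[, 1]); cy <- c(cy, ctr[, 2]); cz <- c(cz, ctr[, 3])
          off <- c(off, off[length(off)] + 2L * npl)
          # abs representation: both lobes, positive coefficients,
          # per-axis exponents permuted onto the lobe axis
          ar <- sh$absrep
          ex_axis <- matrix(ar$ay, 3, npl, byrow = TRUE)
          ex_axis[ax_i, ] <- ar$ax
          if (ax_i == 1) { ex_axis[2, ] <- ar$ay; ex_axis[3, ] <- ar$az }
          if (ax_i == 2) { ex_axis[1, ] <- ar$ay; ex_axis[3, ] <- ar$az }
          if (ax_i == 3) { ex_axis[1, ] <- ar$ay; ex_axis[2, ] <- ar$az }
          octr <- rbind(t(pos + t(outer(ar$x0, e))),
                        t(pos - t(outer(ar$x0, e))))
          aA <- c(aA, ar$A, ar$A)
          aax <- c(aax, ex_axis[1, ], ex_axis[1, ])
          aay <- c(aay, ex_axis[2, ], ex_axis[2, ])
          aaz <- c(aaz, ex_axis[3, ], ex_axis[3, ])
          aox <- c(aox, octr[, 1]); aoy <- c(aoy, octr[, 2])
          aoz <- c(aoz, octr[, 3])
          aoff <- c(aoff, aoff[length(aoff)] + 2L * npl)
        }
      }
    }
  }
  out <- list(
    atom_index = atom_index, shell_label = shell_label,
    is_valence = is_valence, element = element,
    nbf = length(atom_index),
    off = as.integer(off), A = A, alpha = al, x = cx, y = cy, z = cz,
    aoff = as.integer(aoff), aA = aA, aax = aax, aay = aay, aaz = aaz,
    aox = aox, aoy = aoy, aoz = aoz
  )
  class(out) <- "lobe_basis"
  out
}

#' @export
print.lobe_basis <- function(x, ...) {
  cat(sprintf("<lobe_basis> %d orbitals over %d atoms (%d primitives)\n",
              x$nbf, length(unique(x$atom_index)), length(x$A)))
  invisible(x)
}

# evaluate orbital i of a lobe basis at points (n x 3, Bohr)
eval_basis_function <- function(basis, i, points) {
  idx <- (basis$off[i] + 1L):basis$off[i + 1L]
  out <- numeric(nrow(points))
  for (a in idx) {
    d2 <- (points[, 1] - basis$x[a])^2 + (points[, 2] - basis$y[a])^2 +
      (points[, 3] - basis$z[a])^2
    out <- out + basis$A[a] * exp(-basis$alpha[a] * d2)
  }
  out
}
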