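#' Write a density grid as a Gaussian cube file
#'
#' Standard cube layout: two comment lines, atom count and grid origin,
#' three axis records, one record per atom (Z, charge, coordinates, all in
#' Bohr), then values with z varying fastest.
#'
#' @param grid a `density_grid` from [density_on_grid()].
#' @param structure the [atomic_structure()] the density belongs to.
#' @param path output file.
#' @export
write_cube <- function(grid, structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dims
  writeLines(c("lobehf electron density",
               sprintf("grid %d x %d x %d, spacing %.6f Bohr",
                       d[1], d[2], d[3], grid$spacing)), con)
  fmt <- function(...) writeLines(sprintf(...), con)
  fmt("%5d %11.6f %11.6f %11.6f", n_atoms(structure),
      grid$origin[1], grid$origin[2], grid$origin[3])
  fmt("%5d %11.6f %11.6f %11.6f", d[1], grid$spacing, 0, 0)
  fmt("%5d %11.6f %11.6f %11.6f", d[2], 0, grid$spacing, 0)
  fmt("%5d %11.6f %11.6f %11.6f", d[3], 0, 0, grid$spacing)
  for (a in seq_len(n_atoms(structure)))
    fmt("%5d %11.6f %11.6f %11.6f %11.6f", structure$Z[a], structure$Z[a],
        structure$xyz[a, 1], structure$xyz[a, 2], structure$xyz[a, 3])
  # values: x outer, z inner, 6 per line, full precision for round trips;
  # the array is stored (z, y, x) so column-major flattening is z-fastest
  v <- as.vector(grid$values)
  lines <- tapply(sprintf("%.13e", v),
                  (seq_along(v) - 1L) %/% 6L, paste, collapse = " ")
  writeLines(unname(lines), con)
  invisible(path)
}

#' Read a Gaussian cube file written by [write_cube()]
#'
#' @param path cube file path.
#' @return list with `values` (z, y, x array), `origin`, `spacing`, `dims`
#'   and the atom records.
#' @export
read_cube <- function(path) {
  ln <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- num(ln[3])
  nat <- as.integer(hdr[1]); origin <- hdr[2:4]
  ax <- lapply(ln[4:6], num)
  dims <- vapply(ax, function(a) as.integer(a[1]), 1L)
  spacing <- ax[[1]][2]
  atoms <- t(vapply(ln[7:(6 + nat)], num, numeric(5)))
  rownames(atoms) <- NULL
  v <- as.numeric(unlist(strsplit(trimws(ln[-(1:(6 + nat))]), "\\s+")))
  out <- list(values = array(v, dim = rev(dims)), origin = origin,
              spacing = spacing, dims = dims,
              Z = as.integer(atoms[, 1]), xyz = atoms[, 3:5, drop = FALSE])
  class(out) <- "density_grid"
  out
}
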