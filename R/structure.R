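#' Atomic structure container
#'
#' Holds element symbols, atomic numbers and Cartesian coordinates in Bohr,
#' plus optional per-atom metadata (B-factor / pLDDT, residue and chain
#' labels).  Constructors take Angstrom by default, matching the structure
#' file formats.
#'
#' @param elements character vector of element symbols.
#' @param xyz n x 3 numeric matrix of coordinates.
#' @param units `"angstrom"` (default, converted to Bohr) or `"bohr"`.
#' @param bfactor optional numeric vector (pLDDT for predicted models).
#' @param resid,resname,chain,atom_name optional per-atom labels.
#' @param provenance free-form origin string.
#' @return An object of class `atomic_structure`.
#' @export
atomic_structure <- function(elements, xyz, units = c("angstrom", "bohr"),
                             bfactor = NULL, resid = NULL, resname = NULL,
                             chain = NULL, atom_name = NULL,
                             provenance = "constructed") {
  units <- match.arg(units)
  xyz <- as.matrix(xyz)
  if (length(elements) == 0L) {
    xyz <- matrix(numeric(0), 0, 3)
  }
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(elements))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (units == "angstrom") xyz <- ang2bohr(xyz)
  dimnames(xyz) <- NULL
  structure(list(
    elements = as.character(elements),
    Z = if (length(elements)) element_number(elements) else integer(0),
    xyz = xyz,                       # Bohr
    bfactor = bfactor,
    resid = resid, resname = resname, chain = chain, atom_name = atom_name,
    provenance = provenance
  ), class = "atomic_structure")
}

#' @export
print.atomic_structure <- function(x, ...) {
  cat(sprintf("<atomic_structure> %d atoms, %d electrons (neutral), %s\n",
              n_atoms(x), sum(x$Z), x$provenance))
  tab <- table(x$elements)
  cat("  composition:", paste(sprintf("%s%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `atomic_structure`.
#' @export
n_atoms <- function(structure) length(structure$elements)

#' Read a molecular structure file
#'
#' PDB and mmCIF files are parsed with \pkg{bio3d}; XYZ files are parsed
#' directly.  Coordinates are converted from Angstrom to Bohr.  For PDB/mmCIF,
#' hydrogens and HETATM water are retained, alternate location `A` is kept
#' (others dropped with a warning) and the B-factor column is stored (it
#' carries pLDDT for predicted models).  A warning is emitted when a file
#' contains no hydrogens, since protonation is not added automatically.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, `"mmcif"` or `"xyz"`.
#' @return An [atomic_structure()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif", xyz = "xyz",
                     stop("cannot infer format from extension: ", ext))
  }
  st <- switch(format,
    xyz = read_xyz(path),
    pdb = read_pdb_cif(path, "pdb"),
    mmcif = read_pdb_cif(path, "mmcif"))
  if (n_atoms(st) == 0L) stop("empty model in ", path)
  if (!any(st$elements == "H"))
    warning("structure contains no hydrogens; they are not added automatically")
  st
}

read_xyz <- function(path) {
  ln <- readLines(path)
  if (!length(ln)) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(ln[1])))
  if (is.na(n)) stop("malformed XYZ header in ", path)
  if (length(ln) < n + 2L) stop("truncated XYZ file: ", path)
  rows <- strsplit(trimws(ln[seq_len(n) + 2L]), "\\s+")
  el <- vapply(rows, `[[`, "", 1L)
  co <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  atomic_structure(el, co, units = "angstrom",
                   provenance = paste0("xyz:", basename(path)))
}

read_pdb_cif <- function(path, fmt) {
  # keep alternate locations so the A-selection (and its warning) is ours
  pdb <- if (fmt == "pdb")
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  else suppressWarnings(bio3d::read.cif(path, verbose = FALSE,
                                        rm.alt = FALSE))
  at <- pdb$atom
  alt <- at$alt
  if (!is.null(alt)) {
    keepable <- is.na(alt) | alt %in% c("", "A", ".")
    if (!all(keepable)) {
      warning(sum(!keepable), " alternate-location atoms dropped (kept altloc A)")
      at <- at[keepable, , drop = FALSE]
    }
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    el <- sub("^[0-9]*", "", trimws(at$elety))
    el <- substr(el, 1, 1)
  }
  el <- trimws(el)
  if (any(el == "" | is.na(el))) stop("missing element symbol in ", path)
  atomic_structure(el, cbind(at$x, at$y, at$z), units = "angstrom",
                   bfactor = at$b, resid = at$resno, resname = at$resid,
                   chain = at$chain, atom_name = trimws(at$elety),
                   provenance = paste0(fmt, ":", basename(path)))
}

#' Write a structure to an XYZ or PDB file
#'
#' @param structure an [atomic_structure()].
#' @param path output path.
#' @param format `"xyz"` or `"pdb"`; default from extension.
#' @param comment XYZ comment line.
#' @export
write_structure <- function(structure, path, format = c("auto", "xyz", "pdb"),
                            comment = structure$provenance) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "pdb") "pdb" else "xyz"
  xyz_ang <- bohr2ang(structure$xyz)
  if (format == "xyz") {
    n <- n_atoms(structure)
    lines <- c(as.character(n), comment,
               sprintf("%-2s %14.8f %14.8f %14.8f", structure$elements,
                       xyz_ang[, 1], xyz_ang[, 2], xyz_ang[, 3]))
    writeLines(lines, path)
  } else {
    n <- n_atoms(structure)
    resid <- structure$resid %||% rep(1L, n)
    resname <- structure$resname %||% rep("MOL", n)
    b <- structure$bfactor %||% rep(0, n)
    bio3d::write.pdb(file = path, xyz = as.vector(t(xyz_ang)),
                     type = rep("ATOM", n), resno = resid, resid = resname,
                     elety = structure$elements, b = b,
                     elesy = structure$elements)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rigid-body helpers used by fixtures and invariance tests
translate_structure <- function(structure, shift_bohr) {
  structure$xyz <- sweep(structure$xyz, 2, shift_bohr, "+")
  structure
}

rotate_structure <- function(structure, R) {
  structure$xyz <- structure$xyz %*% t(R)
  structure
}

# subset of atoms, keeping metadata aligned
subset_structure <- function(structure, idx) {
  pick <- function(v) if (is.null(v)) NULL else v[idx]
  atomic_structure(structure$elements[idx],
                   structure$xyz[idx, , drop = FALSE], units = "bohr",
                   bfactor = pick(structure$bfactor),
                   resid = pick(structure$resid),
                   resname = pick(structure$resname),
                   chain = pick(structure$chain),
                   atom_name = pick(structure$atom_name),
                   provenance = structure$provenance)
}
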