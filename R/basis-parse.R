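#' Parse Gaussian-dialect basis set text
#'
#' Reads the plain-text "Gaussian" dialect used by the Basis Set Exchange:
#' comment lines start with `!`, each element block starts with
#' `"<symbol> 0"`, is followed by shell blocks (`S n 1.00` or `SP n 1.00`
#' headers with `n` rows of exponent/coefficient columns) and ends with
#' `****`.
#'
#' @param text a single string or character vector of lines.
#' @return A `basis_set_reference`: named list (by element symbol) of shell
#'   lists, each shell holding `type` (`"S"` or `"SP"`), `exponents` and a
#'   coefficient matrix (one column for S, two for SP).
#' @export
parse_basis_reference <- function(text) {
  if (length(text) == 1L && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  raw <- text
  keep <- !grepl("^\\s*!", raw)
  lines <- trimws(raw)
  lineno <- seq_along(lines)
  use <- keep & nzchar(lines)
  lines <- lines[use]; lineno <- lineno[use]
  if (!length(lines)) stop("basis parse error: no content")

  out <- list()
  i <- 1L
  parse_num <- function(s) as.numeric(gsub("[dD]", "e", s))
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    if (length(hdr) != 2L || is.na(suppressWarnings(as.integer(hdr[2]))))
      stop("basis parse error at line ", lineno[i],
           ": expected element header, got '", lines[i], "'")
    elem <- hdr[1]
    i <- i + 1L
    shells <- list()
    repeat {
      if (i > length(lines))
        stop("basis parse error: unterminated block for element ", elem)
      if (lines[i] == "****") { i <- i + 1L; break }
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1])
      nprim <- suppressWarnings(as.integer(sh[2]))
      if (!type %in% c("S", "SP", "P") || is.na(nprim))
        stop("basis parse error at line ", lineno[i],
             ": expected shell header, got '", lines[i], "'")
      i <- i + 1L
      ncol_exp <- if (type == "SP") 3L else 2L
      rows <- matrix(NA_real_, nprim, ncol_exp)
      for (r in seq_len(nprim)) {
        if (i > length(lines))
          stop("basis parse error: truncated shell in element ", elem)
        v <- parse_num(strsplit(lines[i], "\\s+")[[1]])
        if (length(v) != ncol_exp || anyNA(v))
          stop("basis parse error at line ", lineno[i],
               ": expected ", ncol_exp, " numeric columns")
        rows[r, ] <- v
        i <- i + 1L
      }
      shells[[length(shells) + 1L]] <- list(
        type = type,
        exponents = rows[, 1],
        coefficients = rows[, -1, drop = FALSE]
      )
    }
    out[[elem]] <- shells
  }
  class(out) <- "basis_set_reference"
  out
}

#' Load the reference basis shipped with the package
#'
#' The shipped file (`sto-ng-synthetic.gbs`) holds package-generated
#' Stewart-style least-squares expansions of single-zeta Slater orbitals in
#' 6 Gaussians (with 3-Gaussian variants used as fit starting points), in
#' Basis Set Exchange Gaussian dialect.  See `scripts/make-basis-reference.R`
#' for its construction.
#'
#' @param file path to a basis text file; default is the shipped reference.
#' @return A `basis_set_reference`.
#' @export
load_reference_basis <- function(file = system.file("extdata",
                                                    "sto-ng-synthetic.gbs",
                                                    package = "lobehf")) {
  parse_basis_reference(readLines(file))
}

reference_element <- function(ref, elem) {
  sh <- ref[[elem]]
  if (is.null(sh)) stop("element not in basis: ", elem)
  sh
}

# Evaluate a reference contracted shell at points (n x 3, Bohr), shell
# centred at the origin.  component: "s" or one of "px","py","pz" for the
# Cartesian-prefactor p part of an SP shell.  Contractions are normalized.
eval_reference_shell <- function(shell, component, points) {
  ex <- shell$exponents
  r2 <- rowSums(points^2)
  if (component == "s") {
    co <- shell$coefficients[, 1]
    np <- (2 * ex / pi)^0.75
    c_n <- co * np
    # renormalize the contraction exactly
    gsum <- outer(ex, ex, "+")
    ov <- sum(outer(c_n, c_n) * (pi / gsum)^1.5)
    c_n <- c_n / sqrt(ov)
    as.vector(exp(-outer(r2, ex)) %*% c_n)
  } else {
    co <- shell$coefficients[, 2]
    ax <- match(component, c("px", "py", "pz"))
    np <- 2 * sqrt(ex) * (2 * ex / pi)^0.75
    c_n <- co * np
    gsum <- outer(ex, ex, "+")
    ov <- sum(outer(c_n, c_n) * (pi / gsum)^1.5 / (2 * gsum))
    c_n <- c_n / sqrt(ov)
    points[, ax] * as.vector(exp(-outer(r2, ex)) %*% c_n)
  }
}
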