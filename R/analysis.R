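#' Score tracks for structure assessment
#'
#' A `score_track` aligns one value per atom with the structure's file
#' order: raw atomic energies, their smoothed/rescaled versions, pLDDT read
#' from the B-factor column, or neighbour counts.
#'
#' @param values numeric vector, one per atom.
#' @param kind one of `"raw_energy"`, `"smoothed"`, `"rescaled"`, `"plddt"`,
#'   `"neighbour_count"`.
#' @param parameters list of the parameters that produced the track.
#' @return A `score_track`.
#' @export
score_track <- function(values, kind = c("raw_energy", "smoothed", "rescaled",
                                         "plddt", "neighbour_count"),
                        parameters = list()) {
  kind <- match.arg(kind)
  out <- list(values = as.numeric(values), kind = kind,
              parameters = parameters)
  class(out) <- "score_track"
  out
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("<score_track:%s> %d atoms, range [%.3g, %.3g]\n", x$kind,
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Savitzky-Golay smoothing of a per-atom track
#'
#' Least-squares local polynomial smoothing over the atom sequence in file
#' order, removing short-range noise from the atomic energies.  An even
#' window is enlarged to the next odd value; a window longer than the track
#' is shrunk with a warning.  Endpoints use the filter's least-squares
#' startup/ending fits.
#'
#' @param track a [score_track()] (or numeric vector).
#' @param window window length in atoms (default 150).
#' @param polyorder polynomial order (default 3).
#' @return A smoothed `score_track`.
#' @export
smooth_energies <- function(track, window = 150L, polyorder = 3L) {
  v <- if (inherits(track, "score_track")) track$values else as.numeric(track)
  if (window < 3) stop("window must be at least 3")
  if (window %% 2L == 0L) window <- window + 1L
  if (window > length(v)) {
    window <- length(v) - (1L - length(v) %% 2L)
    warning("window shrunk to track length (", window, ")")
  }
  polyorder <- min(polyorder, window - 1L)
  sm <- signal::sgolayfilt(v, p = polyorder, n = window)
  score_track(sm, "smoothed",
              parameters = list(window = window, polyorder = polyorder))
}

#' Linear rescale and clip of a track
#'
#' `v -> min(hi, max(lo, scale * v + offset))`.  With `offset = NULL` the
#' offset is auto-fitted so that the track median matches the median of the
#' reference (pLDDT) track, the reproducible surrogate for the
#' structure-specific offsets used with hand-tuned normalizations.  Clip
#' bounds default to the range of the reference track.
#'
#' @param track a [score_track()] or numeric vector.
#' @param scale multiplicative factor (default 15).
#' @param offset additive shift, or `NULL` for median alignment.
#' @param clip `c(lo, hi)`; default from `reference`.
#' @param reference numeric vector (pLDDT) used for auto-offset/clip.
#' @return A rescaled `score_track`.
#' @export
rescale_clip <- function(track, scale = 15, offset = NULL, clip = NULL,
                         reference = NULL) {
  v <- if (inherits(track, "score_track")) track$values else as.numeric(track)
  if (is.null(clip)) {
    if (is.null(reference)) stop("need clip bounds or a reference track")
    clip <- range(reference)
  }
  if (clip[1] >= clip[2]) stop("clip lower bound must be below upper bound")
  if (is.null(offset)) {
    if (is.null(reference)) stop("need an offset or a reference track")
    offset <- stats::median(reference) - stats::median(scale * v)
  }
  out <- pmin(clip[2], pmax(clip[1], scale * v + offset))
  score_track(out, "rescaled",
              parameters = list(scale = scale, offset = offset,
                                clip_lo = clip[1], clip_hi = clip[2]))
}

#' Neighbour-count baseline track
#'
#' The classical heuristic: for every atom, the number of non-hydrogen
#' atoms within `radius`, excluding itself.
#'
#' @param structure an [atomic_structure()].
#' @param radius Angstrom (default 8).
#' @return A `score_track` of counts.
#' @export
neighbour_count_track <- function(structure, radius = 8) {
  if (radius <= 0) stop("radius must be positive")
  r <- ang2bohr(radius)
  n <- n_atoms(structure)
  heavy <- structure$elements != "H"
  counts <- integer(n)
  hx <- structure$xyz[heavy, , drop = FALSE]
  for (a in seq_len(n)) {
    d2 <- rowSums((hx - matrix(structure$xyz[a, ], nrow(hx), 3,
                               byrow = TRUE))^2)
    counts[a] <- sum(d2 <= r^2) - as.integer(heavy[a])
  }
  score_track(counts, "neighbour_count", parameters = list(radius = radius))
}

#' Compare two score tracks
#'
#' Pearson and Spearman correlations plus per-atom residuals over the
#' overlapping (finite) atom set.
#'
#' @param a,b [score_track()]s or numeric vectors of equal length.
#' @return A `track_comparison`: correlations (NA with an explanatory note
#'   for zero-variance input), residuals and a summary string.
#' @export
compare_tracks <- function(a, b) {
  va <- if (inherits(a, "score_track")) a$values else as.numeric(a)
  vb <- if (inherits(b, "score_track")) b$values else as.numeric(b)
  if (length(va) != length(vb)) stop("tracks differ in length")
  ok <- is.finite(va) & is.finite(vb)
  va <- va[ok]; vb <- vb[ok]
  degenerate <- stats::sd(va) == 0 || stats::sd(vb) == 0
  pear <- if (degenerate) NA_real_ else stats::cor(va, vb)
  spear <- if (degenerate) NA_real_ else
    stats::cor(va, vb, method = "spearman")
  out <- list(pearson = pear, spearman = spear, n = sum(ok),
              residuals = va - vb,
              note = if (degenerate) "zero-variance track: correlation undefined"
                     else NULL,
              summary = sprintf(
                "n=%d atoms, Pearson r=%s, Spearman rho=%s", sum(ok),
                formatC(pear, digits = 3), formatC(spear, digits = 3)))
  class(out) <- "track_comparison"
  out
}

#' @export
print.track_comparison <- function(x, ...) {
  cat("<track_comparison>", x$summary, "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write a track comparison report
#' @param comparison a `track_comparison`.
#' @param path_json,path_tsv output paths (either may be NULL).
#' @param tracks optional named list of tracks to tabulate per atom.
#' @export
write_comparison_report <- function(comparison, path_json = NULL,
                                    path_tsv = NULL, tracks = NULL) {
  if (!is.null(path_json))
    jsonlite::write_json(
      list(pearson = comparison$pearson, spearman = comparison$spearman,
           n = comparison$n, note = comparison$note),
      path_json, digits = NA, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path_tsv)) {
    df <- data.frame(atom = seq_along(comparison$residuals),
                     residual = comparison$residuals)
    if (!is.null(tracks))
      for (nm in names(tracks))
        df[[nm]] <- if (inherits(tracks[[nm]], "score_track"))
          tracks[[nm]]$values else tracks[[nm]]
    utils::write.table(df, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(comparison)
}

#' Atomic-energy structure assessment pipeline
#'
#' Runs the full scoring chain on a structure with per-atom confidence
#' values (pLDDT in the B-factor column): atomic energies from a screened
#' (optionally divide-and-conquer) Hartree-Fock calculation, Savitzky-Golay
#' smoothing, linear rescaling onto the confidence range, the
#' neighbour-count baseline, and correlation reports for both.
#'
#' @param structure an [atomic_structure()] with `bfactor` set.
#' @param window,polyorder smoothing parameters.
#' @param scale rescale factor.
#' @param radius neighbour-count radius, Angstrom.
#' @param dnc use divide-and-conquer (default when the system is large).
#' @param partition,screening,scf configuration objects.
#' @return A `structure_assessment`: all tracks plus the two comparisons.
#' @export
assess_structure <- function(structure, window = 150L, polyorder = 3L,
                             scale = 15, radius = 8,
                             dnc = n_atoms(structure) > 120,
                             partition = partition_config(),
                             screening = screening_config(),
                             scf = scf_config()) {
  if (is.null(structure$bfactor))
    stop("structure has no per-atom confidence values (B-factor column)")
  plddt <- structure$bfactor
  if (dnc) {
    run <- dnc_run(structure, partition, screening, scf)
    raw <- run$atomic_energies
  } else {
    res <- scf_solve(structure, screening = screening, config = scf)
    raw <- atomic_energies(res)$energies
  }
  raw_track <- score_track(raw, "raw_energy")
  smoothed <- smooth_energies(raw_track, window, polyorder)
  rescaled <- rescale_clip(smoothed, scale = scale, reference = plddt)
  neigh <- neighbour_count_track(structure, radius)
  out <- list(
    raw = raw_track, smoothed = smoothed, rescaled = rescaled,
    plddt = score_track(plddt, "plddt"), neighbours = neigh,
    energy_vs_plddt = compare_tracks(rescaled, plddt),
    neighbours_vs_plddt = compare_tracks(neigh, plddt))
  class(out) <- "structure_assessment"
  out
}

#' @export
print.structure_assessment <- function(x, ...) {
  cat("<structure_assessment>\n  energy vs confidence:   ",
      x$energy_vs_plddt$summary, "\n  neighbours vs confidence:",
      x$neighbours_vs_plddt$summary, "\n")
  invisible(x)
}
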