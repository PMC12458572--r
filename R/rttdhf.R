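#' Electric-field pulse parameters
#'
#' Gaussian envelope pulse `E(t) = strength exp(-(t - t0)^2 / (2 sigma^2))`
#' along a polarization direction.  Defaults are the weak-field settings
#' used for linear-response-regime spectra.
#'
#' @param strength field amplitude, atomic units (default 1e-5).
#' @param sigma envelope standard deviation, a.u. time (default 0.2).
#' @param t0 pulse centre, a.u. time (default 2).
#' @param polarization 3-vector, normalized internally.
#' @return A `pulse_params`.
#' @export
pulse_params <- function(strength = 1e-5, sigma = 0.2, t0 = 2,
                         polarization = c(1, 0, 0)) {
  stopifnot(strength > 0, sigma > 0)
  polarization <- polarization / sqrt(sum(polarization^2))
  out <- list(strength = strength, sigma = sigma, t0 = t0,
              polarization = polarization)
  class(out) <- "pulse_params"
  out
}

#' Propagation parameters
#'
#' @param n_steps number of time steps (default 2000).
#' @param dt time step, a.u. (default 0.25; total 500 a.u. = 12.1 fs).
#' @param damping Fourier attenuation factor gamma, a.u. (default 0.01).
#' @param rescale_factor empirical excitation-energy rescaling (default
#'   1.335): computed energies are divided by this factor to counteract the
#'   systematic overestimation of excitation energies.
#' @return A `propagation_params`.
#' @export
propagation_params <- function(n_steps = 2000L, dt = 0.25, damping = 0.01,
                               rescale_factor = 1.335) {
  stopifnot(dt > 0, damping >= 0, n_steps >= 1)
  out <- list(n_steps = as.integer(n_steps), dt = dt, damping = damping,
              rescale_factor = rescale_factor, propagator = "midpoint-exponential")
  class(out) <- "propagation_params"
  out
}

#' Field at time t
#' @param t time(s), a.u.
#' @param pulse a [pulse_params()].
#' @return length(t) x 3 matrix of field vectors (a.u.).
#' @export
field_at <- function(t, pulse = pulse_params()) {
  env <- pulse$strength * exp(-(t - pulse$t0)^2 / (2 * pulse$sigma^2))
  outer(env, pulse$polarization)
}

# exp(-i H dt) for Hermitian H via eigendecomposition
unitary_exp <- function(H, dt) {
  e <- eigen(H, symmetric = TRUE)
  ph <- exp(-1i * e$values * dt)
  e$vectors %*% (ph * Conj(t(e$vectors)))
}

#' Real-time TDHF propagation
#'
#' Starting from a converged ground state, the density matrix is advanced
#' with a unitary exponential-midpoint propagator (one predictor-corrector
#' Fock rebuild per step).  The Fock matrix is reassembled each step from
#' the screened ERI set plus the length-gauge dipole coupling to the pulse;
#' the total (electronic + nuclear) dipole moment is recorded at every
#' step.
#'
#' @param scf a converged `scf_result` (ground state).
#' @param pulse a [pulse_params()].
#' @param prop a [propagation_params()].
#' @param check_every verify trace/idempotency conservation every this many
#'   steps (propagation aborts if the trace drifts by more than 1e-6).
#' @return A `dipole_trace`: times (a.u.), n x 3 dipole (a.u.), the field
#'   samples, and conservation diagnostics.
#' @export
propagate <- function(scf, pulse = pulse_params(),
                      prop = propagation_params(), check_every = 100L) {
  if (!scf$converged) stop("ground-state SCF is not converged")
  X <- scf$X                     # S^{-1/2}
  Xi <- scf$S %*% X              # S^{1/2} (since X S X = I for full rank)
  D <- dipole_matrices(scf$basis)
  nucdip <- colSums(scf$structure$Z * scf$structure$xyz)
  eris <- scf$eris
  H <- scf$H

  # orthonormal-basis density; stays Hermitian under the unitary steps
  Pp <- Xi %*% scf$P %*% Xi
  nel <- scf$n_electrons

  fock_ortho <- function(Pp, t) {
    Pao <- X %*% Pp %*% X
    G <- cpp_fock_2e(eris$nbf, eris$i - 1L, eris$j - 1L, eris$k - 1L,
                     eris$l - 1L, eris$value, eris$weight, Re(Pao)) +
      1i * cpp_fock_2e(eris$nbf, eris$i - 1L, eris$j - 1L, eris$k - 1L,
                       eris$l - 1L, eris$value, eris$weight, Im(Pao))
    Et <- field_at(t, pulse)[1, ]
    # length gauge: H_int = + E(t) . r  (electron charge -1 folded into the
    # dipole expectation below)
    F <- H + Et[1] * D$x + Et[2] * D$y + Et[3] * D$z + G
    Fp <- t(X) %*% F %*% X
    (Fp + Conj(t(Fp))) / 2
  }

  dip_of <- function(Pp) {
    Pao <- X %*% Pp %*% X
    el <- -c(sum(Re(Pao) * D$x), sum(Re(Pao) * D$y), sum(Re(Pao) * D$z))
    el + nucdip
  }

  n <- prop$n_steps
  times <- seq(0, by = prop$dt, length.out = n + 1L)
  dip <- matrix(0, n + 1L, 3)
  field <- matrix(0, n + 1L, 3)
  dip[1, ] <- dip_of(Pp)
  field[1, ] <- field_at(times[1], pulse)[1, ]
  max_trace_drift <- 0; max_idem_dev <- 0

  for (s in seq_len(n)) {
    t0 <- times[s]
    Fp0 <- fock_ortho(Pp, t0)
    U0 <- unitary_exp(Fp0, prop$dt)
    Pp_pred <- U0 %*% Pp %*% Conj(t(U0))
    Fp1 <- fock_ortho(Pp_pred, t0 + prop$dt)
    U <- unitary_exp((Fp0 + Fp1) / 2, prop$dt)
    Pp <- U %*% Pp %*% Conj(t(U))
    dip[s + 1L, ] <- dip_of(Pp)
    field[s + 1L, ] <- field_at(times[s + 1L], pulse)[1, ]
    if (s %% check_every == 0L || s == n) {
      drift <- abs(Re(sum(diag(Pp))) - nel)
      idem <- max(Mod(Pp %*% Pp - 2 * Pp)) / 2
      max_trace_drift <- max(max_trace_drift, drift)
      max_idem_dev <- max(max_idem_dev, idem)
      if (drift > 1e-6)
        stop(sprintf("trace drift %.2e at step %d: propagation aborted",
                     drift, s))
    }
  }

  out <- list(times = times, dipole = dip, field = field,
              ground_dipole = dip[1, ], pulse = pulse, prop = prop,
              max_trace_drift = max_trace_drift,
              max_idempotency_deviation = max_idem_dev)
  class(out) <- "dipole_trace"
  out
}

#' Absorption spectrum from a dipole trace
#'
#' The ground-state dipole is subtracted, the induced dipole is attenuated
#' by `exp(-gamma t)`, and the polarizability along the pulse polarization
#' is `alpha(w) = mu(w) / E(w)` from the discrete Fourier transforms.  The
#' absorption intensity is `S(w) = w Im alpha(w)` (clamped at zero after
#' any polarization folding); the energy axis is divided by the empirical
#' rescale factor.
#'
#' @param trace a `dipole_trace` from [propagate()].
#' @param prop,pulse default to the parameters stored in the trace.
#' @param e_max report energies up to this many eV (after rescaling).
#' @param pad zero-padding factor for the transform (>= 1).  The attenuated
#'   dipole has decayed to ~exp(-gamma T) by the end of the trace, so
#'   padding interpolates the spectrum to sub-bin peak positions with
#'   negligible truncation artefacts.
#' @return A `spectrum`: `energy_ev` (ascending), `intensity` (arbitrary
#'   units, >= 0), `wavelength_nm`, plus the raw polarizability.
#' @export
spectrum_from_dipole <- function(trace, prop = trace$prop,
                                 pulse = trace$pulse, e_max = 40,
                                 pad = 1L) {
  nt <- length(trace$times)
  pol <- pulse$polarization
  mu_ind <- as.vector((trace$dipole -
                         matrix(trace$ground_dipole, nt, 3,
                                byrow = TRUE)) %*% pol)
  if (all(mu_ind == 0)) {
    damp <- rep(0, nt)
  } else {
    damp <- mu_ind * exp(-prop$damping * trace$times)
  }
  ef <- as.vector(trace$field %*% pol)
  if (pad > 1L) {
    damp <- c(damp, rep(0, (pad - 1L) * nt))
    ef <- c(ef, rep(0, (pad - 1L) * nt))
  }
  nft <- length(damp)
  # e^{+i w t} transform convention so that Im[alpha] >= 0 at absorption
  mu_w <- Conj(stats::fft(damp))
  e_w <- Conj(stats::fft(ef))
  w <- 2 * pi * seq(0, nft - 1) / (nft * prop$dt)
  keep <- seq_len(floor(nft / 2))
  alpha <- ifelse(Mod(e_w[keep]) > 0, mu_w[keep] / e_w[keep], 0 + 0i)
  intensity <- w[keep] * Im(alpha)
  energy_ev <- w[keep] * lobehf_units$hartree_ev / prop$rescale_factor
  sel <- energy_ev <= e_max & energy_ev > 0
  out <- list(energy_ev = energy_ev[sel],
              intensity = pmax(intensity[sel], 0),
              raw_intensity = intensity[sel],
              wavelength_nm = 1239.841984 / energy_ev[sel],
              polarizability = alpha[sel],
              resolution_ev = (w[2] - w[1]) * lobehf_units$hartree_ev /
                prop$rescale_factor)
  class(out) <- "spectrum"
  out
}

#' Average spectra over x, y, z polarizations
#'
#' Runs three propagations polarized along the lab axes and averages the
#' resulting intensities (unpolarized comparison).
#'
#' @param scf converged ground state.
#' @param pulse,prop parameter objects (polarization is overridden).
#' @return A `spectrum`.
#' @export
isotropic_spectrum <- function(scf, pulse = pulse_params(),
                               prop = propagation_params()) {
  axes <- diag(3)
  specs <- lapply(1:3, function(a) {
    pulse$polarization <- axes[a, ]
    spectrum_from_dipole(propagate(scf, pulse, prop))
  })
  out <- specs[[1]]
  out$raw_intensity <- (specs[[1]]$raw_intensity + specs[[2]]$raw_intensity +
                          specs[[3]]$raw_intensity) / 3
  out$intensity <- pmax(out$raw_intensity, 0)
  out
}

#' @export
print.spectrum <- function(x, ...) {
  pk <- spectrum_peaks(x, n = 3)
  cat(sprintf("<spectrum> %d points, resolution %.3f eV\n",
              length(x$energy_ev), x$resolution_ev))
  if (nrow(pk))
    cat("  main peaks (eV):", paste(sprintf("%.2f", pk$energy_ev),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.spectrum <- function(x, xlab = "energy (eV)",
                          ylab = "absorption (arb.)", type = "l", ...) {
  graphics::plot(x$energy_ev, x$intensity, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}

#' Locate spectral peaks
#'
#' Local maxima of the intensity, refined by quadratic interpolation
#' through the three bins around each maximum (sub-bin peak positions).
#'
#' @param spectrum a `spectrum`.
#' @param n maximum number of peaks, strongest first.
#' @param min_fraction discard peaks below this fraction of the maximum.
#' @return data.frame with `energy_ev` and `intensity`.
#' @export
spectrum_peaks <- function(spectrum, n = 5, min_fraction = 0.05) {
  y <- spectrum$intensity
  if (!length(y) || max(y) <= 0)
    return(data.frame(energy_ev = numeric(0), intensity = numeric(0)))
  i <- which(diff(sign(diff(y))) == -2) + 1L
  i <- i[y[i] >= min_fraction * max(y)]
  i <- i[order(-y[i])]
  i <- utils::head(i, n)
  e <- spectrum$energy_ev
  refine <- vapply(i, function(k) {
    if (k <= 1L || k >= length(y)) return(e[k])
    denom <- y[k - 1L] - 2 * y[k] + y[k + 1L]
    if (denom >= 0) return(e[k])
    e[k] + 0.5 * (y[k - 1L] - y[k + 1L]) / denom * (e[k + 1L] - e[k])
  }, 0)
  data.frame(energy_ev = refine, intensity = y[i])
}

#' Write a spectrum or dipole trace as TSV
#' @param x a `spectrum` or `dipole_trace`.
#' @param path output file.
#' @param unit `"ev"` or `"nm"` energy axis for spectra.
#' @export
write_spectrum_tsv <- function(x, path, unit = c("ev", "nm")) {
  unit <- match.arg(unit)
  if (inherits(x, "spectrum")) {
    df <- if (unit == "ev")
      data.frame(energy_ev = x$energy_ev, intensity = x$intensity)
    else data.frame(wavelength_nm = x$wavelength_nm, intensity = x$intensity)
  } else {
    df <- data.frame(time_au = x$times, mu_x = x$dipole[, 1],
                     mu_y = x$dipole[, 2], mu_z = x$dipole[, 3])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
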