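# Real-time TDHF: pulse, unitary propagation, spectra.

test_that("the Gaussian pulse has the stated peak, tail and integral", {
  p <- pulse_params()
  expect_equal(sqrt(sum(field_at(p$t0, p)^2)), p$strength, tolerance = 1e-14)
  expect_lt(sqrt(sum(field_at(p$t0 + 5 * p$sigma, p)^2)), 4e-6 * p$strength)
  q <- stats::integrate(function(t) field_at(t, p)[, 1], -Inf, Inf,
                        rel.tol = 1e-10)$value
  expect_equal(q, p$strength * p$sigma * sqrt(2 * pi), tolerance = 1e-6)
})

test_that("propagation is stationary without a field", {
  res <- shared_h2_scf()
  # zero-strength limit: use an absurdly weak pulse (strength must be > 0)
  trace <- propagate(res, pulse_params(strength = 1e-300),
                     propagation_params(n_steps = 2000))
  drift <- apply(trace$dipole, 2, function(v) max(abs(v - v[1])))
  expect_lt(max(drift), 1e-10)
  expect_lt(trace$max_trace_drift, 1e-8)
  expect_lt(trace$max_idempotency_deviation, 1e-8)
})

test_that("the default pulse conserves trace and idempotency for H2", {
  res <- shared_h2_scf()
  trace <- propagate(res, pulse_params(),
                     propagation_params(n_steps = 2000), check_every = 50L)
  expect_lt(trace$max_trace_drift, 1e-8)
  expect_lt(trace$max_idempotency_deviation, 1e-8)
  shared_env$h2_trace <- trace
})

test_that("total propagated time converts to 12.1 fs", {
  prop <- propagation_params()
  t_au <- prop$n_steps * prop$dt
  expect_equal(t_au, 500)
  expect_equal(t_au * lobehf_units$fs_per_au_time, 12.1, tolerance = 1e-3)
})

test_that("H2 absorption peak matches the linear-response excitation", {
  res <- shared_h2_scf()
  # finer step over the same 500 a.u. window keeps the propagator's phase
  # error well below the comparison tolerance
  trace <- propagate(res, pulse_params(),
                     propagation_params(n_steps = 5000, dt = 0.1))
  prop_raw <- propagation_params(n_steps = 5000, dt = 0.1,
                                 rescale_factor = 1)
  spec <- spectrum_from_dipole(trace, prop = prop_raw, pad = 8L)
  peak <- spectrum_peaks(spec, n = 1)
  # real-time HF is linear-response TDHF (RPA); CIS lies visibly above it
  # because it drops the de-excitation coupling
  rpa_ev <- min(oracle_tdhf_energies(res)) * lobehf_units$hartree_ev
  cis_ev <- min(oracle_cis_energies(res)) * lobehf_units$hartree_ev
  expect_lt(abs(peak$energy_ev - rpa_ev), 0.1)
  expect_gt(cis_ev, rpa_ev)
  shared_env$h2_fine_trace <- trace
})

test_that("halving the pulse strength halves the induced dipole", {
  res <- shared_h2_scf()
  prop <- propagation_params(n_steps = 400)
  t1 <- propagate(res, pulse_params(strength = 1e-5), prop)
  t2 <- propagate(res, pulse_params(strength = 5e-6), prop)
  a1 <- max(abs(t1$dipole[, 1] - t1$ground_dipole[1]))
  a2 <- max(abs(t2$dipole[, 1] - t2$ground_dipole[1]))
  expect_equal(a1 / a2, 2, tolerance = 0.01)
})

# impulse-response oscillation: after a delta kick the induced dipole is
# sine-phased, which is what makes w * Im[alpha] an absorptive Lorentzian
# once the Fourier attenuation is applied
synthetic_oscillation_trace <- function(w0, n = 1999, dt = 0.25,
                                        amp = 1e-6) {
  tm <- seq(0, by = dt, length.out = n + 1)
  dip <- cbind(amp * sin(w0 * tm), 0, 0)
  # delta-like reference field so that E(w) is flat
  field <- matrix(0, n + 1, 3); field[1, 1] <- 1
  structure(list(times = tm, dipole = dip, field = field,
                 ground_dipole = c(0, 0, 0), pulse = pulse_params(),
                 prop = propagation_params(n_steps = n, dt = dt)),
            class = "dipole_trace")
}

# FWHM with sub-bin accuracy: linear interpolation of the half-maximum
# crossings
interp_fwhm <- function(e, y) {
  half <- max(y) / 2
  k <- which.max(y)
  lo <- max(which(y[1:k] < half))
  hi <- k - 1L + min(which(y[k:length(y)] < half))
  e_lo <- e[lo] + (half - y[lo]) / (y[lo + 1L] - y[lo]) * (e[lo + 1L] - e[lo])
  e_hi <- e[hi - 1L] + (half - y[hi - 1L]) / (y[hi] - y[hi - 1L]) *
    (e[hi] - e[hi - 1L])
  e_hi - e_lo
}

test_that("a damped oscillation gives a Lorentzian of width 2 gamma", {
  w0 <- 0.30
  # long trace so the line is resolved (~16 bins across the width)
  trace <- synthetic_oscillation_trace(w0, n = 19999)
  fwhm <- vapply(c(0.01, 0.02), function(gam) {
    prop <- propagation_params(n_steps = 19999, damping = gam,
                               rescale_factor = 1)
    spec <- spectrum_from_dipole(trace, prop = prop)
    y <- abs(spec$raw_intensity) / spec$energy_ev
    expect_equal(spec$energy_ev[which.max(y)],
                 w0 * lobehf_units$hartree_ev,
                 tolerance = 2 * spec$resolution_ev /
                   (w0 * lobehf_units$hartree_ev))
    interp_fwhm(spec$energy_ev, y)
  }, 0)
  expect_equal(fwhm[1], 2 * 0.01 * lobehf_units$hartree_ev,
               tolerance = 0.05)
  # doubling gamma doubles the full width at half maximum
  expect_equal(fwhm[2] / fwhm[1], 2, tolerance = 0.05)
})

test_that("an undamped integer-period oscillation is a single DFT bin", {
  n <- 1999; dt <- 0.25
  w0 <- 2 * pi * 40 / ((n + 1) * dt)
  trace <- synthetic_oscillation_trace(w0, n = n, dt = dt)
  prop <- propagation_params(n_steps = n, damping = 0, rescale_factor = 1)
  spec <- spectrum_from_dipole(trace, prop = prop)
  y <- abs(spec$raw_intensity) / spec$energy_ev
  top <- which.max(y)
  expect_equal(spec$energy_ev[top], w0 * lobehf_units$hartree_ev,
               tolerance = 1e-9)
  expect_lt(sort(y, decreasing = TRUE)[2], 1e-8 * y[top])
})

test_that("an all-zero trace yields an all-zero spectrum without NaN", {
  trace <- synthetic_oscillation_trace(0.3, n = 200, amp = 0)
  spec <- spectrum_from_dipole(trace,
                               propagation_params(n_steps = 200,
                                                  rescale_factor = 1))
  expect_true(all(is.finite(spec$intensity)))
  expect_true(all(spec$intensity == 0))
})

test_that("spectra and traces serialize as two-column TSV", {
  trace <- synthetic_oscillation_trace(0.3, n = 100)
  spec <- spectrum_from_dipole(trace, propagation_params(n_steps = 100,
                                                         rescale_factor = 1))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(spec, tmp)
  df <- utils::read.table(tmp, header = TRUE, sep = "\t")
  expect_identical(names(df), c("energy_ev", "intensity"))
  expect_identical(nrow(df), length(spec$energy_ev))
})
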