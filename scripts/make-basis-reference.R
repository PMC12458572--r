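#!/usr/bin/env Rscript
# Generates inst/extdata/sto-ng-synthetic.gbs: 6-Gaussian least-squares
# expansions of single-zeta Slater orbitals (synthetic reference data in
# Basis Set Exchange Gaussian dialect), then fits the lobe basis cache
# (inst/extdata/lobe-basis-cache.json) from it with the package's own
# fitting routines.
#
# Slater exponents: standard molecular-optimized single-zeta values for
# H/He/C/N/O; Slater's rules for P and S.  Contraction coefficients are
# reported for normalized Gaussian primitives, s and p sharing exponents
# within an sp shell as in conventional minimal basis sets.
#
# Run from the repository root:  Rscript scripts/make-basis-reference.R

suppressPackageStartupMessages({
  library(minpack.lm)
})

zeta <- list(
  H  = list("1s" = 1.24),
  He = list("1s" = 1.6875),
  C  = list("1s" = 5.67, "2sp" = 1.72),
  N  = list("1s" = 6.67, "2sp" = 1.95),
  O  = list("1s" = 7.66, "2sp" = 2.25),
  P  = list("1s" = 14.70, "2sp" = 5.425, "3sp" = 1.60),
  S  = list("1s" = 15.70, "2sp" = 5.925, "3sp" = 1.8167)
)

NG <- 6L

# radial grid with trapezoid weights (Slater tails are well inside r = 25/zeta)
radial_grid <- function(zeta, n = 4000L, rmax = 25) {
  r <- seq(1e-6, rmax / zeta, length.out = n)
  w <- rep(diff(r)[1], n); w[c(1, n)] <- w[1] / 2
  list(r = r, w = w)
}

# normalized Slater radial functions (spatial normalization incl. angular)
slater_radial <- function(shell, zeta, r) {
  switch(shell,
    "1s" = sqrt(zeta^3 / pi) * exp(-zeta * r),
    "2s" = sqrt(zeta^5 / (3 * pi)) * r * exp(-zeta * r),
    "2p" = sqrt(zeta^5 / pi) * r * exp(-zeta * r) / r,       # f(r) with psi = x f
    "3s" = sqrt(zeta^7 / (22.5 * pi)) * r^2 * exp(-zeta * r),
    "3p" = sqrt(zeta^7 / (7.5 * pi)) * r * exp(-zeta * r))   # psi = x r f0 -> f = r f0
}

# weighted linear coefficient solve for fixed exponents
solve_coef <- function(M, target, w) {
  sw <- sqrt(w)
  qr.coef(qr(M * sw), target * sw)
}

# fit n Gaussians exp(-a r^2) to an s-type radial function (weight r^2)
fit_s_like <- function(target, r, w, a0) {
  wts <- w * r^2
  resid <- function(lp) {
    M <- exp(-outer(r^2, exp(lp)))
    cf <- solve_coef(M, target, wts)
    (as.vector(M %*% cf) - target) * sqrt(wts)
  }
  fit <- nls.lm(log(a0), fn = resid,
                control = nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  a <- exp(fit$par)
  M <- exp(-outer(r^2, a))
  cf <- as.vector(solve_coef(M, target, wts))
  list(alpha = a, c = cf)
}

# shared-exponent sp fit: s part weighted r^2, p part (psi = x g(r)) r^4
fit_sp <- function(target_s, target_p, r, w, a0) {
  ws <- w * r^2; wp <- w * r^4
  resid <- function(lp) {
    M <- exp(-outer(r^2, exp(lp)))
    cs <- solve_coef(M, target_s, ws)
    cp <- solve_coef(M, target_p, wp)
    c((as.vector(M %*% cs) - target_s) * sqrt(ws),
      (as.vector(M %*% cp) - target_p) * sqrt(wp))
  }
  fit <- nls.lm(log(a0), fn = resid,
                control = nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  a <- exp(fit$par)
  M <- exp(-outer(r^2, a))
  list(alpha = a,
       cs = as.vector(solve_coef(M, target_s, ws)),
       cp = as.vector(solve_coef(M, target_p, wp)))
}

# convert raw spatial coefficients to normalized-primitive contraction
# coefficients (the convention of basis set tables)
to_contraction_s <- function(cf, a) cf / (2 * a / pi)^0.75
to_contraction_p <- function(cf, a) cf / (2 * sqrt(a) * (2 * a / pi)^0.75)

lines_out <- c(
  "! Synthetic minimal-basis reference (Gaussian dialect).",
  "! 6-Gaussian least-squares expansions of single-zeta Slater orbitals,",
  "! generated by scripts/make-basis-reference.R; NOT the published",
  "! STO-6G tabulation, though constructed the same way.",
  "!")

fmt <- function(x) formatC(x, format = "E", digits = 8, width = 17)

for (el in names(zeta)) {
  lines_out <- c(lines_out, sprintf("%-2s    0", el))
  for (shell in names(zeta[[el]])) {
    zt <- zeta[[el]][[shell]]
    g <- radial_grid(zt)
    a0 <- zt^2 * exp(seq(log(23.1), log(0.065), length.out = NG))
    if (shell == "1s") {
      f <- fit_s_like(slater_radial("1s", zt, g$r), g$r, g$w, a0)
      co <- to_contraction_s(f$c, f$alpha)
      lines_out <- c(lines_out, sprintf("S   %d   1.00", NG),
                     paste0(fmt(f$alpha), fmt(co)))
    } else {
      nq <- substr(shell, 1, 1)
      f <- fit_sp(slater_radial(paste0(nq, "s"), zt, g$r),
                  slater_radial(paste0(nq, "p"), zt, g$r),
                  g$r, g$w, a0 / 4)
      cs <- to_contraction_s(f$cs, f$alpha)
      cp <- to_contraction_p(f$cp, f$alpha)
      lines_out <- c(lines_out, sprintf("SP  %d   1.00", NG),
                     paste0(fmt(f$alpha), fmt(cs), fmt(cp)))
    }
  }
  lines_out <- c(lines_out, "****")
}

out_gbs <- "inst/extdata/sto-ng-synthetic.gbs"
writeLines(lines_out, out_gbs)
message("wrote ", out_gbs)

# ---- lobe basis cache -------------------------------------------------
# needs the package loadable (devtools in development, or installed)
if (requireNamespace("pkgload", quietly = TRUE) &&
    file.exists("DESCRIPTION")) {
  pkgload::load_all(".", quiet = TRUE)
} else {
  library(lobehf)
}
ref <- parse_basis_reference(readLines(out_gbs))
def <- fit_basis_set(ref)
write_basis_cache(def, "inst/extdata/lobe-basis-cache.json")
message("wrote inst/extdata/lobe-basis-cache.json")
for (el in names(def$elements))
  for (sh in def$elements[[el]])
    message(sprintf("  %s %d%s: fit rms %.2e", el, sh$n, sh$l, sh$rms))
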