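# Built-in test systems: hard-coded small molecules, idealized chain
# builders, water shells and a planted-quality peptide.  All generators are
# deterministic given their arguments (and seed, where one is taken).

#' Hard-coded small-molecule geometries
#'
#' Standard experimental gas-phase geometries: H2 (0.74 A), H2O (0.9572 A /
#' 104.52 deg), CH4 (1.089 A tetrahedral), NH3 (1.012 A / 106.7 deg),
#' ethylene (C=C 1.339 A), ethane (C-C 1.536 A, staggered), benzene
#' (C-C 1.39 A).
#'
#' @param name molecule name (case-insensitive): `"H2"`, `"H2O"`, `"CH4"`,
#'   `"NH3"`, `"ethylene"`, `"ethane"`, `"benzene"`, `"He"`.
#' @return An [atomic_structure()] (coordinates internally in Bohr).
#' @export
make_molecule <- function(name) {
  key <- tolower(name)
  geo <- switch(key,
    he = list(el = "He", xyz = rbind(c(0, 0, 0))),
    h2 = list(el = c("H", "H"),
              xyz = rbind(c(0, 0, 0), c(0.74, 0, 0))),
    h2o = {
      # r(OH) = 0.9572, HOH = 104.52 deg
      a <- 104.52 * pi / 180
      list(el = c("O", "H", "H"),
           xyz = rbind(c(0, 0, 0),
                       c(0.9572, 0, 0),
                       0.9572 * c(cos(a), sin(a), 0)))
    },
    ch4 = {
      r <- 1.089 / sqrt(3)
      list(el = c("C", "H", "H", "H", "H"),
           xyz = rbind(c(0, 0, 0), r * c(1, 1, 1), r * c(1, -1, -1),
                       r * c(-1, 1, -1), r * c(-1, -1, 1)))
    },
    nh3 = {
      # r(NH) = 1.012, HNH = 106.7 deg -> pyramid
      rnh <- 1.012; hnh <- 106.7 * pi / 180
      rho <- rnh * sqrt(2 - 2 * cos(hnh)) / sqrt(3)  # circumradius of H3
      h <- sqrt(rnh^2 - rho^2)
      ang <- 2 * pi * (0:2) / 3
      list(el = c("N", "H", "H", "H"),
           xyz = rbind(c(0, 0, 0),
                       cbind(rho * cos(ang), rho * sin(ang), -h)))
    },
    ethylene = {
      # C=C 1.339, C-H 1.086, HCC 121.2 deg, planar
      d <- 1.339 / 2; rch <- 1.086; a <- (180 - 121.2) * pi / 180
      hx <- rch * cos(a); hy <- rch * sin(a)
      list(el = c("C", "C", "H", "H", "H", "H"),
           xyz = rbind(c(-d, 0, 0), c(d, 0, 0),
                       c(-d - hx, hy, 0), c(-d - hx, -hy, 0),
                       c(d + hx, hy, 0), c(d + hx, -hy, 0)))
    },
    ethane = {
      # C-C 1.536, C-H 1.091, tetrahedral angles, staggered
      d <- 1.536 / 2; rch <- 1.091
      ct <- cos(1.9106); st <- sin(1.9106)  # HCC = 109.47 deg
      h1 <- t(vapply(2 * pi * (0:2) / 3, function(p)
        c(-d + rch * ct, rch * st * cos(p), rch * st * sin(p)), numeric(3)))
      h2 <- t(vapply(2 * pi * (0:2) / 3 + pi / 3, function(p)
        c(d - rch * ct, rch * st * cos(p), rch * st * sin(p)), numeric(3)))
      list(el = c("C", "C", rep("H", 6)),
           xyz = rbind(c(-d, 0, 0), c(d, 0, 0), h1, h2))
    },
    benzene = {
      rc <- 1.39; rh <- 1.39 + 1.09
      ang <- 2 * pi * (0:5) / 6
      list(el = c(rep("C", 6), rep("H", 6)),
           xyz = rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
                       cbind(rh * cos(ang), rh * sin(ang), 0)))
    },
    stop("unknown fixture molecule: ", name))
  atomic_structure(geo$el, geo$xyz, units = "angstrom",
                   provenance = paste0("fixture:", key))
}

# zigzag chain skeleton: positions with given bond lengths and a constant
# in-plane bond angle, alternating above/below the x axis
zigzag_positions <- function(lengths, angle_deg) {
  half <- (90 - angle_deg / 2) * pi / 180
  p <- matrix(0, length(lengths) + 1L, 3)
  for (k in seq_along(lengths)) {
    s <- if (k %% 2L) +1 else -1
    d <- c(cos(half), s * sin(half), 0)
    p[k + 1L, ] <- p[k, ] + lengths[k] * d
  }
  p
}

#' Idealized chain fixtures
#'
#' All-trans chains with standard bond lengths: `alkane(n)` is CnH2n+2
#' (C-C 1.54, C-H 1.09 A); `polyene(n)` is the conjugated CnHn+2 chain
#' (alternating 1.34/1.46 A, planar); `polyglycine(n)` is the extended
#' n-residue peptide H-(NH-CH2-CO)n-OH with an amide C-N of 1.35 A.
#'
#' @param kind `"alkane"`, `"polyene"` or `"polyglycine"`.
#' @param n number of carbons (alkane/polyene, even for polyene) or
#'   residues (polyglycine).
#' @param seed unused for the deterministic ideal geometries; kept so all
#'   fixture generators share one signature.
#' @return An [atomic_structure()].
#' @export
make_chain <- function(kind = c("alkane", "polyene", "polyglycine"), n,
                       seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
         alkane = make_alkane(n),
         polyene = make_polyene(n),
         polyglycine = make_polyglycine(n))
}

make_alkane <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) {
    st <- make_molecule("ch4")
    st$provenance <- "fixture:alkane1"
    return(st)
  }
  cpos <- zigzag_positions(rep(1.54, n - 1L), 111)
  el <- rep("C", n); xyz <- cpos
  rch <- 1.09
  for (k in seq_len(n)) {
    prev <- if (k > 1) cpos[k - 1L, ] else NULL
    nxt <- if (k < n) cpos[k + 1L, ] else NULL
    # local frame: in-plane bisector + out-of-plane z
    if (!is.null(prev) && !is.null(nxt)) {
      bis <- -((prev - cpos[k, ]) + (nxt - cpos[k, ]))
      bis <- bis / sqrt(sum(bis^2))
      for (s in c(1, -1)) {
        h <- cpos[k, ] + rch * (bis * cos(0.955) + s * c(0, 0, 1) * sin(0.955))
        el <- c(el, "H"); xyz <- rbind(xyz, h)
      }
    } else {
      anchor <- if (is.null(prev)) nxt else prev
      ax <- (cpos[k, ] - anchor) / sqrt(sum((cpos[k, ] - anchor)^2))
      # three H around the chain axis at the tetrahedral angle
      perp1 <- c(-ax[2], ax[1], 0); perp1 <- perp1 / sqrt(sum(perp1^2))
      perp2 <- c(ax[2] * perp1[3] - ax[3] * perp1[2],
                 ax[3] * perp1[1] - ax[1] * perp1[3],
                 ax[1] * perp1[2] - ax[2] * perp1[1])
      for (p in 2 * pi * (0:2) / 3 + pi / 6) {
        d <- ax * cos(1.23) + (perp1 * cos(p) + perp2 * sin(p)) * sin(1.23)
        el <- c(el, "H"); xyz <- rbind(xyz, cpos[k, ] + rch * d)
      }
    }
  }
  atomic_structure(el, xyz, units = "angstrom",
                   provenance = sprintf("fixture:alkane%d", n))
}

make_polyene <- function(n) {
  stopifnot(n >= 2, n %% 2 == 0)
  lens <- rep(c(1.34, 1.46), length.out = n - 1L)
  cpos <- zigzag_positions(lens, 120)
  el <- rep("C", n); xyz <- cpos
  rch <- 1.09
  for (k in seq_len(n)) {
    prev <- if (k > 1) cpos[k - 1L, ] else NULL
    nxt <- if (k < n) cpos[k + 1L, ] else NULL
    dirs <- list()
    if (!is.null(prev) && !is.null(nxt)) {
      bis <- -((prev - cpos[k, ]) + (nxt - cpos[k, ]))
      dirs <- list(bis / sqrt(sum(bis^2)))
    } else {
      anchor <- if (is.null(prev)) nxt else prev
      ax <- (cpos[k, ] - anchor) / sqrt(sum((cpos[k, ] - anchor)^2))
      # two in-plane H on the terminal sp2 carbon
      rot <- function(v, a) c(v[1] * cos(a) - v[2] * sin(a),
                              v[1] * sin(a) + v[2] * cos(a), 0)
      dirs <- list(rot(ax, 60 * pi / 180), rot(ax, -60 * pi / 180))
    }
    for (d in dirs) {
      el <- c(el, "H"); xyz <- rbind(xyz, cpos[k, ] + rch * d)
    }
  }
  atomic_structure(el, xyz, units = "angstrom",
                   provenance = sprintf("fixture:polyene%d", n))
}

make_polyglycine <- function(n, nterm = c("H", "ace")) {
  stopifnot(n >= 1)
  nterm <- match.arg(nterm)
  backbone_idx <- integer(0)
  # backbone: N CA C | N CA C | ... with C-N 1.35, N-CA 1.46, CA-C 1.52,
  # terminal O(H) 1.36; constant 115 deg zigzag.  With an acetyl N-cap the
  # backbone is prefixed by CH3-CO so the first residue looks interior-like
  # (no special NH2 terminus).
  el_bb <- c(rep(c("N", "C", "C"), n), "O")
  lens <- c(rep(c(1.46, 1.52, 1.35), n))
  lens[length(lens)] <- 1.36           # C-OH terminus replaces the last C-N
  bbrole <- c(rep(c("N", "CA", "C"), n), "OT")
  if (nterm == "ace") {
    el_bb <- c("C", "C", el_bb)
    lens <- c(1.52, 1.35, lens)        # CH3-C' and C'-N
    bbrole <- c("CM", "C", bbrole)
  }
  bb <- zigzag_positions(lens, 115)
  el <- character(0); xyz <- NULL
  for (k in seq_along(el_bb)) {
    el <- c(el, el_bb[k]); xyz <- rbind(xyz, bb[k, ])
    backbone_idx <- c(backbone_idx, length(el))
    prev <- if (k > 1) bb[k - 1L, ] else NULL
    nxt <- if (k < length(el_bb)) bb[k + 1L, ] else NULL
    bis <- if (!is.null(prev) && !is.null(nxt)) {
      b <- -((prev - bb[k, ]) + (nxt - bb[k, ])); b / sqrt(sum(b^2))
    } else if (is.null(prev)) {
      a <- (bb[k, ] - nxt) / sqrt(sum((bb[k, ] - nxt)^2)); a
    } else {
      a <- (bb[k, ] - prev) / sqrt(sum((bb[k, ] - prev)^2)); a
    }
    role <- bbrole[k]
    if (role == "N") {
      # amide H in plane; an uncapped terminal N gets a second H
      el <- c(el, "H"); xyz <- rbind(xyz, bb[k, ] + 1.01 * bis)
      if (k == 1) {
        d2 <- bis * cos(1.2) + c(0, 0, 1) * sin(1.2)
        el <- c(el, "H"); xyz <- rbind(xyz, bb[k, ] + 1.01 * d2)
      }
    } else if (role == "CM") {
      # acetyl methyl: three H around the chain start
      for (s in list(c(1, 0), c(-0.5, 1), c(-0.5, -1))) {
        d <- bis * cos(0.955) * abs(s[1]) * sign(s[1]) +
          c(0, 0, 1) * sin(0.955) * s[2] * 0.9
        d <- d / sqrt(sum(d^2))
        el <- c(el, "H"); xyz <- rbind(xyz, bb[k, ] + 1.09 * d)
      }
    } else if (role == "CA") {
      for (s in c(1, -1)) {
        d <- bis * cos(0.955) + s * c(0, 0, 1) * sin(0.955)
        el <- c(el, "H"); xyz <- rbind(xyz, bb[k, ] + 1.09 * d)
      }
    } else if (role == "C") {
      # carbonyl O in plane
      el <- c(el, "O"); xyz <- rbind(xyz, bb[k, ] + 1.23 * bis)
    } else {
      el <- c(el, "H"); xyz <- rbind(xyz, bb[k, ] + 0.96 * bis)
    }
  }
  st <- atomic_structure(el, xyz, units = "angstrom",
                         provenance = sprintf("fixture:polyglycine%d%s", n,
                                              if (nterm == "ace") "ace" else ""))
  attr(st, "backbone") <- backbone_idx
  st
}

# rotate the atoms listed in `moving` about the axis through points a, b
rotate_about_bond <- function(xyz, a, b, moving, angle) {
  ax <- b - a; ax <- ax / sqrt(sum(ax^2))
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, a) %*% t(R),
                         2, a, "+")
  xyz
}

#' Seeded water shell around a solute
#'
#' Rigid waters are placed by rejection sampling inside a shell of the
#' given thickness around the solute surface, with no atom of a new water
#' closer than `min_dist` to any already placed atom.  A stand-in for the
#' solvation step of the external preparation tools.
#'
#' @param solute an [atomic_structure()].
#' @param thickness shell thickness, Angstrom (0 returns the solute
#'   unchanged).
#' @param min_dist minimum intermolecular atom distance, Angstrom.
#' @param seed RNG seed.
#' @param attempts_per_a3 sampling attempts per cubic Angstrom of bounding
#'   volume (controls packing density).
#' @return An [atomic_structure()] of solute plus waters.
#' @export
make_water_shell <- function(solute, thickness, min_dist = 2.4, seed = 1L,
                             attempts_per_a3 = 0.3) {
  if (thickness <= 0) return(solute)
  set.seed(seed)
  sol_ang <- bohr2ang(solute$xyz)
  lo <- apply(sol_ang, 2, min) - thickness
  hi <- apply(sol_ang, 2, max) + thickness
  vol <- prod(hi - lo)
  n_att <- ceiling(attempts_per_a3 * vol)
  # rigid water in its own frame (Angstrom)
  a <- 104.52 * pi / 180
  wat <- rbind(c(0, 0, 0), c(0.9572, 0, 0), 0.9572 * c(cos(a), sin(a), 0))
  wat <- sweep(wat, 2, colMeans(wat))
  placed_el <- solute$elements
  placed <- sol_ang
  n_wat <- 0L
  for (t in seq_len(n_att)) {
    o <- lo + stats::runif(3) * (hi - lo)
    dmin_sol <- sqrt(min(rowSums(sweep(sol_ang, 2, o)^2)))
    if (dmin_sol > thickness + 1.4 || dmin_sol < min_dist) next
    # random rotation from a seeded quaternion
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quat_rot(q)
    cand <- sweep(wat %*% t(R), 2, o, "+")
    d2 <- min(vapply(seq_len(3), function(r)
      min(rowSums(sweep(placed, 2, cand[r, ])^2)), 0))
    if (d2 < min_dist^2) next
    placed <- rbind(placed, cand)
    placed_el <- c(placed_el, "O", "H", "H")
    n_wat <- n_wat + 1L
  }
  atomic_structure(placed_el, placed, units = "angstrom",
                   provenance = sprintf("%s+%dwaters", solute$provenance,
                                        n_wat))
}

quat_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Peptide fixture with a planted quality gradient
#'
#' An ideal polyglycine chain whose trailing `disorder_fraction` of atoms
#' is disordered with increasing severity along the chain, emulating a
#' low-confidence tail: ramped random torsions about the tail backbone
#' bonds (locally well-bonded but globally misplaced geometry, the
#' signature of low-confidence predicted regions) plus ramped Gaussian
#' coordinate noise up to `sigma_max`.  A clash guard halves any torsion
#' that brings non-bonded atoms closer than 1.5 Angstrom.  A synthetic
#' monotone confidence track (pLDDT-like, high to low) is stored in the
#' B-factor slot and returned as the planted quality.
#'
#' @param n residues.
#' @param disorder_fraction fraction of trailing atoms disturbed, in
#'   `[0, 1]`.
#' @param seed RNG seed.
#' @param sigma_max maximum coordinate noise, Angstrom (default 0.3).
#' @param torsion_max maximum torsion noise s.d., radians (default 0.8,
#'   about 45 degrees -- random-coil-like conformational disorder).
#' @return list with `structure` (B-factor = planted track) and `quality`
#'   (numeric per-atom track, monotone non-increasing).
#' @export
make_quality_gradient_peptide <- function(n, disorder_fraction = 0.4,
                                          seed = 1L, sigma_max = 0.3,
                                          torsion_max = 0.8) {
  stopifnot(disorder_fraction >= 0, disorder_fraction <= 1)
  # acetyl-capped head: the ordered region starts interior-like instead of
  # with a special NH2 terminus whose elevated atomic energies would
  # confound the planted gradient
  st <- make_polyglycine(n, nterm = "ace")
  bb <- attr(st, "backbone")
  na <- n_atoms(st)
  set.seed(seed)
  n_tail <- round(disorder_fraction * na)
  quality <- rep(90, na)
  if (n_tail > 0) {
    tail_start <- na - n_tail + 1L
    # ramped torsional disorder about backbone bonds inside the tail
    bb_tail <- bb[bb >= tail_start]
    if (length(bb_tail) >= 2L) {
      for (r in seq_len(length(bb_tail) - 1L)) {
        a <- bb_tail[r]; b <- bb_tail[r + 1L]
        moving <- which(seq_len(na) > b)
        if (!length(moving)) next
        ramp_r <- r / (length(bb_tail) - 1L)
        angle <- stats::rnorm(1, 0, torsion_max * ramp_r)
        for (try in 1:6) {
          cand <- rotate_about_bond(st$xyz, st$xyz[a, ], st$xyz[b, ],
                                    moving, angle)
          dmin <- min(vapply(moving, function(m)
            min(sqrt(rowSums((cand[-unique(c(moving, b)), , drop = FALSE] -
                                matrix(cand[m, ], na - length(moving) - 1L,
                                       3, byrow = TRUE))^2))), 0))
          if (bohr2ang(dmin) >= 1.5) break
          angle <- angle / 2
        }
        st$xyz <- cand
      }
    }
    tail_idx <- tail_start:na
    ramp <- seq_len(n_tail) / n_tail
    # sigma_max is the positional uncertainty (displacement magnitude), so
    # each coordinate gets sigma/sqrt(3)
    sig <- ang2bohr(sigma_max) * ramp / sqrt(3)
    noise <- matrix(stats::rnorm(3 * n_tail), n_tail, 3) * sig
    st$xyz[tail_idx, ] <- st$xyz[tail_idx, ] + noise
    quality[tail_idx] <- 90 - 50 * ramp
  }
  st$bfactor <- quality
  st$provenance <- sprintf("fixture:quality_gradient_peptide%d_f%.2f", n,
                           disorder_fraction)
  list(structure = st, quality = quality)
}
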