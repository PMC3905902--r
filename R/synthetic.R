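#' Synthetic active-site and kinetic data generators
#'
#' Every generator plants known ground truth so that the corresponding
#' analysis can be validated round-trip: attack sites with chosen distance
#' and in-line angle, tetrahedral phosphates of chosen handedness,
#' five-coordinate TBP sites, survey corpora with planted distance
#' distributions, snapshot series with planted inter-snapshot motions, and
#' first-order intensity time courses. All randomness is seeded.
#'
#' @name synthetic_data
NULL

.unit <- function(v) v / sqrt(sum(v * v))

# rotate points (rows) about an axis through `origin` along unit vector `u`
.rotate_about <- function(points, origin, u, angle_deg) {
  th <- angle_deg * pi / 180
  u <- .unit(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(points, 2, origin) %*% t(R), 2, -origin)
}

.atom_row <- function(record, serial, name, resname, chain, resseq, xyz,
                      element, occ = 1, b = 0) {
  data.frame(record = record, serial = serial, name = name, alt_loc = "",
             resname = resname, chain = chain, resseq = resseq, icode = "",
             x = xyz[1], y = xyz[2], z = xyz[3], occ = occ, b = b,
             element = element, stringsAsFactors = FALSE)
}

.bind_atoms <- function(rows) {
  m <- do.call(rbind, rows)
  m$serial <- seq_len(nrow(m))
  m
}

# tetrahedral directions: leaving along +z, the other three 109.47 deg away
.tetra_dirs <- function() {
  polar <- 180 - 109.471
  az <- c(0, 120, 240) * pi / 180
  pz <- polar * pi / 180
  list(leaving = c(0, 0, 1),
       others = rbind(
         c(sin(pz) * cos(az[1]), sin(pz) * sin(az[1]), -cos(pz)),
         c(sin(pz) * cos(az[2]), sin(pz) * sin(az[2]), -cos(pz)),
         c(sin(pz) * cos(az[3]), sin(pz) * sin(az[3]), -cos(pz))))
}

#' Build an idealized near-attack active site
#'
#' Emits an alpha-phosphate (P bonded to the bridging O5' with its C5'
#' anchor, two non-bridging oxygens O1A/O2A, and a bridging leaving atom
#' N3A), a water oxygen placed at exactly \code{d_attack} from P with the
#' stated nucleophile-P-leaving in-line angle, and optionally two
#' coordinating protein atoms mimicking the Val93 main-chain carbonyl and
#' the Asp95 carboxylate within hydrogen-bond distance of the water.
#'
#' @param d_attack water-oxygen to phosphorus distance (Angstrom); the
#'   default is the short pre-catalytic contact of the enzyme-substrate
#'   complex.
#' @param inline_angle nucleophile-P-leaving angle (degrees, in (0, 180]).
#' @param with_coordination add the Val93/Asp95 coordination atoms?
#' @param bond_lengths P-substituent bond lengths for O5', O1A, O2A and
#'   the leaving atom (Angstrom); defaults are the enzyme-substrate
#'   alpha-phosphate values.
#' @param jitter Gaussian coordinate noise (Angstrom, sd).
#' @param seed RNG seed (used when \code{jitter > 0}).
#' @return a \code{pdb_structure}; the planted parameters are attached as
#'   \code{attr(, "planted")}.
#' @export
make_attack_site <- function(d_attack = 2.52, inline_angle = 175,
                             with_coordination = TRUE,
                             bond_lengths = c(1.61, 1.48, 1.52, 1.64),
                             jitter = 0, seed = 1) {
  stopifnot(d_attack > 0, inline_angle > 0, inline_angle <= 180,
            all(bond_lengths > 0), jitter >= 0)
  td <- .tetra_dirs()
  p <- c(0, 0, 0)
  o5p <- bond_lengths[1] * td$others[1, ]
  o1a <- bond_lengths[2] * td$others[2, ]
  o2a <- bond_lengths[3] * td$others[3, ]
  n3a <- bond_lengths[4] * td$leaving
  c5p <- o5p + 1.44 * .unit(o5p - p + c(0.4, 0.2, -0.6))
  th <- inline_angle * pi / 180
  w_dir <- c(sin(th), 0, cos(th))       # angle `inline_angle` from +z
  ow <- d_attack * w_dir
  rows <- list(
    .atom_row("HETATM", 1, "PA", "DUP", "B", 201, p, "P"),
    .atom_row("HETATM", 2, "O5'", "DUP", "B", 201, o5p, "O"),
    .atom_row("HETATM", 3, "C5'", "DUP", "B", 201, c5p, "C"),
    .atom_row("HETATM", 4, "O1A", "DUP", "B", 201, o1a, "O"),
    .atom_row("HETATM", 5, "O2A", "DUP", "B", 201, o2a, "O"),
    .atom_row("HETATM", 6, "N3A", "DUP", "B", 201, n3a, "N"),
    .atom_row("HETATM", 7, "O", "HOH", "W", 1, ow, "O"))
  if (with_coordination) {
    perp <- c(cos(th), 0, -sin(th))     # perpendicular to the attack axis
    val_o <- ow + 2.80 * .unit(w_dir + 0.9 * perp)
    asp_od1 <- ow + 2.70 * .unit(w_dir - 0.9 * perp)
    asp_cg <- asp_od1 + 1.25 * .unit(w_dir - 0.2 * perp + c(0, 0.8, 0))
    asp_od2 <- asp_cg + 1.25 * .unit(w_dir + c(0, 1.2, 0))
    rows <- c(rows, list(
      .atom_row("ATOM", 8, "O", "VAL", "A", 93, val_o, "O"),
      .atom_row("ATOM", 9, "OD1", "ASP", "A", 95, asp_od1, "O"),
      .atom_row("ATOM", 10, "CG", "ASP", "A", 95, asp_cg, "C"),
      .atom_row("ATOM", 11, "OD2", "ASP", "A", 95, asp_od2, "O")))
    # coordinating oxygens must not masquerade as additional nucleophiles
    for (v in list(val_o, asp_od1, asp_od2))
      stopifnot(sqrt(sum((v - p)^2)) > 3.6)
  }
  m <- .bind_atoms(rows)
  if (jitter > 0) {
    set.seed(seed)
    m[, c("x", "y", "z")] <- m[, c("x", "y", "z")] +
      stats::rnorm(3 * nrow(m), sd = jitter)
  }
  out <- pdb_structure(m, id = "synthetic_attack_site")
  attr(out, "planted") <- list(d_attack = d_attack,
                               inline_angle = inline_angle)
  out
}

#' Build a tetrahedral phosphate of chosen handedness
#'
#' The chirality convention orders substituents O5' > O1A > O2A > leaving;
#' \code{handedness} is the sign of the resulting signed volume.
#' \code{invert_phosphate} mirrors the substituents through the plane
#' orthogonal to the leaving-atom axis through the phosphorus, flipping
#' the chirality sign while preserving all bond lengths (the geometric
#' essence of Walden inversion).
#'
#' @param handedness +1 or -1.
#' @param bond_lengths P-substituent bond lengths for O5', O1A, O2A and
#'   the leaving atom (Angstrom).
#' @param leaving_name atom name of the fourth substituent.
#' @return a \code{pdb_structure} of 5 atoms.
#' @export
make_phosphate <- function(handedness = 1,
                           bond_lengths = c(1.61, 1.48, 1.52, 1.64),
                           leaving_name = "O3A") {
  stopifnot(handedness %in% c(-1, 1), all(bond_lengths > 0))
  td <- .tetra_dirs()
  p <- c(0, 0, 0)
  subs <- rbind(bond_lengths[1] * td$others[1, ],
                bond_lengths[2] * td$others[2, ],
                bond_lengths[3] * td$others[3, ],
                bond_lengths[4] * td$leaving)
  vol <- sum((subs[2, ] - p) *
               pracma::cross(subs[3, ] - p, subs[4, ] - p))
  if (sign(vol) != handedness) subs[, 3] <- -subs[, 3]  # mirror in z
  nm <- c("O5'", "O1A", "O2A", leaving_name)
  el <- c("O", "O", "O", if (startsWith(leaving_name, "N")) "N" else "O")
  rows <- c(list(.atom_row("HETATM", 1, "PA", "PO4", "B", 1, p, "P")),
            lapply(1:4, function(i)
              .atom_row("HETATM", i + 1, nm[i], "PO4", "B", 1, subs[i, ], el[i])))
  out <- pdb_structure(.bind_atoms(rows), id = "synthetic_phosphate")
  attr(out, "planted") <- list(handedness = handedness,
                               leaving_name = leaving_name)
  out
}

#' @rdname make_phosphate
#' @param structure a structure from \code{make_phosphate}.
#' @param p_name,axis_name atom names of the phosphorus and of the
#'   leaving/incoming axis atom.
#' @export
invert_phosphate <- function(structure, p_name = "PA",
                             axis_name = NULL) {
  m <- structure$models[[1]]
  if (is.null(axis_name)) {
    axis_name <- attr(structure, "planted")$leaving_name
    if (is.null(axis_name)) stop("axis_name must be given")
  }
  p <- as.numeric(m[m$name == p_name, c("x", "y", "z")])
  ax <- as.numeric(m[m$name == axis_name, c("x", "y", "z")])
  u <- .unit(ax - p)
  refl <- function(x) x - 2 * sum((x - p) * u) * u
  for (i in which(m$name != p_name)) {
    m[i, c("x", "y", "z")] <- refl(as.numeric(m[i, c("x", "y", "z")]))
  }
  out <- pdb_structure(m, id = paste0(structure$id, "_inverted"))
  attr(out, "planted") <- attr(structure, "planted")
  out
}

#' Build a five-coordinate trigonal-bipyramidal phosphorus site
#'
#' Axial ligands are the leaving nitrogen (N3A, along +z) and the incoming
#' water oxygen (OW); equatorial ligands are O5', O1A, O2A at 120 degree
#' spacing. Defaults are the ideal associative-transition-state reference
#' (axial 1.91 Angstrom, equatorial 1.60 Angstrom, axial angle 180).
#'
#' @param ax_lengths 2 axial bond lengths (Angstrom).
#' @param eq_lengths 3 equatorial bond lengths (Angstrom).
#' @param axial_angle axial ligand-P-ligand angle (degrees).
#' @param jitter Gaussian coordinate noise sd (Angstrom).
#' @param seed RNG seed.
#' @return a \code{pdb_structure} of 6 atoms with planted axial pair
#'   attached as \code{attr(, "planted")}.
#' @export
make_tbp_site <- function(ax_lengths = c(1.91, 1.91),
                          eq_lengths = c(1.60, 1.60, 1.60),
                          axial_angle = 180, jitter = 0, seed = 1) {
  stopifnot(length(ax_lengths) == 2, length(eq_lengths) == 3,
            all(c(ax_lengths, eq_lengths) > 0), jitter >= 0)
  p <- c(0, 0, 0)
  th <- axial_angle * pi / 180
  ax1 <- ax_lengths[1] * c(0, 0, 1)
  ax2 <- ax_lengths[2] * c(sin(th), 0, cos(th))
  az <- c(90, 210, 330) * pi / 180
  eq <- t(vapply(1:3, function(i)
    eq_lengths[i] * c(cos(az[i]), sin(az[i]), 0), numeric(3)))
  rows <- list(
    .atom_row("HETATM", 1, "PA", "TBP", "B", 1, p, "P"),
    .atom_row("HETATM", 2, "N3A", "TBP", "B", 1, ax1, "N"),
    .atom_row("HETATM", 3, "OW", "TBP", "B", 1, ax2, "O"),
    .atom_row("HETATM", 4, "O5'", "TBP", "B", 1, eq[1, ], "O"),
    .atom_row("HETATM", 5, "O1A", "TBP", "B", 1, eq[2, ], "O"),
    .atom_row("HETATM", 6, "O2A", "TBP", "B", 1, eq[3, ], "O"))
  m <- .bind_atoms(rows)
  if (jitter > 0) {
    set.seed(seed)
    m[, c("x", "y", "z")] <- m[, c("x", "y", "z")] +
      stats::rnorm(3 * nrow(m), sd = jitter)
  }
  out <- pdb_structure(m, id = "synthetic_tbp_site")
  attr(out, "planted") <- list(axial = c("N3A", "OW"),
                               ax_lengths = ax_lengths,
                               eq_lengths = eq_lengths,
                               axial_angle = axial_angle)
  out
}

#' Build a survey corpus with planted non-bonded P-O distances
#'
#' Each structure holds one phosphorus and water oxygens at exactly the
#' planted distances in random directions, so the survey bookkeeping is
#' known in advance. Distances at or below the geometric bonding
#' threshold would be perceived as covalent bonds and are rejected.
#'
#' @param planted_distances numeric vector of P-O distances (Angstrom).
#' @param n_structures number of structures to spread the pairs over.
#' @param seed RNG seed for the directions.
#' @return list of \code{pdb_structure} objects.
#' @export
make_survey_corpus <- function(planted_distances, n_structures = 1, seed = 1) {
  bond_thr <- covalent_radius("P") + covalent_radius("O") + 0.4
  if (length(planted_distances) > 0 && any(planted_distances <= bond_thr))
    stop("planted distance(s) at or below the bonding threshold (",
         sprintf("%.2f", bond_thr), " A) would be perceived as bonds")
  set.seed(seed)
  groups <- if (length(planted_distances) == 0) rep(list(numeric(0)), n_structures)
  else split(planted_distances,
             rep_len(seq_len(n_structures), length(planted_distances)))
  lapply(seq_len(n_structures), function(s) {
    ds <- if (s <= length(groups)) groups[[s]] else numeric(0)
    rows <- list(.atom_row("HETATM", 1, "P", "PO4", "B", 1, c(0, 0, 0), "P"))
    for (i in seq_along(ds)) {
      dir <- .unit(stats::rnorm(3))
      rows <- c(rows, list(
        .atom_row("HETATM", i + 1, "O", "HOH", "W", i, ds[i] * dir, "O")))
    }
    pdb_structure(.bind_atoms(rows), id = sprintf("synthetic_corpus_%02d", s))
  })
}

#' Simulate first-order decay/rise peak intensity time courses
#'
#' Decaying peaks follow \code{a0 * exp(-k t)}, rising peaks
#' \code{b0 * (1 - exp(-k t))}, with optional additive Gaussian noise.
#' Defaults emulate the six-resonance hydrolysis time course: three
#' substrate peaks decaying and three product peaks rising at equal
#' amplitude, twenty time points spanning three half-lives.
#'
#' @param k shared first-order rate constant (inverse time units).
#' @param a0 amplitudes of the decaying peaks.
#' @param b0 plateau amplitudes of the rising peaks.
#' @param timepoints sampling times; default spans three half-lives.
#' @param noise_sd additive Gaussian noise sd (same units as intensity).
#' @param seed RNG seed.
#' @return a \code{\link{peak_series}}.
#' @export
make_timeseries <- function(k = 0.015, a0 = c(1, 1, 1), b0 = c(1, 1, 1),
                            timepoints = seq(0, 3 * log(2) / k,
                                             length.out = 20),
                            noise_sd = 0, seed = 1) {
  stopifnot(k > 0, noise_sd >= 0, all(diff(timepoints) > 0),
            length(a0) + length(b0) >= 1)
  cols <- c(lapply(a0, function(a) a * exp(-k * timepoints)),
            lapply(b0, function(b) b * (1 - exp(-k * timepoints))))
  series <- do.call(cbind, cols)
  colnames(series) <- c(if (length(a0)) paste0("substrate", seq_along(a0)),
                        if (length(b0)) paste0("product", seq_along(b0)))
  if (noise_sd > 0) {
    set.seed(seed)
    series <- series + matrix(stats::rnorm(length(series), sd = noise_sd),
                              nrow(series))
  }
  peak_series(timepoints, series,
              c(rep("decay", length(a0)), rep("rise", length(b0))))
}
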