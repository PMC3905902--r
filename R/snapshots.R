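#' Synthetic reaction snapshot series with planted motions
#'
#' Builds an idealized four-stage active-site series mirroring the states
#' a dUTPase crystal passes through during alpha-phosphate hydrolysis:
#' \itemize{
#'   \item \code{apo}: protein scaffold plus the bound catalytic water.
#'   \item \code{ES}: enzyme-substrate complex; the alpha-phosphate sits
#'     with its leaving nitrogen in-line with the water nucleophile at the
#'     planted attack distance, the water coordinated by the Val93
#'     main-chain carbonyl and the Asp95 carboxylate. Relative to apo the
#'     Asp95 side chain has rotated by the planted terminal-dihedral
#'     change (default 15.8 degrees) with the planted Od2 displacement
#'     (default 0.61 Angstrom), and Asp42 Cg has moved by the planted
#'     range (default 1.2 Angstrom).
#'   \item \code{EpiP}: post-inversion product; the nucleophile oxygen now
#'     bonds the phosphorus on the attack line and the configuration at
#'     phosphorus is inverted (Walden inversion) relative to ES.
#'   \item \code{EP}: relaxed end product; the alpha-phosphorus is
#'     displaced by the planted shift (default 1.57 Angstrom) and the
#'     terminal oxygens are rotated by the planted angle (default 40
#'     degrees) about the O5'-P bond.
#' }
#' The protein main chain is identical across snapshots, so main-chain
#' superposition is the identity and the planted values are recovered
#' exactly. These structures are synthetic stand-ins with known ground
#' truth, not models of any deposited coordinates.
#'
#' @param d_attack,inline_angle near-attack geometry planted in ES.
#' @param asp95_rotation terminal chi dihedral change of Asp95, apo to ES
#'   (degrees).
#' @param asp95_od2_shift Asp95 Od2 displacement, apo to ES (Angstrom).
#' @param asp42_cg_shift Asp42 Cg displacement, apo to ES (Angstrom).
#' @param p_shift alpha-P displacement, EpiP to EP (Angstrom).
#' @param phosphate_rotation rotation of the terminal oxygens about the
#'   O5'-P axis, EpiP to EP (degrees).
#' @return named list of \code{pdb_structure} objects
#'   (\code{apo}, \code{ES}, \code{EpiP}, \code{EP}).
#' @export
make_snapshot_series <- function(d_attack = 2.52, inline_angle = 175,
                                 asp95_rotation = 15.8,
                                 asp95_od2_shift = 0.61,
                                 asp42_cg_shift = 1.2,
                                 p_shift = 1.57,
                                 phosphate_rotation = 40) {
  td <- .tetra_dirs()
  p <- c(0, 0, 0)
  o5p <- 1.61 * td$others[1, ]
  o1a <- 1.48 * td$others[2, ]
  o2a <- 1.52 * td$others[3, ]
  n3a <- 1.64 * td$leaving
  c5p <- o5p + 1.44 * .unit(o5p - p + c(0.4, 0.2, -0.6))
  th <- inline_angle * pi / 180
  w_dir <- c(sin(th), 0, cos(th))
  ow <- d_attack * w_dir
  perp <- c(cos(th), 0, -sin(th))

  ## --- protein scaffold (identical main chain in every snapshot) -------
  val_o <- ow + 2.80 * .unit(w_dir + 0.9 * perp)
  val_c <- val_o + 1.23 * .unit(c(-0.5, 0.8, -0.4))
  val_ca <- val_c + 1.52 * .unit(c(-1, 0.2, 0.2))
  val_n <- val_ca + 1.46 * .unit(c(-0.4, -1, 0.3))
  ile_ca <- val_ca + c(3.0, 1.8, 1.2)
  ile_n <- ile_ca + 1.46 * .unit(c(-1, 0.4, 0))
  ile_c <- ile_ca + 1.52 * .unit(c(0.9, 0.6, -0.4))
  ile_o <- ile_c + 1.23 * .unit(c(0.2, 1, 0.1))
  ala_ca <- c(-4.0, 3.0, -6.0)
  ala_n <- ala_ca + 1.46 * .unit(c(0.6, 0.8, 0.2))
  ala_c <- ala_ca + 1.52 * .unit(c(-0.8, -0.3, 0.7))
  ala_o <- ala_c + 1.23 * .unit(c(0, -1, 0.4))

  # Asp95: ES side-chain conformation coordinates the water via OD1
  asp_od1 <- ow + 2.70 * .unit(w_dir - 0.9 * perp)
  asp_cg <- asp_od1 + 1.25 * .unit(w_dir - 0.2 * perp + c(0, 0.8, 0))
  asp_od2 <- asp_cg + 1.25 * .unit(w_dir + c(0, 1.2, 0))
  asp_cb <- asp_cg - 1.52 * .unit(.unit(asp_od1 - asp_cg) +
                                    .unit(asp_od2 - asp_cg))
  asp_ca <- asp_cb + 1.52 * .unit(c(0.3, -1, -0.8))
  asp_n <- asp_ca + 1.46 * .unit(c(-1, 0.2, -0.4))
  asp_c <- asp_ca + 1.52 * .unit(c(0.8, 0.5, -0.6))
  asp_o <- asp_c + 1.23 * .unit(c(0.3, 1, 0))

  # Asp42: apo side-chain conformation; ES rotated about CA-CB so that
  # CG moves by exactly asp42_cg_shift
  d42_ca <- c(2.0, 5.0, -8.0)
  d42_n <- d42_ca + 1.46 * .unit(c(-1, 0.3, 0.2))
  d42_c <- d42_ca + 1.52 * .unit(c(1, 0.4, -0.3))
  d42_o <- d42_c + 1.23 * .unit(c(0.3, 1, 0.2))
  d42_cb <- d42_ca + 1.52 * .unit(c(0.3, -1, 0.5))
  d42_cg <- d42_cb + 1.52 * .unit(c(0.8, -0.5, 0.9))
  d42_od1 <- d42_cg + 1.25 * .unit(c(1, 0, 0.3))
  d42_od2 <- d42_cg + 1.25 * .unit(c(-0.2, -1, 0.6))
  d42_side_apo <- rbind(d42_cg, d42_od1, d42_od2)
  u42 <- .unit(d42_cb - d42_ca)
  f42 <- function(g) {
    moved <- .rotate_about(d42_side_apo, d42_cb, u42, g)
    sqrt(sum((moved[1, ] - d42_cg)^2)) - asp42_cg_shift
  }
  if (f42(170) < 0) stop("requested Asp42 Cg shift is geometrically infeasible")
  g42 <- stats::uniroot(f42, c(0, 170), tol = 1e-12)$root
  d42_side_es <- .rotate_about(d42_side_apo, d42_cb, u42, g42)

  # Asp95 apo conformation: undo a terminal-dihedral (chi2) rotation of
  # asp95_rotation about CB-CG, then a chi1 rotation about CA-CB chosen
  # so that OD2 moves by exactly asp95_od2_shift (chi1 leaves the
  # terminal dihedral unchanged, so the planted rotation is preserved)
  u_chi2 <- .unit(asp_cg - asp_cb)
  od_apo0 <- .rotate_about(rbind(asp_od1, asp_od2), asp_cg, u_chi2,
                           -asp95_rotation)
  u_chi1 <- .unit(asp_cb - asp_ca)
  f95 <- function(beta) {
    moved <- .rotate_about(rbind(asp_cg, od_apo0), asp_cb, u_chi1, -beta)
    sqrt(sum((moved[3, ] - asp_od2)^2)) - asp95_od2_shift
  }
  if (f95(0) > 0)
    stop("chi2 rotation alone already exceeds the requested Od2 shift")
  b95 <- stats::uniroot(f95, c(0, 90), tol = 1e-12)$root
  side95_apo <- .rotate_about(rbind(asp_cg, od_apo0), asp_cb, u_chi1, -b95)

  protein_rows <- function(asp95_side, asp42_side) list(
    .atom_row("ATOM", 0, "N", "ALA", "A", 39, ala_n, "N"),
    .atom_row("ATOM", 0, "CA", "ALA", "A", 39, ala_ca, "C"),
    .atom_row("ATOM", 0, "C", "ALA", "A", 39, ala_c, "C"),
    .atom_row("ATOM", 0, "O", "ALA", "A", 39, ala_o, "O"),
    .atom_row("ATOM", 0, "N", "ASP", "A", 42, d42_n, "N"),
    .atom_row("ATOM", 0, "CA", "ASP", "A", 42, d42_ca, "C"),
    .atom_row("ATOM", 0, "C", "ASP", "A", 42, d42_c, "C"),
    .atom_row("ATOM", 0, "O", "ASP", "A", 42, d42_o, "O"),
    .atom_row("ATOM", 0, "CB", "ASP", "A", 42, d42_cb, "C"),
    .atom_row("ATOM", 0, "CG", "ASP", "A", 42, asp42_side[1, ], "C"),
    .atom_row("ATOM", 0, "OD1", "ASP", "A", 42, asp42_side[2, ], "O"),
    .atom_row("ATOM", 0, "OD2", "ASP", "A", 42, asp42_side[3, ], "O"),
    .atom_row("ATOM", 0, "N", "VAL", "A", 93, val_n, "N"),
    .atom_row("ATOM", 0, "CA", "VAL", "A", 93, val_ca, "C"),
    .atom_row("ATOM", 0, "C", "VAL", "A", 93, val_c, "C"),
    .atom_row("ATOM", 0, "O", "VAL", "A", 93, val_o, "O"),
    .atom_row("ATOM", 0, "N", "ILE", "A", 94, ile_n, "N"),
    .atom_row("ATOM", 0, "CA", "ILE", "A", 94, ile_ca, "C"),
    .atom_row("ATOM", 0, "C", "ILE", "A", 94, ile_c, "C"),
    .atom_row("ATOM", 0, "O", "ILE", "A", 94, ile_o, "O"),
    .atom_row("ATOM", 0, "N", "ASP", "A", 95, asp_n, "N"),
    .atom_row("ATOM", 0, "CA", "ASP", "A", 95, asp_ca, "C"),
    .atom_row("ATOM", 0, "C", "ASP", "A", 95, asp_c, "C"),
    .atom_row("ATOM", 0, "O", "ASP", "A", 95, asp_o, "O"),
    .atom_row("ATOM", 0, "CB", "ASP", "A", 95, asp_cb, "C"),
    .atom_row("ATOM", 0, "CG", "ASP", "A", 95, asp95_side[1, ], "C"),
    .atom_row("ATOM", 0, "OD1", "ASP", "A", 95, asp95_side[2, ], "O"),
    .atom_row("ATOM", 0, "OD2", "ASP", "A", 95, asp95_side[3, ], "O"))

  side95_es <- rbind(asp_cg, asp_od1, asp_od2)
  water_row <- list(.atom_row("HETATM", 0, "O", "HOH", "W", 1, ow, "O"))

  ## --- apo -------------------------------------------------------------
  apo <- pdb_structure(.bind_atoms(c(protein_rows(side95_apo, d42_side_apo),
                                     water_row)), id = "synthetic_apo")

  ## --- ES --------------------------------------------------------------
  lig_es <- list(
    .atom_row("HETATM", 0, "PA", "DUP", "B", 201, p, "P"),
    .atom_row("HETATM", 0, "O5'", "DUP", "B", 201, o5p, "O"),
    .atom_row("HETATM", 0, "C5'", "DUP", "B", 201, c5p, "C"),
    .atom_row("HETATM", 0, "O1A", "DUP", "B", 201, o1a, "O"),
    .atom_row("HETATM", 0, "O2A", "DUP", "B", 201, o2a, "O"),
    .atom_row("HETATM", 0, "N3A", "DUP", "B", 201, n3a, "N"))
  es <- pdb_structure(.bind_atoms(c(protein_rows(side95_es, d42_side_es),
                                    lig_es, water_row)), id = "synthetic_ES")

  ## --- EpiP: Walden inversion ------------------------------------------
  # phosphorus crosses the O5'/O1A/O2A plane; the incoming oxygen sits on
  # the former attack line at covalent distance
  nrm <- .unit(pracma::cross(o1a - o5p, o2a - o5p))
  p_pi <- p - 2 * sum((p - o5p) * nrm) * nrm
  ow_pi <- p_pi + 1.61 * .unit(ow - p_pi)
  sign_es <- chirality_descriptor(p, rbind(o5p, o1a, o2a, n3a))$sign
  sign_pi <- chirality_descriptor(p_pi, rbind(o5p, o1a, o2a, ow_pi))$sign
  stopifnot(sign_es * sign_pi == -1)
  lig_pi <- list(
    .atom_row("HETATM", 0, "PA", "UMP", "B", 201, p_pi, "P"),
    .atom_row("HETATM", 0, "O5'", "UMP", "B", 201, o5p, "O"),
    .atom_row("HETATM", 0, "C5'", "UMP", "B", 201, c5p, "C"),
    .atom_row("HETATM", 0, "O1A", "UMP", "B", 201, o1a, "O"),
    .atom_row("HETATM", 0, "O2A", "UMP", "B", 201, o2a, "O"),
    .atom_row("HETATM", 0, "OW", "UMP", "B", 201, ow_pi, "O"))
  epip <- pdb_structure(.bind_atoms(c(protein_rows(side95_es, d42_side_apo),
                                      lig_pi)), id = "synthetic_EpiP")

  ## --- EP: planted P shift + torsion about O5'-P -----------------------
  u_ax <- .unit(p_pi - o5p)
  shift_dir <- .unit((ow_pi - p_pi) - sum((ow_pi - p_pi) * u_ax) * u_ax)
  p_ep <- p_pi + p_shift * shift_dir
  term_names <- c("O1A", "O2A", "OW")
  term_pi <- rbind(o1a, o2a, ow_pi)
  term_ep <- term_pi
  for (i in 1:3) {
    az_pre <- dihedral_xyz(c5p, o5p, p_pi, term_pi[i, ])
    polar <- angle_xyz(o5p, p_ep, term_pi[i, ] + p_ep - p_pi)
    len <- sqrt(sum((term_pi[i, ] - p_pi)^2))
    term_ep[i, ] <- .place_by_azimuth(c5p, o5p, p_ep, len,
                                      polar, az_pre + phosphate_rotation)
  }
  lig_ep <- list(
    .atom_row("HETATM", 0, "PA", "UMP", "B", 201, p_ep, "P"),
    .atom_row("HETATM", 0, "O5'", "UMP", "B", 201, o5p, "O"),
    .atom_row("HETATM", 0, "C5'", "UMP", "B", 201, c5p, "C"),
    .atom_row("HETATM", 0, "O1A", "UMP", "B", 201, term_ep[1, ], "O"),
    .atom_row("HETATM", 0, "O2A", "UMP", "B", 201, term_ep[2, ], "O"),
    .atom_row("HETATM", 0, "OW", "UMP", "B", 201, term_ep[3, ], "O"))
  ep <- pdb_structure(.bind_atoms(c(protein_rows(side95_es, d42_side_apo),
                                    lig_ep)), id = "synthetic_EP")

  out <- list(apo = apo, ES = es, EpiP = epip, EP = ep)
  attr(out, "planted") <- list(
    d_attack = d_attack, inline_angle = inline_angle,
    asp95_rotation = asp95_rotation, asp95_od2_shift = asp95_od2_shift,
    asp42_cg_shift = asp42_cg_shift, p_shift = p_shift,
    phosphate_rotation = phosphate_rotation)
  out
}

# place an atom X at distance `len` from `c_pos` with angle(b_pos, c_pos, X)
# = `polar` degrees and dihedral(a_pos, b_pos, c_pos, X) = `azimuth` degrees
.place_by_azimuth <- function(a_pos, b_pos, c_pos, len, polar, azimuth) {
  u <- .unit(c_pos - b_pos)
  r0 <- (a_pos - b_pos) - sum((a_pos - b_pos) * u) * u
  v <- .unit(r0)
  w <- pracma::cross(u, v)
  thp <- (180 - polar) * pi / 180  # `polar` is the angle at c towards b
  for (sgn in c(1, -1)) {
    phi <- sgn * azimuth * pi / 180
    x <- c_pos + len * (cos(thp) * u +
                          sin(thp) * (cos(phi) * v + sin(phi) * w))
    got <- dihedral_xyz(a_pos, b_pos, c_pos, x)
    if (abs(((got - azimuth + 180) %% 360) - 180) < 1e-6) return(x)
  }
  stop("azimuth placement failed to match the dihedral convention")
}
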