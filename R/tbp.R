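#' Ideal trigonal-bipyramidal reference geometry
#'
#' Reference constants for the transition state of the associative
#' concerted A_N D_N phosphoryl transfer: equatorial P-O bonds of 1.60
#' Angstrom, axial bonds of 1.91 Angstrom, and angles of 180 (axial-axial),
#' 120 (equatorial-equatorial) and 90 degrees (axial-equatorial).
#'
#' @param eq_length,ax_length bond lengths (Angstrom).
#' @param ax_angle,eq_angle,ax_eq_angle angles (degrees).
#' @return object of class \code{tbp_reference}.
#' @export
tbp_reference <- function(eq_length = 1.60, ax_length = 1.91,
                          ax_angle = 180, eq_angle = 120, ax_eq_angle = 90) {
  structure(list(eq_length = eq_length, ax_length = ax_length,
                 ax_angle = ax_angle, eq_angle = eq_angle,
                 ax_eq_angle = ax_eq_angle), class = "tbp_reference")
}

#' Assign axial/equatorial roles at a five-coordinate phosphorus
#'
#' The axial pair is the ligand pair subtending the largest
#' ligand-P-ligand angle (ties broken towards the larger mean P-ligand
#' distance, then by ligand label order); the remaining three ligands are
#' equatorial. All inter-ligand angles and P-ligand distances are
#' reported.
#'
#' @param p phosphorus position (length-3).
#' @param ligands 5 x 3 matrix of ligand positions; row names, when
#'   present, label the ligands.
#' @return object of class \code{tbp_assignment} with \code{axial},
#'   \code{equatorial} (indices into the ligand rows), \code{axial_angle},
#'   \code{ax_distances}, \code{eq_distances}, \code{eq_angles} (3) and
#'   \code{ax_eq_angles} (6).
#' @export
assign_tbp <- function(p, ligands) {
  ligands <- as.matrix(ligands)
  if (nrow(ligands) != 5) stop("exactly 5 ligand positions are required")
  labels <- rownames(ligands)
  if (is.null(labels)) labels <- as.character(seq_len(5))
  d <- apply(ligands, 1, function(v) dist_xyz(p, v))
  if (any(d < 1e-6)) stop("ligand coincident with the phosphorus")
  pairs <- utils::combn(5, 2)
  pair_angle <- apply(pairs, 2, function(ij)
    angle_xyz(ligands[ij[1], ], p, ligands[ij[2], ]))
  pair_meand <- apply(pairs, 2, function(ij) mean(d[ij]))
  pair_label <- apply(pairs, 2, function(ij)
    paste(sort(labels[ij]), collapse = "|"))
  ord <- order(-pair_angle, -pair_meand, pair_label)
  best <- pairs[, ord[1]]
  axial <- sort(best)
  equatorial <- setdiff(seq_len(5), axial)
  ax_angle <- pair_angle[ord[1]]
  eqp <- utils::combn(equatorial, 2)
  eq_angles <- apply(eqp, 2, function(ij)
    angle_xyz(ligands[ij[1], ], p, ligands[ij[2], ]))
  ax_eq <- expand.grid(ax = axial, eq = equatorial)
  ax_eq_angles <- mapply(function(a, e)
    angle_xyz(ligands[a, ], p, ligands[e, ]), ax_eq$ax, ax_eq$eq)
  structure(list(
    axial = axial, equatorial = equatorial, labels = labels,
    axial_angle = ax_angle,
    ax_distances = d[axial], eq_distances = d[equatorial],
    eq_angles = as.numeric(eq_angles),
    ax_eq_angles = as.numeric(ax_eq_angles)), class = "tbp_assignment")
}

#' @export
print.tbp_assignment <- function(x, ...) {
  cat(sprintf(
    "<tbp_assignment: axial {%s} at %.1f deg; equatorial {%s}>\n",
    paste(x$labels[x$axial], collapse = ", "), x$axial_angle,
    paste(x$labels[x$equatorial], collapse = ", ")))
  invisible(x)
}

#' Deviation of a five-coordinate site from the ideal TBP geometry
#'
#' Per-feature deltas are observed minus reference; root-mean-square
#' aggregates are reported separately for angles (degrees, over the
#' axial-axial, three equatorial-equatorial and six axial-equatorial
#' angles) and bond lengths (Angstrom, over the five P-ligand distances).
#'
#' @param assignment a \code{\link{assign_tbp}} result.
#' @param reference a \code{\link{tbp_reference}}.
#' @return object of class \code{tbp_deviation} with \code{deltas} (named
#'   list) plus \code{rms_angles} and \code{rms_lengths}.
#' @export
tbp_deviation <- function(assignment, reference = tbp_reference()) {
  stopifnot(inherits(assignment, "tbp_assignment"))
  deltas <- list(
    ax_distances = assignment$ax_distances - reference$ax_length,
    eq_distances = assignment$eq_distances - reference$eq_length,
    axial_angle  = assignment$axial_angle - reference$ax_angle,
    eq_angles    = assignment$eq_angles - reference$eq_angle,
    ax_eq_angles = assignment$ax_eq_angles - reference$ax_eq_angle)
  angle_d <- c(deltas$axial_angle, deltas$eq_angles, deltas$ax_eq_angles)
  length_d <- c(deltas$ax_distances, deltas$eq_distances)
  structure(list(deltas = deltas,
                 rms_angles = sqrt(mean(angle_d^2)),
                 rms_lengths = sqrt(mean(length_d^2)),
                 reference = reference), class = "tbp_deviation")
}

#' @export
print.tbp_deviation <- function(x, ...) {
  cat(sprintf("<tbp_deviation: RMS %.2f deg over angles, %.3f A over lengths>\n",
              x$rms_angles, x$rms_lengths))
  invisible(x)
}

#' TBP assignment for a phosphorus atom within a structure
#'
#' Convenience wrapper: ligands are the five atoms bonded to the
#' phosphorus (per \code{\link{perceive_bonds}} with a tolerance wide
#' enough to capture the elongated transition-state bonds).
#'
#' @param structure a \code{pdb_structure}.
#' @param p_descriptor phosphorus atom descriptor.
#' @param tolerance bond-perception tolerance (Angstrom); the default is
#'   wider than for ground-state bonds because transition-state axial
#'   bonds are stretched.
#' @param model model number.
#' @return a \code{tbp_assignment}.
#' @export
assign_tbp_site <- function(structure, p_descriptor, tolerance = 0.6,
                            model = 1) {
  m <- structure$models[[model]]
  d <- parse_atom_descriptor(p_descriptor)
  p <- which(m$chain == d$chain & m$resseq == d$resseq & m$name == d$name)[1]
  if (is.na(p)) stop("phosphorus not found: ", p_descriptor)
  bonds <- perceive_bonds(structure, tolerance = tolerance, model = model)
  lig <- bonded_to(bonds, p)
  if (length(lig) != 5)
    stop("phosphorus has ", length(lig), " bonded ligands, need 5")
  pos <- as.matrix(m[lig, c("x", "y", "z")])
  rownames(pos) <- m$name[lig]
  assign_tbp(as.numeric(m[p, c("x", "y", "z")]), pos)
}
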