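#' Chirality descriptor at a tetrahedral phosphorus
#'
#' The handedness of a substituted tetrahedral centre is captured by the
#' signed volume of the parallelepiped spanned by the vectors from the
#' phosphorus to substituents 2, 3 and 4 of a fixed, caller-applied
#' ordering; for the alpha-phosphate the convention is bridging-to-
#' nucleoside first (O5'), then the non-bridging oxygens by name (O1A,
#' O2A), then the leaving/incoming atom last. Backside attack with
#' departure of the leaving group (Walden inversion) flips the sign.
#'
#' @param p phosphorus position (length-3).
#' @param substituents 4 x 3 matrix of substituent positions in the fixed
#'   order.
#' @param planarity_threshold absolute signed volume (Angstrom^3) below
#'   which the centre is flagged planar and the sign treated as 0.
#' @return object of class \code{chirality_descriptor} with
#'   \code{signed_volume}, \code{sign} and \code{planarity_flag}.
#' @export
chirality_descriptor <- function(p, substituents, planarity_threshold = 0.1) {
  substituents <- as.matrix(substituents)
  if (nrow(substituents) != 4 || ncol(substituents) != 3)
    stop("exactly 4 substituent positions are required")
  v2 <- substituents[2, ] - p
  v3 <- substituents[3, ] - p
  v4 <- substituents[4, ] - p
  vol <- sum(v2 * pracma::cross(v3, v4))
  planar <- abs(vol) < planarity_threshold
  structure(list(signed_volume = vol,
                 sign = if (planar) 0L else as.integer(sign(vol)),
                 planarity_flag = planar), class = "chirality_descriptor")
}

#' @export
print.chirality_descriptor <- function(x, ...) {
  cat(sprintf("<chirality: signed volume %.3f A^3, sign %+d%s>\n",
              x$signed_volume, x$sign,
              if (x$planarity_flag) ", planar" else ""))
  invisible(x)
}

.mapped_positions <- function(structure, descriptors, model = 1) {
  t(vapply(descriptors, function(d) atom_xyz(structure, d, model), numeric(3)))
}

#' Detect inversion of configuration at a phosphorus between two snapshots
#'
#' The substituent mapping pairs the four substituents across the two
#' structures; when the leaving atom has been replaced by the incoming
#' nucleophile oxygen (substitution with inversion), the mapping names that
#' replacement explicitly, e.g. \code{"B/201/N3A" = "B/201/OW"}. Inversion
#' is called iff the two chirality signs are opposite; a planar descriptor
#' on either side leaves the call undefined (\code{NA}).
#'
#' @param pre,post \code{pdb_structure} snapshots.
#' @param p_descriptor atom descriptor of the phosphorus (same in both, or
#'   length-2 vector \code{c(pre, post)}).
#' @param mapping named character vector of 4 substituent descriptors:
#'   names address \code{pre}, values address \code{post}, in the fixed
#'   chirality order.
#' @param planarity_threshold passed to \code{\link{chirality_descriptor}}.
#' @return object of class \code{inversion_call} with the two descriptors
#'   and \code{inverted} (logical, \code{NA} when degenerate).
#' @export
detect_inversion <- function(pre, post, p_descriptor, mapping,
                             planarity_threshold = 0.1) {
  if (length(mapping) != 4 || is.null(names(mapping)))
    stop("mapping must be a named character vector of 4 substituents")
  pd <- if (length(p_descriptor) == 2) p_descriptor else rep(p_descriptor, 2)
  pre_desc <- chirality_descriptor(
    atom_xyz(pre, pd[1]), .mapped_positions(pre, names(mapping)),
    planarity_threshold)
  post_desc <- chirality_descriptor(
    atom_xyz(post, pd[2]), .mapped_positions(post, unname(mapping)),
    planarity_threshold)
  inverted <- if (pre_desc$sign == 0 || post_desc$sign == 0) NA
  else pre_desc$sign * post_desc$sign == -1
  structure(list(pre = pre_desc, post = post_desc, inverted = inverted,
                 substituent_mapping = mapping), class = "inversion_call")
}

#' @export
print.inversion_call <- function(x, ...) {
  cat(sprintf("<inversion call: %s (signs %+d -> %+d)>\n",
              if (is.na(x$inverted)) "undefined (planar)"
              else if (x$inverted) "INVERTED" else "retained",
              x$pre$sign, x$post$sign))
  invisible(x)
}

# Azimuth of an atom about the axis a1 -> a2, measured as the dihedral
# ref-a1-a2-atom. Dihedrals are invariant to rigid motion, so each
# structure is measured in its own frame and the axis may itself shift
# between conformers (as the alpha-phosphate does on product relaxation).
.azimuth <- function(structure, ref, a1, a2, atom, model = 1) {
  dihedral_xyz(atom_xyz(structure, ref, model), atom_xyz(structure, a1, model),
               atom_xyz(structure, a2, model), atom_xyz(structure, atom, model))
}

.pick_azimuth_reference <- function(structure, a1, a2, model = 1) {
  bonds <- perceive_bonds(structure, model = model)
  m <- structure$models[[model]]
  d1 <- parse_atom_descriptor(a1); d2 <- parse_atom_descriptor(a2)
  i1 <- which(m$chain == d1$chain & m$resseq == d1$resseq & m$name == d1$name)[1]
  i2 <- which(m$chain == d2$chain & m$resseq == d2$resseq & m$name == d2$name)[1]
  cand <- setdiff(bonded_to(bonds, i1), i2)
  if (length(cand) == 0) stop("no reference atom bonded to axis atom ", a1)
  i <- cand[which.max(m$element[cand] == "C")]  # prefer a carbon anchor
  sprintf("%s/%d/%s", m$chain[i], m$resseq[i], m$name[i])
}

#' Rotation of an atom set about a bond axis between two snapshots
#'
#' Measures how far \code{rotating_set} has turned about the
#' \code{axis[1]}-\code{axis[2]} bond from \code{pre} to \code{post}, as
#' the least-squares common shift of the atoms' azimuths (dihedral angles
#' \code{reference-axis1-axis2-atom}). Because dihedrals are invariant to
#' rigid motion, the measurement needs no prior superposition and remains
#' well defined when the axis itself translates between conformers, as the
#' alpha-phosphate does during product relaxation.
#'
#' @param pre,post \code{pdb_structure} snapshots.
#' @param axis length-2 character, descriptors of the axis atoms (the atom
#'   nearer the fixed part first, e.g. O5' then the phosphorus).
#' @param rotating_set character vector of atom descriptors off the axis.
#' @param reference optional descriptor of the azimuth reference atom
#'   bonded to \code{axis[1]}; auto-detected from bonding when NULL.
#' @param model model number.
#' @return rotation angle in degrees, in [0, 180].
#' @export
axis_rotation <- function(pre, post, axis, rotating_set, reference = NULL,
                          model = 1) {
  stopifnot(length(axis) == 2, length(rotating_set) >= 1)
  if (is.null(reference))
    reference <- .pick_azimuth_reference(pre, axis[1], axis[2], model)
  # reject rotating atoms lying on the axis (azimuth undefined)
  for (s in list(pre, post)) {
    a1 <- atom_xyz(s, axis[1], model); a2 <- atom_xyz(s, axis[2], model)
    u <- (a2 - a1) / .vnorm(a2 - a1)
    for (at in rotating_set) {
      v <- atom_xyz(s, at, model) - a2
      perp <- v - sum(v * u) * u
      if (.vnorm(perp) < 1e-6) stop("rotating atom lies on the axis: ", at)
    }
  }
  delta <- vapply(rotating_set, function(at) {
    d <- .azimuth(post, reference, axis[1], axis[2], at, model) -
      .azimuth(pre, reference, axis[1], axis[2], at, model)
    ((d + 180) %% 360) - 180
  }, numeric(1))
  # least-squares common rotation on the circle: circular mean of shifts
  rad <- delta * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  abs(ang)
}

#' Displacement of one atom between two snapshots
#'
#' The post-snapshot is brought into the pre-snapshot frame by the given
#' superposition (\code{"mainchain"} pairs shared protein main-chain
#' N/CA/C/O atoms; \code{list(method = "atoms", atoms = ...)} superposes on
#' explicit descriptors; \code{"none"} compares as-is).
#'
#' @param pre,post \code{pdb_structure} snapshots.
#' @param atom atom descriptor present in both.
#' @param frame superposition frame specification.
#' @param model model number.
#' @return displacement in Angstrom.
#' @export
atom_displacement <- function(pre, post, atom, frame = "mainchain", model = 1) {
  tr <- .resolve_frame(pre, post, frame, model)
  dist_xyz(atom_xyz(pre, atom, model),
           apply_transform(atom_xyz(post, atom, model), tr))
}

.sidechain_terminal_dihedral <- list(
  ASP = c("CA", "CB", "CG", "OD1"), ASN = c("CA", "CB", "CG", "OD1"),
  GLU = c("CB", "CG", "CD", "OE1"), GLN = c("CB", "CG", "CD", "OE1"),
  SER = c("N", "CA", "CB", "OG"),   THR = c("N", "CA", "CB", "OG1"),
  VAL = c("N", "CA", "CB", "CG1"),  LEU = c("CA", "CB", "CG", "CD1"),
  ILE = c("CA", "CB", "CG1", "CD1"), ARG = c("CG", "CD", "NE", "CZ"),
  LYS = c("CG", "CD", "CE", "NZ"),  PHE = c("CA", "CB", "CG", "CD1"),
  TYR = c("CA", "CB", "CG", "CD1"), HIS = c("CA", "CB", "CG", "ND1"),
  TRP = c("CA", "CB", "CG", "CD1"), MET = c("CB", "CG", "SD", "CE"),
  CYS = c("N", "CA", "CB", "SG"))

.mainchain_names <- c("N", "CA", "C", "O", "OXT")

#' Side-chain motion of one residue between two snapshots
#'
#' Rotation is the change in the side chain's terminal chi dihedral (for
#' aspartate: CA-CB-CG-OD1), wrapped to [0, 180]; displacement is the
#' maximum over side-chain atoms after frame superposition.
#'
#' @param pre,post \code{pdb_structure} snapshots.
#' @param residue residue descriptor \code{"chain/resseq"}.
#' @param frame superposition frame specification.
#' @param model model number.
#' @return list with \code{rotation} (degrees), \code{max_displacement}
#'   (Angstrom) and the per-atom \code{displacements}.
#' @export
residue_motion <- function(pre, post, residue, frame = "mainchain", model = 1) {
  parts <- strsplit(residue, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("residue descriptor must be chain/resseq")
  ch <- parts[1]; rs <- as.integer(parts[2])
  mpre <- pre$models[[model]]
  sel <- which(mpre$chain == ch & mpre$resseq == rs)
  if (length(sel) == 0) stop("residue not found: ", residue)
  resname <- mpre$resname[sel[1]]
  dihe <- .sidechain_terminal_dihedral[[resname]]
  if (is.null(dihe)) stop("no terminal dihedral defined for ", resname)
  desc <- function(nm) sprintf("%s/%d/%s", ch, rs, nm)
  get_dihe <- function(s) {
    pos <- lapply(dihe, function(nm) atom_xyz(s, desc(nm), model))
    do.call(dihedral_xyz, pos)
  }
  dchi <- get_dihe(post) - get_dihe(pre)
  rotation <- abs(((dchi + 180) %% 360) - 180)
  tr <- .resolve_frame(pre, post, frame, model)
  side_atoms <- mpre$name[sel][!(mpre$name[sel] %in% .mainchain_names)]
  disp <- vapply(side_atoms, function(nm) {
    dist_xyz(atom_xyz(pre, desc(nm), model),
             apply_transform(atom_xyz(post, desc(nm), model), tr))
  }, numeric(1))
  list(rotation = rotation, max_displacement = max(disp),
       displacements = disp)
}

#' Tabulated per-atom displacements between two snapshots
#'
#' @param pre,post \code{pdb_structure} snapshots.
#' @param atoms character vector of atom descriptors.
#' @param frame superposition frame specification.
#' @param model model number.
#' @return data frame with columns \code{atom} and \code{displacement}.
#' @export
motion_report <- function(pre, post, atoms, frame = "mainchain", model = 1) {
  tr <- .resolve_frame(pre, post, frame, model)
  data.frame(
    atom = atoms,
    displacement = vapply(atoms, function(a)
      dist_xyz(atom_xyz(pre, a, model),
               apply_transform(atom_xyz(post, a, model), tr)), numeric(1)),
    row.names = NULL)
}
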