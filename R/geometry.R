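#' Elementary geometric measurements
#'
#' Distances in Angstrom, angles in degrees. Dihedrals follow the IUPAC
#' sign convention and lie in (-180, 180].
#'
#' @param a,b,c,d numeric length-3 coordinate vectors.
#' @return scalar measurement.
#' @name geometry
NULL

.vnorm <- function(v) sqrt(sum(v * v))

#' @rdname geometry
#' @export
dist_xyz <- function(a, b) {
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  .vnorm(b - a)
}

#' @rdname geometry
#' @export
angle_xyz <- function(a, b, c) {
  u <- a - b; v <- c - b
  nu <- .vnorm(u); nv <- .vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) stop("degenerate angle: coincident points")
  cosang <- sum(u * v) / (nu * nv)
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

#' @rdname geometry
#' @export
dihedral_xyz <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (.vnorm(n1) < 1e-12 || .vnorm(n2) < 1e-12)
    stop("degenerate dihedral: collinear points")
  m1 <- pracma::cross(n1, b2 / .vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{mobile} onto \code{reference} over the paired atoms. Reflections
#' are excluded: the rotation determinant is +1 by construction, so
#' mirror-related point sets retain a positive residual.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param pairing optional two-column integer matrix (mobile row,
#'   reference row); defaults to row-by-row pairing.
#' @return object of class \code{transform}: list with \code{rotation}
#'   (3 x 3, det +1), \code{translation} (length 3) and \code{rmsd}
#'   (Angstrom) such that \code{y = x \%*\% t(rotation) + translation}.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(pairing)) {
    if (nrow(mobile) != nrow(reference))
      stop("unequal atom counts and no pairing supplied")
    pairing <- cbind(seq_len(nrow(mobile)), seq_len(nrow(reference)))
  }
  X <- mobile[pairing[, 1], , drop = FALSE]
  Y <- reference[pairing[, 2], , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("superposition needs at least 3 paired atoms")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  if (min(sv$d) < 1e-10 && sv$d[2] < 1e-10)
    stop("collinear point set: superposition is degenerate")
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- as.numeric(cy - R %*% cx)
  moved <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Yc)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "transform")
}

#' @export
print.transform <- function(x, ...) {
  cat(sprintf("<transform: rmsd %.4f A>\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix or length-3 vector.
#' @param transform a \code{transform} from \code{\link{superpose}}.
#' @return transformed coordinates, same shape as input.
#' @export
apply_transform <- function(coords, transform) {
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, nrow = 1) else as.matrix(coords)
  out <- sweep(m %*% t(transform$rotation), 2, -transform$translation)
  if (vec) as.numeric(out) else out
}

# Superposition "frame" used by the snapshot-comparison metrics.
#   method "mainchain": pair N/CA/C/O of residues present in both models
#   method "atoms":     pair the explicitly listed descriptors
#   method "none":      identity (structures already in a common frame)
.resolve_frame <- function(pre, post, frame = list(method = "mainchain"),
                           model = 1) {
  if (is.null(frame)) frame <- list(method = "mainchain")
  if (is.character(frame)) frame <- list(method = frame)
  if (frame$method == "none")
    return(structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmsd = 0), class = "transform"))
  if (frame$method == "atoms") {
    X <- t(vapply(frame$atoms, function(d) atom_xyz(post, d, model), numeric(3)))
    Y <- t(vapply(frame$atoms, function(d) atom_xyz(pre, d, model), numeric(3)))
    return(superpose(X, Y))
  }
  if (frame$method != "mainchain") stop("unknown frame method: ", frame$method)
  mpre <- pre$models[[model]]; mpost <- post$models[[model]]
  bb <- c("N", "CA", "C", "O")
  kpre <- paste(mpre$chain, mpre$resseq, mpre$icode, mpre$name)
  kpost <- paste(mpost$chain, mpost$resseq, mpost$icode, mpost$name)
  sel_pre <- which(mpre$name %in% bb & mpre$resname %in% .std_residues)
  shared <- intersect(kpre[sel_pre], kpost)
  if (length(shared) < 3) stop("fewer than 3 shared main-chain atoms for frame")
  ip <- match(shared, kpre); iq <- match(shared, kpost)
  superpose(as.matrix(mpost[iq, c("x", "y", "z")]),
            as.matrix(mpre[ip, c("x", "y", "z")]))
}
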