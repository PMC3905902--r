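#' Near-attack-site search specification
#'
#' Defaults capture a water oxygen approaching a phosphorus in-line with the
#' scissile bond: attack distances up to 3.6 Angstrom (the upper end of the
#' observed pre-catalytic P-O range) and a nucleophile-P-leaving angle of at
#' least 150 degrees. \code{required_coordination} lists protein contacts
#' the nucleophile must make, e.g. the Val93 main-chain carbonyl and the
#' conserved Asp95 carboxylate that orient the catalytic water in dUTPase.
#'
#' @param max_attack_distance maximum nucleophile-P distance (Angstrom).
#' @param min_inline_angle minimum nucleophile-P-leaving angle (degrees).
#' @param required_coordination data frame with columns \code{resname},
#'   \code{name} (atom name, or a vector of alternatives separated by
#'   \code{|}) and \code{max_dist} (Angstrom), or \code{NULL} for none.
#' @return object of class \code{site_spec}.
#' @export
site_spec <- function(max_attack_distance = 3.6, min_inline_angle = 150,
                      required_coordination = NULL) {
  stopifnot(max_attack_distance > 0,
            min_inline_angle >= 0, min_inline_angle <= 180)
  structure(list(max_attack_distance = max_attack_distance,
                 min_inline_angle = min_inline_angle,
                 required_coordination = required_coordination),
            class = "site_spec")
}

#' Coordination contacts of the dUTPase catalytic water
#'
#' Convenience constructor for the two contacts that define the catalytic
#' water binding site: the Val93 main-chain carbonyl oxygen and either
#' carboxylate oxygen of Asp95.
#'
#' @param max_dist hydrogen-bond distance ceiling (Angstrom).
#' @export
dutpase_water_coordination <- function(max_dist = 3.5) {
  data.frame(resname = c("VAL", "ASP"),
             name = c("O", "OD1|OD2"),
             max_dist = max_dist,
             stringsAsFactors = FALSE)
}

.water_resnames <- c("HOH", "WAT")

.contact_matches <- function(model, nuc_xyz, contact) {
  names_ok <- strsplit(contact$name, "|", fixed = TRUE)[[1]]
  cand <- which(model$resname == contact$resname & model$name %in% names_ok)
  if (length(cand) == 0) return(NULL)
  d <- vapply(cand, function(i)
    dist_xyz(nuc_xyz, as.numeric(model[i, c("x", "y", "z")])), numeric(1))
  ok <- which(d <= contact$max_dist)
  if (length(ok) == 0) return(NULL)
  best <- ok[which.min(d[ok])]
  list(index = cand[best], distance = d[best])
}

#' Detect near-attack conformations at phosphorus centres
#'
#' For every phosphorus atom, candidate nucleophiles are non-bonded oxygen
#' atoms within \code{spec$max_attack_distance}. The leaving atom is the
#' bonded bridging O or N that maximizes the nucleophile-P-leaving angle. A
#' site is reported iff that in-line angle reaches
#' \code{spec$min_inline_angle} and every required coordination contact of
#' the nucleophile is satisfied. Bonded oxygens of the phosphorus are split
#' into bridging (bonded onward to another heavy atom, e.g. O5' to the
#' sugar) and non-bridging (terminal, e.g. O1A/O2A).
#'
#' @param structure a \code{\link{pdb_structure}}.
#' @param bonds a \code{bond_graph} from \code{\link{perceive_bonds}};
#'   computed on demand when \code{NULL}.
#' @param spec a \code{\link{site_spec}}.
#' @param model model number.
#' @return list of \code{attack_site} objects (possibly empty), each with
#'   atom indices (\code{phosphorus}, \code{nucleophile}, \code{leaving},
#'   \code{bridging}, \code{nonbridging}), \code{d_attack},
#'   \code{inline_angle} and a \code{contacts} data frame.
#' @export
find_attack_sites <- function(structure, bonds = NULL, spec = site_spec(),
                              model = 1) {
  m <- structure$models[[model]]
  if (is.null(bonds)) bonds <- perceive_bonds(structure, model = model)
  p_idx <- which(m$element == "P")
  if (length(p_idx) == 0) stop("structure contains no phosphorus atom")
  sites <- list()
  for (p in p_idx) {
    pxyz <- as.numeric(m[p, c("x", "y", "z")])
    nb <- bonded_to(bonds, p)
    leav_cand <- nb[m$element[nb] %in% c("O", "N")]
    if (length(leav_cand) == 0) next
    ox <- which(m$element == "O")
    ox <- setdiff(ox, nb)
    if (length(ox) == 0) next
    d <- vapply(ox, function(i)
      dist_xyz(pxyz, as.numeric(m[i, c("x", "y", "z")])), numeric(1))
    near <- ox[d > 0 & d <= spec$max_attack_distance]
    dn <- d[d > 0 & d <= spec$max_attack_distance]
    for (k in seq_along(near)) {
      nuc <- near[k]
      nxyz <- as.numeric(m[nuc, c("x", "y", "z")])
      angs <- vapply(leav_cand, function(l)
        angle_xyz(nxyz, pxyz, as.numeric(m[l, c("x", "y", "z")])), numeric(1))
      leaving <- leav_cand[which.max(angs)]
      inline <- max(angs)
      if (inline < spec$min_inline_angle) next
      contacts <- data.frame(index = integer(0), distance = numeric(0))
      ok <- TRUE
      rc <- spec$required_coordination
      if (!is.null(rc)) {
        for (r in seq_len(nrow(rc))) {
          hit <- .contact_matches(m, nxyz, rc[r, ])
          if (is.null(hit)) { ok <- FALSE; break }
          contacts <- rbind(contacts,
                            data.frame(index = hit$index, distance = hit$distance))
        }
      }
      if (!ok) next
      others <- setdiff(nb, leaving)
      others <- others[m$element[others] %in% c("O", "N")]
      bridging <- others[vapply(others, function(i)
        length(setdiff(bonded_to(bonds, i), p)) > 0, logical(1))]
      nonbridging <- setdiff(others, bridging)
      sites[[length(sites) + 1]] <- structure(list(
        phosphorus = p, nucleophile = nuc, leaving = leaving,
        bridging = bridging, nonbridging = nonbridging,
        d_attack = dn[k], inline_angle = inline,
        contacts = contacts, model = model), class = "attack_site")
    }
  }
  sites
}

#' @export
print.attack_site <- function(x, ...) {
  cat(sprintf(
    "<attack_site: P #%d, nucleophile #%d at %.2f A, in-line angle %.1f deg, %d contact(s)>\n",
    x$phosphorus, x$nucleophile, x$d_attack, x$inline_angle, nrow(x$contacts)))
  invisible(x)
}

#' Reaction coordinates from bond-breaking/forming distances
#'
#' \code{q1 = d_break - d_form} combines the breaking (P-leaving) and
#' forming (P-nucleophile) bond distances; \code{q2} additionally couples
#' the proton transfer from the catalytic water to the Asp95 carboxylate:
#' \code{q2 = q1 + 0.5 * (d_hw_ow - d_hw_oasp)}. Hydrogen distances must be
#' given together or not at all (crystal structures carry no hydrogens; Q2
#' therefore only applies to modelled or synthetic input).
#'
#' @param d_break distance P-leaving atom (Angstrom).
#' @param d_form distance P-nucleophile oxygen (Angstrom).
#' @param d_hw_ow optional distance from the transferring water proton to
#'   the water oxygen.
#' @param d_hw_oasp optional distance from that proton to the acceptor
#'   carboxylate oxygen.
#' @return object of class \code{reaction_coordinate} with fields
#'   \code{q1} and (when hydrogens are supplied) \code{q2}.
#' @export
reaction_coordinate <- function(d_break, d_form,
                                d_hw_ow = NULL, d_hw_oasp = NULL) {
  stopifnot(d_break > 0, d_form > 0)
  if (xor(is.null(d_hw_ow), is.null(d_hw_oasp)))
    stop("both hydrogen distances are required for Q2, or neither")
  q1 <- d_break - d_form
  out <- list(d_break = d_break, d_form = d_form, q1 = q1,
              d_hw_ow = d_hw_ow, d_hw_oasp = d_hw_oasp, q2 = NULL)
  if (!is.null(d_hw_ow)) {
    stopifnot(d_hw_ow > 0, d_hw_oasp > 0)
    out$q2 <- q1 + 0.5 * (d_hw_ow - d_hw_oasp)
  }
  structure(out, class = "reaction_coordinate")
}

#' @export
print.reaction_coordinate <- function(x, ...) {
  cat(sprintf("<reaction coordinate: q1 = %.3f A%s>\n", x$q1,
              if (!is.null(x$q2)) sprintf(", q2 = %.3f A", x$q2) else ""))
  invisible(x)
}
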