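#' Macromolecular structure container
#'
#' A \code{pdb_structure} is a list with an \code{id} and a list of
#' \code{models}; each model is a data frame with one row per atom and
#' columns \code{record} (ATOM/HETATM), \code{serial}, \code{name},
#' \code{alt_loc}, \code{resname}, \code{chain}, \code{resseq},
#' \code{icode}, \code{x}, \code{y}, \code{z}, \code{occ}, \code{b},
#' \code{element}. Coordinates are orthogonal Angstrom as deposited; no
#' symmetry expansion is performed.
#'
#' @param models list of atom data frames (at least one).
#' @param id structure identifier string.
#' @return object of class \code{pdb_structure}.
#' @export
pdb_structure <- function(models, id = "") {
  if (is.data.frame(models)) models <- list(models)
  if (length(models) < 1) stop("a structure needs at least one model")
  needed <- c("record", "serial", "name", "alt_loc", "resname", "chain",
              "resseq", "icode", "x", "y", "z", "occ", "b", "element")
  models <- lapply(models, function(m) {
    missing_cols <- setdiff(needed, names(m))
    for (col in missing_cols) {
      m[[col]] <- switch(col,
        record = "ATOM", serial = seq_len(nrow(m)), alt_loc = "",
        icode = "", occ = 1, b = 0,
        stop("model lacks required column: ", col))
    }
    if (nrow(m) > 0) {
      if (!all(is.finite(as.matrix(m[, c("x", "y", "z")]))))
        stop("non-finite atom coordinates")
      m$occ[is.na(m$occ)] <- 1
      if (any(m$occ < 0 | m$occ > 1))
        stop("occupancies must lie in [0, 1]")
      key <- paste(m$chain, m$resseq, m$icode, m$name, m$alt_loc, sep = "|")
      if (anyDuplicated(key))
        warning("duplicate atom keys (chain/resseq/icode/name/altloc) in model")
    }
    m[, needed]
  })
  structure(list(id = id, models = models), class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure '%s': %d model(s), %d atoms in model 1>\n",
              x$id, length(x$models), nrow(x$models[[1]])))
  invisible(x)
}

#' Number of models in a structure
#' @param structure a \code{pdb_structure}.
#' @export
n_models <- function(structure) length(structure$models)

.std_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

.guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CL", "BR", "MG", "NA", "ZN", "FE", "MN", "SE"),
                two, substr(gsub("^[0-9']+", "", nm), 1, 1))
  out
}

# Pre-scan coordinate fields so that malformed records are reported with
# their line numbers (the backend parser aborts without this context).
.validate_pdb_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  coord <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in coord) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[i], 31, 38), substr(lines[i], 39, 46),
      substr(lines[i], 47, 54))))
    if (anyNA(xyz) || !all(is.finite(xyz)))
      stop("malformed coordinate field at line ", i, " of ", path)
  }
  invisible(length(coord))
}

.collapse_altloc <- function(m, policy) {
  if (policy == "all" || nrow(m) == 0) return(m)
  key <- paste(m$chain, m$resseq, m$icode, m$resname, m$name, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(m)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- m[idx, ]
    if (policy == "first") return(idx[order(sub$alt_loc)][1])
    # highest occupancy; ties resolved towards altloc "A" (lowest letter)
    idx[order(-sub$occ, sub$alt_loc)][1]
  }), use.names = FALSE)
  m <- m[sort(keep), ]
  rownames(m) <- NULL
  m
}

#' Read a PDB structure file
#'
#' Parsing is delegated to \pkg{bio3d}; all ATOM/HETATM records and model
#' boundaries are honoured. Alternate locations are collapsed according to
#' \code{altloc_policy}: \code{"highest"} keeps the highest-occupancy
#' conformer (ties towards altloc \code{"A"}), \code{"first"} keeps the
#' first altloc alphabetically, \code{"all"} keeps every conformer.
#'
#' @param path path to a PDB-format file.
#' @param altloc_policy one of \code{"highest"}, \code{"first"}, \code{"all"}.
#' @param id structure id; defaults to the file base name.
#' @return a \code{\link{pdb_structure}}.
#' @export
read_structure <- function(path, altloc_policy = c("highest", "first", "all"),
                           id = NULL) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_text(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  base <- data.frame(
    record  = at$type,
    serial  = at$eleno,
    name    = trimws(at$elety),
    alt_loc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resname = trimws(at$resid),
    chain   = ifelse(is.na(at$chain), "", at$chain),
    resseq  = at$resno,
    icode   = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    b   = ifelse(is.na(at$b), 0, at$b),
    element = toupper(ifelse(is.na(at$elesy) | trimws(at$elesy) == "",
                             .guess_element(at$elety), trimws(at$elesy))),
    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  models <- lapply(seq_len(nrow(xyz)), function(k) {
    m <- base
    co <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    m$x <- co[, 1]; m$y <- co[, 2]; m$z <- co[, 3]
    .collapse_altloc(m, altloc_policy)
  })
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  pdb_structure(models, id = id)
}

.format_atom_name <- function(name, element) {
  # short names start in column 14 unless the element symbol is two letters
  if (nchar(name) >= 4) return(substr(sprintf("%-4s", name), 1, 4))
  if (nchar(element) == 2) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

#' Write a structure as PDB
#'
#' Multi-model structures are emitted as ordered MODEL/ENDMDL blocks.
#'
#' @param structure a \code{\link{pdb_structure}}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "pdb_structure"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(sprintf("REMARK   3 %s", structure$id), con)
  multi <- length(structure$models) > 1
  for (k in seq_along(structure$models)) {
    m <- structure$models[[k]]
    if (multi) writeLines(sprintf("MODEL %8d", k), con)
    if (nrow(m) > 0) {
      lines <- vapply(seq_len(nrow(m)), function(i) {
        sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                m$record[i], m$serial[i] %% 100000L,
                .format_atom_name(m$name[i], m$element[i]),
                substr(paste0(m$alt_loc[i], " "), 1, 1),
                m$resname[i], substr(paste0(m$chain[i], " "), 1, 1),
                m$resseq[i] %% 10000L,
                substr(paste0(m$icode[i], " "), 1, 1),
                m$x[i], m$y[i], m$z[i], m$occ[i], m$b[i],
                sprintf("%2s", m$element[i]))
      }, character(1))
      writeLines(lines, con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atom indices in a model
#'
#' All filter arguments are optional; \code{NULL} means no constraint.
#'
#' @param structure a \code{pdb_structure}.
#' @param chain,resseq,name,resname,element filters (vectors allowed).
#' @param model model number, default 1.
#' @return integer row indices into the model's atom table.
#' @export
atom_select <- function(structure, chain = NULL, resseq = NULL, name = NULL,
                        resname = NULL, element = NULL, model = 1) {
  m <- structure$models[[model]]
  keep <- rep(TRUE, nrow(m))
  if (!is.null(chain))   keep <- keep & m$chain %in% chain
  if (!is.null(resseq))  keep <- keep & m$resseq %in% resseq
  if (!is.null(name))    keep <- keep & m$name %in% name
  if (!is.null(resname)) keep <- keep & m$resname %in% resname
  if (!is.null(element)) keep <- keep & m$element %in% .norm_element(element)
  which(keep)
}

#' Parse an atom descriptor string
#'
#' Descriptors are \code{"chain/resseq/name"}, e.g. \code{"A/95/OD2"}; an
#' empty chain field matches chain-less atoms.
#'
#' @param descriptor descriptor string.
#' @return list with \code{chain}, \code{resseq}, \code{name}.
#' @export
parse_atom_descriptor <- function(descriptor) {
  parts <- strsplit(descriptor, "/", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("atom descriptor must be chain/resseq/name: ",
                               descriptor)
  list(chain = parts[1], resseq = as.integer(parts[2]), name = parts[3])
}

#' Coordinates of one atom addressed by descriptor or index
#'
#' @param structure a \code{pdb_structure}.
#' @param atom descriptor string (\code{"chain/resseq/name"}) or integer
#'   row index.
#' @param model model number.
#' @return numeric length-3 coordinate vector (Angstrom).
#' @export
atom_xyz <- function(structure, atom, model = 1) {
  m <- structure$models[[model]]
  if (is.character(atom)) {
    d <- parse_atom_descriptor(atom)
    idx <- which(m$chain == d$chain & m$resseq == d$resseq & m$name == d$name)
    if (length(idx) == 0) stop("atom not found: ", atom)
    if (length(idx) > 1) idx <- idx[1]
  } else idx <- atom
  as.numeric(m[idx, c("x", "y", "z")])
}

#' Coordinate matrix of a model
#' @inheritParams atom_xyz
#' @return n x 3 numeric matrix.
#' @export
coord_matrix <- function(structure, model = 1) {
  as.matrix(structure$models[[model]][, c("x", "y", "z")])
}

#' Perceive covalent bonds geometrically
#'
#' A pair is bonded iff its distance does not exceed the sum of covalent
#' radii plus \code{tolerance}. Coincident distinct atoms (d below 0.01
#' Angstrom) are flagged as clashes, never bonded. CONECT records are not
#' consulted.
#'
#' @param structure a \code{pdb_structure}.
#' @param tolerance slack added to the covalent-radius sum (Angstrom).
#' @param model model number.
#' @param radii radius table (see \code{\link{default_radii}}).
#' @return object of class \code{bond_graph}: list with \code{n_atoms},
#'   \code{bonds} (two-column index matrix, i < j) and \code{clashes}.
#' @export
perceive_bonds <- function(structure, tolerance = 0.4, model = 1,
                           radii = default_radii()) {
  m <- structure$models[[model]]
  n <- nrow(m)
  cov <- covalent_radius(m$element, table = radii)  # errors on unknowns
  out_bonds <- matrix(integer(0), ncol = 2)
  out_clash <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    d <- as.matrix(stats::dist(m[, c("x", "y", "z")]))
    thr <- outer(cov, cov, "+") + tolerance
    pair <- which(upper.tri(d) & d <= thr, arr.ind = TRUE)
    if (nrow(pair) > 0) {
      dd <- d[pair]
      clash <- dd < 0.01
      out_clash <- pair[clash, , drop = FALSE]
      out_bonds <- pair[!clash, , drop = FALSE]
    }
  }
  colnames(out_bonds) <- colnames(out_clash) <- c("i", "j")
  structure(list(n_atoms = n, bonds = out_bonds, clashes = out_clash),
            class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat(sprintf("<bond_graph: %d atoms, %d bonds, %d clashes>\n",
              x$n_atoms, nrow(x$bonds), nrow(x$clashes)))
  invisible(x)
}

#' Are two atoms bonded?
#' @param graph a \code{bond_graph}.
#' @param i,j atom row indices.
#' @export
is_bonded <- function(graph, i, j) {
  a <- pmin(i, j); b <- pmax(i, j)
  any(graph$bonds[, 1] == a & graph$bonds[, 2] == b)
}

#' Indices of atoms bonded to a given atom
#' @param graph a \code{bond_graph}.
#' @param i atom row index.
#' @export
bonded_to <- function(graph, i) {
  c(graph$bonds[graph$bonds[, 1] == i, 2],
    graph$bonds[graph$bonds[, 2] == i, 1])
}
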