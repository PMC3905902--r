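#' Linear morph trajectory across an ordered snapshot series
#'
#' Builds a multi-model "molecular movie": every snapshot is first
#' superposed onto the first one, then consecutive pairs are joined by
#' linear interpolation in Cartesian coordinates. Endpoint models
#' reproduce the superposed snapshots exactly and junction frames are
#' shared, so the trajectory holds
#' \code{(n_snapshots - 1) * frames_per_transition + 1} models.
#'
#' @param snapshots ordered list of \code{pdb_structure} objects (>= 2).
#'   The ordering along the reaction path is taken as given, not inferred.
#' @param frames_per_transition number of interpolation steps per
#'   consecutive pair (>= 1; 1 reproduces just the snapshots).
#' @param atom_mapping character vector of atom descriptors to animate;
#'   defaults to all atoms (by chain/resseq/icode/name key) present in
#'   every snapshot. Atoms absent from any snapshot are dropped with a
#'   warning.
#' @param frame \code{"shared"} (superpose on the mapped atoms),
#'   \code{"mainchain"} or \code{"none"}.
#' @param model model number taken from each snapshot.
#' @return a multi-model \code{pdb_structure}.
#' @export
morph <- function(snapshots, frames_per_transition = 10, atom_mapping = NULL,
                  frame = c("shared", "mainchain", "none"), model = 1) {
  frame <- match.arg(frame)
  if (length(snapshots) < 2) stop("morphing needs at least 2 snapshots")
  stopifnot(frames_per_transition >= 1)
  keys <- lapply(snapshots, function(s) {
    m <- s$models[[model]]
    paste(m$chain, m$resseq, m$icode, m$name, sep = "/")
  })
  shared <- Reduce(intersect, keys)
  if (!is.null(atom_mapping)) {
    missing <- setdiff(atom_mapping, shared)
    if (length(missing) > 0)
      stop("mapped atoms absent from some snapshot: ",
           paste(missing, collapse = ", "))
    shared <- atom_mapping
  } else {
    dropped <- setdiff(unique(unlist(keys)), shared)
    if (length(dropped) > 0)
      warning(length(dropped), " atom(s) absent from some snapshot dropped ",
              "from the trajectory")
  }
  if (length(shared) == 0) stop("no shared atoms to morph")
  first <- snapshots[[1]]$models[[model]]
  idx1 <- match(shared, keys[[1]])
  template <- first[idx1, ]
  rownames(template) <- NULL
  coords <- lapply(seq_along(snapshots), function(k) {
    m <- snapshots[[k]]$models[[model]]
    co <- as.matrix(m[match(shared, keys[[k]]), c("x", "y", "z")])
    if (k == 1 || frame == "none") return(co)
    ref <- as.matrix(template[, c("x", "y", "z")])
    tr <- if (frame == "shared") superpose(co, ref)
    else .resolve_frame(snapshots[[1]], snapshots[[k]], "mainchain", model)
    apply_transform(co, tr)
  })
  models <- list()
  for (k in seq_len(length(snapshots) - 1)) {
    ts <- seq(0, 1, length.out = frames_per_transition + 1)
    if (k > 1) ts <- ts[-1]  # junction frame shared with previous pair
    for (t in ts) {
      co <- (1 - t) * coords[[k]] + t * coords[[k + 1]]
      m <- template
      m$x <- co[, 1]; m$y <- co[, 2]; m$z <- co[, 3]
      models[[length(models) + 1]] <- m
    }
  }
  pdb_structure(models, id = paste0(snapshots[[1]]$id, "_morph"))
}
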