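#' Survey non-bonded P-O contact distances
#'
#' Counts, over a corpus of structures, every unordered phosphorus-oxygen
#' pair that is not covalently bonded (per \code{\link{perceive_bonds}})
#' and lies within \code{max_distance}. The histogram uses half-open bins
#' \code{[lo, hi)}; \code{band_fraction} is the fraction of surveyed pairs
#' whose distance falls in the half-open \code{band}. In large structure
#' corpora roughly 90 percent of non-bonded P-O pairs fall in the 3.3-4.5
#' Angstrom band; pairs well below the 3.32 Angstrom van der Waals sum mark
#' chemically engaged contacts.
#'
#' @param structures a \code{pdb_structure} or list of them.
#' @param max_distance survey cutoff (Angstrom).
#' @param bin_width histogram bin width (Angstrom).
#' @param band length-2 numeric, the reference band \code{c(lo, hi)}.
#' @param tolerance bond-perception tolerance passed on.
#' @return object of class \code{po_survey}: \code{bin_edges},
#'   \code{counts}, \code{n_pairs}, \code{band}, \code{band_fraction}
#'   (\code{NA} with \code{undefined = TRUE} for an empty survey) and the
#'   raw \code{distances}.
#' @export
survey_nonbonded_po <- function(structures, max_distance = 4.5,
                                bin_width = 0.1, band = c(3.3, 4.5),
                                tolerance = 0.4) {
  stopifnot(max_distance > 0, bin_width > 0, length(band) == 2,
            band[1] < band[2])
  if (inherits(structures, "pdb_structure")) structures <- list(structures)
  dists <- numeric(0)
  for (s in structures) {
    for (k in seq_along(s$models)) {
      m <- s$models[[k]]
      p_idx <- which(m$element == "P")
      o_idx <- which(m$element == "O")
      if (length(p_idx) == 0 || length(o_idx) == 0) next
      bonds <- perceive_bonds(s, tolerance = tolerance, model = k)
      for (p in p_idx) {
        nb <- bonded_to(bonds, p)
        ox <- setdiff(o_idx, nb)
        if (length(ox) == 0) next
        d <- sqrt((m$x[ox] - m$x[p])^2 + (m$y[ox] - m$y[p])^2 +
                    (m$z[ox] - m$z[p])^2)
        dists <- c(dists, d[d > 0 & d <= max_distance])
      }
    }
  }
  edges <- seq(0, max_distance + bin_width, by = bin_width)
  counts <- if (length(dists))
    vapply(seq_len(length(edges) - 1), function(i)
      sum(dists >= edges[i] & dists < edges[i + 1]), integer(1))
  else integer(length(edges) - 1)
  n_pairs <- length(dists)
  in_band <- sum(dists >= band[1] & dists < band[2])
  structure(list(
    bin_edges = edges, counts = counts, n_pairs = n_pairs, band = band,
    band_fraction = if (n_pairs > 0) in_band / n_pairs else NA_real_,
    undefined = n_pairs == 0, distances = dists), class = "po_survey")
}

#' @export
print.po_survey <- function(x, ...) {
  if (x$undefined) {
    cat("<po_survey: empty corpus, band fraction undefined>\n")
  } else {
    cat(sprintf(
      "<po_survey: %d non-bonded P-O pairs, %.1f%% in [%.2f, %.2f) A>\n",
      x$n_pairs, 100 * x$band_fraction, x$band[1], x$band[2]))
  }
  invisible(x)
}

#' Write a survey as TSV histogram plus JSON summary
#'
#' @param survey a \code{po_survey}.
#' @param tsv_path,json_path output paths (either may be \code{NULL}).
#' @return invisibly, the survey.
#' @export
write_survey <- function(survey, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    n <- length(survey$counts)
    utils::write.table(
      data.frame(bin_lo = survey$bin_edges[seq_len(n)],
                 bin_hi = survey$bin_edges[seq_len(n) + 1],
                 count = survey$counts),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_pairs = survey$n_pairs,
      band = survey$band,
      band_fraction = if (survey$undefined) NULL else survey$band_fraction,
      undefined = survey$undefined), json_path,
      auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(survey)
}

#' Plot the survey histogram
#'
#' @param x a \code{po_survey}.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @export
plot.po_survey <- function(x, ...) {
  n <- length(x$counts)
  mids <- (x$bin_edges[seq_len(n)] + x$bin_edges[seq_len(n) + 1]) / 2
  graphics::barplot(x$counts, names.arg = sprintf("%.1f", mids),
                    xlab = "P-O distance (A)", ylab = "pairs", ...)
  invisible(x)
}
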