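#' First-order 31P multiplet
#'
#' A multiplet with n scalar couplings expands to 2^n Lorentzian lines of
#' equal area at offsets of all sign combinations of J/2 from the centre
#' (doublet: centre +/- J/2; doublet of doublets: +/- (J1 +/- J2)/2). The
#' total area equals \code{intensity}.
#'
#' @param species species label.
#' @param center chemical shift (ppm).
#' @param j_couplings numeric vector of scalar couplings (Hz); empty for a
#'   singlet.
#' @param intensity relative total area (> 0).
#' @param linewidth full width at half maximum (Hz, > 0).
#' @return object of class \code{multiplet}.
#' @export
multiplet <- function(species, center, j_couplings = numeric(0),
                      intensity = 1, linewidth = 0.5) {
  stopifnot(intensity > 0, linewidth > 0, all(j_couplings > 0))
  structure(list(species = species, center = center,
                 j_couplings = as.numeric(j_couplings),
                 intensity = intensity, linewidth = linewidth),
            class = "multiplet")
}

#' @export
print.multiplet <- function(x, ...) {
  mult <- c("s", "d", "dd", "ddd")[min(length(x$j_couplings) + 1, 4)]
  cat(sprintf("<multiplet %s: %.2f ppm (%s%s), area %.3g>\n", x$species,
              x$center, mult,
              if (length(x$j_couplings))
                paste0(", J = ", paste(x$j_couplings, collapse = "/"), " Hz")
              else "", x$intensity))
  invisible(x)
}

# line positions (ppm) and areas of a first-order multiplet
.multiplet_lines <- function(m, field) {
  offsets_hz <- 0
  for (j in m$j_couplings) offsets_hz <- c(offsets_hz - j / 2, offsets_hz + j / 2)
  data.frame(ppm = m$center + offsets_hz / field,
             area = m$intensity / length(offsets_hz))
}

#' Reference multiplet sets from the dUTPase 31P study
#'
#' \code{imido_dutp_multiplets} returns the three substrate resonances of
#' alpha,beta-imido-dUTP (alpha-P -4.5 ppm d 16.0 Hz; beta-P -7.16 ppm dd
#' 16.0/10.8 Hz; gamma-P 0.8 ppm d 10.8 Hz); \code{product_multiplets}
#' returns the hydrolysis products at equal concentration (amino-
#' pyrophosphate doublets at 3.27 and 0.27 ppm, J = 6.5 Hz; the dUMP
#' singlet at 3.48 ppm).
#'
#' @param intensity common relative area per species.
#' @param linewidth line full width at half maximum (Hz).
#' @return list of \code{\link{multiplet}} objects.
#' @export
imido_dutp_multiplets <- function(intensity = 1, linewidth = 0.5) {
  list(multiplet("alpha-P", -4.5, 16.0, intensity, linewidth),
       multiplet("beta-P", -7.16, c(16.0, 10.8), intensity, linewidth),
       multiplet("gamma-P", 0.8, 10.8, intensity, linewidth))
}

#' @rdname imido_dutp_multiplets
#' @export
product_multiplets <- function(intensity = 1, linewidth = 0.5) {
  list(multiplet("PPN-P1", 3.27, 6.5, intensity, linewidth),
       multiplet("PPN-P2", 0.27, 6.5, intensity, linewidth),
       multiplet("dUMP", 3.48, numeric(0), intensity, linewidth))
}

#' Simulate a 31P spectrum from first-order multiplets
#'
#' Each multiplet expands to its first-order line pattern; every line is a
#' Lorentzian of the stated width and the contributions add. The default
#' field of 101.25 MHz is the 31P frequency at which couplings in Hz
#' convert to ppm separations of J/101.25.
#'
#' @param multiplets list of \code{\link{multiplet}} objects.
#' @param field spectrometer 31P frequency (MHz).
#' @param ppm_range length-2 numeric, grid limits (low, high).
#' @param step grid spacing (ppm).
#' @return object of class \code{nmr_spectrum}: \code{ppm} (ascending),
#'   \code{intensity}, \code{field}, \code{lines}.
#' @export
simulate_spectrum <- function(multiplets, field = 101.25,
                              ppm_range = c(-10, 6), step = 2e-4) {
  stopifnot(field > 0, length(ppm_range) == 2, ppm_range[1] < ppm_range[2],
            step > 0)
  if (inherits(multiplets, "multiplet")) multiplets <- list(multiplets)
  lines <- do.call(rbind, lapply(multiplets, function(m) {
    ln <- .multiplet_lines(m, field)
    ln$species <- m$species
    ln$hwhm_ppm <- (m$linewidth / 2) / field
    ln
  }))
  out_of_grid <- lines$ppm < ppm_range[1] | lines$ppm > ppm_range[2]
  if (any(out_of_grid))
    stop("multiplet lines outside the grid at ppm: ",
         paste(sprintf("%.3f", lines$ppm[out_of_grid]), collapse = ", "))
  ppm <- seq(ppm_range[1], ppm_range[2], by = step)
  intensity <- numeric(length(ppm))
  for (i in seq_len(nrow(lines))) {
    hw <- lines$hwhm_ppm[i]
    intensity <- intensity +
      lines$area[i] / pi * hw / ((ppm - lines$ppm[i])^2 + hw^2)
  }
  structure(list(ppm = ppm, intensity = intensity, field = field,
                 lines = lines), class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum: %d points, %.2f..%.2f ppm, %d lines, %.2f MHz>\n",
              length(x$ppm), min(x$ppm), max(x$ppm), nrow(x$lines), x$field))
  invisible(x)
}

#' @export
plot.nmr_spectrum <- function(x, ...) {
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = rev(range(x$ppm)),
                 xlab = "ppm", ylab = "intensity", ...)
  invisible(x)
}

#' Integrate a spectrum over a ppm window
#'
#' Trapezoidal integration between the window limits, with linear
#' interpolation at the window edges.
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param window length-2 numeric \code{c(lo, hi)} in ppm.
#' @return integrated area.
#' @export
integrate_spectrum <- function(spectrum, window) {
  stopifnot(length(window) == 2)
  if (window[1] >= window[2]) stop("inverted integration window")
  if (window[1] < min(spectrum$ppm) || window[2] > max(spectrum$ppm))
    stop("integration window outside the spectral grid")
  inside <- spectrum$ppm > window[1] & spectrum$ppm < window[2]
  xs <- c(window[1], spectrum$ppm[inside], window[2])
  ys <- c(stats::approx(spectrum$ppm, spectrum$intensity, window[1])$y,
          spectrum$intensity[inside],
          stats::approx(spectrum$ppm, spectrum$intensity, window[2])$y)
  pracma::trapz(xs, ys)
}

#' Default integration window of a multiplet
#'
#' Centre plus/minus half the total coupling span plus \code{k} linewidths,
#' converted to ppm. The margin must be many linewidths wide for
#' quantitative work: a Lorentzian line truncated at \code{k} linewidths
#' retains only \code{(2/pi) * atan(2k)} of its area, so the default of 25
#' linewidths captures about 98.7 percent; narrow lines keep the absolute
#' window small enough not to swallow neighbouring multiplets.
#'
#' @param m a \code{\link{multiplet}}.
#' @param field spectrometer frequency (MHz).
#' @param k number of linewidths of margin on each side.
#' @return length-2 numeric window (ppm).
#' @export
multiplet_window <- function(m, field = 101.25, k = 25) {
  half <- (sum(m$j_couplings) / 2 + k * m$linewidth) / field
  c(m$center - half, m$center + half)
}

#' Reference 31P peak assignment table
#'
#' Chemical shifts and multiplicities of the species observed during
#' alpha,beta-imido-dUTP hydrolysis: the three substrate phosphorus
#' resonances, the two amino-pyrophosphate product doublets, the dUMP
#' product singlet and the inorganic-phosphate impurity.
#'
#' @return data frame with columns \code{species}, \code{ppm},
#'   \code{multiplicity}.
#' @export
reference_peak_table <- function() {
  data.frame(
    species = c("alpha-P imido-dUTP", "beta-P imido-dUTP",
                "gamma-P imido-dUTP", "amino-PPi P1", "amino-PPi P2",
                "dUMP", "phosphate impurity"),
    ppm = c(-4.5, -7.16, 0.8, 3.27, 0.27, 3.48, 0.10),
    multiplicity = c("d", "dd", "d", "d", "d", "s", "s"),
    stringsAsFactors = FALSE)
}

#' Assign observed peaks to reference species
#'
#' Nearest-shift matching within \code{tolerance} with multiplicity
#' agreement; unmatched peaks are labelled \code{"unknown"}; two observed
#' peaks claiming the same reference entry raise an error.
#'
#' @param observed data frame with columns \code{ppm} and
#'   \code{multiplicity} (\code{"s"}, \code{"d"}, \code{"dd"}, ...).
#' @param reference assignment table, defaults to
#'   \code{\link{reference_peak_table}()}.
#' @param tolerance maximum shift mismatch (ppm).
#' @return the observed data frame with an added \code{species} column.
#' @export
assign_peaks <- function(observed, reference = reference_peak_table(),
                         tolerance = 0.15) {
  stopifnot(all(c("ppm", "multiplicity") %in% names(observed)))
  species <- character(nrow(observed))
  claimed <- integer(0)
  for (i in seq_len(nrow(observed))) {
    ok <- which(reference$multiplicity == observed$multiplicity[i] &
                  abs(reference$ppm - observed$ppm[i]) <= tolerance)
    if (length(ok) == 0) { species[i] <- "unknown"; next }
    best <- ok[which.min(abs(reference$ppm[ok] - observed$ppm[i]))]
    if (best %in% claimed)
      stop("ambiguous assignment: two observed peaks match reference entry '",
           reference$species[best], "'")
    claimed <- c(claimed, best)
    species[i] <- reference$species[best]
  }
  observed$species <- species
  observed
}

#' Write a spectrum as TSV
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param path output path.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.table(data.frame(ppm = spectrum$ppm,
                                intensity = spectrum$intensity),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
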