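#' Run a configured analysis and write report files
#'
#' Programmatic orchestration layer: one call dispatches a named analysis
#' with a validated configuration and writes machine-readable reports
#' (JSON summary plus TSV detail where applicable). All supplied
#' parameters are echoed into the JSON for provenance. Commands:
#' \describe{
#'   \item{simulate}{write a synthetic attack-site PDB and a synthetic
#'     peak time series (fields: \code{out}, \code{seed}, optional
#'     \code{d_attack}, \code{inline_angle}, \code{k}, \code{noise_sd}).}
#'   \item{attack}{near-attack-site detection on \code{input} (PDB path);
#'     optional \code{max_attack_distance}, \code{min_inline_angle},
#'     \code{require_dutpase_coordination}.}
#'   \item{survey}{non-bonded P-O distance survey over \code{inputs}
#'     (vector of PDB paths); optional \code{max_distance},
#'     \code{bin_width}, \code{band}.}
#'   \item{inversion}{chirality comparison between \code{pre} and
#'     \code{post} (paths) at \code{phosphorus} with \code{mapping}
#'     (named list).}
#'   \item{tbp}{axial/equatorial assignment and TBP deviation on
#'     \code{input} at \code{phosphorus}.}
#'   \item{nmr_fit}{global shared-rate fit of the time series at
#'     \code{input} (TSV, see \code{\link{read_timeseries}}).}
#'   \item{morph}{linear morph across \code{inputs} with
#'     \code{frames_per_transition}, written as multi-model PDB.}
#' }
#'
#' @param config list or path to a YAML file with at least \code{command}
#'   and \code{out} (output directory).
#' @return invisibly, a list of written file paths.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$command)) stop("config lacks a 'command' field")
  if (is.null(config$out)) stop("config lacks an 'out' directory")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  cmd <- gsub("-", "_", config$command)
  handler <- switch(cmd,
    simulate = .run_simulate, attack = .run_attack, survey = .run_survey,
    inversion = .run_inversion, tbp = .run_tbp, nmr_fit = .run_nmr_fit,
    morph = .run_morph,
    stop("unknown command: ", config$command))
  for (field in c("input", "pre", "post"))
    if (!is.null(config[[field]]) && !file.exists(config[[field]]))
      stop("input path does not exist: ", config[[field]])
  for (pth in config$inputs)
    if (!file.exists(pth)) stop("input path does not exist: ", pth)
  files <- handler(config)
  invisible(files)
}

.report_json <- function(config, payload, path) {
  cfg <- config[setdiff(names(config), "command")]
  jsonlite::write_json(c(list(command = config$command, parameters = cfg),
                         payload),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

.cfg <- function(config, name, default) {
  if (is.null(config[[name]])) default else config[[name]]
}

.run_simulate <- function(config) {
  seed <- .cfg(config, "seed", 1)
  site <- make_attack_site(
    d_attack = .cfg(config, "d_attack", 2.52),
    inline_angle = .cfg(config, "inline_angle", 175),
    seed = seed)
  pdb_path <- file.path(config$out, "synthetic_site.pdb")
  write_structure(site, pdb_path)
  ts <- make_timeseries(k = .cfg(config, "k", 0.015),
                        noise_sd = .cfg(config, "noise_sd", 0), seed = seed)
  ts_path <- file.path(config$out, "synthetic_timeseries.tsv")
  write_timeseries(ts, ts_path)
  js <- .report_json(config, list(seed = seed, files = c(pdb_path, ts_path)),
                     file.path(config$out, "simulate_report.json"))
  c(pdb_path, ts_path, js)
}

.run_attack <- function(config) {
  s <- read_structure(config$input)
  spec <- site_spec(
    max_attack_distance = .cfg(config, "max_attack_distance", 3.6),
    min_inline_angle = .cfg(config, "min_inline_angle", 150),
    required_coordination =
      if (isTRUE(config$require_dutpase_coordination))
        dutpase_water_coordination() else NULL)
  sites <- find_attack_sites(s, spec = spec)
  m <- s$models[[1]]
  desc <- function(i) sprintf("%s/%d/%s", m$chain[i], m$resseq[i], m$name[i])
  payload <- list(n_sites = length(sites), sites = lapply(sites, function(x)
    list(phosphorus = desc(x$phosphorus), nucleophile = desc(x$nucleophile),
         leaving = desc(x$leaving), d_attack = x$d_attack,
         inline_angle = x$inline_angle,
         contacts = if (nrow(x$contacts)) data.frame(
           atom = vapply(x$contacts$index, desc, character(1)),
           distance = x$contacts$distance) else NULL)))
  .report_json(config, payload, file.path(config$out, "attack_report.json"))
}

.run_survey <- function(config) {
  structures <- lapply(config$inputs, read_structure)
  sv <- survey_nonbonded_po(
    structures,
    max_distance = .cfg(config, "max_distance", 4.5),
    bin_width = .cfg(config, "bin_width", 0.1),
    band = unlist(.cfg(config, "band", c(3.3, 4.5))))
  tsv <- file.path(config$out, "survey_histogram.tsv")
  js <- file.path(config$out, "survey_report.json")
  write_survey(sv, tsv, NULL)
  .report_json(config, list(n_pairs = sv$n_pairs, band = sv$band,
                            band_fraction = if (sv$undefined) NULL
                            else sv$band_fraction,
                            undefined = sv$undefined), js)
  c(tsv, js)
}

.run_inversion <- function(config) {
  pre <- read_structure(config$pre)
  post <- read_structure(config$post)
  mapping <- unlist(config$mapping)
  call <- detect_inversion(pre, post, config$phosphorus, mapping)
  .report_json(config, list(
    inverted = call$inverted,
    pre_sign = call$pre$sign, post_sign = call$post$sign,
    pre_signed_volume = call$pre$signed_volume,
    post_signed_volume = call$post$signed_volume),
    file.path(config$out, "inversion_report.json"))
}

.run_tbp <- function(config) {
  s <- read_structure(config$input)
  asg <- assign_tbp_site(s, config$phosphorus,
                         tolerance = .cfg(config, "tolerance", 0.6))
  dev <- tbp_deviation(asg)
  .report_json(config, list(
    axial = asg$labels[asg$axial], equatorial = asg$labels[asg$equatorial],
    axial_angle = asg$axial_angle,
    ax_distances = asg$ax_distances, eq_distances = asg$eq_distances,
    rms_angles = dev$rms_angles, rms_lengths = dev$rms_lengths),
    file.path(config$out, "tbp_report.json"))
}

.run_nmr_fit <- function(config) {
  ts <- read_timeseries(config$input)
  fit <- fit_shared_rate(ts, init = config$init)
  path <- file.path(config$out, "nmr_fit_report.json")
  write_fit_report(fit, path)
  path
}

.run_morph <- function(config) {
  snaps <- lapply(config$inputs, read_structure)
  traj <- morph(snaps,
                frames_per_transition = .cfg(config, "frames_per_transition", 10))
  path <- file.path(config$out, "morph_trajectory.pdb")
  write_structure(traj, path)
  path
}

#' Aggregate per-pair motion reports into one ordered table
#'
#' Rows are keyed by (snapshot pair, metric); input order is preserved,
#' exact duplicate rows are dropped with a warning, and rows that repeat
#' a key with a different value are rejected as conflicting.
#'
#' @param reports list of data frames with columns \code{pair},
#'   \code{metric}, \code{value}.
#' @return one combined data frame.
#' @export
aggregate_snapshot_report <- function(reports) {
  if (length(reports) < 1) stop("at least one report is required")
  tab <- do.call(rbind, reports)
  stopifnot(all(c("pair", "metric", "value") %in% names(tab)))
  key <- paste(tab$pair, tab$metric, sep = "::")
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      vals <- unique(tab$value[key == k])
      if (length(vals) > 1)
        stop("conflicting values for ", k, ": ",
             paste(format(vals), collapse = " vs "))
    }
    warning(sum(dup), " duplicated report row(s) dropped")
    tab <- tab[!dup, ]
  }
  rownames(tab) <- NULL
  tab
}
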