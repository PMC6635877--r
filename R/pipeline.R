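# build simulator objects from a config list
.config_optics <- function(config) {
  o <- config$optics %||% list()
  optical_model(psf_sigma_lateral = o$psf_sigma_lateral %||% 160,
                psf_sigma_axial = o$psf_sigma_axial %||% 400,
                pixel_size = o$pixel_size %||% 80,
                counts_per_photon = o$counts_per_photon %||% 10,
                baseline = o$baseline %||% 100,
                exposure = o$exposure %||% 5)
}

.config_geometry <- function(config) {
  g <- config$cell %||% list()
  cell_geometry(length = g$length %||% 3, radius = g$radius %||% 0.5,
                thylakoid_thickness = g$thylakoid_thickness %||% 0.1,
                thylakoid_photon_density = g$thylakoid_photon_density %||% 0,
                cytosol_photon_density = g$cytosol_photon_density %||% 0)
}

.config_organelles <- function(config) {
  lapply(config$organelles, function(o)
    organelle_spec(position = unlist(o$position) %||% c(0, 0, 0),
                   diameter = o$diameter %||% 200,
                   copy_number = o$copy_number %||% 1,
                   photons_per_fluorophore = o$photons_per_fluorophore %||% 100,
                   bleach_rate = o$bleach_rate %||% 0,
                   diffusion_coefficient = o$diffusion_coefficient %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a CSV with the configuration echoed in comment headers
.write_csv_with_header <- function(df, path, config, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config: ", jsonlite::toJSON(config,
                                                   auto_unbox = TRUE)),
             con)
  if (!is.null(units)) writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  path
}

#' Run one stage of the quantification pipeline
#'
#' Orchestrates the package's modules behind a single entry point with
#' deterministic outputs for a given configuration and seed:
#' \describe{
#'   \item{simulate}{renders a Slimfield photobleach stack
#'     (`config$mode = "slimfield"`) or a diffusion time-lapse
#'     (`"timelapse"`) and writes TIFF + ground-truth sidecar.}
#'   \item{slimfield}{tracks foci through a photobleach stack, estimates
#'     the characteristic single-fluorophore intensity and writes a
#'     per-focus table (`track_id`, `frame0_intensity`, `copies`, `snr`,
#'     `flags`).}
#'   \item{diffusion}{tracks a time-lapse stack and writes per-track
#'     apparent diffusion coefficients and anomalous exponents.}
#'   \item{report}{summarizes per-focus copy tables into
#'     peak +/- HWHM, n and functional units per protein.}
#' }
#'
#' @param subcommand One of `"simulate"`, `"slimfield"`, `"diffusion"`,
#'   `"report"`.
#' @param config Configuration list or path to a YAML file.
#' @param seed Integer seed overriding `config$seed`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of result objects / output paths.
#' @export
run_pipeline <- function(subcommand, config, seed = NULL,
                         out_dir = ".") {
  if (is.character(config)) config <- read_config(config)
  seed <- seed %||% config$seed %||% 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(subcommand,
    simulate = .run_simulate(config, seed, out_dir),
    slimfield = .run_slimfield(config, seed, out_dir),
    diffusion = .run_diffusion(config, seed, out_dir),
    report = .run_report(config, out_dir),
    stop(sprintf("unknown subcommand '%s'", subcommand), call. = FALSE))
}

.run_simulate <- function(config, seed, out_dir) {
  .require_keys(config, c("mode", "organelles"), "simulate")
  optics <- .config_optics(config)
  geom <- .config_geometry(config)
  orgs <- .config_organelles(config)
  sim <- if (config$mode == "slimfield") {
    simulate_photobleach_stack(geom, orgs, optics,
                               n_frames = config$n_frames %||% 300,
                               seed = seed)
  } else {
    simulate_diffusion_stack(geom, orgs, optics,
                             n_frames = config$n_frames %||% 40,
                             frame_interval = config$frame_interval %||% 60,
                             seed = seed)
  }
  path <- file.path(out_dir, paste0(config$mode, "_stack.tif"))
  write_stack(sim$stack, path, truth = sim$truth, config = config)
  invisible(list(stack = path, truth = sim$truth))
}

.run_slimfield <- function(config, seed, out_dir) {
  .require_keys(config, "input", "slimfield")
  set.seed(seed)
  stack <- read_stack(config$input)
  tracks <- track_stack(stack,
                        mask_sigma = config$mask_sigma %||% 2,
                        snr_threshold = config$snr_threshold %||% 0.4,
                        max_gap = config$max_gap %||% 3,
                        overtrack_frames = config$overtrack_frames %||% 100)
  # stoichiometry needs the full bleach course: keep tracks present from
  # the start of illumination and long enough to fit a decay
  min_len <- config$min_track_length %||% 30
  start_by <- config$track_start_by %||% 3
  tracks <- Filter(function(t)
    nrow(t$measurements) >= min_len && t$measurements$frame[1] <= start_by,
    tracks)
  if (length(tracks) == 0) stop("no foci tracked", call. = FALSE)
  unit <- unit_intensity_endpoint(tracks,
                                  tail_fraction = config$tail_fraction %||% 0.25)
  atten <- config$attenuation_factor %||% 1
  rows <- lapply(tracks, function(tr) {
    cp <- copies_per_focus(tr, unit, attenuation_factor = atten)
    data.frame(track_id = tr$id, frame0_intensity = cp$initial_intensity,
               copies = cp$copies,
               snr = mean(tr$measurements$snr[is.finite(tr$measurements$snr)]),
               flags = if (any(tr$measurements$edge_truncated)) "edge" else "")
  })
  df <- do.call(rbind, rows)
  path <- .write_csv_with_header(df, file.path(out_dir, "per_focus.csv"),
                                 config, "intensity: counts; copies: molecules")
  jsonlite::write_json(list(unit_intensity = unit$value,
                            unit_uncertainty = unit$uncertainty,
                            n_tracks = nrow(df), seed = seed),
                       file.path(out_dir, "slimfield_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(per_focus = df, unit = unit, csv = path))
}

.run_diffusion <- function(config, seed, out_dir) {
  .require_keys(config, "input", "diffusion")
  set.seed(seed)
  stack <- read_stack(config$input)
  if (is.na(stack$frame_interval))
    stack$frame_interval <- config$frame_interval %||% 60
  tracks <- track_timelapse(stack,
                            expected_D = config$expected_D %||% 2e-5,
                            register = isTRUE(config$register))
  tracks <- Filter(function(t) nrow(t) >= 12, tracks)
  rows <- lapply(seq_along(tracks), function(i) {
    prof <- fit_apparent_D(msd(tracks[[i]][, c("x", "y")],
                               frame_interval = stack$frame_interval))
    data.frame(track_id = i, apparent_D = prof$apparent_D,
               intercept = prof$intercept,
               alpha = anomalous_exponent(prof),
               n_frames = nrow(tracks[[i]]))
  })
  df <- do.call(rbind, rows)
  path <- .write_csv_with_header(df, file.path(out_dir, "per_track.csv"),
                                 config, "apparent_D: um^2/s; alpha: unitless")
  invisible(list(per_track = df, csv = path))
}

.run_report <- function(config, out_dir) {
  .require_keys(config, c("tables", "oligomer_sizes"), "report")
  rows <- lapply(names(config$tables), function(label) {
    tab <- utils::read.csv(config$tables[[label]], comment.char = "#")
    dist <- kde_estimate(tab$copies)
    m <- config$oligomer_sizes[[label]]
    if (is.null(m))
      stop(sprintf("no oligomer size for '%s'", label), call. = FALSE)
    data.frame(protein = label, peak = dist$peak, hwhm = dist$hwhm,
               n = dist$n,
               functional_units = functional_units(dist$peak, m),
               functional_units_hwhm = functional_units(dist$hwhm, m))
  })
  df <- do.call(rbind, rows)
  path <- .write_csv_with_header(df, file.path(out_dir, "summary.csv"),
                                 config, "peak/hwhm: molecules")
  invisible(list(summary = df, csv = path))
}
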