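#' Write an image stack as multi-frame 16-bit TIFF with JSON sidecar
#'
#' Camera counts are rounded to integers, clamped to the 16-bit range
#' and written one frame per TIFF page; acquisition metadata, the
#' configuration and any simulation ground truth go into a `.json`
#' sidecar next to the image so a stack round-trips losslessly.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @param truth,config Optional lists stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, truth = NULL, config = NULL) {
  frames <- lapply(stack$frames, function(f)
    pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  meta <- list(pixel_size = stack$pixel_size, exposure = stack$exposure,
               frame_interval = stack$frame_interval, truth = truth,
               config = config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' Frames are returned in acquisition order as camera counts; metadata
#' is restored from the `.json` sidecar when present. Colour (RGB)
#' pages are refused with the offending page named; a truncated or
#' unparseable file raises an explicit error rather than a partial
#' read.
#'
#' @param path TIFF path.
#' @return An `image_stack`.
#' @export
read_stack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("cannot parse '%s' as TIFF: %s", path,
                                   conditionMessage(e)), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3)
      stop(sprintf("page %d of '%s' is not grayscale", i, path),
           call. = FALSE)
    storage.mode(pages[[i]]) <- "double"
  }
  meta <- list(pixel_size = NA_real_, exposure = NA_real_,
               frame_interval = NA_real_)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    m <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in names(meta)) if (!is.null(m[[k]])) meta[[k]] <- m[[k]]
  }
  structure(list(frames = pages, pixel_size = meta$pixel_size,
                 exposure = meta$exposure,
                 frame_interval = meta$frame_interval),
            class = "image_stack")
}

#' Read a pipeline configuration file
#'
#' YAML configuration holding acquisition metadata (pixel size nm,
#' exposure ms, frame interval s, attenuation factor), analysis
#' parameters (ROI radii, SNR threshold, filter window/exponent, kernel
#' widths, oligomer size map, resolution radius, group size) and the
#' random seed. Missing keys fall back to package defaults at use.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# all-at-once schema check: report every missing key
.require_keys <- function(config, keys, where) {
  missing <- setdiff(keys, names(config))
  if (length(missing))
    stop(sprintf("config for '%s' is missing keys: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
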