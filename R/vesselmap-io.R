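# Vessel map I/O: an 8-bit single-channel PNG holding the label codes
# {0, 1, 2, 3} plus a JSON metadata sidecar.

#' Write / read a labeled vessel map
#'
#' `writeVesselMap()` stores the label raster as an 8-bit grayscale PNG
#' (label codes written verbatim as pixel values) and the metadata as a
#' JSON sidecar next to it; `readVesselMap()` reverses this losslessly.
#' Reading validates the format: pixel values outside the label alphabet
#' {0, 1, 2, 3} or missing required metadata keys are format errors.
#'
#' @param map a [VesselMap-class].
#' @param path file path; the `.png` extension is added if absent, and the
#'   sidecar replaces it with `.json`.
#' @return `writeVesselMap()` returns `path` invisibly; `readVesselMap()`
#'   returns a [VesselMap-class].
#' @examples
#' eye <- generateEye(eyeParams(odDiameterUmMean = 720, odDiameterUmSd = 0),
#'                    seed = 3)
#' map <- renderView(eye, viewSpec("ODC"))
#' f <- file.path(tempdir(), "eye3.png")
#' writeVesselMap(map, f)
#' map2 <- readVesselMap(f)
#' identical(vesselLabels(map), vesselLabels(map2))
#' @export
writeVesselMap <- function(map, path) {
  stopifnot(is(map, "VesselMap"))
  validObject(map)
  if (!grepl("\\.png$", path)) path <- paste0(path, ".png")
  # PNG rows are the vertical axis: transpose from [x, y] storage
  png::writePNG(t(map@labels) / 255, path)
  meta <- map@meta
  if (!is.null(meta$vesselTruth))
    meta$vesselTruth <- as.data.frame(meta$vesselTruth)
  jsonlite::write_json(meta, sub("\\.png$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeVesselMap
#' @param strict when TRUE (default) unknown label codes or missing
#'   metadata keys raise an error.
#' @export
readVesselMap <- function(path, strict = TRUE) {
  if (!grepl("\\.png$", path)) path <- paste0(path, ".png")
  if (!file.exists(path)) stop("no such file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  labels <- t(matrix(as.integer(round(img * 255)), nrow(img), ncol(img)))
  if (strict && (min(labels) < 0L || max(labels) > 3L))
    stop("format error: label codes outside {0, 1, 2, 3}")
  jsonPath <- sub("\\.png$", ".json", path)
  if (!file.exists(jsonPath))
    stop("format error: missing metadata sidecar ", jsonPath)
  meta <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  if (strict) {
    missing <- setdiff(VESSELMAP_META_KEYS, names(meta))
    if (length(missing))
      stop("format error: missing metadata keys: ",
           paste(missing, collapse = ", "))
  }
  meta$odCenter <- as.numeric(meta$odCenter)
  new("VesselMap", labels = labels, meta = meta)
}
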