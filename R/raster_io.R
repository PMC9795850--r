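## Registered-raster and plot-geometry I/O, and per-plot clipping.
##
## Scenes travel as plain TIFF rasters with ESRI world-file sidecars
## (.tfw) carrying the affine transform — the long-standing plain-text
## georeferencing convention — plus a small JSON sidecar for the DSM,
## which stores elevations rescaled to [0, 1] with an explicit offset and
## scale (TIFF float samples are stored in [0, 1]) together with the
## acquisition date and nodata sentinel.

worldFileFor <- function(path) sub("\\.tiff?$", ".tfw", path)

writeWorldFile <- function(path, transform) {
  g <- transform[["xres"]]
  lines <- formatC(c(g, 0, 0, transform[["yres"]],
                     transform[["xmin"]] + g / 2,
                     transform[["ymax"]] + transform[["yres"]] / 2),
                   format = "f", digits = 10)
  writeLines(lines, worldFileFor(path))
}

readWorldFile <- function(path) {
  wf <- worldFileFor(path)
  if (!file.exists(wf))
    stop("missing world file: ", wf)
  v <- as.numeric(readLines(wf))
  if (length(v) != 6L || any(is.na(v)) || v[2] != 0 || v[3] != 0)
    stop("unsupported world file (rotation terms must be zero): ", wf)
  c(xres = v[1], yres = v[4], xmin = v[5] - v[1] / 2, ymax = v[6] - v[4] / 2)
}

#' Write a scene to disk
#'
#' Writes the RGB bands as an 8-bit 3-band TIFF and the DSM as a 32-bit
#' float TIFF (elevations rescaled to `[0, 1]`; offset/scale recorded in a
#' JSON sidecar `<dsm>.meta.json`), each with an ESRI world-file sidecar
#' holding the map transform.
#'
#' @param scene a [SceneStack-class].
#' @param rgbPath,dsmPath output TIFF paths.
#' @return invisibly, the two paths.
#' @seealso [readScene()]
#' @export
writeScene <- function(scene, rgbPath, dsmPath) {
  stopifnot(is(scene, "SceneStack"))
  tiff::writeTIFF(scene@rgb / 255, rgbPath, bits.per.sample = 8L,
                  compression = "none", reduce = FALSE)
  writeWorldFile(rgbPath, scene@transform)
  lo <- min(scene@dsm); hi <- max(scene@dsm)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((scene@dsm - lo) / scale, dsmPath, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  writeWorldFile(dsmPath, scene@transform)
  jsonlite::write_json(
    list(offset = lo, scale = scale, date = scene@date,
         nodata = scene@nodata),
    paste0(dsmPath, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(rgb = rgbPath, dsm = dsmPath))
}

#' Read a registered RGB + DSM scene
#'
#' Reads the raster pair written by [writeScene()], restoring DN values,
#' elevations and the map transform, and rejects mismatched grids.
#'
#' @param rgbPath path to the 3-band byte RGB TIFF.
#' @param dsmPath path to the single-band float DSM TIFF.
#' @return a [SceneStack-class] with bands ordered R, G, B.
#' @export
readScene <- function(rgbPath, dsmPath) {
  for (p in c(rgbPath, dsmPath))
    if (!file.exists(p)) stop("raster not found: ", p)
  rgb <- tiff::readTIFF(rgbPath)
  if (length(dim(rgb)) != 3L || dim(rgb)[3] < 3L)
    stop("expected a 3-band RGB raster: ", rgbPath)
  rgb <- round(rgb[, , 1:3, drop = FALSE] * 255)
  dsm <- tiff::readTIFF(dsmPath)
  if (length(dim(dsm)) == 3L) {
    if (dim(dsm)[3] != 1L)
      stop("expected a single-band DSM raster: ", dsmPath)
    dsm <- dsm[, , 1]
  }
  if (!identical(dim(rgb)[1:2], dim(dsm)))
    stop("rgb and dsm grids differ: ", paste(dim(rgb)[1:2], collapse = "x"),
         " vs ", paste(dim(dsm), collapse = "x"))
  trRgb <- readWorldFile(rgbPath)
  trDsm <- readWorldFile(dsmPath)
  if (!isTRUE(all.equal(trRgb, trDsm, tolerance = 1e-9)))
    stop("rgb and dsm transforms differ")
  metaPath <- paste0(dsmPath, ".meta.json")
  if (!file.exists(metaPath)) stop("missing DSM sidecar: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  dsm <- dsm * meta$scale + meta$offset
  SceneStack(meta$date, rgb, dsm, trRgb, nodata = meta$nodata)
}

#' Read / write the plot geometry and ground table
#'
#' CSV with columns `plot_id`, `cultivar_id`, `xmin`, `ymin`, `xmax`,
#' `ymax`, `lodging`, `grain_number`, `grain_weight` (plus any extras such
#' as `is_control`). Lodging must be in 1..5 where present and rectangles
#' must have positive area.
#'
#' @param path CSV path.
#' @return data.frame of plot records.
#' @export
readPlotTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "cultivar_id", "xmin", "ymin", "xmax", "ymax")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("plot table lacks columns: ", paste(miss, collapse = ", "))
  if (any(tab$xmax <= tab$xmin | tab$ymax <= tab$ymin))
    stop("plot rectangles must have positive area")
  if ("lodging" %in% colnames(tab)) {
    bad <- !is.na(tab$lodging) & !(tab$lodging %in% 1:5)
    if (any(bad))
      stop("lodging must be in 1..5: ", paste(tab$plot_id[bad], collapse = ", "))
  }
  tab
}

#' @rdname readPlotTable
#' @param plots plot table data.frame.
#' @export
writePlotTable <- function(plots, path) {
  write.csv(plots, path, row.names = FALSE)
  invisible(path)
}

#' Clip the pixel block of one plot from a scene
#'
#' Selects all pixels whose centres fall inside the plot rectangle, under
#' the half-open window convention `[row0, row1) x [col0, col1)` (0-based,
#' row-major, origin top-left). A rectangle aligned to the pixel grid of
#' size `L x W` metres at ground sampling distance `g` therefore yields an
#' exact `L/g x W/g` block. Clipping is side-effect free and idempotent.
#'
#' @param scene a [SceneStack-class].
#' @param plot single-row plot record (or any list with `xmin`, `ymin`,
#'   `xmax`, `ymax` and optionally `plot_id`).
#' @return list with `rgb` (rows x cols x 3 DN array), `dsm`
#'   (rows x cols matrix), and `window` (1-based row/col index ranges).
#' @export
clipPlot <- function(scene, plot) {
  stopifnot(is(scene, "SceneStack"))
  d <- dim(scene@dsm)
  w <- rectWindow(scene@transform, d[1], d[2],
                  plot$xmin, plot$ymin, plot$xmax, plot$ymax)
  if (is.null(w)) {
    id <- if (!is.null(plot$plot_id)) plot$plot_id else "<unnamed>"
    stop("plot ", id, " does not intersect the raster extent")
  }
  list(rgb = scene@rgb[w$rows, w$cols, , drop = FALSE],
       dsm = scene@dsm[w$rows, w$cols, drop = FALSE],
       window = w)
}
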