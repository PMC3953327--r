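# Raster and report I/O. Rasters travel as 8/16-bit single-channel PNG
# or TIFF; matrices are [row, col] with intensities in [0, 1].

readRaster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format '", ext, "' for ", path))
  if (is.list(img)) stop("multi-page raster not supported: ", path)
  img
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG/TIFF; RGB(A) input is converted by luminance
#' (0.299 R + 0.587 G + 0.114 B). Intensities are returned in `[0, 1]`.
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
readGrayImage <- function(path) {
  img <- readRaster(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L)
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    else img <- img[, , 1L]
  }
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Read a binary boundary map
#'
#' Any nonzero pixel is treated as marked, so 0/1 and 0/255 masks load
#' identically.
#'
#' @param path file path.
#' @return binary matrix (0/1).
#' @export
readBoundaryMap <- function(path) {
  (readGrayImage(path) != 0) * 1
}

#' Write a binary boundary map
#'
#' Marked pixels are written as white (255), blank as black, as 8-bit
#' single-channel PNG or TIFF depending on the file extension.
#' `readBoundaryMap(writeBoundaryMap(...))` is the identity.
#'
#' @param map binary matrix.
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
writeBoundaryMap <- function(map, path) {
  checkBinary(map)
  ext <- tolower(tools::file_ext(path))
  img <- matrix(as.numeric(map != 0), nrow(map), ncol(map))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported raster format '", ext, "' for ", path))
  invisible(path)
}

#' Write a grayscale image
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return `path`, invisibly.
#' @export
writeGrayImage <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported raster format '", ext, "' for ", path))
  invisible(path)
}

#' Write a metric report as JSON and TSV
#'
#' The TSV mirrors a per-image results table: one row per image plus a
#' final `average` row holding the macro metrics; the JSON carries the
#' full per-image and macro values losslessly.
#'
#' @param reports data frame of per-image metrics ([evaluateBoundary()]
#'   rows); row names (or an `image` column) identify the images.
#' @param path output path; `.json` and `.tsv` siblings are written when
#'   `path` has no extension, otherwise the matching single format.
#' @return character vector of the files written, invisibly.
#' @export
writeMetricReport <- function(reports, path) {
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0L) stop("no reports to write")
  if (is.null(reports$image))
    reports <- cbind(image = if (is.null(rownames(reports)))
      as.character(seq_len(nrow(reports))) else rownames(reports), reports)
  macro <- macroMetrics(reports[, setdiff(names(reports), "image"),
                                drop = FALSE])
  ext <- tolower(tools::file_ext(path))
  base <- if (ext == "") path else tools::file_path_sans_ext(path)
  files <- character(0)
  if (ext %in% c("", "json")) {
    f <- paste0(base, ".json")
    jsonlite::write_json(list(images = reports,
                              macro = as.list(macro),
                              nImages = nrow(reports)),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  if (ext %in% c("", "tsv")) {
    f <- paste0(base, ".tsv")
    avg <- reports[1L, ]
    avg$image <- "average"
    for (cn in names(macro)) avg[[cn]] <- macro[[cn]]
    utils::write.table(rbind(reports, avg), f, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
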