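# Grayscale image and manifest I/O. PNG output is 8-bit, TIFF output 16-bit;
# everything in memory is a numeric matrix in [0, 1].

#' Read a grayscale image
#'
#' Reads a PNG or TIFF image as a numeric matrix in `[0, 1]`. Multi-channel
#' images are collapsed to luminance by channel averaging.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  stop_if_not(is.character(path) && length(path) == 1L && file.exists(path),
              "path must name an existing file")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  clamp01(img)
}

#' Write a grayscale image
#'
#' Writes a matrix in `[0, 1]` as 8-bit PNG or 16-bit TIFF, chosen by file
#' extension.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  assert_gray(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write a dataset manifest as JSON lines
#'
#' One JSON record per image (row of `manifest`); if `specs` is given, each
#' record carries the full generating specification under `spec`.
#'
#' @param manifest data.frame with one row per image.
#' @param path output `.jsonl` path.
#' @param specs optional list of `phantom_spec` objects, one per row.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, specs = NULL) {
  stop_if_not(is.data.frame(manifest), "manifest must be a data.frame")
  lines <- vapply(seq_len(nrow(manifest)), function(i) {
    rec <- as.list(manifest[i, , drop = FALSE])
    if (!is.null(specs)) rec$spec <- unclass(specs[[i]])
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines manifest
#'
#' @param path `.jsonl` path written by [write_manifest()].
#' @return data.frame (nested `spec` fields dropped).
#' @export
read_manifest <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  flat <- lapply(recs, function(r) as.data.frame(r[names(r) != "spec"],
                                                 stringsAsFactors = FALSE))
  do.call(rbind, flat)
}
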