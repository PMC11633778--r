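#' Write a field's channels (and optional truth labels) to TIFF
#'
#' One 16-bit TIFF per channel, named
#' `{barcode}_{well}_f{field}_{channel}.tif`; ground truth (when present)
#' is written as label TIFFs plus a JSON sidecar with the spot table and
#' compartment sums.
#'
#' @param field field object (e.g. from [render_field()]).
#' @param dir output directory.
#' @param barcode,well,fieldno naming metadata (defaults taken from the
#'   field object when present).
#' @return Character vector of files written, invisibly.
#' @export
write_field_tiff <- function(field, dir, barcode = field$barcode,
                             well = field$well, fieldno = field$field) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, paste0(barcode, "_", well, "_f", fieldno))
  files <- character(0)
  for (ch in names(field$channels)) {
    f <- paste0(stem, "_", ch, ".tif")
    EBImage::writeImage(EBImage::Image(field$channels[[ch]] / 65535),
                        f, type = "tiff", bits.per.sample = 16L)
    files <- c(files, f)
  }
  if (!is.null(field$truth)) {
    for (lab in c("nucleus_labels", "cell_labels")) {
      f <- paste0(stem, "_", lab, ".tif")
      EBImage::writeImage(EBImage::Image(field$truth[[lab]] / 65535),
                          f, type = "tiff", bits.per.sample = 16L)
      files <- c(files, f)
    }
    f <- paste0(stem, "_truth.json")
    jsonlite::write_json(
      list(spots = field$truth$spots,
           compartment_sums = field$truth$compartment_sums,
           blur_sigma = field$truth$blur_sigma,
           is_out_of_focus = field$truth$is_out_of_focus),
      f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a field written by [write_field_tiff()]
#'
#' @param dir directory.
#' @param barcode,well,fieldno naming metadata.
#' @param channels channel names to read.
#' @return Field object (list with `channels`, `bit_depth`, metadata, and
#'   `truth` when sidecars are present).
#' @export
read_field_tiff <- function(dir, barcode, well, fieldno,
                            channels = c("DAPI", "phalloidin", "NOTCH1")) {
  stem <- file.path(dir, paste0(barcode, "_", well, "_f", fieldno))
  chs <- list()
  for (ch in channels) {
    f <- paste0(stem, "_", ch, ".tif")
    if (!file.exists(f)) stop("missing channel file: ", f)
    img <- tryCatch(EBImage::readImage(f),
                    error = function(e) stop("unreadable TIFF: ", f))
    chs[[ch]] <- round(matrix(EBImage::imageData(img),
                              dim(img)[1], dim(img)[2]) * 65535)
  }
  out <- list(channels = chs, bit_depth = 16L, barcode = barcode,
              well = well, field = fieldno)
  tj <- paste0(stem, "_truth.json")
  if (file.exists(tj)) {
    tr <- jsonlite::read_json(tj, simplifyVector = TRUE)
    for (lab in c("nucleus_labels", "cell_labels")) {
      f <- paste0(stem, "_", lab, ".tif")
      if (file.exists(f)) {
        img <- EBImage::readImage(f)
        tr[[lab]] <- round(matrix(EBImage::imageData(img), dim(img)[1],
                                  dim(img)[2]) * 65535)
      }
    }
    out$truth <- tr
  }
  out
}
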