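# File interfaces: PNG boards/crops/curve images via EBImage, spectrum and
# manifest CSVs. Arrays are (rows, cols, channels) in [0, 255]; EBImage
# stores x-first, hence the transposes.

#' Write an image array as PNG
#'
#' @param img H x W (grayscale) or H x W x 3 array in \[0, 255\].
#' @param path Output file path.
#' @export
writeImagePng <- function(img, path) {
  if (length(dim(img)) == 2) {
    EBImage::writeImage(EBImage::Image(t(img) / 255), path)
  } else {
    EBImage::writeImage(EBImage::Image(aperm(img, c(2, 1, 3)) / 255,
                                       colormode = "Color"), path)
  }
  invisible(path)
}

#' Read an image file into an H x W x 3 array in \[0, 255\]
#'
#' Reads PNG/JPEG/TIFF; grayscale images are replicated to 3 channels,
#' alpha channels dropped.
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array.
#' @export
readImageArray <- function(path) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  aperm(img, c(2, 1, 3)) * 255
}

#' Write a spectrum as CSV (`wavelength_nm,reflectance`)
#'
#' @param curve A [SpectralCurve-class].
#' @param path Output file path.
#' @export
writeSpectrumCsv <- function(curve, path) {
  write.csv(data.frame(wavelength_nm = curve@wavelengths,
                       reflectance = curve@reflectance),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum CSV (`wavelength_nm,reflectance`)
#'
#' @param path CSV file path.
#' @return A [SpectralCurve-class].
#' @export
readSpectrumCsv <- function(path) {
  df <- read.csv(path)
  stopIfNot(all(c("wavelength_nm", "reflectance") %in% names(df)),
            "invalid argument: CSV needs wavelength_nm and reflectance columns")
  SpectralCurve(df$wavelength_nm, df$reflectance)
}

#' Write seed crops and their manifest
#'
#' Crops are written as `{board}_{index:04d}.png` with a manifest CSV
#' (`crop_file,board_file,row0,col0,row1,col1`).
#'
#' @param crops List of [SeedCrop-class].
#' @param dir Output directory (created if missing).
#' @param boardName Board identifier used in file names.
#' @return Invisibly, the manifest data frame.
#' @export
writeCrops <- function(crops, dir, boardName = "board") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(crops), function(i) {
    f <- sprintf("%s_%04d.png", boardName, i)
    writeImagePng(crops[[i]]@pixels, file.path(dir, f))
    bb <- crops[[i]]@sourceBbox
    data.frame(crop_file = f, board_file = boardName, row0 = bb[1],
               col0 = bb[2], row1 = bb[3], col1 = bb[4])
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, paste0(boardName, "_crops.csv")),
            row.names = FALSE)
  invisible(manifest)
}
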