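#' Multiband reflectance image stack
#'
#' A `spectral_stack` holds co-registered reflectance images acquired at a set
#' of narrow wavelengths (for seed work: 19 LED bands from 375 to 970 nm).
#' Pixels are percent reflectance in `[0, 100]`, stored as a
#' `rows x cols x bands` array with bands in ascending wavelength order.
#'
#' @param pixels numeric array `rows x cols x bands`, reflectance in percent.
#' @param wavelengths numeric vector of band wavelengths in nm, strictly
#'   increasing, one per band.
#' @return an object of class `spectral_stack` with elements `pixels`,
#'   `wavelengths` and `resolution` (rows, cols).
#' @examples
#' px <- array(runif(4 * 4 * 3, 0, 100), c(4, 4, 3))
#' st <- spectral_stack(px, c(450, 660, 940))
#' dim(st$pixels)
#' @export
spectral_stack <- function(pixels, wavelengths) {
  if (length(dim(pixels)) != 3) {
    stop("`pixels` must be a rows x cols x bands array")
  }
  wavelengths <- as.numeric(wavelengths)
  if (dim(pixels)[3] != length(wavelengths)) {
    stop("number of bands (", dim(pixels)[3], ") must equal number of wavelengths (",
         length(wavelengths), ")")
  }
  if (any(!is.finite(pixels))) stop("pixel data must be finite numeric")
  if (min(pixels) < 0 || max(pixels) > 100) {
    stop("reflectance must lie in [0, 100]")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  structure(
    list(pixels = pixels, wavelengths = wavelengths,
         resolution = dim(pixels)[1:2]),
    class = "spectral_stack"
  )
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat("spectral_stack:", x$resolution[1], "x", x$resolution[2], "pixels,",
      length(x$wavelengths), "bands (", min(x$wavelengths), "-",
      max(x$wavelengths), "nm )\n")
  invisible(x)
}

# Sidecar file naming convention: <stem>.wavelengths.txt next to the TIFF.
sidecar_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".wavelengths.txt")
}

#' Write a spectral stack as a multi-page TIFF with wavelength sidecar
#'
#' One 16-bit greyscale page per band, pages in ascending wavelength order.
#' The per-page wavelengths (nm) are written, one per line and in page order,
#' to an adjacent plain-text sidecar `<stem>.wavelengths.txt`. Reflectance is
#' stored as `value / 100` on the 16-bit grid; data already quantized to that
#' grid (as the synthetic generator produces) round-trip bit-identically.
#'
#' @param stack a [spectral_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spectral_stack"))
  ord <- order(stack$wavelengths)
  # snap to the exact 16-bit grid: writeTIFF truncates, and (p/100) can fall
  # one ulp below k/65535 after the percent scaling, so re-derive k directly
  pages <- lapply(ord, function(b) {
    round(stack$pixels[, , b] / 100 * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  writeLines(format(stack$wavelengths[ord], trim = TRUE, scientific = FALSE),
             sidecar_path(path))
  invisible(path)
}

#' Read a spectral stack from a multi-page TIFF with wavelength sidecar
#'
#' Bands are returned in ascending wavelength order regardless of the page
#' order on disk: the sidecar lists the wavelength of each page in page order
#' and the pages are sorted accordingly.
#'
#' @param path TIFF path written by [write_stack()] (or compatible).
#' @return a [spectral_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing wavelength sidecar: ", sc)
  wl <- suppressWarnings(as.numeric(readLines(sc)))
  if (any(is.na(wl))) stop("non-numeric wavelength in sidecar: ", sc)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(wl)) {
    stop("band/wavelength mismatch: ", length(pages), " pages but ",
         length(wl), " wavelengths listed")
  }
  if (any(!vapply(pages, is.matrix, logical(1)))) {
    stop("expected single-channel greyscale pages")
  }
  ord <- order(wl)
  px <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(ord)) px[, , i] <- pages[[ord[i]]] * 100
  spectral_stack(px, wl[ord])
}

#' Write a binary mask as a single-page TIFF
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path TIFF path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (!is.matrix(m)) stop("expected a single-channel mask TIFF")
  m > 0.5
}
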