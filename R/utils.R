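# Internal helpers shared across modules.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# Snap reflectance (%) to the 16-bit storage grid p = 100*k/65535 so that
# TIFF write/read is exactly the identity. Values are clipped to [0, 100].
quantize_reflectance <- function(p) {
  p[p < 0] <- 0
  p[p > 100] <- 100
  k <- round(p / 100 * 65535)
  out <- 100 * (k / 65535)
  if (!is.null(dim(p))) dim(out) <- dim(p)
  out
}

#' Label connected components of a binary image
#'
#' Breadth-first labelling of foreground components. Foreground components use
#' 8-connectivity by default (the convention fixed for seed segmentation);
#' 4-connectivity is used for background/hole components.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels, 0 for background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- mask > 0
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nextid <- 0L
  todo <- which(fg & lab == 0L)
  while (length(todo)) {
    nextid <- nextid + 1L
    lab[todo[1L]] <- nextid
    fr <- ((todo[1L] - 1L) %% nr) + 1L
    fc <- ((todo[1L] - 1L) %/% nr) + 1L
    while (length(fr)) {
      nbr <- rep(fr, times = length(dr)) + rep(dr, each = length(fr))
      nbc <- rep(fc, times = length(dc)) + rep(dc, each = length(fc))
      ok <- nbr >= 1L & nbr <= nr & nbc >= 1L & nbc <= nc
      idx <- (nbc[ok] - 1L) * nr + nbr[ok]
      idx <- unique(idx[fg[idx] & lab[idx] == 0L])
      if (!length(idx)) break
      lab[idx] <- nextid
      fr <- ((idx - 1L) %% nr) + 1L
      fc <- ((idx - 1L) %/% nr) + 1L
    }
    todo <- which(fg & lab == 0L)
  }
  lab
}

# Fill interior holes of a binary mask (logical matrix in, logical out).
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(mask * 1L)
  matrix(as.logical(filled > 0), nrow(mask), ncol(mask))
}

# Count connected components robustly against rasterization: the mask is
# dilated by one pixel before 8-connected labelling, so fragments of one
# thin structure (a fissure split by aliasing at some orientations) count
# once, while structures further than two pixels apart stay separate.
count_components_robust <- function(mask) {
  if (!any(mask)) return(0L)
  dil <- EBImage::dilate(mask * 1L, EBImage::makeBrush(3, "box"))
  max(label_components(matrix(dil > 0, nrow(mask), ncol(mask)),
                       connectivity = 8))
}

# Count interior holes (background components fully enclosed by the
# foreground) of a binary mask.
count_holes <- function(mask) {
  holes <- fill_holes(mask) & !mask
  count_components_robust(holes)
}

# Count components after a one-pixel erosion: thin separating fissures stay
# separating (their gap widens) and one-pixel rasterization slivers drop out,
# so the count is stable under rotation. Used for damage patches, which are
# split by cracks that plain dilation would bridge.
count_components_eroded <- function(mask) {
  if (!any(mask)) return(0L)
  ero <- EBImage::erode(mask * 1L, EBImage::makeBrush(3, "box"))
  ero <- matrix(ero > 0, nrow(mask), ncol(mask))
  if (!any(ero)) return(1L)
  max(label_components(ero, connectivity = 8))
}
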