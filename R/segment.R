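#' Segment individual seeds from a spectral stack
#'
#' Thresholds the band-mean image by Otsu's criterion, labels 8-connected
#' foreground components, discards components smaller than `min_area`, and
#' fills interior holes of each surviving component to obtain the seed
#' footprint. The pre-fill mask (with holes) is kept alongside, since hole
#' geometry feeds the binary features. Regions are ordered by the top-left
#' corner of their bounding box, `(row0, col0)`.
#'
#' Coordinates are 0-based and bounding boxes half-open, `(row0, col0, row1,
#' col1)`.
#'
#' @param stack a [spectral_stack()].
#' @param min_area minimum component area in pixels (default 50, rejecting
#'   debris at the default 10 px/mm scale).
#' @return list of `seed_region` objects (possibly empty): `region_id`,
#'   `mask` (filled footprint, full image size), `mask_prefill`, `bbox`,
#'   `area`.
#' @export
segment_seeds <- function(stack, min_area = 50) {
  stopifnot(inherits(stack, "spectral_stack"), min_area >= 1)
  m <- apply(stack$pixels, c(1, 2), mean)
  if (diff(range(m)) < 1e-9) return(list()) # blank image: no foreground
  # Otsu on log-reflectance: compresses the bright within-seed range so the
  # criterion separates background from seed rather than dark from bright
  # seed tissue when interior damage is extensive
  lm <- log1p(m) / log1p(100)
  th <- EBImage::otsu(EBImage::Image(lm), range = c(0, 1), levels = 65536)
  fg <- lm > th
  if (!any(fg)) return(list())
  lab <- label_components(fg, connectivity = 8)
  regions <- list()
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    if (sum(comp) < min_area) next
    filled <- fill_holes(comp)
    rr <- range(which(rowSums(filled) > 0))
    cc <- range(which(colSums(filled) > 0))
    regions[[length(regions) + 1L]] <- structure(
      list(region_id = NA_integer_, mask = filled, mask_prefill = comp,
           bbox = c(row0 = rr[1] - 1L, col0 = cc[1] - 1L,
                    row1 = rr[2], col1 = cc[2]),
           area = sum(filled)),
      class = "seed_region")
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r$bbox[1], 0),
               vapply(regions, function(r) r$bbox[2], 0))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$region_id <- i
  regions
}

#' Jaccard overlap between two binary masks
#' @param a,b logical matrices of equal size.
#' @return intersection over union, in `[0, 1]`.
#' @export
mask_jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}
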