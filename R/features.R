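#' Names of the 19 per-seed variables, in frozen order
#'
#' Seven shape variables, nine colour variables and three binary variables,
#' reconstructing the "seed shape, colour and binary features" taxonomy used
#' for damage scoring. The order is frozen here so fitted scoring models are
#' portable; the set is configurable in [fit_scoring_model()].
#'
#' @return character vector of length 19.
#' @export
msi_feature_names <- function() {
  c("area_px", "perimeter_px", "length_px", "width_px", "aspect_ratio",
    "circularity", "compactness",
    "mean_450", "mean_525", "mean_590", "mean_660", "mean_780", "mean_940",
    "lab_l", "lab_a", "lab_b",
    "hole_count", "damaged_fraction", "damaged_patch_count")
}

# Digital perimeter: length of the outer contour polygon after a circular
# moving-average smoothing of the contour vertices. Smoothing suppresses the
# staircase overestimate of raw chain codes and, importantly, makes the
# estimate nearly rotation-invariant (orientation SD ~0.1% on ellipses,
# accuracy within ~1% on discs).
mask_perimeter <- function(mask, window = 7) {
  oc <- EBImage::ocontour(mask * 1L)
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  n <- nrow(pts)
  if (n < window) return(0.948 * (n + 1))
  k <- (window - 1) / 2
  idx <- function(i) ((i - 1) %% n) + 1
  sm <- vapply(1:2, function(j) {
    v <- pts[, j]
    vapply(seq_len(n), function(i) mean(v[idx((i - k):(i + k))]), 0)
  }, numeric(n))
  d <- diff(rbind(sm, sm[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Axis lengths from second moments of the pixel coordinates: for a filled
# ellipse the variance along the major axis is (a/2)^2 / ... = a^2/4 with a
# the semi-axis, so full axis length = 4 * sqrt(eigenvalue).
mask_axes <- function(coords) {
  cv <- stats::cov(coords) * (nrow(coords) - 1) / nrow(coords)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  c(length = 4 * sqrt(max(ev[1], 0)), width = 4 * sqrt(max(ev[2], 1e-12)))
}

# Convex hull area in pixel units. The hull of pixel centres is dilated to
# pixel squares (shoelace + half hull perimeter + 1) so that for convex
# shapes the hull area is not smaller than the pixel-count area.
mask_hull_area <- function(coords) {
  if (nrow(coords) < 3) return(nrow(coords))
  h <- grDevices::chull(coords[, 2], coords[, 1])
  p <- coords[h, c(2, 1), drop = FALSE]
  n <- nrow(p)
  nxt <- c(2:n, 1)
  shoelace <- abs(sum(p[, 1] * p[nxt, 2] - p[nxt, 1] * p[, 2])) / 2
  perim <- sum(sqrt(rowSums((p[nxt, , drop = FALSE] - p)^2)))
  shoelace + perim / 2 + 1
}

# Mean reflectance over the footprint in the band nearest each requested
# nominal wavelength, averaged across the requested set.
band_mean <- function(stack, mask, wl_nominal) {
  idx <- vapply(wl_nominal,
                function(w) which.min(abs(stack$wavelengths - w)), 0L)
  mean(vapply(unique(idx), function(b) {
    mean(stack$pixels[, , b][mask])
  }, 0))
}

# CIELab from linear RGB reflectance fractions via a fixed nominal
# sRGB/D65 transform; relative (not colorimetrically exact) values, which is
# all the downstream scoring model needs.
rgb_to_lab <- function(r, g, b) {
  M <- matrix(c(0.4124, 0.3576, 0.1805,
                0.2126, 0.7152, 0.0722,
                0.0193, 0.1192, 0.9505), 3, 3, byrow = TRUE)
  xyz <- as.vector(M %*% c(r, g, b)) / c(0.95047, 1, 1.08883)
  f <- ifelse(xyz > (6 / 29)^3, xyz^(1 / 3), xyz / (3 * (6 / 29)^2) + 4 / 29)
  c(lab_l = 116 * f[2] - 16, lab_a = 500 * (f[1] - f[2]),
    lab_b = 200 * (f[2] - f[3]))
}

# Coerce a logical mask to a minimal seed_region (prefill = mask).
region_from_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("empty region")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  structure(list(region_id = 1L, mask = fill_holes(mask), mask_prefill = mask,
                 bbox = c(row0 = rr[1] - 1L, col0 = cc[1] - 1L,
                          row1 = rr[2], col1 = cc[2]),
                 area = sum(fill_holes(mask))),
            class = "seed_region")
}

#' Extract the 19 shape, colour and binary variables for one seed region
#'
#' Shape (7): area, perimeter, major/minor axis length, length/width ratio,
#' circularity \eqn{4\pi A / P^2}, compactness (area / convex-hull area).
#' Colour (9): mean footprint reflectance in the 450, 525, 590, 660, 780 and
#' 940 nm bands, plus CIELab-style L*, a*, b* computed from visible-band
#' means. Binary (3): interior hole count of the pre-fill mask, damaged-area
#' fraction (footprint pixels whose discriminant-transformed value exceeds
#' the model's damage threshold), and damaged-patch count (8-connected).
#'
#' When `ncda_model` is `NULL` the two transform-derived binary features are 0
#' and the result carries attribute `ncda_missing = TRUE`.
#'
#' @param stack a [spectral_stack()].
#' @param region a `seed_region` from [segment_seeds()], or a logical mask
#'   matrix of the stack's spatial size.
#' @param ncda_model optional [fit_ncda()] model for the damage features.
#' @return named numeric vector of length 19 (order of [msi_feature_names()]).
#' @export
extract_features <- function(stack, region, ncda_model = NULL) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (is.matrix(region)) region <- region_from_mask(region)
  stopifnot(inherits(region, "seed_region"))
  if (!all(dim(region$mask) == stack$resolution)) {
    stop("region mask size does not match stack resolution")
  }
  mask <- region$mask
  if (!any(mask)) stop("empty region")

  coords <- which(mask, arr.ind = TRUE)
  area <- nrow(coords)
  perim <- mask_perimeter(mask)
  ax <- mask_axes(coords)
  circ <- 4 * pi * area / perim^2
  comp <- min(1, area / mask_hull_area(coords))

  col6 <- vapply(c(450, 525, 590, 660, 780, 940),
                 function(w) band_mean(stack, mask, w), 0)
  lab <- rgb_to_lab(band_mean(stack, mask, c(630, 645, 660)) / 100,
                    band_mean(stack, mask, c(525, 570)) / 100,
                    band_mean(stack, mask, c(450, 470)) / 100)

  holes <- count_holes(region$mask_prefill)
  if (is.null(ncda_model)) {
    dmg_frac <- 0
    dmg_patches <- 0
  } else {
    timg <- apply_ncda(ncda_model, stack)
    dmask <- mask & (timg > ncda_model$damage_threshold)
    dmg_frac <- sum(dmask) / area
    dmg_patches <- count_components_eroded(dmask)
  }

  fv <- c(area, perim, ax[["length"]], ax[["width"]],
          ax[["length"]] / ax[["width"]], circ, comp,
          col6, lab, holes, dmg_frac, dmg_patches)
  names(fv) <- msi_feature_names()
  if (any(!is.finite(fv))) stop("non-finite feature value for region")
  if (is.null(ncda_model)) attr(fv, "ncda_missing") <- TRUE
  fv
}

#' Build the per-seed feature table (the features/scoring file contract)
#'
#' @param stacks named list of [spectral_stack()]s.
#' @param regions parallel list of `seed_region`s or logical masks (one seed
#'   per stack).
#' @param meta data.frame with one row per stack: `seed_id`, `variety_id`,
#'   `side`, and optionally `true_class`.
#' @param ncda_model optional [fit_ncda()] model.
#' @return data.frame: meta columns followed by the 19 feature columns.
#' @export
extract_features_table <- function(stacks, regions, meta, ncda_model = NULL) {
  stopifnot(length(stacks) == length(regions), nrow(meta) == length(stacks))
  fv <- t(vapply(seq_along(stacks), function(i) {
    extract_features(stacks[[i]], regions[[i]], ncda_model)
  }, numeric(19)))
  cbind(meta, as.data.frame(fv), row.names = NULL)
}

#' Per-class mean reflectance spectra
#'
#' Arithmetic mean reflectance per band over all footprint pixels of all
#' seeds of each class (pixel-weighted, so a merged group's spectrum is the
#' area-weighted mean of the group spectra).
#'
#' @param stacks list of [spectral_stack()]s (equal wavelength axes).
#' @param masks parallel list of logical footprint masks.
#' @param classes vector of class labels, one per stack.
#' @return matrix with one row per class (sorted), one column per wavelength.
#' @export
mean_spectrum <- function(stacks, masks, classes) {
  stopifnot(length(stacks) == length(masks), length(stacks) == length(classes),
            length(stacks) >= 1)
  wl <- stacks[[1]]$wavelengths
  nb <- length(wl)
  cls <- sort(unique(classes))
  sums <- matrix(0, length(cls), nb, dimnames = list(cls, wl))
  npix <- numeric(length(cls))
  for (i in seq_along(stacks)) {
    k <- match(classes[i], cls)
    m <- masks[[i]]
    if (!any(m)) next
    npix[k] <- npix[k] + sum(m)
    for (b in seq_len(nb)) {
      sums[k, b] <- sums[k, b] + sum(stacks[[i]]$pixels[, , b][m])
    }
  }
  if (any(npix == 0)) {
    stop("no footprint pixels for class ", paste(cls[npix == 0], collapse = ", "))
  }
  sums / npix
}
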