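#' Default LED wavelengths of the 19-band seed imaging setup
#'
#' @return numeric vector of 19 wavelengths in nm (375-970).
#' @export
msi_default_wavelengths <- function() {
  c(375, 405, 435, 450, 470, 505, 525, 570, 590, 630, 645, 660, 700,
    780, 850, 870, 890, 940, 970)
}

# Tissue role codes used in ground-truth tissue maps.
TISSUE_ROLES <- c(background = 0L, pericarp = 1L, outer_testa = 2L,
                  inner_testa = 3L, embryo = 4L)

#' Simulation configuration for the synthetic seed image generator
#'
#' Defaults describe the emulated study conditions: 60 seeds per damage class,
#' 18 varieties with per-band colour shifts, 19 bands from 375 to 970 nm,
#' additive Gaussian reflectance noise, and a pixel scale of 10 px/mm (typical
#' polished monogerm seeds are 3.5-4.75 mm).
#'
#' @param n_seeds_per_class seeds generated per damage class (5 classes).
#' @param n_varieties number of varieties; seeds are assigned round-robin.
#' @param image_size `c(rows, cols)` of each single-seed image.
#' @param wavelengths band wavelengths in nm, strictly increasing.
#' @param noise_sd SD of i.i.d. additive Gaussian reflectance noise (percent).
#' @param variety_color_shift_sd SD (percent) of the fixed per-variety,
#'   per-band reflectance offset emulating pericarp colour differences.
#' @param px_per_mm pixel scale used to size the elliptical seed body.
#' @param rng_seed integer seed making the whole dataset reproducible.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_seeds_per_class = 60,
                              n_varieties = 18,
                              image_size = c(80, 80),
                              wavelengths = msi_default_wavelengths(),
                              noise_sd = 0.5,
                              variety_color_shift_sd = 0.03,
                              px_per_mm = 10,
                              rng_seed = 1L) {
  stopifnot(n_seeds_per_class >= 1, n_varieties >= 1,
            length(image_size) == 2, all(image_size >= 8))
  wavelengths <- as.numeric(wavelengths)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (variety_color_shift_sd < 0) stop("variety_color_shift_sd must be >= 0")
  structure(list(n_seeds_per_class = as.integer(n_seeds_per_class),
                 n_varieties = as.integer(n_varieties),
                 image_size = as.integer(image_size),
                 wavelengths = wavelengths,
                 noise_sd = noise_sd,
                 variety_color_shift_sd = variety_color_shift_sd,
                 px_per_mm = px_per_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# Piecewise-linear spectrum through anchor points (wavelength, reflectance).
spectrum_from_anchors <- function(wl, anchors) {
  stats::approx(anchors[, 1], anchors[, 2], xout = wl, rule = 2)$y
}

# Offset that is `vis` below 700 nm, `nir` above 780 nm, linear in between.
vis_nir_offset <- function(wl, vis, nir) {
  spectrum_from_anchors(wl, cbind(c(375, 700, 780, 970), c(vis, vis, nir, nir)))
}

# Base tissue reflectance spectra (%). Tissues are nearly indistinguishable in
# the visible region and spread apart in the NIR; deeper tissues reflect more
# NIR, so exposed/damaged areas appear bright after the discriminant transform.
base_tissue_spectra <- function(wl) {
  pericarp <- spectrum_from_anchors(
    wl, cbind(c(375, 700, 780, 970), c(18, 26, 30, 42)))
  background <- 4 + 0.5 * (wl - min(wl)) / max(1, diff(range(wl)))
  rbind(background   = background,
        pericarp     = pericarp,
        outer_testa  = pericarp + vis_nir_offset(wl, 1.5, 5),
        inner_testa  = pericarp + vis_nir_offset(wl, 3.0, 8),
        embryo       = pericarp + spectrum_from_anchors(
          wl, cbind(c(375, 505, 570, 660, 700, 780, 970),
                    c(7, 8, 10, 13, 13, 48, 48))))
}

# Internal invariant checks for a class spectral profile.
validate_profile <- function(p) {
  sp <- p$tissue_spectra
  if (min(sp) < 0 || max(sp) > 100) stop("profile reflectance outside [0, 100]")
  wl <- p$wavelengths
  vis <- wl < 700
  nir <- wl >= 700
  tis <- setdiff(rownames(sp), c("background", "embryo_damaged"))
  for (i in seq_along(tis)) for (j in seq_len(i - 1)) {
    d <- sp[tis[i], ] - sp[tis[j], ]
    if (sqrt(sum(d[nir]^2)) <= sqrt(sum(d[vis]^2))) {
      stop("tissue spectra must differ more in the NIR than in the visible (",
           tis[i], " vs ", tis[j], ")")
    }
  }
  g <- p$damage_geometry
  stopifnot(g$pericarp_removed_frac >= 0, g$pericarp_removed_frac <= 1,
            g$inner_crushed_frac >= 0, g$inner_crushed_frac <= 1,
            g$embryo_damage_frac >= 0, g$embryo_damage_frac <= 1,
            g$embryo_absent_prob >= 0, g$embryo_absent_prob <= 1)
  invisible(p)
}

#' Default per-class spectral and damage-geometry profiles
#'
#' Builds one profile per damage class (1-5) of mechanically processed sugar
#' beet seeds:
#' \describe{
#'   \item{1}{partially broken pericarp/outer testa, inner testa intact;}
#'   \item{2}{pericarp and outer testa completely broken, inner testa intact;}
#'   \item{3}{fractured pericarp/outer testa, inner testa partially crushed,
#'     embryo sound;}
#'   \item{4}{partially broken pericarp/outer testa, inner testa damaged,
#'     embryo intact;}
#'   \item{5}{severe embryo damage, including embryo-absent variants.}
#' }
#' Tissue spectra show little between-tissue diversity in the visible bands
#' and substantially more in the NIR; deeper tissue layers reflect more NIR,
#' and the class-5 profile carries additional NIR brightening of deteriorated
#' inner testa and damaged embryo tissue.
#'
#' @param rng_seed integer; controls the small per-profile spectral wiggle.
#' @return list of 5 `class_spectral_profile` objects.
#' @export
make_default_profiles <- function(rng_seed = 0L) {
  wl <- msi_default_wavelengths()
  with_seed(rng_seed, {
    geoms <- list(
      list(pericarp_removed_frac = 0.12, exposed_tissue = "outer_testa",
           inner_crushed_frac = 0.00, embryo_present = TRUE,
           embryo_absent_prob = 0.00, embryo_damage_frac = 0.00,
           mean_cracks = 0.00, chip_frac = 0.01),
      list(pericarp_removed_frac = 0.97, exposed_tissue = "inner_testa",
           inner_crushed_frac = 0.00, embryo_present = TRUE,
           embryo_absent_prob = 0.00, embryo_damage_frac = 0.00,
           mean_cracks = 1.0, chip_frac = 0.04),
      list(pericarp_removed_frac = 0.60, exposed_tissue = "inner_testa",
           inner_crushed_frac = 0.30, embryo_present = TRUE,
           embryo_absent_prob = 0.00, embryo_damage_frac = 0.00,
           mean_cracks = 2.0, chip_frac = 0.07),
      list(pericarp_removed_frac = 0.30, exposed_tissue = "outer_testa",
           inner_crushed_frac = 0.58, embryo_present = TRUE,
           embryo_absent_prob = 0.00, embryo_damage_frac = 0.00,
           mean_cracks = 3.0, chip_frac = 0.10),
      list(pericarp_removed_frac = 0.10, exposed_tissue = "inner_testa",
           inner_crushed_frac = 0.80, embryo_present = TRUE,
           embryo_absent_prob = 0.12, embryo_damage_frac = 0.85,
           mean_cracks = 4.0, chip_frac = 0.14))
    lapply(1:5, function(k) {
      sp <- base_tissue_spectra(wl)
      if (k == 5) {
        # deteriorated tissue of severely damaged seeds is NIR-bright
        sp["inner_testa", ] <- sp["inner_testa", ] + vis_nir_offset(wl, 3, 30)
      }
      sp <- rbind(sp, embryo_damaged = sp["embryo", ] + vis_nir_offset(wl, 0.5, 5))
      # small reproducible per-profile wiggle so profiles are not textbook-flat
      wig <- matrix(stats::rnorm(length(sp), 0, 0.15), nrow(sp))
      wig["background" == rownames(sp), ] <- 0
      sp <- pmin(pmax(sp + wig, 0), 100)
      p <- structure(list(damage_class = k, wavelengths = wl,
                          tissue_spectra = sp, damage_geometry = geoms[[k]]),
                     class = "class_spectral_profile")
      validate_profile(p)
    })
  })
}

#' Render one side of one synthetic seed
#'
#' Draws an elliptical seed body on a dark background, assigns tissue roles
#' per the profile's damage geometry (an angular sector of removed pericarp
#' exposing deeper tissue, crushed-testa blobs exposing the embryo, an
#' optional interior crack rendered as background-dark shadow), then adds the
#' variety colour shift and i.i.d. Gaussian reflectance noise, clips to
#' `[0, 100]` and quantizes to the 16-bit storage grid.
#'
#' Geometry randomness is drawn from the current RNG stream; wrap the call in
#' a fixed-seed context for reproducible output.
#'
#' @param profile a `class_spectral_profile`.
#' @param side `"ventral"` or `"dorsal"`.
#' @param variety_shift per-band reflectance offset (scalar or one per band).
#' @param config a [simulation_config()].
#' @param seed_id,variety_id identifiers recorded in the ground truth.
#' @param dims optional list `major_mm`, `aspect` fixing the seed's physical
#'   dimensions (shared between a seed's two sides); drawn when `NULL`.
#' @param layout optional seed-level damage-placement draws (see
#'   `draw_seed_layout()`), shared between a seed's two sides; drawn when
#'   `NULL`.
#' @return list with elements `stack` ([spectral_stack()]) and `truth`
#'   (a `ground_truth_record`: seed_id, variety_id, side, true_class, mask,
#'   tissue_map, embryo_present).
#' @export
render_seed <- function(profile, side = c("ventral", "dorsal"),
                        variety_shift = 0, config = simulation_config(),
                        seed_id = "seed001", variety_id = 1L, dims = NULL,
                        layout = NULL) {
  side <- match.arg(side)
  wl <- config$wavelengths
  if (length(wl) != length(profile$wavelengths) ||
      any(wl != profile$wavelengths)) {
    stop("config wavelengths do not match profile wavelengths")
  }
  nb <- length(wl)
  nr <- config$image_size[1]
  nc <- config$image_size[2]
  g <- profile$damage_geometry
  if (is.null(layout)) layout <- draw_seed_layout()

  # seed body: ellipse sized in mm (polished seeds are graded to a narrow
  # size band; both sides of a seed share its physical dimensions via `dims`),
  # random orientation, centred with jitter
  if (is.null(dims)) {
    dims <- list(major_mm = stats::runif(1, 4.36, 4.44),
                 aspect = stats::runif(1, 1.15, 1.17))
  }
  major_mm <- dims$major_mm
  aspect <- dims$aspect
  a <- major_mm / 2 * config$px_per_mm
  b <- a / aspect
  if (2 * a + 6 > min(nr, nc)) {
    stop("image_size too small to contain a seed of ", round(2 * a), " px")
  }
  theta <- stats::runif(1, 0, pi)
  cy <- (nr + 1) / 2 + stats::runif(1, -2, 2)
  cx <- (nc + 1) / 2 + stats::runif(1, -2, 2)
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  u <- ((xx - cx) * cos(theta) + (yy - cy) * sin(theta)) / a
  v <- (-(xx - cx) * sin(theta) + (yy - cy) * cos(theta)) / b
  r2 <- u^2 + v^2
  footprint <- r2 <= 1

  # abrasion geometry: the pericarp-removed sector starts at a random angle;
  # the chipped-margin bite sits at the middle of that sector (abrasion
  # damage concentrates where the pericarp was rubbed off), so the bite's
  # tissue composition is consistent between a seed's two sides
  phi0 <- layout$phi0

  # chipped margin: abrasion knocks a bite out of the seed edge, its area
  # fraction grading with damage severity (shape features track severity)
  bite_clear <- TRUE
  if (g$chip_frac > 0) {
    phic <- phi0 + pi * max(g$pericarp_removed_frac, 0.02)
    rc <- sqrt(2 * g$chip_frac)
    bited2 <- (u - cos(phic))^2 + (v - sin(phic))^2
    bite <- bited2 <= rc^2
    footprint <- footprint & !bite
    r2[bite] <- Inf # bitten-off pixels are outside the seed for all overlays
    bite_clear <- bited2 > (rc + 0.2)^2 # cracks must not join the bite
  }

  tissue <- matrix(TISSUE_ROLES[["background"]], nr, nc)
  tissue[footprint] <- TISSUE_ROLES[["pericarp"]]

  # pericarp-removed angular sector exposing deeper tissue
  if (g$pericarp_removed_frac > 0) {
    ang <- (atan2(v, u) - phi0) %% (2 * pi)
    sector <- footprint & ang < 2 * pi * g$pericarp_removed_frac
    tissue[sector] <- TISSUE_ROLES[[g$exposed_tissue]]
  }

  # crushed inner testa: one disc in normalized ellipse coordinates (a single
  # patch keeps the realized area equal to the requested fraction), exposing
  # the embryo, or the inner cavity when the embryo is absent
  embryo_px <- matrix(FALSE, nr, nc)
  if (g$inner_crushed_frac > 0) {
    rb <- sqrt(g$inner_crushed_frac)
    rad <- layout$blob_rad * min(0.03, max(0, 0.8 - rb))
    psi <- layout$blob_psi
    blob <- footprint & ((u - rad * cos(psi))^2 + (v - rad * sin(psi))^2 <= rb^2)
    if (isTRUE(g$embryo_present)) {
      tissue[blob] <- TISSUE_ROLES[["embryo"]]
      embryo_px <- embryo_px | blob
    } else {
      tissue[blob] <- TISSUE_ROLES[["inner_testa"]]
    }
  }

  # damaged fraction of the exposed embryo (class 5 with embryo present)
  damaged_embryo <- matrix(FALSE, nr, nc)
  if (g$embryo_damage_frac > 0 && any(embryo_px)) {
    idx <- which(embryo_px)
    take <- with_seed(layout$speckle_seed,
                      sample(idx, size = round(g$embryo_damage_frac * length(idx))))
    damaged_embryo[take] <- TRUE
  }

  # interior cracks: thin parallel dark fissures that do not reach the seed
  # margin, each leaving its own enclosed hole in the non-background
  # footprint; the expected crack count grades with damage severity
  n_cracks <- floor(g$mean_cracks) + (layout$crack_frac_u < g$mean_cracks %% 1)
  if (n_cracks > 0) {
    # cracks run along the seed's long axis (the direction polishing stress
    # fractures follow), keeping their extent consistent across sides
    psi <- theta + layout$crack_psi_jit
    jy <- layout$crack_jy * b
    jx <- layout$crack_jx * a
    dd <- (xx - cx - jx) * sin(psi) - (yy - cy - jy) * cos(psi)
    for (i in seq_len(n_cracks)) {
      ti <- (i - (n_cracks + 1) / 2) * 0.9 * b / max(1, n_cracks)
      crack <- (r2 <= 0.72) & bite_clear & (abs(dd - ti) <= 0.6)
      tissue[crack] <- TISSUE_ROLES[["background"]]
    }
  }

  sp <- profile$tissue_spectra
  tm1 <- as.vector(tissue) + 1L # role code -> spectra row (background first)
  px <- array(0, c(nr, nc, nb))
  fgv <- as.vector(tissue) > 0L
  # cracks drawn over the blob revert pixels to background; only pixels still
  # labelled embryo take the damaged-embryo spectrum
  dmg <- as.vector(damaged_embryo) & (as.vector(tissue) == TISSUE_ROLES[["embryo"]])
  if (length(variety_shift) == 1) variety_shift <- rep(variety_shift, nb)
  for (bnd in seq_len(nb)) {
    v0 <- sp[tm1, bnd]
    v0[dmg] <- sp["embryo_damaged", bnd]
    v0[fgv] <- v0[fgv] + variety_shift[bnd]
    px[, , bnd] <- v0
  }
  if (config$noise_sd > 0) {
    px <- px + stats::rnorm(length(px), 0, config$noise_sd)
  }
  px <- quantize_reflectance(px)

  truth <- structure(list(seed_id = seed_id, variety_id = as.integer(variety_id),
                          side = side, true_class = profile$damage_class,
                          mask = tissue > 0L, tissue_map = tissue,
                          embryo_present = isTRUE(g$embryo_present)),
                     class = "ground_truth_record")
  list(stack = spectral_stack(px, wl), truth = truth)
}

# Per-seed severity variation: within a damage grade most seeds sit tightly
# around the grade's nominal severity (log-normal scale jitter), while a
# small fraction are borderline cases with clearly milder damage -- grading
# thresholds bound a class's severity from above, so the within-grade
# distribution is left-skewed. The milder tail widens each class's
# calibration score spread (and hence its score range) without pushing any
# bulk seed past the upper range bound, and creates the overlap between
# adjacent grades seen in real samples.
jitter_geometry <- function(g, scale) {
  g$pericarp_removed_frac <- min(1, max(0, g$pericarp_removed_frac * scale))
  g$inner_crushed_frac <- min(1, max(0, g$inner_crushed_frac * scale))
  g$chip_frac <- min(0.3, max(0, g$chip_frac * scale))
  g
}

# Seed-level damage-placement draws shared by both sides of a seed: the
# angular position of the abraded sector, crush-blob placement, crack
# placement jitter and the fractional-crack draw. Rendering a seed's two
# sides with the same layout leaves only placement (orientation, centring)
# and sensor noise side-specific.
draw_seed_layout <- function() {
  list(phi0 = stats::runif(1, -pi, pi),
       blob_rad = stats::runif(1, 0, 1),
       blob_psi = stats::runif(1, 0, 2 * pi),
       crack_psi_jit = stats::rnorm(1, 0, 0.05),
       crack_frac_u = stats::runif(1),
       crack_jy = stats::runif(1, -0.1, 0.1),
       crack_jx = stats::runif(1, -0.1, 0.1),
       speckle_seed = sample.int(1e6, 1))
}

#' Generate a full labelled synthetic dataset
#'
#' Renders `n_seeds_per_class` seeds for each of the 5 damage classes, two
#' sides (ventral, dorsal) per seed. Seeds are assigned round-robin to
#' `n_varieties` varieties; each variety carries a fixed per-band reflectance
#' offset drawn with SD `variety_color_shift_sd`. Each seed draws a severity
#' jitter shared by both of its sides; class-5 seeds are rendered without an
#' embryo with probability `embryo_absent_prob` (an empty shell with almost
#' fully exposed inner cavity). Fully reproducible from `config$rng_seed`.
#'
#' @param config a [simulation_config()].
#' @param profiles optional list of 5 profiles; default
#'   `make_default_profiles(config$rng_seed)`.
#' @return list of class `msi_dataset`: `stacks` (named list of
#'   [spectral_stack()], `"<seed_id>_<side>"`), `truth` (parallel list of
#'   ground-truth records), `truth_table` (data.frame seed_id, variety_id,
#'   side, true_class), `variety_shifts`, `config`, `profiles`.
#' @export
generate_dataset <- function(config = simulation_config(), profiles = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(profiles)) profiles <- make_default_profiles(config$rng_seed)
  stopifnot(length(profiles) == 5)
  with_seed(config$rng_seed, {
    nb <- length(config$wavelengths)
    shifts <- matrix(stats::rnorm(config$n_varieties * nb, 0,
                                  config$variety_color_shift_sd),
                     config$n_varieties, nb)
    stacks <- list()
    truth <- list()
    idx <- 0L
    for (k in 1:5) for (i in seq_len(config$n_seeds_per_class)) {
      idx <- idx + 1L
      variety <- ((idx - 1L) %% config$n_varieties) + 1L
      sid <- sprintf("seed%03d", idx)
      prof <- profiles[[k]]
      # grading bounds a class's severity from above, so within-grade
      # severity is left-skewed: a tight log-normal bulk at the nominal
      # severity, and a minority of borderline seeds with clearly milder
      # damage
      scale <- exp(stats::rnorm(1, 0, 0.015))
      # class 5 is qualitatively defined (destroyed or missing embryo) and
      # does not grade down continuously; its milder-looking minority is the
      # embryo-absent subtype drawn below
      if (k < 5 && stats::runif(1) < 0.15) {
        scale <- scale * stats::runif(1, 0.7, 0.88)
      }
      prof$damage_geometry <- jitter_geometry(prof$damage_geometry, scale)
      # a minority of seeds retain darker corky pericarp patches after
      # polishing; the darkening acts where pericarp dominates (strongest in
      # class 1, whose score spread it sets)
      if (stats::runif(1) < 0.15) {
        prof$tissue_spectra["pericarp", ] <-
          pmax(prof$tissue_spectra["pericarp", ] - stats::runif(1, 1.5, 3), 0)
      }
      if (stats::runif(1) < prof$damage_geometry$embryo_absent_prob) {
        prof$damage_geometry$embryo_present <- FALSE
        prof$damage_geometry$inner_crushed_frac <- 0
        prof$damage_geometry$pericarp_removed_frac <- 0.95
        prof$damage_geometry$exposed_tissue <- "inner_testa"
      }
      dims <- list(major_mm = stats::runif(1, 4.36, 4.44),
                   aspect = stats::runif(1, 1.15, 1.17))
      layout <- draw_seed_layout()
      for (side in c("ventral", "dorsal")) {
        r <- render_seed(prof, side, shifts[variety, ], config, sid, variety,
                         dims = dims, layout = layout)
        stacks[[paste0(sid, "_", side)]] <- r$stack
        truth[[paste0(sid, "_", side)]] <- r$truth
      }
    }
    tt <- data.frame(
      seed_id = vapply(truth, `[[`, "", "seed_id"),
      variety_id = vapply(truth, `[[`, 0L, "variety_id"),
      side = vapply(truth, `[[`, "", "side"),
      true_class = vapply(truth, `[[`, 0, "true_class"),
      row.names = NULL)
    structure(list(stacks = stacks, truth = truth, truth_table = tt,
                   variety_shifts = shifts, config = config,
                   profiles = profiles),
              class = "msi_dataset")
  })
}

#' Write a synthetic dataset to disk
#'
#' Stacks go to `stacks/<id>.tif` (multi-page TIFF + wavelength sidecar),
#' ground-truth masks to `masks/<id>.tif`, and the label table to
#' `ground_truth.tsv`.
#'
#' @param dataset an `msi_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "msi_dataset"))
  dir.create(file.path(dir, "stacks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$stacks)) {
    write_stack(dataset$stacks[[id]], file.path(dir, "stacks", paste0(id, ".tif")))
    write_mask(dataset$truth[[id]]$mask, file.path(dir, "masks", paste0(id, ".tif")))
  }
  utils::write.table(dataset$truth_table, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
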