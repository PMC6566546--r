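test_that("a disc yields circularity and aspect ratio near 1", {
  mask <- disc_mask(50)
  st <- uniform_stack(rep(40, 3), nrow(mask), ncol(mask))
  fv <- extract_features(st, mask)
  expect_lt(abs(fv["circularity"] - 1), 0.02)
  expect_lt(abs(fv["aspect_ratio"] - 1), 0.02)
  expect_gt(fv["compactness"], 0.97)
  expect_lte(fv["compactness"], 1)
  # area and axes of a disc of radius 50
  expect_lt(abs(fv["area_px"] - pi * 50^2) / (pi * 50^2), 0.01)
  expect_lt(abs(fv["length_px"] - 100) / 100, 0.02)
})

test_that("a mask with one interior hole reports hole count 1", {
  mask <- disc_mask(20)
  ctr <- (nrow(mask) + 1) / 2 # carve a hole at the disc centre
  mask[(ctr - 2):(ctr + 2), (ctr - 2):(ctr + 2)] <- FALSE
  st <- uniform_stack(rep(40, 3), nrow(mask), ncol(mask))
  fv <- extract_features(st, mask)
  expect_identical(unname(fv["hole_count"]), 1)
  # the footprint (filled) area includes the hole
  expect_equal(unname(fv["area_px"]), sum(disc_mask(20)))
})

test_that("colour features report footprint band means", {
  st <- uniform_stack(c(10, 20, 30, 40, 50, 60),
                      30, 30,
                      wavelengths = c(450, 525, 590, 660, 780, 940))
  mask <- disc_mask(10, 30)
  fv <- extract_features(st, mask)
  expect_equal(unname(fv[c("mean_450", "mean_525", "mean_590",
                           "mean_660", "mean_780", "mean_940")]),
               c(10, 20, 30, 40, 50, 60))
})

test_that("class-2 seeds have a larger damaged-area fraction than class-1", {
  cfg <- tiny_config(n = 2, seed = 21)
  ds <- generate_dataset(cfg)
  tt <- ds$truth_table
  tp <- with_seed(1, msiseed:::sample_tissue_pixels(ds$stacks, ds$truth, 500))
  nm <- fit_ncda(tp$x, tp$labels)
  nm <- calibrate_damage_threshold(nm, ds$stacks,
                                   lapply(ds$truth, `[[`, "mask"),
                                   tt$true_class)
  i1 <- which(tt$true_class == 1)[1]
  i2 <- which(tt$true_class == 2)[1]
  f1 <- extract_features(ds$stacks[[i1]], ds$truth[[i1]]$mask, nm)
  f2 <- extract_features(ds$stacks[[i2]], ds$truth[[i2]]$mask, nm)
  expect_gt(f2["damaged_fraction"], f1["damaged_fraction"])
})

test_that("without an nCDA model the damage features are zero and flagged", {
  st <- uniform_stack(rep(40, 3), 30, 30)
  fv <- extract_features(st, disc_mask(10, 30))
  expect_identical(unname(fv[c("damaged_fraction", "damaged_patch_count")]),
                   c(0, 0))
  expect_true(isTRUE(attr(fv, "ncda_missing")))
})

test_that("feature extraction is translation invariant and scales correctly", {
  base <- disc_mask(12, 60, cy = 20, cx = 20)
  shifted <- disc_mask(12, 60, cy = 40, cx = 37)
  st <- uniform_stack(rep(40, 3), 60, 60)
  f1 <- extract_features(st, base)
  f2 <- extract_features(st, shifted)
  expect_equal(f1, f2, tolerance = 1e-12, ignore_attr = TRUE)

  # integer upscaling: area ~ s^2, perimeter ~ s within discretization error
  s <- 3
  base_big <- disc_mask(20, 60)
  f1 <- extract_features(uniform_stack(rep(40, 3), 60, 60), base_big)
  up <- disc_mask(20 * s, 60 * s)
  fu <- extract_features(uniform_stack(rep(40, 3), 60 * s, 60 * s), up)
  expect_lt(abs(fu["area_px"] / f1["area_px"] - s^2) / s^2, 0.05)
  expect_lt(abs(fu["perimeter_px"] / f1["perimeter_px"] - s) / s, 0.05)
})

test_that("mean_spectrum averages per class, pixel-weighted", {
  wl <- c(450, 660, 940)
  st1 <- uniform_stack(rep(40, 3), 20, 20, wl)
  expect_equal(unname(mean_spectrum(list(st1), list(disc_mask(5, 20)),
                                    1)[1, ]),
               rep(40, 3))

  # equal areas at 20% and 60% -> mean 40 per band
  st_a <- uniform_stack(rep(20, 3), 20, 20, wl)
  st_b <- uniform_stack(rep(60, 3), 20, 20, wl)
  m <- disc_mask(5, 20)
  expect_equal(unname(mean_spectrum(list(st_a, st_b), list(m, m),
                                    c(1, 1))[1, ]),
               rep(40, 3))

  # merged group equals area-weighted mean of group spectra
  m_small <- disc_mask(3, 20)
  merged <- mean_spectrum(list(st_a, st_b), list(m, m_small), c(1, 1))
  w <- c(sum(m), sum(m_small))
  expect_equal(unname(merged[1, ]),
               rep((20 * w[1] + 60 * w[2]) / sum(w), 3))

  # an empty group is an error
  expect_error(mean_spectrum(list(st_a), list(m & FALSE), 1), "no footprint")
})

test_that("degenerate regions are rejected", {
  st <- uniform_stack(rep(40, 3), 20, 20)
  expect_error(extract_features(st, matrix(FALSE, 20, 20)))
  expect_error(extract_features(st, disc_mask(5, 30)), "does not match")
})
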