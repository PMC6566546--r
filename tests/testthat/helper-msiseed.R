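# Shared fixtures, generated in code.

# Small simulation config keeping unit tests fast.
tiny_config <- function(n = 3, seed = 42, noise = 0.5, nv = 2, img = 60) {
  simulation_config(n_seeds_per_class = n, n_varieties = nv,
                    image_size = c(img, img), noise_sd = noise,
                    rng_seed = seed)
}

# Logical disc mask of radius r centred in an n x n image.
disc_mask <- function(r, n = 2 * r + 11, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

# Uniform-reflectance stack: one value per band over the whole image.
uniform_stack <- function(values, nrows = 20, ncols = 20,
                          wavelengths = seq(400, by = 50,
                                            length.out = length(values))) {
  px <- array(0, c(nrows, ncols, length(values)))
  for (b in seq_along(values)) px[, , b] <- values[b]
  spectral_stack(px, wavelengths)
}

# Two-class Gaussian pixel sample with given means and common covariance.
two_class_pixels <- function(n, mu1, mu2, sigma) {
  p <- length(mu1)
  L <- chol(sigma)
  x1 <- matrix(stats::rnorm(n * p), n, p) %*% L
  x2 <- matrix(stats::rnorm(n * p), n, p) %*% L
  x <- rbind(sweep(x1, 2, mu1, "+"), sweep(x2, 2, mu2, "+"))
  list(x = x, labels = rep(1:2, each = n))
}

# Closed-form two-class Fisher direction for the ridge-regularized
# within-class scatter (the oracle path: direct solve, not eigen).
fisher_oracle <- function(x, labels, reg_eps = 1e-6) {
  cls <- sort(unique(labels))
  p <- ncol(x)
  sw <- matrix(0, p, p)
  mus <- list()
  for (k in cls) {
    xk <- x[labels == k, , drop = FALSE]
    mus[[as.character(k)]] <- colMeans(xk)
    sw <- sw + crossprod(sweep(xk, 2, colMeans(xk)))
  }
  swr <- sw + reg_eps * sum(diag(sw)) / p * diag(p)
  w <- solve(swr, mus[[2]] - mus[[1]])
  w / sqrt(sum(w^2))
}

# Relative direction error up to sign.
direction_error <- function(w1, w2) {
  if (sum(w1 * w2) < 0) w2 <- -w2
  sqrt(sum((w1 - w2)^2)) / sqrt(sum(w2^2))
}

# 4-seed, 2-feature table whose sample correlation is exactly 0.5
# (y = 0.5 x + sqrt(0.75) * z with z orthogonal to x in-sample).
toy_rho05 <- function() {
  x <- c(-3, -1, 1, 3)
  z <- c(1, -1, -1, 1)
  y <- 0.5 * x + sqrt(0.75) * (sd(x) / sd(z)) * z
  data.frame(f1 = x, f2 = y)
}

# Random confusion table over 5 classes.
random_counts <- function() {
  matrix(stats::rpois(25, 4) + diag(5) * stats::rpois(5, 30), 5, 5,
         dimnames = list(true = 1:5, predicted = 1:5))
}
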