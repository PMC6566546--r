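#' Fit a normalized canonical discriminant (nCDA) pixel transform
#'
#' Learns the linear band combination that maximizes the ratio of
#' between-class to within-class variance of labelled training pixels: the
#' leading solution \eqn{w} of the generalized eigenproblem
#' \eqn{S_B w = \lambda S_W w}, where \eqn{S_B} and \eqn{S_W} are the
#' between- and within-class scatter matrices of the centred pixel vectors.
#' \eqn{S_W} is ridge-regularized as
#' \eqn{S_W + \epsilon\,\mathrm{tr}(S_W)/p\,I} with \eqn{\epsilon = 10^{-6}}
#' so strongly correlated bands stay invertible. The output normalization
#' maps the 1st/99th percentiles of the projected training pixels to
#' \eqn{[0, 1]}; the sign is fixed so the highest-labelled class has the
#' highest mean projection (damaged/deep tissue bright). A damage threshold
#' on the normalized scale is stored as the midpoint between the two lowest
#' class means: pixels brighter than typical for the least damage-indicative
#' class are flagged by the binary damage features.
#'
#' @param x numeric matrix, one training pixel per row, one band per column.
#' @param labels class label per pixel (integer-like; at least 2 classes and
#'   at least 20 pixels per class).
#' @param reg_eps ridge coefficient (default `1e-6`).
#' @return an `ncda_model`: `weights` (unit norm), `band_means`, `norm_low`,
#'   `norm_high`, `damage_threshold`, `n_bands`.
#' @export
fit_ncda <- function(x, labels, reg_eps = 1e-6) {
  x <- as.matrix(x)
  labels <- as.vector(labels)
  stopifnot(nrow(x) == length(labels))
  cls <- sort(unique(labels))
  if (length(cls) < 2) stop("at least 2 pixel classes are required")
  cnt <- table(labels)
  if (any(cnt < 20)) {
    stop("at least 20 pixels per class are required (smallest class has ",
         min(cnt), ")")
  }
  p <- ncol(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  if (max(abs(xc)) < 1e-12) stop("degenerate training data: all pixels identical")

  sw <- matrix(0, p, p)
  sb <- matrix(0, p, p)
  for (k in cls) {
    xk <- xc[labels == k, , drop = FALSE]
    mk <- colMeans(xk)
    xkc <- sweep(xk, 2, mk)
    sw <- sw + crossprod(xkc)
    sb <- sb + nrow(xk) * tcrossprod(mk)
  }
  swr <- sw + reg_eps * sum(diag(sw)) / p * diag(p)

  # whitened symmetric form: eigenvectors of L^-1 Sb L^-T, w = L^-T u
  L <- t(chol(swr))
  m <- forwardsolve(L, t(forwardsolve(L, sb)))
  m <- (m + t(m)) / 2
  u <- eigen(m, symmetric = TRUE)$vectors[, 1]
  w <- backsolve(t(L), u)
  w <- w / sqrt(sum(w^2))

  proj <- as.vector(xc %*% w)
  hi <- mean(proj[labels == max(cls)])
  lo <- mean(proj[labels == min(cls)])
  if (hi < lo) {
    w <- -w
    proj <- -proj
  }
  q <- stats::quantile(proj, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("degenerate projection: percentile range collapsed")

  cm <- vapply(cls, function(k) mean(proj[labels == k]), 0)
  cmn <- sort((cm - q[1]) / (q[2] - q[1]))
  # threshold between the two least-damage-indicative class means: pixels
  # brighter than typical for the lowest class are flagged as damage
  structure(list(weights = as.vector(w), band_means = mu,
                 norm_low = q[1], norm_high = q[2],
                 damage_threshold = mean(cmn[1:2]),
                 n_bands = p),
            class = "ncda_model")
}

#' Apply an nCDA model to a spectral stack
#'
#' Projects each pixel's centred band vector on the discriminant weights and
#' affinely maps `[norm_low, norm_high]` to `[0, 1]`, clipping outside.
#'
#' @param model an `ncda_model` from [fit_ncda()].
#' @param stack a [spectral_stack()] with the model's band count.
#' @return numeric matrix (stack spatial size) with values in `[0, 1]`.
#' @export
apply_ncda <- function(model, stack) {
  stopifnot(inherits(model, "ncda_model"), inherits(stack, "spectral_stack"))
  nb <- dim(stack$pixels)[3]
  if (nb != model$n_bands) {
    stop("stack has ", nb, " bands but the model expects ", model$n_bands)
  }
  d <- dim(stack$pixels)
  flat <- matrix(stack$pixels, d[1] * d[2], d[3])
  proj <- as.vector(sweep(flat, 2, model$band_means) %*% model$weights)
  out <- (proj - model$norm_low) / (model$norm_high - model$norm_low)
  out[out < 0] <- 0
  out[out > 1] <- 1
  matrix(out, d[1], d[2])
}

#' Recalibrate the damage threshold from per-damage-class footprint means
#'
#' Sets the model's damage threshold (used by the binary features) to the
#' midpoint between the two lowest per-class means of the normalized
#' transformed image over seed footprints of a labelled calibration set, so
#' pixels brighter than typical for the least-damaged class count as damage.
#'
#' @param model an `ncda_model`.
#' @param stacks list of calibration [spectral_stack()]s.
#' @param masks parallel list of logical footprint masks.
#' @param classes damage class label per stack.
#' @return the model with an updated `damage_threshold`.
#' @export
calibrate_damage_threshold <- function(model, stacks, masks, classes) {
  stopifnot(length(stacks) == length(masks), length(stacks) == length(classes))
  cls <- sort(unique(classes))
  sums <- numeric(length(cls))
  npx <- numeric(length(cls))
  for (i in seq_along(stacks)) {
    k <- match(classes[i], cls)
    t_img <- apply_ncda(model, stacks[[i]])
    sums[k] <- sums[k] + sum(t_img[masks[[i]]])
    npx[k] <- npx[k] + sum(masks[[i]])
  }
  m <- sort(sums / npx)
  model$damage_threshold <- mean(m[1:2])
  model
}

# Draw up to max_per_class labelled training pixels per tissue role from
# ground-truth tissue maps (background excluded).
sample_tissue_pixels <- function(stacks, truth, max_per_class = 2000) {
  xs <- list()
  ls <- list()
  for (i in seq_along(stacks)) {
    tm <- truth[[i]]$tissue_map
    idx <- which(tm > 0L)
    d <- dim(stacks[[i]]$pixels)
    flat <- matrix(stacks[[i]]$pixels, d[1] * d[2], d[3])
    xs[[i]] <- flat[idx, , drop = FALSE]
    ls[[i]] <- as.vector(tm)[idx]
  }
  x <- do.call(rbind, xs)
  lab <- unlist(ls)
  keep <- unlist(lapply(sort(unique(lab)), function(k) {
    idx <- which(lab == k)
    if (length(idx) > max_per_class) sample(idx, max_per_class) else idx
  }))
  list(x = x[keep, , drop = FALSE], labels = lab[keep])
}

#' Serialize an nCDA model to a plain-text key-value file
#' @param model an `ncda_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ncda_model <- function(model, path) {
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  writeLines(c(paste0("weights: ", num(model$weights)),
               paste0("band_means: ", num(model$band_means)),
               paste0("norm_low: ", num(model$norm_low)),
               paste0("norm_high: ", num(model$norm_high)),
               paste0("damage_threshold: ", num(model$damage_threshold))),
             path)
  invisible(path)
}

#' Read an nCDA model written by [write_ncda_model()]
#' @param path file path.
#' @return an `ncda_model`.
#' @export
read_ncda_model <- function(path) {
  ln <- readLines(path)
  get <- function(key) {
    v <- sub(paste0("^", key, ": "), "", ln[startsWith(ln, paste0(key, ":"))])
    as.numeric(strsplit(v, " +")[[1]])
  }
  w <- get("weights")
  structure(list(weights = w, band_means = get("band_means"),
                 norm_low = get("norm_low"), norm_high = get("norm_high"),
                 damage_threshold = get("damage_threshold"),
                 n_bands = length(w)),
            class = "ncda_model")
}
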