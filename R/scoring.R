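#' Fit the factor-analytic scoring model on a calibration feature table
#'
#' Features are standardized to zero mean and unit SD on the calibration set,
#' a principal-component factor extraction is run on their correlation
#' matrix, and the first factor's loadings are converted to scoring
#' coefficients by dividing by the square root of its eigenvalue — the
#' normalization under which the calibration scores have variance exactly 1
#' ("united variance" scores). The sign is fixed so the mean calibration
#' score of the highest class exceeds that of the lowest (more damage, higher
#' score); without class labels, so the coefficient sum is positive. The
#' number of factors with eigenvalue > 1 is retained for diagnostics only:
#' scoring uses factor 1, matching the one-dimensional mean-plus/minus-SD
#' range rule downstream.
#'
#' @param calibration data.frame containing the feature columns and
#'   optionally `true_class`.
#' @param feature_cols feature column names (default the frozen 19-variable
#'   set, [msi_feature_names()]).
#' @return a `scoring_model`: `feature_names`, `feature_means`,
#'   `feature_sds`, `scoring_coefficients`, `n_factors_retained`,
#'   `eigenvalues`.
#' @export
fit_scoring_model <- function(calibration, feature_cols = msi_feature_names()) {
  missing_cols <- setdiff(feature_cols, names(calibration))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(calibration[, feature_cols, drop = FALSE])
  if (nrow(x) < 2) stop("at least 2 calibration seeds are required")
  mu <- colMeans(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(feature_cols[sds == 0], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")
  r <- stats::cor(x)
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  lambda1 <- e$values[1]
  coef <- e$vectors[, 1] / sqrt(lambda1)
  scores <- as.vector(z %*% coef)

  if (!is.null(calibration$true_class) &&
      length(unique(calibration$true_class)) >= 2) {
    tc <- calibration$true_class
    if (mean(scores[tc == max(tc)]) < mean(scores[tc == min(tc)])) coef <- -coef
  } else if (sum(coef) < 0) {
    coef <- -coef
  }
  structure(list(feature_names = feature_cols, feature_means = mu,
                 feature_sds = sds, scoring_coefficients = as.vector(coef),
                 n_factors_retained = sum(e$values > 1),
                 eigenvalues = e$values),
            class = "scoring_model")
}

#' Score seeds with a fitted scoring model
#'
#' Each seed side's score is the linear combination of its standardized
#' features with the scoring coefficients:
#' `sum(coef * (feature - calibration mean) / calibration SD)`.
#'
#' @param model a `scoring_model` from [fit_scoring_model()].
#' @param features data.frame with exactly the model's feature columns plus
#'   any identifier columns (`seed_id`, `side`, ... are carried through).
#' @return data.frame of the identifier columns present (`seed_id`,
#'   `variety_id`, `side`, `true_class`) plus `score`.
#' @export
score_seeds <- function(model, features) {
  stopifnot(inherits(model, "scoring_model"))
  missing_cols <- setdiff(model$feature_names, names(features))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  id_cols <- intersect(c("seed_id", "variety_id", "side", "true_class"),
                       names(features))
  extra <- setdiff(names(features), c(model$feature_names, id_cols))
  if (length(extra)) {
    stop("unexpected extra columns: ", paste(extra, collapse = ", "))
  }
  x <- as.matrix(features[, model$feature_names, drop = FALSE])
  z <- sweep(sweep(x, 2, model$feature_means), 2, model$feature_sds, "/")
  out <- features[, id_cols, drop = FALSE]
  out$score <- as.vector(z %*% model$scoring_coefficients)
  row.names(out) <- NULL
  out
}

#' Derive per-class score ranges (mean +/- SD, with contiguity correction)
#'
#' Each class's provisional range is `[mean - SD, mean + SD]` of its
#' calibration scores (sample SD, n-1 denominator). Classes are ordered by
#' ascending mean score; overlaps or gaps between adjacent provisional ranges
#' are then corrected by setting each upper class's minimum to the previous
#' class's maximum, so the corrected ranges tile an interval with no gaps or
#' overlaps. For classification the outermost bounds are treated as extended
#' to plus/minus infinity (see [classify_pair()]).
#'
#' @param scores numeric vector of calibration scores.
#' @param classes class label per score (>= 2 seeds per class).
#' @param expected_classes optional set of class labels that must all be
#'   present (the seed pipeline passes `1:5`).
#' @return data.frame of class `class_ranges`, ordered by ascending class
#'   mean: `damage_class`, `low`, `high` (intervals `[low, high)`, last class
#'   closed).
#' @export
derive_class_ranges <- function(scores, classes, expected_classes = NULL) {
  stopifnot(length(scores) == length(classes))
  cls <- sort(unique(classes))
  if (!is.null(expected_classes) && !setequal(cls, expected_classes)) {
    stop("expected classes ", paste(expected_classes, collapse = ","),
         " but found ", paste(cls, collapse = ","))
  }
  if (length(cls) < 2) stop("at least 2 classes are required to derive ranges")
  n <- vapply(cls, function(k) sum(classes == k), 0L)
  if (any(n < 2)) {
    stop("at least 2 seeds per class are required (class ",
         paste(cls[n < 2], collapse = ","), ")")
  }
  m <- vapply(cls, function(k) mean(scores[classes == k]), 0)
  s <- vapply(cls, function(k) stats::sd(scores[classes == k]), 0)
  if (anyDuplicated(m)) stop("tied class mean scores: class order is ambiguous")
  ord <- order(m)
  low <- m[ord] - s[ord]
  high <- m[ord] + s[ord]
  for (i in seq_along(ord)[-1]) low[i] <- high[i - 1] # contiguity correction
  if (any(low >= high)) {
    stop("corrected range collapsed for class ",
         paste(cls[ord][low >= high], collapse = ","))
  }
  structure(data.frame(damage_class = cls[ord], low = low, high = high),
            class = c("class_ranges", "data.frame"))
}

# Map scores to class labels via the corrected range boundaries, with the
# outer ranges extended to +/- infinity so every score classifies.
classify_score <- function(ranges, score) {
  breaks <- c(-Inf, ranges$high[-nrow(ranges)], Inf)
  ranges$damage_class[findInterval(score, breaks, left.open = FALSE,
                                   rightmost.closed = TRUE)]
}

#' Classify a ventral/dorsal score pair
#'
#' Each side's score is mapped to the class whose corrected (extended) range
#' contains it; the seed is then assigned the more severe (numerically
#' larger) of the two side classes under the default `"max"` rule, so the
#' undamaged class is only assigned when both sides fall in its range — the
#' conservative behaviour wanted for the pelleting-quality class. The
#' `"mean"` rule classifies the average of the two side scores instead.
#'
#' @param ranges a `class_ranges` table from [derive_class_ranges()].
#' @param ventral_score,dorsal_score numeric side scores.
#' @param combine `"max"` (default, severity-max) or `"mean"`.
#' @return predicted class label(s).
#' @export
classify_pair <- function(ranges, ventral_score, dorsal_score,
                          combine = c("max", "mean")) {
  combine <- match.arg(combine)
  stopifnot(inherits(ranges, "class_ranges"),
            length(ventral_score) == length(dorsal_score))
  if (combine == "mean") {
    return(classify_score(ranges, (ventral_score + dorsal_score) / 2))
  }
  pmax(classify_score(ranges, ventral_score),
       classify_score(ranges, dorsal_score))
}

#' Classify all seeds from a side-score table
#'
#' @param ranges a `class_ranges` table.
#' @param scores data.frame from [score_seeds()] with `seed_id`, `side`
#'   (`"ventral"`/`"dorsal"`) and `score`; optional `variety_id`,
#'   `true_class` are carried through.
#' @param combine side-combination rule, see [classify_pair()].
#' @return data.frame: `seed_id`, `variety_id`, `ventral_score`,
#'   `dorsal_score`, `predicted_class`, `true_class` (NA when unknown).
#' @export
classify_seeds <- function(ranges, scores, combine = c("max", "mean")) {
  combine <- match.arg(combine)
  stopifnot(all(c("seed_id", "side", "score") %in% names(scores)))
  v <- scores[scores$side == "ventral", ]
  d <- scores[scores$side == "dorsal", ]
  ids <- intersect(v$seed_id, d$seed_id)
  if (!length(ids)) stop("no complete ventral/dorsal pairs found")
  v <- v[match(ids, v$seed_id), ]
  d <- d[match(ids, d$seed_id), ]
  out <- data.frame(
    seed_id = ids,
    variety_id = if ("variety_id" %in% names(v)) v$variety_id else NA_integer_,
    ventral_score = v$score, dorsal_score = d$score,
    predicted_class = classify_pair(ranges, v$score, d$score, combine),
    true_class = if ("true_class" %in% names(v)) v$true_class else NA)
  row.names(out) <- NULL
  out
}

#' Serialize a scoring model and class ranges to a plain-text key-value file
#' @param model a `scoring_model`.
#' @param ranges optional `class_ranges` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_model <- function(model, path, ranges = NULL) {
  num <- function(x) paste(format(x, digits = 17), collapse = " ")
  ln <- c(paste0("feature_names: ", paste(model$feature_names, collapse = " ")),
          paste0("feature_means: ", num(model$feature_means)),
          paste0("feature_sds: ", num(model$feature_sds)),
          paste0("scoring_coefficients: ", num(model$scoring_coefficients)),
          paste0("n_factors_retained: ", model$n_factors_retained))
  if (!is.null(ranges)) {
    ln <- c(ln,
            paste0("range_classes: ", paste(ranges$damage_class, collapse = " ")),
            paste0("range_lows: ", num(ranges$low)),
            paste0("range_highs: ", num(ranges$high)))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a scoring model written by [write_scoring_model()]
#' @param path file path.
#' @return list with `model` (a `scoring_model`) and `ranges` (a
#'   `class_ranges` table or `NULL`).
#' @export
read_scoring_model <- function(path) {
  ln <- readLines(path)
  get <- function(key, numeric = TRUE) {
    row <- ln[startsWith(ln, paste0(key, ":"))]
    if (!length(row)) return(NULL)
    v <- strsplit(sub(paste0("^", key, ": "), "", row), " +")[[1]]
    if (numeric) as.numeric(v) else v
  }
  fn <- get("feature_names", numeric = FALSE)
  model <- structure(
    list(feature_names = fn,
         feature_means = stats::setNames(get("feature_means"), fn),
         feature_sds = stats::setNames(get("feature_sds"), fn),
         scoring_coefficients = get("scoring_coefficients"),
         n_factors_retained = as.integer(get("n_factors_retained")),
         eigenvalues = NULL),
    class = "scoring_model")
  ranges <- NULL
  if (!is.null(get("range_classes"))) {
    ranges <- structure(data.frame(damage_class = get("range_classes"),
                                   low = get("range_lows"),
                                   high = get("range_highs")),
                        class = c("class_ranges", "data.frame"))
  }
  list(model = model, ranges = ranges)
}
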