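# Trainable false-positive score: standardize -> PCA -> convex hull around
# confirmed calls in the (PC1, PC3) plane -> within-hull labelling -> logistic
# GLM on the raw seven metrics. Also the top:second-best support-ratio
# rejection of seeds subject to non-integrase recombination.

#' Train the false-positive scoring model
#'
#' Standardizes the seven metrics, projects onto principal components, draws
#' a convex hull around the confirmed calls in the chosen component plane
#' (by default PC1 vs PC3, which spreads the data more than PC1 vs PC2),
#' labels every call by hull membership, and fits a logistic-link linear
#' model on the raw metrics to predict that label from a random training
#' fraction. The reported score is oriented so that higher means more likely
#' false positive; calls pass when their score is at or below the cutoff
#' (chosen to maximize Youden's J on the training split). Model performance
#' is recorded as the held-out AUROC.
#'
#' @param metrics Matrix or data.frame, one row per call, columns the seven
#'   metrics in canonical order.
#' @param confirmed Logical vector: was the call confirmed by the
#'   comparative-genomic mapper?
#' @param trainFrac Training fraction (default 0.75).
#' @param seed RNG seed for the split.
#' @param hullPlane Integer pair of principal components for the hull.
#' @return An [FpModel-class].
#' @export
trainFpModel <- function(metrics, confirmed, trainFrac = 0.75, seed = 1L,
                         hullPlane = c(1L, 3L)) {
  metrics <- as.matrix(metrics)
  colnames(metrics) <- .FP_METRICS
  n <- nrow(metrics)
  if (n < 50L) stop("need at least 50 labelled metric vectors")
  if (!any(confirmed) || all(confirmed)) stop("need both labels present")
  if (sum(confirmed) < 3L) stop("degenerate hull: fewer than 3 confirmed")
  ctr <- colMeans(metrics)
  scl <- apply(metrics, 2L, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(metrics, 2L, ctr), 2L, scl, "/")
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pts <- pca$x[, hullPlane, drop = FALSE]
  conf <- pts[confirmed, , drop = FALSE]
  hull <- conf[grDevices::chull(conf), , drop = FALSE]
  inHull <- mgcv::in.out(rbind(hull, hull[1L, ]), pts)
  set.seed(seed)
  idx <- sample.int(n)
  nTrain <- max(2L, floor(trainFrac * n))
  tr <- idx[seq_len(nTrain)]
  te <- idx[-seq_len(nTrain)]
  df <- data.frame(y = as.integer(inHull), metrics)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df[tr, , drop = FALSE], family = stats::binomial()))
  eta <- as.numeric(cbind(1, metrics) %*% stats::coef(fit))
  # orient as a false-positive score: higher = more likely false
  fpCoef <- -stats::coef(fit)
  score <- -eta
  # Youden-optimal cutoff on the training split
  thr <- sort(unique(score[tr]))
  youden <- vapply(thr, function(t) {
    pass <- score[tr] <= t
    mean(pass[inHull[tr]]) - mean(pass[!inHull[tr]])
  }, 0)
  cutoff <- thr[which.max(youden)]
  auroc <- if (length(te) && length(unique(inHull[te])) == 2L) {
    as.numeric(pROC::auc(pROC::roc(response = inHull[te],
                                   predictor = -score[te], quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  } else NA_real_
  names(fpCoef) <- c("(Intercept)", .FP_METRICS)
  new("FpModel", coefficients = fpCoef, cutoff = cutoff, auroc = auroc,
      center = ctr, scale = scl, rotation = pca$rotation,
      hullPlane = as.integer(hullPlane), hull = hull)
}

#' Score a call with a trained false-positive model
#'
#' @param v Named numeric of the seven metrics (canonical order), or a
#'   matrix with one row per call.
#' @param model An [FpModel-class].
#' @return data.frame with `score` (higher = more likely false positive) and
#'   `pass` (`score <= cutoff`).
#' @export
fpScore <- function(v, model) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L,
                                   dimnames = list(NULL, names(v)))
  v <- as.matrix(v[, .FP_METRICS, drop = FALSE])
  if (anyNA(v)) stop("missing metric value")
  score <- as.numeric(cbind(1, v) %*% model@coefficients)
  data.frame(score = score, pass = score <= model@cutoff)
}

#' Write / read a false-positive model as JSON
#'
#' @param model An [FpModel-class].
#' @param path JSON file path.
#' @export
writeFpModel <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model serialization requires jsonlite")
  obj <- list(coefficients = as.list(model@coefficients),
              cutoff = model@cutoff, auroc = model@auroc,
              center = as.list(model@center), scale = as.list(model@scale),
              rotation = model@rotation, hullPlane = model@hullPlane,
              hull = model@hull)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFpModel
#' @return `readFpModel` returns the [FpModel-class].
#' @export
readFpModel <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("model serialization requires jsonlite")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FpModel", coefficients = unlist(obj$coefficients),
      cutoff = obj$cutoff, auroc = obj$auroc %||% NA_real_,
      center = unlist(obj$center), scale = unlist(obj$scale),
      rotation = as.matrix(obj$rotation),
      hullPlane = as.integer(obj$hullPlane), hull = as.matrix(obj$hull))
}

#' Reject seeds subject to recombination not due to their integrase
#'
#' Regions of frequent rearrangement by other agents (e.g. integron cassette
#' shuffling) produce many overlapping raw calls for one seed with similar
#' support values. Seeds whose overlapping-call cluster has at least
#' `overlapCutoff` members and a top:second-best support ratio below
#' `ratioCutoff` are rejected, together with their dependent calls.
#'
#' @param calls Raw call data.frame (multiple seeds).
#' @param ratioCutoff Reject when top:second support ratio is below this
#'   (default 4).
#' @param overlapCutoff ...and the overlapping cluster has at least this many
#'   calls (default 5).
#' @return Character vector of rejected seed ids.
#' @export
supportRatioFilter <- function(calls, ratioCutoff = 4, overlapCutoff = 5L) {
  rejected <- character(0)
  for (sd in unique(calls$seed)) {
    g <- calls[calls$seed == sd, , drop = FALSE]
    if (nrow(g) < 2L) next
    top <- which.max(g$support)
    ov <- which(pmax(g$left, g$left[top]) <= pmin(g$right, g$right[top]))
    if (length(ov) < 2L) next
    sup <- sort(g$support[ov], decreasing = TRUE)
    ratio <- sup[1L] / sup[2L]
    if (length(ov) >= overlapCutoff && ratio < ratioCutoff)
      rejected <- c(rejected, sd)
  }
  rejected
}
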