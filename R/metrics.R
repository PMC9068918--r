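#' Per-pixel error rate of a prediction plane
#'
#' Fraction of pixels where the thresholded prediction disagrees with the
#' binary ground truth; equals `1 - accuracy` exactly.
#'
#' @param pred_plane probability (or binary) matrix.
#' @param truth_plane binary matrix of the same shape.
#' @param threshold decision threshold (default 0.5).
#' @export
pixel_error_rate <- function(pred_plane, truth_plane, threshold = 0.5) {
  if (!all(dim(pred_plane) == dim(truth_plane)))
    abort("prediction and truth shapes differ")
  mean((pred_plane > threshold) != (truth_plane > 0.5))
}

#' Depth-classification accuracy and maximum error
#'
#' @param pred_classes,true_classes integer class vectors (bins of 100
#'   micrometers).
#' @return List with `accuracy` (exact-class fraction) and `max_error_um`
#'   (largest class error times 100 micrometers).
#' @export
depth_metrics <- function(pred_classes, true_classes) {
  if (!length(pred_classes) || length(pred_classes) != length(true_classes))
    abort("class vectors must be non-empty and of equal length")
  list(accuracy = mean(pred_classes == true_classes),
       max_error_um = max(abs(pred_classes - true_classes)) * 100)
}

#' Mean normalized deviation of a continuous prediction
#'
#' Mean over pixels of `|pred - truth|` divided by the dynamic range of the
#' truth; the percent pixel-error convention used for the deblurring and
#' depth-map outputs.
#'
#' @param pred,truth numeric matrices of equal shape.
#' @export
mean_normalized_deviation <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) abort("shapes differ")
  rng <- diff(range(truth))
  if (rng <= 0) rng <- 1
  mean(abs(pred - truth)) / rng
}

#' Per-layer sensitivity and specificity
#'
#' Sensitivity is the fraction of ground-truth cell pixels predicted as
#' cells (TP / (TP + FN)); specificity the fraction of ground-truth empty
#' pixels predicted empty (TN / (TN + FP)). Planes without any ground-truth
#' cell pixel have undefined sensitivity and are dropped from the average
#' with a warning.
#'
#' @param pred_planes list of probability planes.
#' @param truth_planes list of binary planes, same shapes.
#' @param threshold decision threshold.
#' @return A `pixel_metrics` list: tibble `per_layer` (layer, error_rate,
#'   sensitivity, specificity) plus averaged `sensitivity`, `specificity`,
#'   `error_rate`.
#' @export
sensitivity_specificity <- function(pred_planes, truth_planes, threshold = 0.5) {
  stopifnot(length(pred_planes) == length(truth_planes))
  rows <- lapply(seq_along(pred_planes), function(k) {
    p <- pred_planes[[k]] > threshold
    t <- truth_planes[[k]] > 0.5
    if (!all(dim(p) == dim(t))) abort("plane shapes differ")
    tp <- sum(p & t); fn <- sum(!p & t)
    tn <- sum(!p & !t); fp <- sum(p & !t)
    tibble::tibble(layer = k,
                   error_rate = (fp + fn) / length(p),
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  per_layer <- dplyr::bind_rows(rows)
  if (anyNA(per_layer$sensitivity))
    warn("plane(s) without ground-truth cell pixels excluded from mean sensitivity")
  structure(list(per_layer = per_layer,
                 sensitivity = mean(per_layer$sensitivity, na.rm = TRUE),
                 specificity = mean(per_layer$specificity, na.rm = TRUE),
                 error_rate = mean(per_layer$error_rate)),
            class = "pixel_metrics")
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf("<pixel_metrics | err %.3f | sens %.3f | spec %.3f>\n",
              x$error_rate, x$sensitivity, x$specificity))
  print(x$per_layer)
  invisible(x)
}

#' Receiver operating characteristic over pooled pixels
#'
#' Pixels are pooled across all planes; the threshold is swept from high to
#' low and the area under the curve computed by the trapezoid rule.
#'
#' @param pred_planes list of probability planes (or one matrix).
#' @param truth_planes matching binary planes.
#' @param n_thresholds number of thresholds in the sweep (>= 2).
#' @return A `roc_curve` list: tibble `points` (threshold, tpr, fpr) and
#'   `auc`.
#' @export
roc_curve <- function(pred_planes, truth_planes, n_thresholds = 101) {
  if (n_thresholds < 2) abort("`n_thresholds` must be >= 2")
  if (is.matrix(pred_planes)) pred_planes <- list(pred_planes)
  if (is.matrix(truth_planes)) truth_planes <- list(truth_planes)
  p <- unlist(lapply(pred_planes, as.numeric))
  t <- unlist(lapply(truth_planes, as.numeric)) > 0.5
  if (all(t) || !any(t))
    abort("ROC undefined: ground truth has a single class",
          class = "degenerate_curve")
  thr <- seq(max(p) + 1e-9, min(p) - 1e-9, length.out = n_thresholds)
  tpr <- vapply(thr, function(th) mean(p[t] > th), numeric(1))
  fpr <- vapply(thr, function(th) mean(p[!t] > th), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = tibble::tibble(threshold = thr, tpr = tpr, fpr = fpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve | %d thresholds | AUC %.3f>\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' @rdname roc_curve
#' @param object a `roc_curve` (for `autoplot`).
#' @param ... unused.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc))
}

#' Average per-layer detector error over a test set
#'
#' Applies [pixel_error_rate()] per sample and layer, then averages per layer
#' over samples (per-sample metric first, then mean).
#'
#' @param pred list (per sample) of lists of probability planes.
#' @param samples the matching dataset samples with `label_planes`.
#' @param threshold decision threshold.
#' @return Numeric vector of 4 per-layer mean error rates.
#' @export
detector_layer_errors <- function(pred, samples, threshold = 0.5) {
  per <- vapply(seq_along(samples), function(i)
    vapply(1:4, function(k)
      pixel_error_rate(pred[[i]][[k]], samples[[i]]$label_planes[[k]],
                       threshold), numeric(1)),
    numeric(4))
  rowMeans(per)
}
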