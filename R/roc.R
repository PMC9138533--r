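# ROC curves, trapezoidal AUC, and vertical curve averaging.

#' ROC curve from scores and binary labels
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped), producing a monotone sequence of (FPR, TPR) points from (0,0)
#' to (1,1), and integrates it by the trapezoid rule. The trapezoidal AUC
#' equals the rank-based (Mann--Whitney) AUC with ties counted 1/2.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Binary labels (0/1, logical, or two-level factor with the
#'   second level as positive).
#' @return An object of class `roc_curve` with `fpr`, `tpr`, `thresholds`
#'   and `auc`.
#' @export
roc_points <- function(scores, labels) {
  y <- to_binary(labels)
  assert_that(length(scores) == length(y), "scores and labels sizes differ")
  assert_that(all(is.finite(scores)), "scores must be finite")
  np <- sum(y == 1); nn <- sum(y == 0)
  assert_that(np > 0 && nn > 0, "both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(yy); fp <- cumsum(1 - yy)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, s[last]), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "False positive rate", ylab = "True positive rate", ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else {
    graphics::lines(x$fpr, x$tpr, ...)
  }
  invisible(x)
}

#' Trapezoidal AUC of a curve or scores
#'
#' @param x A `roc_curve`, or numeric scores (then `labels` is required).
#' @param labels Binary labels when `x` is a score vector.
#' @return The AUC in [0, 1].
#' @export
auc <- function(x, labels = NULL) {
  if (inherits(x, "roc_curve")) return(x$auc)
  roc_points(x, labels)$auc
}

# TPR at arbitrary FPR values by linear interpolation along the polyline;
# vertical segments (repeated FPR) take their upper envelope when a grid
# point hits them exactly and are never interpolated across.
roc_interpolate <- function(roc, fpr_grid) {
  x <- roc$fpr; y <- roc$tpr
  vapply(fpr_grid, function(f) {
    hit <- x == f
    if (any(hit)) return(max(y[hit]))
    i <- findInterval(f, x)
    y[i] + (y[i + 1] - y[i]) * (f - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

#' Vertically average ROC curves on a common FPR grid
#'
#' The fold curves are linearly interpolated at each grid FPR and their
#' TPRs averaged.
#'
#' @param rocs List of `roc_curve` objects.
#' @param fpr_grid Common grid (default 0 to 1 in steps of 0.01).
#' @return A `roc_curve` on the grid; its `auc` is the trapezoidal area of
#'   the averaged curve.
#' @export
average_roc <- function(rocs, fpr_grid = seq(0, 1, by = 0.01)) {
  assert_that(length(rocs) >= 1 && all(vapply(rocs, inherits, logical(1),
                                              "roc_curve")),
              "rocs must be a list of roc_curve objects")
  tprs <- vapply(rocs, roc_interpolate, numeric(length(fpr_grid)), fpr_grid)
  tpr <- rowMeans(tprs)
  auc <- sum(diff(fpr_grid) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(fpr = fpr_grid, tpr = tpr, thresholds = NULL, auc = auc),
            class = "roc_curve")
}
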