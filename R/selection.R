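# Median dichotomization, two-group ANOVA screening and Pearson
# correlation pruning.

#' Dichotomize an outcome at its median
#'
#' Labels a subject `"high"` when its value is greater than or equal to the
#' median and `"low"` otherwise. With an odd number of distinct values the
#' median subject lands in the high group, so 15 distinct values give
#' 7 low / 8 high.
#'
#' @param x Numeric outcome values for >= 4 subjects.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_by_median <- function(x) {
  assert_that(is.numeric(x) && length(x) >= 4,
              "need at least 4 numeric values")
  assert_that(!anyNA(x), "missing outcome values")
  assert_that(max(x) > min(x), "all outcome values identical")
  factor(ifelse(x >= median(x), "high", "low"), levels = c("low", "high"))
}

#' Two-group one-way ANOVA p-value
#'
#' Classic F test with 1 and n-2 degrees of freedom; algebraically
#' identical to the two-sided pooled-variance t-test (F = t^2).
#'
#' @param values Numeric feature values.
#' @param labels Two-level grouping with >= 2 subjects per group.
#' @return The p-value.
#' @export
anova_p <- function(values, labels) {
  labels <- as.factor(labels)
  assert_that(nlevels(droplevels(labels)) == 2, "labels must have two groups")
  assert_that(all(table(labels) >= 2), "each group needs >= 2 subjects")
  assert_that(!anyNA(values), "missing feature values")
  n <- length(values)
  gm <- tapply(values, labels, mean)
  ng <- tapply(values, labels, length)
  ssb <- sum(ng * (gm - mean(values))^2)
  ssw <- sum((values - gm[labels])^2)
  if (ssw <= 0) {
    if (ssb <= 0) stop_pr("degenerate feature: zero variance within and between groups")
    return(0)
  }
  f <- ssb / (ssw / (n - 2))
  pf(f, 1, n - 2, lower.tail = FALSE)
}

#' Screen and prune candidate features
#'
#' Two-stage selection: (1) drop every feature whose two-group ANOVA
#' p-value exceeds `p_threshold` (features with undefined p --- zero
#' variance --- are dropped as degenerate); (2) order the survivors by
#' ascending p (ties broken lexicographically by name) and keep each one
#' greedily unless its absolute Pearson correlation with an already-kept
#' feature exceeds `r_cutoff`. Deterministic, and invariant to the input
#' column order.
#'
#' @param data Data frame holding the candidate feature columns.
#' @param features Character vector of candidate column names (>= 2).
#' @param labels Two-level group labels (e.g. from
#'   [dichotomize_by_median]).
#' @param p_threshold ANOVA screen threshold (default 0.1).
#' @param r_cutoff Pearson pruning cutoff (default 0.5).
#' @param adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust] (default `"none"`, matching the original screen).
#' @return An object of class `selection_result`: `table` (per-feature p,
#'   status, reason), `kept`, `dropped`, and `cor_matrix` over the screen
#'   survivors.
#' @export
select_features <- function(data, features, labels, p_threshold = 0.1,
                            r_cutoff = 0.5, adjust = "none") {
  assert_that(length(features) >= 2, "need at least 2 candidate features")
  assert_that(all(features %in% names(data)),
              paste0("missing feature column(s): ",
                     paste(setdiff(features, names(data)), collapse = ", ")))
  features <- sort(features)
  p <- setNames(rep(NA_real_, length(features)), features)
  for (f in features) {
    v <- data[[f]]
    ok <- !anyNA(v) && var(v) > 0
    if (ok) p[f] <- tryCatch(anova_p(v, labels), error = function(e) NA_real_)
  }
  p_adj <- p
  p_adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = adjust)

  status <- rep("dropped", length(features))
  reason <- character(length(features))
  names(status) <- names(reason) <- features
  reason[is.na(p)] <- "degenerate (zero variance or missing)"
  reason[!is.na(p_adj) & p_adj > p_threshold] <-
    sprintf("p > %g", p_threshold)

  surv <- features[!is.na(p_adj) & p_adj <= p_threshold]
  surv <- surv[order(p_adj[surv], surv)]
  cm <- if (length(surv) >= 2)
    cor(as.matrix(data[surv])) else
    matrix(1, length(surv), length(surv), dimnames = list(surv, surv))
  kept <- character(0)
  for (f in surv) {
    if (length(kept)) {
      r <- abs(cm[f, kept])
      if (any(r > r_cutoff)) {
        culprit <- kept[which.max(r)]
        reason[f] <- sprintf("|r| = %.2f with %s", max(r), culprit)
        next
      }
    }
    kept <- c(kept, f)
    status[f] <- "kept"
    reason[f] <- ""
  }
  structure(list(
    table = data.frame(feature = features, p = unname(p),
                       p_adjusted = unname(p_adj),
                       status = unname(status), reason = unname(reason),
                       stringsAsFactors = FALSE),
    kept = kept,
    dropped = setdiff(features, kept),
    cor_matrix = cm,
    p_threshold = p_threshold, r_cutoff = r_cutoff, adjust = adjust),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection: %d candidates, %d kept (p <= %g, |r| <= %g)\n",
              nrow(x$table), length(x$kept), x$p_threshold, x$r_cutoff))
  if (length(x$kept)) {
    tab <- x$table[x$table$status == "kept", c("feature", "p")]
    tab <- tab[order(tab$p), ]
    for (i in seq_len(nrow(tab)))
      cat(sprintf("  %-24s p = %.4g\n", tab$feature[i], tab$p[i]))
  }
  invisible(x)
}
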