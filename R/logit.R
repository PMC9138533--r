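# Binary logistic inflammation model.
#
# The fit maximizes the Bernoulli log-likelihood with an intercept ("model
# constant") by iteratively reweighted least squares, with an optional
# ridge penalty on the slopes.  Predictors are standardized internally with
# the training data's statistics; coefficients are reported on the original
# scale.  At seven or eight training subjects with several predictors the
# classes are frequently linearly separable; on detection the fit is
# repeated with a small ridge (lambda = 1e-3) and flagged, which keeps
# coefficients finite and runs reproducible.

# IRLS core on a fixed design matrix (first column = intercept).  lambda
# penalizes all columns except the intercept (on the standardized scale).
irls_logistic <- function(X, y, lambda = 0, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      solve(XtW %*% X + pen, XtW %*% z),
      error = function(e) NULL)
    if (is.null(beta_new)) break
    beta_new <- drop(beta_new)
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    if (max(abs(beta)) > 1e8) break
  }
  list(beta = beta, converged = converged, iterations = it)
}

#' Fit a binary logistic model (matrix interface)
#'
#' @param x Numeric matrix or data frame of predictors (subjects x
#'   features); zero columns give an intercept-only model.
#' @param y Binary outcome: 0/1, logical, or a two-level factor (second
#'   level = event).
#' @param lambda Ridge penalty on the standardized slopes (>= 0; 0 = plain
#'   maximum likelihood).
#' @param separation_lambda Fallback ridge applied when (quasi-)separation
#'   is detected at `lambda = 0`.
#' @param standardize Standardize predictors internally (training
#'   statistics; coefficients are mapped back to the input scale).
#' @return An object of class `infl_logit` with coefficients, intercept,
#'   and fitting diagnostics (`converged`, `iterations`, `separation`,
#'   `lambda_used`).
#' @seealso [inflammation_logit()] for the formula interface.
#' @export
fit_logistic <- function(x, y, lambda = 0, separation_lambda = 1e-3,
                         standardize = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(x)) x <- matrix(numeric(0), nrow = length(y), ncol = 0)
  assert_that(is.matrix(x) && is.numeric(x) || ncol(x) == 0,
              "x must be a numeric matrix")
  y <- to_binary(y)
  n <- length(y)
  assert_that(nrow(x) == n, "x and y sizes differ")
  assert_that(length(unique(y)) == 2 || ncol(x) == 0,
              "outcome must contain both classes")
  assert_that(lambda >= 0, "lambda must be >= 0")
  if (ncol(x) > 0) {
    cs <- apply(x, 2, sd)
    assert_that(all(cs > 0), "all-constant predictor column")
  }

  if (ncol(x) == 0) {
    p1 <- mean(y)
    obj <- structure(list(
      coefficients = numeric(0), intercept = qlogis(max(min(p1, 1 - 1e-12), 1e-12)),
      feature_names = character(0), center = numeric(0), scale = numeric(0),
      converged = TRUE, iterations = 0L, separation = FALSE,
      lambda = lambda, lambda_used = lambda, n = n, y = y,
      x = x), class = "infl_logit")
    return(obj)
  }

  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, sd) else rep(1, ncol(x))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  X <- cbind(1, xs)

  fit <- irls_logistic(X, y, lambda = lambda)
  separation <- FALSE
  lambda_used <- lambda
  # diverging standardized slopes => (quasi-)separation
  if (lambda == 0 && (!fit$converged || max(abs(fit$beta[-1])) > 20)) {
    separation <- TRUE
    lambda_used <- separation_lambda
    fit <- irls_logistic(X, y, lambda = lambda_used)
  }

  beta_std <- fit$beta
  slopes <- beta_std[-1] / scl
  intercept <- beta_std[1] - sum(beta_std[-1] * ctr / scl)
  structure(list(
    coefficients = setNames(slopes, colnames(x)),
    intercept = intercept,
    feature_names = colnames(x),
    center = ctr, scale = scl,
    converged = fit$converged, iterations = fit$iterations,
    separation = separation, lambda = lambda, lambda_used = lambda_used,
    n = n, y = y, x = x), class = "infl_logit")
}

to_binary <- function(y) {
  if (is.factor(y)) {
    assert_that(nlevels(droplevels(y)) <= 2, "outcome must be binary")
    as.integer(y == levels(y)[2])
  } else if (is.logical(y)) as.integer(y)
  else {
    assert_that(all(y %in% c(0, 1)), "numeric outcome must be 0/1")
    as.integer(y)
  }
}

#' Fit the lung-inflammation logistic model
#'
#' Formula interface over [fit_logistic()]: the response is a binary
#' inflammation label (e.g. the high/low CD45 group) and the right-hand
#' side lists the selected predictors.
#'
#' @param formula Model formula, e.g.
#'   `group ~ ct_average_gray + NLR + GM_CSF`.
#' @param data Data frame holding response and predictors.
#' @param lambda,separation_lambda,standardize See [fit_logistic()].
#' @return An `infl_logit` object.
#' @examples
#' spec <- cohort_spec(seed = 11)
#' cohort <- generate_tabular_cohort(spec)
#' cohort$NLR <- derive_ratios(cohort)$NLR
#' fit <- inflammation_logit(group ~ NLR + GM_CSF, cohort, lambda = 1e-3)
#' coef(fit)
#' head(predict(fit, type = "response"))
#' @export
inflammation_logit <- function(formula, data, lambda = 0,
                               separation_lambda = 1e-3, standardize = TRUE) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (is.character(y)) y <- factor(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  fit <- fit_logistic(X, y, lambda = lambda,
                      separation_lambda = separation_lambda,
                      standardize = standardize)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit$response_levels <- if (is.factor(y)) levels(droplevels(y)) else c("0", "1")
  fit
}

#' @export
coef.infl_logit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
print.infl_logit <- function(x, ...) {
  cat("Binary logistic inflammation model\n")
  if (!is.null(x$call)) cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("n = %d, lambda = %g%s%s\n", x$n, x$lambda_used,
              if (x$separation) " (ridge fallback: separation detected)" else "",
              if (!x$converged) " [not converged]" else ""))
  print(round(coef(x), 6))
  invisible(x)
}

#' @export
predict.infl_logit <- function(object, newdata = NULL,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) {
    object$x
  } else if (!is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata)
    m <- stats::model.matrix(tt, mf)
    m[, setdiff(colnames(m), "(Intercept)"), drop = FALSE]
  } else {
    as.matrix(newdata[, object$feature_names, drop = FALSE])
  }
  eta <- object$intercept +
    if (length(object$coefficients))
      drop(as.matrix(X[, object$feature_names, drop = FALSE]) %*%
             object$coefficients)
    else 0
  if (type == "link") eta else plogis(eta)
}

#' @export
residuals.infl_logit <- function(object,
                                 type = c("deviance", "pearson", "response"),
                                 ...) {
  type <- match.arg(type)
  mu <- predict(object, type = "response")
  y <- object$y
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(pmax(mu * (1 - mu), 1e-12)),
         deviance = sign(y - mu) *
           sqrt(pmax(-2 * (y * log(pmax(mu, 1e-12)) +
                           (1 - y) * log(pmax(1 - mu, 1e-12))), 0)))
}

#' @export
simulate.infl_logit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object, type = "response")
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, rbinom(length(mu), 1, mu)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
summary.infl_logit <- function(object, ...) {
  k <- length(object$coefficients)
  est <- coef(object)
  if (k > 0) {
    xs <- sweep(sweep(object$x, 2, object$center), 2, object$scale, `/`)
    X <- cbind(1, xs)
    eta <- object$intercept +
      drop(object$x %*% object$coefficients)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- t(X * w) %*% X + diag(c(0, rep(object$lambda_used, k)))
    se_std <- sqrt(diag(solve(info)))
    # map standard errors back to the input scale
    se <- c(NA, se_std[-1] / object$scale)
    se[1] <- se_std[1]  # intercept SE reported on the standardized scale
  } else se <- NA
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, n = object$n,
              separation = object$separation,
              lambda_used = object$lambda_used,
              converged = object$converged)
  class(out) <- "summary.infl_logit"
  out
}

#' @export
print.summary.infl_logit <- function(x, ...) {
  cat(sprintf("Binary logistic inflammation model (n = %d, lambda = %g)\n",
              x$n, x$lambda_used))
  if (x$separation)
    cat("Note: separation detected; ridge-stabilized estimates.\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
plot.infl_logit <- function(x, ...) {
  roc <- roc_points(predict(x, type = "response"), x$y)
  plot(roc, main = "In-sample ROC", ...)
  invisible(roc)
}
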