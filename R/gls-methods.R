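#' @export
print.lsgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic-spatial GLS fit",
      if (x$correlation == "none") "(OLS: alpha = 0)", "\n")
  cat("Call: ", deparse(x$call), "\n\n")
  print(round(x$coefficients, digits))
  if (x$correlation != "none")
    cat(sprintf("\nalpha = %.3f, beta = %.3f, gamma = %.1f km\n",
                x$params[1], x$params[2], x$params[3]))
  cat(sprintf("sigma2 = %.4g, logLik = %.3f, n = %d\n", x$sigma2, x$logLik, x$n))
  invisible(x)
}

#' @export
summary.lsgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tval, `Pr(>|t|)` = object$pval)
  structure(list(call = object$call, coefficients = tab,
                 params = object$params, sigma2 = object$sigma2,
                 logLik = object$logLik, n = object$n,
                 df.residual = object$df.residual,
                 correlation = object$correlation),
            class = "summary.lsgls")
}

#' @export
print.summary.lsgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic-spatial GLS",
      if (x$correlation == "none") "(OLS: alpha = 0)", "\n")
  cat("Call: ", deparse(x$call), "\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  if (x$correlation != "none")
    cat(sprintf("\nCorrelation parameters: alpha = %.3f, beta = %.3f, gamma = %.1f km\n",
                x$params[1], x$params[2], x$params[3]))
  cat(sprintf("sigma2 (ML) = %.4g on n = %d cells; logLik = %.3f\n",
              x$sigma2, x$n, x$logLik))
  invisible(x)
}

#' @export
coef.lsgls <- function(object, ...) object$coefficients

#' @export
logLik.lsgls <- function(object, ...) {
  df <- object$p + 1L + if (object$correlation == "none") 0L else 3L
  structure(object$logLik, df = df, nobs = object$n, class = "logLik")
}

#' @export
vcov.lsgls <- function(object, ...) {
  C <- .fit_correlation(object)
  U <- chol(C)
  tX <- backsolve(U, object$X, transpose = TRUE)
  V <- object$sigma2 * chol2inv(chol(crossprod(tX)))
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

.fit_correlation <- function(object) {
  if (object$correlation == "none") return(diag(1, object$n))
  build_correlation(object$params[1], object$params[2], object$params[3],
                    object$P, object$D)
}

#' Residuals of an lsgls fit
#'
#' @param object an `lsgls` fit.
#' @param type `"response"` (raw), `"standardized"` (divided by the residual
#'   standard deviation; the correlation matrix has unit diagonal so this is
#'   per-cell standardization), or `"whitened"` (decorrelated,
#'   `U^-T r / sigma` with `U` the Cholesky factor of `C`; iid standard
#'   normal under a correctly specified model).
#' @param ... unused.
#' @return numeric vector.
#' @export
residuals.lsgls <- function(object,
                            type = c("response", "standardized", "whitened"),
                            ...) {
  type <- match.arg(type)
  r <- unname(object$residuals)
  if (type == "response") return(r)
  s <- sqrt(object$sigma2)
  # numerically perfect fit: residuals are zero, not zero-over-zero
  if (object$sigma2 <= 1e-14 * stats::var(object$y))
    return(numeric(length(r)))
  switch(type,
         standardized = r / s,
         whitened = unname(object$whitened) / s)
}

#' Predictions from an lsgls fit
#'
#' `type = "fitted"` returns `X b`.  `type = "loo"` returns leave-one-out
#' conditional predictions: each cell's prediction combines its fixed-effect
#' mean with the kriging-style conditional expectation of its residual given
#' the residuals of all other cells,
#' `yhat_i = x_i b + C[i,-i] C[-i,-i]^{-1} (y - X b)[-i]`,
#' computed for all cells at once from the precision matrix.  With `C = I`
#' the conditional term vanishes and both types agree.
#'
#' @param object an `lsgls` fit.
#' @param type `"fitted"` or `"loo"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.lsgls <- function(object, type = c("fitted", "loo"), ...) {
  type <- match.arg(type)
  if (type == "fitted" || object$correlation == "none")
    return(object$fitted.values)
  C <- .fit_correlation(object)
  Ci <- chol2inv(chol(C))
  r <- object$residuals
  drop(object$y - (Ci %*% r) / diag(Ci))
}

#' Simulate responses from a fitted lsgls model
#'
#' Draws from `MVN(X b, sigma2 C)` at the fitted parameter values.
#'
#' @param object an `lsgls` fit.
#' @param nsim number of response vectors.
#' @param seed optional seed (the user RNG stream is restored afterwards
#'   when given).
#' @param ... unused.
#' @return data frame with `nsim` columns.
#' @export
simulate.lsgls <- function(object, nsim = 1, seed = NULL, ...) {
  C <- .fit_correlation(object)
  U <- chol(C)
  draw <- function() {
    z <- stats::rnorm(object$n)
    object$fitted.values + sqrt(object$sigma2) * drop(crossprod(U, z))
  }
  sims <- if (!is.null(seed)) {
    .with_preserved_rng({ set.seed(seed); replicate(nsim, draw()) })
  } else replicate(nsim, draw())
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Likelihood-ratio test between nested lsgls fits
#'
#' `LR = 2 (logLik_full - logLik_reduced)` referred to a chi-square with
#' `df` equal to the number of dropped coefficient columns.  Both models
#' must be maximum-likelihood fits on the same data.  A materially negative
#' LR (optimizer noise) triggers one refit of the reduced model started
#' from the full model's correlation-parameter optimum; tiny negative
#' values are clamped to zero.
#'
#' @param full,reduced `lsgls` fits, reduced nested in full.
#' @param df degrees of freedom; defaults to the difference in coefficient
#'   counts (a k-level factor contributes k - 1).
#' @return list of class `lsgls_lr` with `statistic`, `df`, `p.value`.
#' @export
lr_test <- function(full, reduced, df = NULL) {
  stopifnot(inherits(full, "lsgls"), inherits(reduced, "lsgls"))
  if (full$n != reduced$n) stop("models were fitted to different numbers of cells")
  if (reduced$p > full$p) stop("reduced model is not nested in full (p_reduced > p_full)")
  if (is.null(df)) df <- max(1L, full$p - reduced$p)
  LR <- 2 * (full$logLik - reduced$logLik)
  if (LR < -1e-6 && full$correlation != "none" &&
      reduced$correlation != "none") {
    # a negative LR means one optimizer run found a worse local optimum;
    # restart each model's correlation search from the other's optimum
    restart <- function(m, from) {
      if (!all(is.finite(from))) return(m$logLik)
      ctrl <- m$control
      ctrl$start_params <- rbind(ctrl$start_params,
                                 matrix(unname(from), nrow = 1))
      est <- .lsgls_ml(m$y, m$X, m$P, m$D, ctrl)
      max(m$logLik, -est$nll)
    }
    full$logLik <- restart(full, reduced$params)
    reduced$logLik <- restart(reduced, full$params)
    LR <- 2 * (full$logLik - reduced$logLik)
  }
  if (LR < -1e-4)
    stop("negative likelihood ratio (", signif(LR, 3),
         ") persists after refitting the reduced model")
  LR <- max(0, LR)
  structure(list(statistic = LR, df = df,
                 p.value = stats::pchisq(LR, df, lower.tail = FALSE),
                 logLik_full = full$logLik, logLik_reduced = reduced$logLik),
            class = "lsgls_lr")
}

#' @export
print.lsgls_lr <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: LR = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
anova.lsgls <- function(object, ...) {
  others <- list(...)
  others <- Filter(function(o) inherits(o, "lsgls"), others)
  if (length(others) != 1L)
    stop("anova.lsgls compares exactly two nested lsgls fits")
  m <- list(object, others[[1]])
  ord <- order(vapply(m, `[[`, 0L, "p"))
  reduced <- m[[ord[1]]]; full <- m[[ord[2]]]
  lr <- lr_test(full, reduced)
  out <- data.frame(p = c(reduced$p, full$p),
                    logLik = c(reduced$logLik, full$logLik),
                    LR = c(NA, lr$statistic), df = c(NA, lr$df),
                    `Pr(>Chi)` = c(NA, lr$p.value), check.names = FALSE)
  rownames(out) <- c("reduced", "full")
  structure(out, class = c("anova", "data.frame"),
            heading = "Likelihood ratio test of nested GLS fits")
}

#' Leave-one-out predicted R-squared
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` with `yhat` the
#' leave-one-out conditional predictions of [predict.lsgls()]
#' (`type = "loo"`).  Under the GLS model, predictions borrow strength from
#' the correlated residuals of other cells, so predicted R-squared can
#' exceed the OLS value; the GLS-minus-OLS difference measures how much of
#' the apparent variance explained is carried by spatial autocorrelation
#' and phylogenetic non-independence.  For an OLS fit (`C = I`) this is the
#' classical in-sample R-squared.
#'
#' @param object an `lsgls` fit.
#' @return scalar in `(-Inf, 1]`.
#' @export
predicted_r2 <- function(object) {
  stopifnot(inherits(object, "lsgls"))
  if (object$n < 3L) stop("predicted R2 needs at least 3 cells")
  yhat <- predict(object, type = "loo")
  1 - sum((object$y - yhat)^2) / sum((object$y - mean(object$y))^2)
}

#' Standardized residuals with hotspot flags
#'
#' Residuals are scaled by the residual standard deviation (the correlation
#' matrix has unit diagonal, so all cells share one scale) and flagged when
#' `|r| >= threshold`; cells above the threshold have materially more (or
#' fewer) languages than the model predicts.  Normality of the whitened
#' residuals is assessed with a Shapiro-Wilk test.
#'
#' @param object an `lsgls` fit.
#' @param threshold flag threshold on the standardized scale (default 1.96).
#' @return list with `standardized`, `whitened`, `flag` (+1 / -1 / 0) and
#'   `shapiro_p`.
#' @export
standardized_residuals <- function(object, threshold = 1.96) {
  r <- residuals(object, type = "standardized")
  w <- residuals(object, type = "whitened")
  flag <- integer(length(r))
  flag[r >= threshold] <- 1L
  flag[r <= -threshold] <- -1L
  shapiro_p <- if (length(w) >= 3 && length(w) <= 5000 && stats::sd(w) > 0)
    stats::shapiro.test(w)$p.value else NA_real_
  list(standardized = r, whitened = w, flag = flag, shapiro_p = shapiro_p)
}

#' Diagnostic plots for an lsgls fit
#'
#' Fitted-versus-residual scatter and a normal QQ plot of the whitened
#' residuals.
#'
#' @param x an `lsgls` fit.
#' @param ... passed to plotting functions.
#' @export
plot.lsgls <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$fitted.values, residuals(x, "standardized"),
                 xlab = "fitted", ylab = "standardized residual", ...)
  graphics::abline(h = c(-1.96, 0, 1.96), lty = c(3, 1, 3))
  w <- residuals(x, "whitened")
  stats::qqnorm(w, main = "whitened residuals")
  stats::qqline(w)
  invisible(x)
}
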