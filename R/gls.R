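#' Residual correlation matrix of the phylogenetic-spatial GLS model
#'
#' Assembles `C = (1 - alpha) I + alpha [beta P + (1 - beta) K]` with
#' `K = exp(-(d / gamma)^2)`, the model in which a fraction `alpha` of the
#' residual variance is structured (shared between cells), and of that
#' fraction `beta` follows phylogenetic similarity and `1 - beta` Gaussian
#' spatial decay.  The diagonal is exactly 1 for any admissible parameters.
#'
#' @param alpha,beta proportions in `[0, 1]`.
#' @param gamma spatial decay scale, km (> 0).
#' @param P phylogenetic similarity matrix (e.g. [phylosor_matrix()]).
#' @param D great-circle distance matrix, km.
#' @return correlation matrix with unit diagonal.
#' @export
build_correlation <- function(alpha, beta, gamma, P, D) {
  if (!all(dim(P) == dim(D))) stop("P and D have different dimensions")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  C <- alpha * (beta * P + (1 - beta) * gaussian_decay(D, gamma))
  diag(C) <- diag(C) + (1 - alpha)
  C
}

# Profiled Gaussian likelihood pieces at a given correlation matrix.
# Returns NULL when C cannot be factorized even with a ridge.
.gls_profile <- function(C, y, X, ridge = 1e-10) {
  n <- length(y)
  U <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(U))
    U <- tryCatch(chol(C + diag(ridge, n)), error = function(e) NULL)
  if (is.null(U)) return(NULL)
  ty <- backsolve(U, y, transpose = TRUE)
  tX <- backsolve(U, X, transpose = TRUE)
  XtX <- crossprod(tX)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  b <- drop(chol2inv(R) %*% crossprod(tX, ty))
  names(b) <- colnames(X)
  wres <- drop(ty - tX %*% b)
  sigma2 <- sum(wres^2) / n
  ldet <- 2 * sum(log(diag(U)))
  nll <- if (sigma2 <= 0) -Inf else n / 2 * log(2 * pi * sigma2) + ldet / 2 + n / 2
  list(b = b, sigma2 = sigma2, nll = nll, U = U, wres = wres,
       XtCiX_inv = chol2inv(R))
}

#' Profiled negative log-likelihood of the GLS model
#'
#' For fixed correlation parameters the coefficients and residual variance
#' have closed-form maximum-likelihood solutions, leaving a profiled
#' objective `(n/2) log(2 pi sigma2_hat) + log|C| / 2 + n/2`.  All solves go
#' through the Cholesky factor of `C`; no explicit inverse is formed.
#'
#' @param params numeric `c(alpha, beta, gamma)`.
#' @param y response vector.
#' @param X design matrix (including intercept column).
#' @param P,D similarity and distance matrices as in [build_correlation()].
#' @param ridge diagonal ridge added if the Cholesky factorization fails.
#' @return the negative log-likelihood (scalar).
#' @export
gls_negloglik <- function(params, y, X, P, D, ridge = 1e-10) {
  C <- build_correlation(params[1], params[2], params[3], P, D)
  prof <- .gls_profile(C, y, X, ridge)
  if (is.null(prof))
    stop("correlation matrix is numerically singular even after repair; ",
         "consider heavier grid subsampling")
  prof$nll
}

#' Control parameters for [lsgls()]
#'
#' @param n_starts number of Nelder-Mead restarts, taken from the best
#'   points of the coarse screen.
#' @param reltol convergence tolerance on the objective.
#' @param maxit maximum simplex iterations per start.
#' @param screen_alpha,screen_beta,screen_gamma_mult coarse screening grid;
#'   gamma values are multiples of the median positive inter-cell distance.
#' @param gamma_lower,gamma_upper bounds for gamma, km; the upper default is
#'   5 times the maximum distance.
#' @param jitter_sd standard deviation of the start jitter on the
#'   transformed scale.
#' @param seed seed for the start jitter (the user RNG stream is restored
#'   afterwards).
#' @param ridge diagonal ridge used when a Cholesky factorization fails.
#' @param start_params optional matrix (rows of `c(alpha, beta, gamma)`) of
#'   additional optimizer starts.
#' @return a list of class `lsgls_control`.
#' @export
lsgls_control <- function(n_starts = 5L, reltol = 1e-8, maxit = 2000L,
                          screen_alpha = c(0.05, 0.2, 0.5, 0.8, 0.95),
                          screen_beta = c(0.05, 0.5, 0.95),
                          screen_gamma_mult = c(0.5, 1, 2),
                          gamma_lower = 1, gamma_upper = NULL,
                          jitter_sd = 0.05, seed = 1L, ridge = 1e-10,
                          start_params = NULL) {
  structure(list(n_starts = as.integer(n_starts), reltol = reltol,
                 maxit = as.integer(maxit),
                 screen_alpha = screen_alpha, screen_beta = screen_beta,
                 screen_gamma_mult = screen_gamma_mult,
                 gamma_lower = gamma_lower, gamma_upper = gamma_upper,
                 jitter_sd = jitter_sd, seed = as.integer(seed),
                 ridge = ridge, start_params = start_params),
            class = "lsgls_control")
}

# bijections between the box-constrained correlation parameters and an
# unconstrained optimizer scale
.theta_to_params <- function(theta, lg_lo, lg_hi) {
  c(alpha = stats::plogis(theta[1]),
    beta = stats::plogis(theta[2]),
    gamma = exp(lg_lo + (lg_hi - lg_lo) * stats::plogis(theta[3])))
}
.params_to_theta <- function(params, lg_lo, lg_hi) {
  clamp <- function(p) pmin(1 - 1e-6, pmax(1e-6, p))
  u <- (log(params[3]) - lg_lo) / (lg_hi - lg_lo)
  c(stats::qlogis(clamp(params[1])), stats::qlogis(clamp(params[2])),
    stats::qlogis(clamp(u)))
}

.with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  expr
}

# Maximum-likelihood estimation of (alpha, beta, gamma) by coarse screening
# plus multi-start Nelder-Mead on the transformed scale.
.lsgls_ml <- function(y, X, P, D, control) {
  dpos <- D[upper.tri(D)]
  dmed <- stats::median(dpos[dpos > 0])
  dmax <- max(dpos)
  lg_lo <- log(control$gamma_lower)
  lg_hi <- log(if (is.null(control$gamma_upper)) 5 * dmax else control$gamma_upper)
  obj <- function(theta) {
    p <- .theta_to_params(theta, lg_lo, lg_hi)
    C <- build_correlation(p[1], p[2], p[3], P, D)
    prof <- .gls_profile(C, y, X, control$ridge)
    if (is.null(prof) || !is.finite(prof$nll)) return(1e10)
    prof$nll
  }
  screen <- expand.grid(alpha = control$screen_alpha, beta = control$screen_beta,
                        gamma = control$screen_gamma_mult * dmed)
  if (!is.null(control$start_params))
    screen <- rbind(screen, stats::setNames(as.data.frame(control$start_params),
                                            names(screen)))
  thetas <- t(apply(screen, 1, .params_to_theta, lg_lo = lg_lo, lg_hi = lg_hi))
  vals <- apply(thetas, 1, obj)
  ord <- order(vals)
  n_starts <- min(control$n_starts, nrow(thetas))
  starts <- thetas[ord[seq_len(n_starts)], , drop = FALSE]
  jit <- .with_preserved_rng({
    set.seed(control$seed)
    matrix(stats::rnorm(length(starts), sd = control$jitter_sd), nrow(starts))
  })
  starts <- starts + jit
  fits <- lapply(seq_len(nrow(starts)), function(i)
    stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(reltol = control$reltol, maxit = control$maxit)))
  vals_nm <- vapply(fits, `[[`, 0, "value")
  if (all(vals_nm >= 1e10))
    stop("optimizer failed to find a usable correlation matrix from any start; ",
         "consider heavier grid subsampling")
  best <- fits[[which.min(vals_nm)]]
  # polish: restart the simplex from the incumbent until no further gain
  for (round in 1:3) {
    again <- stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(reltol = control$reltol,
                                         maxit = control$maxit))
    if (again$value < best$value - 1e-9) best <- again else break
  }
  params <- .theta_to_params(best$par, lg_lo, lg_hi)
  list(params = params, nll = best$value,
       converged = best$convergence == 0L,
       n_starts = nrow(starts), screen_best = vals[ord[1]])
}

#' Fit a phylogenetic-spatial generalized least squares model
#'
#' Fits a linear model by maximum likelihood with residual correlation
#' `(1 - alpha) I + alpha [beta P + (1 - beta) exp(-(d/gamma)^2)]` between
#' grid cells, where `P` is phylogenetic (PhyloSor) similarity and `d`
#' great-circle distance.  The correlation parameters are estimated by
#' derivative-free multi-start optimization with coefficients and residual
#' variance profiled out; `correlation = "none"` pins `alpha = 0`, which
#' collapses the fit to ordinary least squares (closed form).
#'
#' @param formula model formula; the response is used as given (log
#'   transforms go in the formula or upstream).
#' @param data data frame (typically a cell table) with one row per grid
#'   cell, aligned with `P` and `D`.
#' @param P phylogenetic similarity matrix; rows/cols in `data` order.
#' @param D distance matrix, km; same order.
#' @param correlation `"phylospatial"` (default) or `"none"` (OLS).
#' @param params optional fixed `c(alpha, beta, gamma)`; skips estimation
#'   and profiles the linear part at these values.
#' @param control an [lsgls_control()] list.
#' @return an object of class `lsgls`: coefficients, standard errors,
#'   t and two-sided p values (df = n - p), `sigma2`, estimated `params`,
#'   log-likelihood, fitted values and residuals, with the usual
#'   `print`/`summary`/`coef`/`logLik`/`vcov`/`residuals`/`predict`/
#'   `simulate`/`anova` methods.
#' @examples
#' sim <- simulate_language_data(synth_config(seed = 2, n_families = 12))
#' fit <- lsgls(log_diversity ~ temp_seasonality + land_fraction,
#'              data = sim$cells, P = sim$P, D = sim$D)
#' summary(fit)
#' @export
lsgls <- function(formula, data, P = NULL, D = NULL,
                  correlation = c("phylospatial", "none"),
                  params = NULL, control = lsgls_control()) {
  correlation <- match.arg(correlation)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient (collinear predictors): ",
         paste(colnames(X), collapse = ", "))
  }
  if (n < p + 1L) stop("need at least rank(X) + 1 observations")

  if (correlation == "phylospatial") {
    if (is.null(P) || is.null(D)) stop("phylospatial correlation needs P and D")
    P <- as.matrix(P); D <- as.matrix(D)
    if (!all(dim(P) == n) || !all(dim(D) == n))
      stop("P and D must be n x n matrices aligned with data rows")
  }

  if (correlation == "none") {
    prof <- .gls_profile(diag(1, n), y, X)
    est <- list(params = c(alpha = 0, beta = 0, gamma = NA_real_),
                nll = prof$nll, converged = TRUE, n_starts = 0L)
  } else if (!is.null(params)) {
    stopifnot(length(params) == 3)
    C <- build_correlation(params[1], params[2], params[3], P, D)
    prof <- .gls_profile(C, y, X, control$ridge)
    if (is.null(prof))
      stop("correlation matrix is numerically singular even after repair; ",
           "consider heavier grid subsampling")
    est <- list(params = c(alpha = params[1], beta = params[2], gamma = params[3]),
                nll = prof$nll, converged = TRUE, n_starts = 0L)
  } else {
    est <- .lsgls_ml(y, X, P, D, control)
    C <- build_correlation(est$params[1], est$params[2], est$params[3], P, D)
    prof <- .gls_profile(C, y, X, control$ridge)
  }

  se <- stats::setNames(sqrt(prof$sigma2 * diag(prof$XtCiX_inv)), names(prof$b))
  tval <- prof$b / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  fitted <- drop(X %*% prof$b)
  structure(list(
    coefficients = prof$b, se = se, tval = tval, pval = pval,
    sigma2 = prof$sigma2, params = est$params,
    logLik = -prof$nll, n = n, p = p, df.residual = n - p,
    fitted.values = fitted, residuals = y - fitted,
    whitened = prof$wres,
    correlation = correlation, converged = est$converged,
    y = y, X = X, P = if (correlation == "none") NULL else P,
    D = if (correlation == "none") NULL else D,
    control = control, call = match.call(),
    terms = attr(mf, "terms"), xlevels = stats::.getXlevels(attr(mf, "terms"), mf)
  ), class = "lsgls")
}

#' Ordinary least squares fit in the lsgls framework
#'
#' Convenience wrapper: [lsgls()] with `correlation = "none"` (alpha pinned
#' at 0).  Coefficients equal the textbook closed form; `sigma2` is the
#' maximum-likelihood estimate (divisor n), consistent with the GLS fits it
#' is compared against.
#'
#' @inheritParams lsgls
#' @return an `lsgls` object.
#' @export
lsgls_ols <- function(formula, data, control = lsgls_control()) {
  cl <- match.call()
  out <- lsgls(formula, data, correlation = "none", control = control)
  out$call <- cl
  out
}
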