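# Beta regression in the mean-precision parameterization, fitted by maximum
# likelihood. The response y in (0,1) is modelled as
#
#   y ~ Beta(mu * phi, (1 - mu) * phi),   E(y) = mu,
#   Var(y) = mu (1 - mu) / (1 + phi),
#
# with g(mu) = x' beta through a Cauchy (default), logit or probit mean link
# and log(phi) = z' gamma through a log precision link. The Cauchy link
# g(mu) = tan(pi (mu - 1/2)) is the standard Cauchy quantile function; its
# heavy tails let fitted means saturate slowly toward 0/1, which suits
# canopy fractions that sit near their observed maximum in most years.

.kb_link <- function(link) {
  link <- match.arg(link, c("cauchy", "logit", "probit"))
  obj <- stats::make.link(switch(link, cauchy = "cauchit", link))
  obj$name <- link
  obj
}

#' Cauchy mean link and its inverse
#'
#' `cauchy_link()` maps a mean in (0, 1) to the real line via the standard
#' Cauchy quantile function, `eta = tan(pi * (mu - 1/2))`;
#' `inverse_cauchy_link()` maps back via the Cauchy CDF,
#' `mu = atan(eta) / pi + 1/2`.
#'
#' @param mu mean value(s) strictly inside (0, 1).
#' @param eta linear predictor value(s).
#' @return numeric vector.
#' @export
cauchy_link <- function(mu) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must be strictly inside (0, 1)")
  qcauchy(mu)
}

#' @rdname cauchy_link
#' @export
inverse_cauchy_link <- function(eta) pcauchy(eta)

# log-density sum of the beta likelihood; -Inf signals an invalid point
.kb_loglik <- function(y, mu, phi) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1) ||
      any(!is.finite(phi)) || any(phi <= 0)) return(-Inf)
  sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' Beta log-likelihood for a model specification
#'
#' Evaluates the beta-regression log-likelihood at given coefficients: the
#' mean submodel through the chosen link and the precision submodel through
#' a log link.
#'
#' @param beta mean-submodel coefficients (length `ncol(X)`).
#' @param gamma precision-submodel coefficients on the log scale (length
#'   `ncol(Z)`); a single value means constant precision `phi = exp(gamma)`.
#' @param y response in (0, 1).
#' @param X mean-submodel design matrix.
#' @param Z precision-submodel design matrix (default intercept only).
#' @param link mean link: `"cauchy"`, `"logit"` or `"probit"`.
#' @return scalar log-likelihood (`-Inf` outside the parameter space).
#' @export
betareg_loglik <- function(beta, gamma, y, X, Z = matrix(1, length(y), 1),
                           link = "cauchy") {
  lk <- .kb_link(link)
  mu <- lk$linkinv(drop(X %*% beta))
  phi <- exp(drop(Z %*% gamma))
  .kb_loglik(y, mu, phi)
}

# analytic score of the loglik in (beta, gamma); mu/phi mildly clamped so
# the gradient stays finite while the optimizer skirts the boundary
.kb_score <- function(theta, y, X, Z, lk) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  mu <- pmin(pmax(lk$linkinv(eta), 1e-12), 1 - 1e-12)
  phi <- pmin(exp(drop(Z %*% theta[-seq_len(p)])), 1e12)
  ystar <- qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gb <- drop(crossprod(X, phi * (ystar - mustar) * lk$mu.eta(eta)))
  dphi <- mu * (ystar - mustar) + log(1 - y) -
    digamma((1 - mu) * phi) + digamma(phi)
  gg <- drop(crossprod(Z, dphi * phi))
  c(gb, gg)
}

#' Beta regression with a Cauchy mean link
#'
#' Fits a beta regression by maximum likelihood. The two-part formula
#' `y ~ x | z` specifies the mean submodel before the bar and the precision
#' submodel (log link) after it; `y ~ x` fits constant precision. Estimation
#' uses BFGS with the analytic score, starting from least squares on the
#' link-transformed response with a method-of-moments precision. Standard
#' errors come from the inverse observed information (numerical Hessian at
#' the optimum) and p-values are two-sided Wald tests against the standard
#' normal.
#'
#' @param formula model formula, optionally two-part (`y ~ x | z`).
#' @param data data.frame holding the variables.
#' @param link mean link function: `"cauchy"` (default), `"logit"` or
#'   `"probit"`.
#' @param control list of optimizer settings: `maxit` (default 500),
#'   `reltol` (default 1e-12), `grad_tol` (gradient norm reported against,
#'   default 1e-4).
#' @param start optional starting vector `c(beta, gamma)`.
#' @return an object of class `"kelpbeta"` with components `coefficients`
#'   (list `mean`, `precision`), `se`, `z`, `p`, `loglik`, `df`, `aic`,
#'   `pseudo_r2`, `fitted.values`, `phi`, `converged`, `n` and the model
#'   frame pieces needed by the methods.
#' @seealso [summary.kelpbeta()], [pseudo_r2()], [lrtest_precision()],
#'   [compare_models()]
#' @examples
#' d <- data.frame(x = seq(-2, 2, length.out = 40))
#' d$y <- inverse_cauchy_link(0.3 - 0.8 * d$x) * 0.9 + 0.05
#' fit <- kelpbeta(y ~ x, data = d)
#' coef(fit)
#' @export
kelpbeta <- function(formula, data, link = c("cauchy", "logit", "probit"),
                     control = list(), start = NULL) {
  cl <- match.call()
  lk <- .kb_link(match.arg(link))
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12,
                                 grad_tol = 1e-4), control)

  # split a two-part formula `y ~ x | z`
  rhs <- formula[[3L]]
  if (is.call(rhs) && identical(rhs[[1L]], as.name("|"))) {
    mean_f <- formula
    mean_f[[3L]] <- rhs[[2L]]
    prec_f <- stats::as.formula(call("~", rhs[[3L]]), env = environment(formula))
  } else {
    mean_f <- formula
    prec_f <- ~1
  }
  mt_mean <- terms(mean_f, data = data)
  mt_prec <- terms(prec_f, data = data)
  resp_name <- all.vars(mean_f[[2L]])
  rhs_vars <- setdiff(unique(c(all.vars(mean_f), all.vars(prec_f))), resp_name)
  if (!length(rhs_vars)) rhs_vars <- "1"
  mf <- model.frame(reformulate(rhs_vars, response = mean_f[[2L]]),
                    data = data, na.action = stats::na.omit)
  y <- model.response(mf)
  X <- model.matrix(delete.response(mt_mean), mf)
  Z <- model.matrix(mt_prec, mf)
  n <- length(y)
  p <- ncol(X); q <- ncol(Z)
  if (any(y <= 0 | y >= 1))
    stop("response must lie strictly inside (0, 1); see scale_to_max()")
  if (n < p + q + 1L)
    stop("need at least ", p + q + 1L, " observations for ", p + q,
         " parameters")

  # starting values: OLS on the link scale, method-of-moments precision
  if (is.null(start)) {
    gy <- lk$linkfun(y)
    b0 <- qr.coef(qr(X), gy)
    b0[is.na(b0)] <- 0
    mu0 <- pmin(pmax(lk$linkinv(drop(X %*% b0)), 0.01), 0.99)
    v0 <- mean((y - mu0)^2)
    phi0 <- max(mean(mu0 * (1 - mu0)) / max(v0, 1e-8) - 1, 1.1)
    start <- c(b0, log(phi0), rep(0, q - 1L))
  }
  stopifnot(length(start) == p + q)

  negll <- function(theta) {
    mu <- lk$linkinv(drop(X %*% theta[seq_len(p)]))
    phi <- exp(drop(Z %*% theta[-seq_len(p)]))
    ll <- .kb_loglik(y, mu, phi)
    if (!is.finite(ll)) 1e10 else -ll
  }
  neggr <- function(theta) -.kb_score(theta, y, X, Z, lk)

  opt <- optim(start, negll, neggr, method = "BFGS",
               control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  theta <- opt$par
  grad <- .kb_score(theta, y, X, Z, lk)
  converged <- opt$convergence == 0L && all(is.finite(grad))

  H <- tryCatch(optimHess(theta, negll, neggr), error = function(e) NULL)
  vc <- if (!is.null(H))
    tryCatch(solve(H), error = function(e) NULL) else NULL
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    se <- rep(NA_real_, p + q)
    vc <- matrix(NA_real_, p + q, p + q)
    converged <- FALSE
  } else {
    se <- sqrt(diag(vc))
  }

  beta <- theta[seq_len(p)]; gamma <- theta[-seq_len(p)]
  names(beta) <- colnames(X)
  names(gamma) <- paste0("(phi)_", colnames(Z))
  nm <- c(names(beta), names(gamma))
  names(se) <- nm
  dimnames(vc) <- list(nm, nm)
  zval <- theta / se
  pval <- 2 * pnorm(-abs(zval))
  names(zval) <- names(pval) <- nm

  eta <- drop(X %*% beta)
  mu <- lk$linkinv(eta)
  phi <- exp(drop(Z %*% gamma))
  loglik <- .kb_loglik(y, mu, phi)
  k <- p + q
  gy <- lk$linkfun(y)
  pr2 <- if (stats::var(eta) == 0 || stats::var(gy) == 0) 0
  else cor(eta, gy)^2

  structure(list(
    coefficients = list(mean = beta, precision = gamma),
    se = se, z = zval, p = pval, vcov = vc,
    loglik = loglik, df = k, aic = -2 * loglik + 2 * k,
    pseudo_r2 = pr2,
    fitted.values = mu, eta = eta, phi = phi, y = y, X = X, Z = Z,
    link = lk$name, linkobj = lk,
    n = n, converged = converged, grad = grad,
    optim = opt[c("convergence", "counts")],
    formula = formula, terms = list(mean = mt_mean, precision = mt_prec),
    call = cl
  ), class = "kelpbeta")
}

#' @export
print.kelpbeta <- function(x, digits = 4, ...) {
  cat("Beta regression (", x$link, " mean link)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Mean submodel coefficients:\n")
  print(round(x$coefficients$mean, digits))
  cat("Precision submodel (log link):\n")
  print(round(x$coefficients$precision, digits))
  cat(sprintf("\nlogLik: %.4f  AIC: %.4f  pseudo-R2: %.4f  n: %d%s\n",
              x$loglik, x$aic, x$pseudo_r2, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Summarize a beta regression fit
#'
#' @param object a [kelpbeta()] fit.
#' @param ... unused.
#' @return a `"summary.kelpbeta"` object with Wald coefficient tables for
#'   the mean and precision submodels.
#' @export
summary.kelpbeta <- function(object, ...) {
  p <- length(object$coefficients$mean)
  tab <- cbind(Estimate = unlist(object$coefficients, use.names = FALSE),
               `Std. Error` = object$se, `z value` = object$z,
               `Pr(>|z|)` = object$p)
  rownames(tab) <- names(object$se)
  structure(list(call = object$call, link = object$link,
                 mean_table = tab[seq_len(p), , drop = FALSE],
                 precision_table = tab[-seq_len(p), , drop = FALSE],
                 loglik = object$loglik, aic = object$aic,
                 pseudo_r2 = object$pseudo_r2, n = object$n,
                 converged = object$converged),
            class = "summary.kelpbeta")
}

#' @export
print.summary.kelpbeta <- function(x, digits = 4, ...) {
  cat("Beta regression (", x$link, " mean link)\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\nMean submodel:\n")
  stats::printCoefmat(x$mean_table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nPrecision submodel (log link):\n")
  stats::printCoefmat(x$precision_table, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nlogLik: %.4f  AIC: %.4f  pseudo-R2: %.4f  n: %d%s\n",
              x$loglik, x$aic, x$pseudo_r2, x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.kelpbeta <- function(object, model = c("full", "mean", "precision"),
                          ...) {
  model <- match.arg(model)
  switch(model,
         full = c(object$coefficients$mean, object$coefficients$precision),
         mean = object$coefficients$mean,
         precision = object$coefficients$precision)
}

#' @export
vcov.kelpbeta <- function(object, ...) object$vcov

#' @export
logLik.kelpbeta <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n,
            class = "logLik")
}

#' @export
nobs.kelpbeta <- function(object, ...) object$n

#' @export
fitted.kelpbeta <- function(object, ...) object$fitted.values

#' Predictions from a beta regression fit
#'
#' @param object a [kelpbeta()] fit.
#' @param newdata optional data.frame; defaults to the fitting data.
#' @param type `"response"` (mean mu), `"link"` (linear predictor),
#'   `"precision"` (phi) or `"variance"` (`mu (1 - mu) / (1 + phi)`).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.kelpbeta <- function(object, newdata = NULL,
                             type = c("response", "link", "precision",
                                      "variance"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$eta; phi <- object$phi
  } else {
    X <- model.matrix(delete.response(object$terms$mean),
                      model.frame(delete.response(object$terms$mean), newdata))
    Z <- model.matrix(object$terms$precision,
                      model.frame(object$terms$precision, newdata))
    eta <- drop(X %*% object$coefficients$mean)
    phi <- exp(drop(Z %*% object$coefficients$precision))
  }
  mu <- object$linkobj$linkinv(eta)
  switch(type, response = mu, link = eta, precision = phi,
         variance = mu * (1 - mu) / (1 + phi))
}

#' Residuals of a beta regression fit
#'
#' @param object a [kelpbeta()] fit.
#' @param type `"response"` (`y - mu`) or `"pearson"` (response residual
#'   divided by the model standard deviation).
#' @param ... unused.
#' @return numeric vector.
#' @export
residuals.kelpbeta <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted.values
  if (type == "pearson")
    r <- r / sqrt(object$fitted.values * (1 - object$fitted.values) /
                    (1 + object$phi))
  r
}

#' Simulate responses from a fitted beta regression
#'
#' @param object a [kelpbeta()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed passed to [set.seed()].
#' @param ... unused.
#' @return data.frame with `nsim` columns of Beta draws at the fitted mean
#'   and precision.
#' @export
simulate.kelpbeta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values; phi <- object$phi
  out <- as.data.frame(replicate(nsim,
    rbeta(length(mu), mu * phi, (1 - mu) * phi)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a beta regression fit against its first covariate
#'
#' Scatter of the observed response against the first non-intercept
#' mean-submodel covariate with the fitted mean curve.
#'
#' @param x a [kelpbeta()] fit.
#' @param ... passed to [plot()].
#' @export
plot.kelpbeta <- function(x, ...) {
  Xc <- x$X[, setdiff(colnames(x$X), "(Intercept)"), drop = FALSE]
  if (ncol(Xc) == 0L) {
    plot(x$y, ylab = "response", xlab = "index", ...)
    graphics::abline(h = x$fitted.values[1L], col = 2)
    return(invisible(x))
  }
  v <- Xc[, 1L]
  o <- order(v)
  plot(v, x$y, xlab = colnames(Xc)[1L], ylab = "response",
       ylim = c(0, 1), ...)
  lines(v[o], x$fitted.values[o], col = 2, lwd = 2)
  invisible(x)
}

#' Pseudo-R-squared of a beta regression fit
#'
#' The squared Pearson correlation between the fitted linear predictor and
#' the link-transformed response, using the same link as the fit. Defined
#' as 0 for an intercept-only model.
#'
#' @param fit a [kelpbeta()] fit.
#' @return scalar in \[0, 1\].
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(inherits(fit, "kelpbeta"))
  fit$pseudo_r2
}

#' Likelihood-ratio test for precision misspecification
#'
#' Compares a constant-precision fit against a nested fit whose precision
#' depends on covariates (`y ~ x | x`). The statistic
#' `2 * (logLik(full) - logLik(reduced))` is clamped at 0 and referred to a
#' chi-squared distribution with the difference in parameter counts.
#'
#' @param fit_constant the reduced (constant-precision) fit.
#' @param fit_varying the full (covariate-dependent precision) fit on the
#'   same data.
#' @return an `"htest"` with the statistic, df and p-value.
#' @export
lrtest_precision <- function(fit_constant, fit_varying) {
  stopifnot(inherits(fit_constant, "kelpbeta"), inherits(fit_varying, "kelpbeta"))
  if (!fit_constant$converged || !fit_varying$converged)
    stop("refusing to compare non-converged fits")
  if (fit_constant$n != fit_varying$n ||
      !isTRUE(all.equal(fit_constant$y, fit_varying$y)))
    stop("fits are not on the same observations")
  if (!isTRUE(all.equal(unname(fit_constant$X), unname(fit_varying$X))))
    stop("mean submodels differ; models are not nested in precision only")
  df <- fit_varying$df - fit_constant$df
  if (df < 0) stop("the varying-precision model must not have fewer parameters")
  stat <- max(0, 2 * (fit_varying$loglik - fit_constant$loglik))
  if (df == 0L) {
    # identical specifications: degenerate comparison, no evidence either way
    if (!isTRUE(all.equal(unname(fit_constant$Z), unname(fit_varying$Z))))
      stop("models have equal parameter counts but different precision terms")
    stat <- 0
  }
  structure(list(
    statistic = c(LR = stat), parameter = c(df = df),
    p.value = if (df == 0L) 1 else pchisq(stat, df, lower.tail = FALSE),
    method = "Likelihood-ratio test of precision misspecification",
    data.name = paste(deparse(fit_constant$formula), "vs",
                      deparse(fit_varying$formula))
  ), class = "htest")
}

#' Rank beta regression fits by AIC
#'
#' Orders fits by AIC and flags every fit within `delta` of the minimum as
#' co-best (competing fits closer than 1 AIC unit are conventionally not
#' distinguished).
#'
#' @param fits named list of [kelpbeta()] fits on the same response rows.
#' @param delta AIC margin for co-best models (default 1).
#' @return data.frame ordered by AIC with columns `model`, `loglik`, `df`,
#'   `aic`, `delta_aic`, `co_best`.
#' @export
compare_models <- function(fits, delta = 1) {
  if (inherits(fits, "kelpbeta")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "kelpbeta")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model_", seq_along(fits))
  if (any(!vapply(fits, `[[`, TRUE, "converged")))
    stop("refusing to rank non-converged fits")
  ns <- vapply(fits, `[[`, 0L, "n")
  if (length(unique(ns)) != 1L)
    stop("fits have different sample sizes; not comparable by AIC")
  y1 <- fits[[1L]]$y
  same <- vapply(fits, function(f) isTRUE(all.equal(f$y, y1)), TRUE)
  if (!all(same)) stop("fits are not on the same response rows")
  aic <- vapply(fits, `[[`, 0, "aic")
  out <- data.frame(model = names(fits),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    df = vapply(fits, `[[`, 0L, "df"),
                    aic = aic, delta_aic = aic - min(aic))
  out$co_best <- out$delta_aic < delta
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  out
}
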