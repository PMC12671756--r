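# The beta-regression core: links, likelihood, fitting, pseudo-R2,
# precision LR test and AIC ranking.

test_that("Cauchy link and inverse are mutual inverses with known points", {
  expect_equal(cauchy_link(0.5), 0)
  expect_equal(inverse_cauchy_link(1), 0.75)
  expect_equal(inverse_cauchy_link(cauchy_link(0.2)), 0.2, tolerance = 1e-12)
  expect_equal(cauchy_link(0.75), tan(pi * 0.25), tolerance = 1e-12)
  expect_error(cauchy_link(1), "strictly inside")
})

test_that("log-likelihood matches the direct log-gamma form", {
  # Beta(1,1) is Uniform(0,1): loglik 0
  expect_equal(betareg_loglik(0, log(2), y = 0.5, X = matrix(1)), 0)

  d <- toy_beta_data()
  X <- cbind(1, d$x)
  ll <- betareg_loglik(c(0.3, -0.8), log(8), d$y, X, link = "cauchy")
  direct <- direct_beta_loglik(0.3, -0.8, log(8), d$x, d$y,
                               function(e) atan(e) / pi + 0.5)
  expect_equal(ll, direct, tolerance = 1e-10)

  # concentration: with mu = y fixed, loglik increases in phi
  y <- 0.37
  lls <- vapply(c(2, 10, 50, 250), function(phi)
    betareg_loglik(cauchy_link(y), log(phi), y, matrix(1)), numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("intercept-only fit on a symmetric sample gives a zero predictor", {
  y <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  f <- kelpbeta(y ~ 1, data.frame(y = y))
  expect_true(f$converged)
  expect_lt(abs(f$eta[1]), 1e-6)
  expect_equal(pseudo_r2(f), 0)
})

test_that("the MLE beats the generating parameters on the toy data", {
  d <- toy_beta_data()
  f <- kelpbeta(y ~ x, d)
  expect_true(f$converged)
  expect_gte(f$loglik, direct_beta_loglik(0.3, -0.8, log(8), d$x, d$y,
                                          function(e) atan(e) / pi + 0.5))
  # score approximately zero at the optimum
  expect_lt(max(abs(f$grad)), 1e-4)
  # AIC identity
  expect_equal(f$aic, -2 * f$loglik + 2 * f$df)
})

test_that("parameters are recovered within 3 standard errors at n = 2000", {
  set.seed(71)
  x <- rnorm(2000)
  mu <- inverse_cauchy_link(0.3 - 0.8 * x)
  y <- rbeta(2000, mu * 20, (1 - mu) * 20)
  f <- kelpbeta(y ~ x, data.frame(x = x, y = y))
  expect_true(f$converged)
  est <- coef(f)
  truth <- c(0.3, -0.8, log(20))
  expect_true(all(abs(est - truth) <= 3 * f$se))
})

test_that("fits agree with an independent quasi-Newton oracle", {
  d <- toy_beta_data()
  for (lk in c("cauchy", "logit")) {
    linkinv <- if (lk == "cauchy") function(e) atan(e) / pi + 0.5 else
      function(e) 1 / (1 + exp(-e))
    f <- kelpbeta(y ~ x, d, link = lk)
    oracle <- stats::nlminb(c(0, 0, 1), function(th)
      -direct_beta_loglik(th[1], th[2], th[3], d$x, d$y, linkinv))
    expect_equal(f$loglik, -oracle$objective, tolerance = 1e-6)
  }
})

test_that("pseudo-R2 is the squared link-scale correlation", {
  # exact linearity on the link scale: pseudo-R2 1
  x <- seq(-2, 2, length.out = 30)
  d <- data.frame(x = x, y = inverse_cauchy_link(0.2 - 0.6 * x))
  f <- kelpbeta(y ~ x, d)
  expect_equal(pseudo_r2(f), 1, tolerance = 1e-6)

  set.seed(13)
  mu <- inverse_cauchy_link(0.2 - 0.6 * x)
  d2 <- data.frame(x = x, y = rbeta(30, mu * 10, (1 - mu) * 10))
  f2 <- kelpbeta(y ~ x, d2)
  expect_equal(pseudo_r2(f2), cor(f2$eta, tan(pi * (d2$y - 0.5)))^2,
               tolerance = 1e-12)
  expect_gte(pseudo_r2(f2), 0)
  expect_lte(pseudo_r2(f2), 1)
})

test_that("precision LR test is degenerate on identical models and detects
          strong precision trends", {
  set.seed(31)
  x <- rnorm(300); mu <- inverse_cauchy_link(0.1 - 0.4 * x)
  d <- data.frame(x = x, y = rbeta(300, mu * 15, (1 - mu) * 15))
  f0 <- kelpbeta(y ~ x, d)
  same <- lrtest_precision(f0, kelpbeta(y ~ x, d))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  f1 <- kelpbeta(y ~ x | x, d)
  lr <- lrtest_precision(f0, f1)
  expect_gte(unname(lr$statistic), 0)
  expect_equal(unname(lr$parameter["df"]), 1)
  # AIC bookkeeping: AIC difference is 2 * extra params - LR
  expect_equal(f1$aic - f0$aic, 2 - unname(lr$statistic), tolerance = 1e-8)

  # power: precision strongly dependent on the covariate, n = 1000
  set.seed(32)
  x2 <- rnorm(1000); mu2 <- inverse_cauchy_link(0.1 - 0.4 * x2)
  phi2 <- exp(3 + 1.2 * x2)
  y2 <- rbeta(1000, mu2 * phi2, (1 - mu2) * phi2)
  # extreme low-precision draws can underflow to the boundary; nudge them
  # inside like the 0.01/0.99 scaling rule would
  y2 <- pmin(pmax(y2, 0.001), 0.999)
  d2 <- data.frame(x = x2, y = y2)
  lr2 <- lrtest_precision(kelpbeta(y ~ x, d2), kelpbeta(y ~ x | x, d2))
  expect_lt(lr2$p.value, 0.01)

  expect_error(lrtest_precision(f0, kelpbeta(y ~ x, d[1:200, ])), "same")
})

test_that("AIC ranking flags co-best fits within 1 unit", {
  fake <- function(aic, y) structure(
    list(aic = aic, loglik = -(aic - 2 * 3) / 2, df = 3L, n = length(y),
         y = y, converged = TRUE), class = "kelpbeta")
  y <- (1:10) / 11
  cmp <- compare_models(list(warm = fake(-23.1, y), anom = fake(-27.7, y),
                             days = fake(-27.8, y)))
  expect_equal(cmp$model, c("days", "anom", "warm"))
  expect_equal(cmp$co_best, c(TRUE, TRUE, FALSE))

  single <- compare_models(list(only = fake(10, y)))
  expect_true(single$co_best)
  cmp2 <- compare_models(list(a = fake(10, y), b = fake(20, y)))
  expect_equal(cmp2$co_best, c(TRUE, FALSE))
  expect_error(compare_models(list(a = fake(1, y), b = fake(1, (1:8) / 9))),
               "sample sizes")
})

test_that("methods: predict, residuals, simulate and summary are coherent", {
  set.seed(17)
  x <- rnorm(120); mu <- inverse_cauchy_link(0.2 - 0.7 * x)
  d <- data.frame(x = x, y = rbeta(120, mu * 25, (1 - mu) * 25))
  f <- kelpbeta(y ~ x, d)
  expect_equal(predict(f), fitted(f))
  nd <- data.frame(x = c(-1, 0, 1))
  expect_equal(predict(f, nd, type = "link"),
               coef(f, "mean")[1] + coef(f, "mean")[2] * nd$x,
               ignore_attr = TRUE)
  expect_equal(predict(f, nd),
               inverse_cauchy_link(predict(f, nd, type = "link")))
  expect_equal(residuals(f), d$y - fitted(f))
  rp <- residuals(f, "pearson")
  expect_equal(rp, residuals(f) / sqrt(predict(f, type = "variance")))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(120L, 3L))
  expect_true(all(sims > 0 & sims < 1))
  s <- summary(f)
  expect_s3_class(s, "summary.kelpbeta")
  expect_equal(unname(s$mean_table[, "Estimate"]), unname(coef(f, "mean")))
  expect_equal(AIC(f), f$aic)
  expect_output(print(f), "Cauchy|cauchy")
})

test_that("responses outside (0,1) and undersized data are rejected", {
  expect_error(kelpbeta(y ~ x, data.frame(x = 1:5, y = c(0.2, 1, 0.3, 0.4, 0.5))),
               "strictly inside")
  expect_error(kelpbeta(y ~ x, data.frame(x = 1:3, y = c(0.2, 0.4, 0.5))),
               "observations")
})
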