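# Shared in-code fixtures for the test suite. Everything is generated at
# test time; the only stored data are the published sub-region summary
# numbers under inst/extdata.

# a deterministic noise-free seasonal SST table with one +2 degC event that
# fills June 2014 exactly
event_sst <- function(zone = "Z1", years = 2010:2015) {
  simulate_sst(zone, years, mean_sst = 10, seasonal_amplitude = 3,
               ar1 = 0, noise_sd = 0,
               events = data.frame(start = as.Date("2014-06-01"),
                                   duration_days = 30, intensity_c = 2),
               seed = 1)
}

# fixed 12-point toy dataset for beta-regression oracles (x and y frozen;
# y was drawn once from the Cauchy-link model at beta0=0.3, beta1=-0.8,
# phi=8 and rounded to 3 decimals)
toy_beta_data <- function() {
  data.frame(
    x = seq(-1.5, 1.5, length.out = 12),
    y = c(0.894, 0.717, 0.625, 0.642, 0.698, 0.293,
          0.579, 0.866, 0.411, 0.649, 0.105, 0.218)
  )
}

# direct beta-regression log-likelihood from the log-gamma form, written
# independently of the package internals
direct_beta_loglik <- function(b0, b1, log_phi, x, y, linkinv) {
  mu <- linkinv(b0 + b1 * x)
  phi <- exp(log_phi)
  sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
        (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log(1 - y))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n1 + n2, n1) group assignments (no ties assumed)
enumerate_wilcoxon_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  w_obs <- sum(outer(a, b, `>`))
  picks <- utils::combn(n1 + n2, n1)
  ws <- apply(picks, 2, function(i)
    sum(outer(pooled[i], pooled[-i], `>`)))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# brute-force Moran's I by explicit double sum
brute_morans_i <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  acc <- 0
  for (i in 1:n) for (j in 1:n) acc <- acc + w[i, j] * z[i] * z[j]
  (n / sum(w)) * acc / sum(z^2)
}

# one shared end-to-end fixture per test run (building it is cheap but not
# free, and several files inspect it)
shared_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- suppressMessages(make_fixture(seed = 99))
    val
  }
})
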