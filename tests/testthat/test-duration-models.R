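test_that("Kaplan-Meier estimates match hand product-limit calculations", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km@time, c(0, 1, 2, 3))
  expect_equal(km@surv, c(1, 2/3, 1/3, 0))
  ## censoring at 2: risk set {3} at t=3, so S drops to 0 there
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2@surv[km2@time == 1], 2/3)
  expect_equal(km2@surv[km2@time == 3], 0)
  ## fully censored input: flat at 1
  km3 <- kmEstimate(c(5, 6), c(0, 0))
  expect_true(all(km3@surv == 1))
  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
  ## with no censoring KM is exactly the empirical survival function
  set.seed(5)
  t <- rlnorm(40, 2, 0.5)
  km4 <- kmEstimate(t, rep(1, 40))
  for (q in quantile(t, c(0.2, 0.5, 0.8))) {
    i <- max(which(km4@time <= q))
    expect_equal(km4@surv[i], mean(t > km4@time[i]), tolerance = 1e-12)
  }
  ## Greenwood band contains the point estimate
  ok <- !is.na(km4@lower) & !is.na(km4@upper)
  expect_true(all(km4@lower[ok] <= km4@surv[ok] + 1e-12))
  expect_true(all(km4@upper[ok] >= km4@surv[ok] - 1e-12))
})

test_that("censored likelihood matches closed forms and a quadrature oracle", {
  ## exponential, all observed: -(n log rate - rate * sum(t))
  t <- c(2, 4, 6)
  expect_equal(negLoglikCensored("exponential", c(rate = 0.25), t, c(1, 1, 1)),
               -(3 * log(0.25) - 0.25 * 12), tolerance = 1e-12)
  ## zero coefficients reduce to the covariate-free likelihood
  X <- cbind(x = c(-1, 0, 2))
  expect_equal(
    negLoglikCensored("lognormal", c(meanlog = 1, sdlog = 0.5), t, c(1, 0, 1), X, 0),
    negLoglikCensored("lognormal", c(meanlog = 1, sdlog = 0.5), t, c(1, 0, 1)),
    tolerance = 1e-12)
  ## independent oracle: hand-coded densities, survival by numeric quadrature
  fix <- data.frame(t = c(1.5, 3, 7, 12, 30), ev = c(1, 0, 1, 1, 0))
  dln <- function(x, m, s) exp(-(log(x) - m)^2 / (2 * s^2)) / (x * s * sqrt(2 * pi))
  dwb <- function(x, k, l) (k / l) * (x / l)^(k - 1) * exp(-(x / l)^k)
  for (case in list(
    list(fam = "lognormal", par = c(meanlog = 1.8, sdlog = 0.7),
         f = function(x) dln(x, 1.8, 0.7)),
    list(fam = "weibull", par = c(shape = 2.181, scale = 34.243),
         f = function(x) dwb(x, 2.181, 34.243)))) {
    oracle <- -sum(vapply(seq_len(nrow(fix)), function(i) {
      if (fix$ev[i] == 1) log(case$f(fix$t[i]))
      else log(1 - stats::integrate(case$f, 0, fix$t[i], rel.tol = 1e-12)$value)
    }, numeric(1)))
    expect_equal(negLoglikCensored(case$fam, case$par, fix$t, fix$ev), oracle,
                 tolerance = 1e-7)
  }
  ## out-of-support parameters are an error, not a clip
  expect_error(negLoglikCensored("weibull", c(shape = -1, scale = 2), t, c(1, 1, 1)),
               "support")
})

test_that("censored exponential MLE equals the events-over-exposure closed form", {
  expect_equal(params(fitFamily("exponential",
    data.frame(duration_min = c(2, 4, 6), event_observed = 1)))[["rate"]],
    0.25, tolerance = 1e-8)
  expect_equal(params(fitFamily("exponential",
    data.frame(duration_min = c(2, 4, 6), event_observed = c(1, 0, 1))))[["rate"]],
    2 / 12, tolerance = 1e-8)
  set.seed(11)
  for (i in 1:5) {
    t <- rexp(60, 0.3)
    ev <- rbinom(60, 1, 0.7)
    f <- fitFamily("exponential", data.frame(duration_min = t, event_observed = ev))
    expect_equal(params(f)[["rate"]], sum(ev) / sum(t), tolerance = 1e-8)
  }
})

test_that("censored fits recover generating parameters and agree with flexsurv", {
  cfg <- quietConfig()
  set.seed(2)
  d <- simulateBoutDurations(cfg, "AS", 3000)
  f <- fitFamily("lognormal", d)
  expect_lt(abs(params(f)[["meanlog"]] - 4.137), 3 * stdErrors(f)[["meanlog"]])
  expect_lt(abs(params(f)[["sdlog"]] - 0.891), 3 * stdErrors(f)[["sdlog"]])

  ## development-time oracle: the established survival-regression package
  set.seed(8)
  n <- 400
  x <- runif(n, -2, 2)
  t <- rlnorm(n, meanlog = 2 + 0.2 * x, sdlog = 0.6)
  ev <- as.integer(t < 15)
  t <- pmin(t, 15)
  df <- data.frame(duration_min = t, event_observed = ev, x = x)
  mine <- fitFamily("lognormal", df, covariateNames = "x",
                    centering = c(x = 0))
  fs <- flexsurv::flexsurvreg(survival::Surv(duration_min, event_observed) ~ x,
                              data = df, dist = "lnorm")
  expect_lt(abs(params(mine)[["meanlog"]] - fs$res["meanlog", "est"]), 1e-4)
  expect_lt(abs(params(mine)[["sdlog"]] - fs$res["sdlog", "est"]), 1e-4)
  expect_lt(abs(coefs(mine)[["x"]] - fs$res["x", "est"]), 1e-4)
  expect_lt(abs(logLik(mine) - fs$loglik), 1e-5)

  tw <- rweibull(n, shape = 1.8, scale = 20 * exp(0.15 * x))
  evw <- as.integer(tw < 30)
  dfw <- data.frame(duration_min = pmin(tw, 30), event_observed = evw, x = x)
  mw <- fitFamily("weibull", dfw, covariateNames = "x", centering = c(x = 0))
  fw <- flexsurv::flexsurvreg(survival::Surv(duration_min, event_observed) ~ x,
                              data = dfw, dist = "weibull")
  expect_lt(abs(params(mw)[["shape"]] - fw$res["shape", "est"]), 1e-4)
  expect_lt(abs(params(mw)[["scale"]] - fw$res["scale", "est"]), 1e-3)
  expect_lt(abs(coefs(mw)[["x"]] - fw$res["x", "est"]), 1e-4)
})

test_that("Weibull likelihood dominates the nested exponential", {
  set.seed(13)
  for (i in 1:6) {
    t <- rweibull(80, shape = runif(1, 0.7, 2.5), scale = 10)
    ev <- rbinom(80, 1, 0.8)
    d <- data.frame(duration_min = t, event_observed = ev)
    expect_gte(logLik(fitFamily("weibull", d)) + 1e-6,
               logLik(fitFamily("exponential", d)))
  }
})

test_that("AFT time-scaling equivariance holds for every family", {
  set.seed(17)
  x <- runif(120, -1, 1)
  t <- rlnorm(120, 2 + 0.3 * x, 0.5)
  ev <- rbinom(120, 1, 0.75)
  d1 <- data.frame(duration_min = t, event_observed = ev, x = x)
  d2 <- transform(d1, duration_min = duration_min * 3)
  cen <- c(x = 0)
  fe1 <- fitFamily("exponential", d1); fe2 <- fitFamily("exponential", d2)
  expect_equal(params(fe2)[["rate"]], params(fe1)[["rate"]] / 3, tolerance = 1e-8)
  fl1 <- fitFamily("lognormal", d1, "x", centering = cen)
  fl2 <- fitFamily("lognormal", d2, "x", centering = cen)
  expect_equal(params(fl2)[["meanlog"]], params(fl1)[["meanlog"]] + log(3),
               tolerance = 1e-4)
  expect_equal(params(fl2)[["sdlog"]], params(fl1)[["sdlog"]], tolerance = 1e-4)
  expect_equal(coefs(fl2)[["x"]], coefs(fl1)[["x"]], tolerance = 1e-4)
  fw1 <- fitFamily("weibull", d1, "x", centering = cen)
  fw2 <- fitFamily("weibull", d2, "x", centering = cen)
  expect_equal(params(fw2)[["scale"]], params(fw1)[["scale"]] * 3, tolerance = 1e-3)
  expect_equal(params(fw2)[["shape"]], params(fw1)[["shape"]], tolerance = 1e-3)
})

test_that("AIC ranking reproduces published-style deltas and breaks ties", {
  ## three candidate fits with the wakefulness AIC triple
  fits <- list(
    fakeFit("lognormal", c(meanlog = 3.187, sdlog = 0.996), 264.629),
    fakeFit("weibull", c(shape = 1.1, scale = 20), 273.282),
    fakeFit("exponential", c(rate = 0.05), 271.608))
  sel <- selectModel(fits)
  expect_equal(sel$ranking$family, c("lognormal", "exponential", "weibull"))
  expect_equal(sel$ranking$delta, c(0, 6.979, 8.653), tolerance = 1e-9)
  ## single fit: delta zero
  expect_equal(selectModel(fits[1])$ranking$delta, 0)
  ## refuse cross-dataset comparison
  other <- fakeFit("exponential", c(rate = 0.1), 100, fingerprint = "different")
  expect_error(selectModel(list(fits[[1]], other)), "identical bout sets")
  ## AIC ties: fewer parameters win, then fixed family order
  tie <- list(fakeFit("lognormal", c(meanlog = 1, sdlog = 1), 200),
              fakeFit("exponential", c(rate = 0.2), 200))
  expect_equal(selectModel(tie)$ranking$family[1], "exponential")
})

test_that("a null covariate never beats the base model under AIC", {
  set.seed(23)
  wins <- 0L
  for (i in 1:8) {
    t <- rlnorm(150, 2, 0.6)
    d <- data.frame(duration_min = t, event_observed = 1,
                    z = runif(150))  # independent of duration
    f0 <- fitFamily("lognormal", d)
    f1 <- fitFamily("lognormal", d, "z", centering = c(z = 0.5))
    ## Delta loglik -> 0 under the null, so the +2 penalty dominates
    if (aic(f1) < aic(f0)) wins <- wins + 1L
  }
  expect_lte(wins, 2L)
})

test_that("tail classification follows the selected family and Weibull shape", {
  expect_equal(classifyTail(fakeFit("lognormal", c(meanlog = 1, sdlog = 1), 50)), "heavy")
  expect_equal(classifyTail(fakeFit("powerlaw", c(exponent = 2.5), 50)), "heavy")
  expect_equal(classifyTail(fakeFit("exponential", c(rate = 1), 50)), "exponential-like")
  expect_equal(classifyTail(fakeFit("weibull", c(shape = 2.181, scale = 34.243), 50)),
               "light")
  expect_equal(classifyTail(fakeFit("weibull", c(shape = 1, scale = 10), 50)),
               "exponential-like")
  expect_warning(
    cls <- classifyTail(fakeFit("weibull", c(shape = 0.8, scale = 10), 50)),
    "shape < 1")
  expect_equal(cls, "heavy")
})

test_that("acceleration factors are exp(coefficient) with Wald intervals", {
  f <- fakeFit("lognormal", c(meanlog = 3, sdlog = 1), 80,
               coefficients = c(pma_weeks = log(1.146)),
               se = c(meanlog = 0.1, sdlog = 0.1, pma_weeks = 0.05))
  af <- accelerationFactor(f, "pma_weeks")
  expect_equal(af[["factor"]], 1.146, tolerance = 1e-12)
  expect_equal(af[["lower"]], exp(log(1.146) - qnorm(0.975) * 0.05), tolerance = 1e-12)
  expect_equal(af[["upper"]], exp(log(1.146) + qnorm(0.975) * 0.05), tolerance = 1e-12)
  f0 <- fakeFit("lognormal", c(meanlog = 3, sdlog = 1), 80,
                coefficients = c(z = 0),
                se = c(meanlog = 0.1, sdlog = 0.1, z = 0.2))
  expect_equal(accelerationFactor(f0, "z")[["factor"]], 1)
  expect_error(accelerationFactor(f, "nope"), "not in fit")
})

test_that("likelihood-ratio test recognises nesting and detects Weibull shape", {
  set.seed(29)
  t <- rweibull(500, shape = 2.181, scale = 34.243)
  d <- data.frame(duration_min = t, event_observed = 1)
  fe <- fitFamily("exponential", d)
  fw <- fitFamily("weibull", d)
  lrt <- likelihoodRatioTest(fe, fw)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  expect_lt(lrt$p.value, 0.05)   # strong shape signal at n = 500
  ## identical models: statistic 0, p 1
  self <- likelihoodRatioTest(fe, fe)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)
  ## non-nested pairs refused
  fl <- fitFamily("lognormal", d)
  expect_error(likelihoodRatioTest(fl, fw), "not nested")
})

test_that("fitted survival curves obey the family closed forms", {
  d <- data.frame(duration_min = c(2, 4, 6), event_observed = 1)
  fe <- fitFamily("exponential", d)   # rate 0.25
  expect_equal(fittedSurvival(fe, times = c(0, 4))@surv, c(1, exp(-1)),
               tolerance = 1e-6)
  fln <- fakeFit("lognormal", c(meanlog = 4.137, sdlog = 0.891), 100)
  expect_equal(fittedSurvival(fln, times = exp(4.137))@surv, 0.5, tolerance = 1e-12)
  fwb <- fakeFit("weibull", c(shape = 2.181, scale = 34.243), 100)
  expect_equal(fittedSurvival(fwb, times = 34.243)@surv, exp(-1), tolerance = 1e-12)
  expect_error(fittedSurvival(fe, times = c(-1, 2)), "negative")
})
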