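test_that("meltEval matches direct evaluation and respects its domain", {
  mp <- MeltParams(3000, 10, 0)
  expect_equal(meltEval(mp, 300), 0.5)           # exp argument is 0
  # independent scalar oracle: logistic evaluation of the same argument
  expect_equal(meltEval(mp, 280), plogis(3000 / 280 - 10))
  expect_equal(meltEval(mp, 280), 0.6713475, tolerance = 1e-6)
  # high-temperature limit: (1-p)/(1+exp(b)) + p, within 1e-3 of the
  # plateau for b = 10
  expect_equal(meltEval(MeltParams(3000, 10, 0.2), 1e10),
               0.8 / (1 + exp(10)) + 0.2, tolerance = 1e-9)
  expect_equal(meltEval(MeltParams(3000, 10, 0.2), 1e10), 0.2,
               tolerance = 1e-3)
  expect_error(meltEval(mp, 0), "domain")
  expect_error(meltEval(mp, -10), "domain")
})

test_that("meltEval is strictly decreasing and bounded in (plateau, 1)", {
  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, 500, 4000); b <- runif(1, 5, 40)
    p <- runif(1, 0, 0.45)
    mp <- MeltParams(a, b, p)
    tg <- seq(10, 120, length.out = 80)
    y <- meltEval(mp, tg)
    # monotone decreasing; strict except where the curve saturates
    # numerically at its asymptotes
    expect_true(all(diff(y) <= 0))
    expect_true(any(diff(y) < 0))
    expect_true(all(y >= p & y <= 1))
    mid <- y > p + 1e-9 & y < 1 - 1e-9
    if (sum(mid) > 2) expect_true(all(diff(y[mid]) < 0))
  }
})

test_that("closed-form melting point equals the bisection root", {
  expect_equal(meltingPoint(MeltParams(3000, 10, 0)), 300)
  expect_equal(meltingPoint(MeltParams(3000, 10, 0.2)),
               bisectTm(3000, 10, 0.2), tolerance = 1e-8)
  expect_equal(meltingPoint(MeltParams(3000, 10, 0.2)), 316.1497,
               tolerance = 1e-4)
  set.seed(11)
  for (i in 1:200) {
    a <- runif(1, 300, 5000); b <- runif(1, 3, 40)
    p <- runif(1, 0, 0.45)
    if (b + log(1 - 2 * p) <= 0) next
    tm <- meltingPoint(MeltParams(a, b, p))
    expect_equal(tm, bisectTm(a, b, p), tolerance = 1e-8)
    expect_equal(meltEval(MeltParams(a, b, p), tm), 0.5, tolerance = 1e-10)
  }
})

test_that("melting point is undefined for plateau >= 0.5", {
  expect_error(meltingPoint(MeltParams(3000, 10, 0.5)), "undefined")
  expect_error(meltingPoint(MeltParams(3000, 10, 0.7)), "undefined")
  # denominator b + log(1 - 2p) <= 0 is also undefined
  expect_error(meltingPoint(MeltParams(3000, 0.5, 0.3)), "undefined")
})

test_that("analytic slope matches numerical differentiation and behaves", {
  mp <- MeltParams(3000, 10, 0)
  expect_equal(meltSlope(mp), -3000 / (4 * 300^2), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:50) {
    a <- runif(1, 500, 4000); b <- runif(1, 5, 40)
    p <- runif(1, 0, 0.45)
    if (b + log(1 - 2 * p) <= 0) next
    mp <- MeltParams(a, b, p)
    tm <- meltingPoint(mp)
    h <- 1e-4
    num <- (meltEval(mp, tm + h) - meltEval(mp, tm - h)) / (2 * h)
    s <- meltSlope(mp)
    expect_lt(s, 0)
    expect_equal(s, num, tolerance = 1e-6)
  }
  # doubling a with b rescaled to hold Tm fixed steepens the transition
  s1 <- meltSlope(MeltParams(3000, 10, 0))
  s2 <- meltSlope(MeltParams(6000, 20, 0))  # same Tm = 300
  expect_equal(meltingPoint(MeltParams(6000, 20, 0)), 300)
  expect_lt(s2, s1)
})

test_that("normalization to the reference temperature", {
  z <- normalizeToReference(c(100, 50, 25), c(30, 50, 70))
  expect_equal(z$fc, c(1, 0.5, 0.25))
  expect_true(is.na(z$reason))
  expect_equal(normalizeToReference(c(7, 7, 7), c(30, 50, 70))$fc,
               c(1, 1, 1))
  z <- normalizeToReference(c(NA, 50, 25), c(30, 50, 70))
  expect_null(z$fc)
  expect_equal(z$reason, "no_reference")
  expect_equal(normalizeToReference(c(0, 5, 2), c(30, 50, 70))$reason,
               "no_reference")
})

test_that("fitMeltCurve recovers noiseless parameters", {
  # Tm of (a=3500, b=11, p=0.1) is ~324.8, so use a gradient spanning
  # that transition
  tt <- seq(280, 380, length.out = 10)
  truth <- MeltParams(3500, 11, 0.1)
  fc <- meltEval(truth, tt)
  fit <- fitMeltCurve(fc, tt)
  expect_true(fit@converged)
  expect_equal(fit@tm, meltingPoint(truth), tolerance = 1e-4)
  expect_gte(fit@r2, 0.9999)
  # all parameters, not just Tm
  expect_equal(fit@params@a, 3500, tolerance = 1e-3)
  expect_equal(fit@params@b, 11, tolerance = 1e-3)
  expect_equal(fit@params@plateau, 0.1, tolerance = 1e-4)
})

test_that("fitMeltCurve under seeded multiplicative noise stays near truth", {
  # steep curve on the ten-point gradient (Tm ~52, slope ~-0.1);
  # tolerance verified by repetition (max error 0.64 over 50 seeded reps)
  tt <- defaultTemperatures
  truth <- MeltParams(1216.8, 23.62, 0.1)
  tmTrue <- meltingPoint(truth)
  set.seed(2024)
  for (i in 1:10) {
    fc <- meltEval(truth, tt) * exp(rnorm(length(tt), 0, 0.03))
    fc <- fc / fc[1]
    fit <- suppressWarnings(fitMeltCurve(fc, tt))
    expect_true(fit@converged)
    expect_lt(abs(fit@tm - tmTrue), 1.0)
  }
})

test_that("non-melting and degenerate inputs never raise mid-pipeline", {
  tt <- defaultTemperatures
  up <- seq(1, 2, length.out = length(tt))  # monotone increasing: no melt
  fit <- suppressWarnings(fitMeltCurve(up, tt))
  expect_false(isTRUE(fit@qcPass))
  few <- fitMeltCurve(c(1, 0.5, 0.2, NA, NA, NA, NA, NA, NA, NA), tt)
  expect_false(few@converged)
  expect_true(is.na(few@tm))
  allna <- fitMeltCurve(rep(NA_real_, 10), tt)
  expect_false(allna@converged)
})

test_that("fitting is invariant to rescaling raw intensities", {
  sim <- smallSim(n = 6, noise = 0.05, seed = 5)
  pq <- sim$quants$control
  f1 <- fitProteome(pq)
  scaled <- ProteomeQuant(intensities(pq) * 73.1, temperatures(pq),
                          condition(pq))
  f2 <- fitProteome(scaled)
  # fold changes agree to rounding (one extra division), so fits do too
  expect_equal(f1$tm, f2$tm, tolerance = 1e-6)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
})

test_that("pairwise stringency QC enumerates every failed criterion", {
  crit <- qcCriteria(r2Min = 0.8, plateauMax = 0.3, slopeMax = -0.01)
  good <- mkFit(52, r2 = 0.95, plateau = 0.1, slope = -0.05)
  expect_true(passesQC(good, good, crit)$pass)
  badPlateau <- mkFit(52, r2 = 0.95, plateau = 0.4, slope = -0.05)
  r <- passesQC(badPlateau, good, crit)
  expect_false(r$pass)
  expect_equal(r$reasons, "plateau")
  badBoth <- mkFit(52, r2 = 0.75, plateau = 0.4, slope = -0.05)
  r <- passesQC(badBoth, good, qcCriteria(r2Min = 0.8, plateauMax = 0.3,
                                          slopeMax = -0.01))
  expect_false(r$pass)
  expect_setequal(r$reasons, c("r2", "plateau"))
  # treatment-side slope failure also fails the pair
  shallow <- mkFit(52, slope = -0.005)
  expect_true("slope" %in% passesQC(good, shallow, crit)$reasons)
})
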