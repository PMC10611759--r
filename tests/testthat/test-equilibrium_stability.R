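test_that("noiseless urea curves invert exactly", {
  cv <- simulateUnfoldingCurve(
    stabilitySimSpec(dG0 = 3, mValue = 1.5, noiseSd = 0, seed = 1),
    seq(0, 6, by = 0.5), temperature = 293.15)
  fit <- fitUreaUnfolding(cv)
  expect_equal(fit@dG0, 3.000, tolerance = 1e-6)
  expect_equal(fit@mValue, 1.500, tolerance = 1e-6)
  # the f_u = 0.5 point sits at dG = 0 (K = 1)
  mid <- fit@pointwise[abs(fit@pointwise$urea_M - 2) < 1e-9, ]
  expect_equal(mid$dG, 0, tolerance = 1e-6)
  # Eq-1 identity: every stored point reproduces -RT ln K
  RT <- GAS_CONSTANT_KCAL * 293.15
  K <- fit@pointwise$fraction_unfolded / (1 - fit@pointwise$fraction_unfolded)
  expect_equal(fit@pointwise$dG, -RT * log(K), tolerance = 1e-9)
})

test_that("urea fit handles sloped baselines and fixed-m mode", {
  cv <- simulateUnfoldingCurve(
    stabilitySimSpec(dG0 = 3, mValue = 1.5,
                     baselines = c(folded = 1, unfolded = 0.1,
                                   foldedSlope = -0.01,
                                   unfoldedSlope = 0.005),
                     noiseSd = 0, seed = 1),
    seq(0, 6, by = 0.4), temperature = 293.15)
  fit <- fitUreaUnfolding(cv)
  expect_equal(fit@dG0, 3, tolerance = 0.01)
  expect_equal(fit@mValue, 1.5, tolerance = 0.01)

  fit_fixed <- fitUreaUnfolding(cv, mValueMode = "fixed", mFixed = 1.5)
  expect_equal(fit_fixed@dG0, 3, tolerance = 0.01)
  expect_identical(fit_fixed@mValue, 1.5)
})

test_that("flat curves without a transition are rejected", {
  flat <- UnfoldingCurve("denaturant_molar", seq(0, 6, by = 1),
                         matrix(seq(1, 0.94, length.out = 7), 7),
                         temperature = 293.15)
  expect_error(fitUreaUnfolding(flat), "transition")
})

test_that("dG0 recovery within 0.2 kcal/mol at 2% noise (median, 100 seeds)", {
  errs <- vapply(1:100, function(seed) {
    cv <- simulateUnfoldingCurve(
      stabilitySimSpec(dG0 = 3, mValue = 1.5, noiseSd = 0.02, seed = seed),
      seq(0, 6, length.out = 12), temperature = 293.15)
    # the simulated curves have flat baselines; fit the matching model
    fit <- tryCatch(fitUreaUnfolding(cv, baselines = "constant"),
                    error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit@dG0 - 3)
  }, 0)
  expect_lte(median(errs, na.rm = TRUE), 0.2)
  expect_lte(mean(is.na(errs)), 0.05)
})

test_that("temperature extrapolation reproduces the closed-form line", {
  Tc <- c(20, 22, 23, 28, 32)
  est <- extrapolateDGToTemperature(10 - 0.2 * Tc, Tc + 273.15,
                                    target = 310.15)
  expect_equal(est@dG0Water, 2.60, tolerance = 1e-9)

  # all points equal: flat line, same value at 37 C
  flat <- extrapolateDGToTemperature(rep(4.2, 4),
                                     c(293, 296, 300, 305) + 0.15)
  expect_equal(flat@dG0Water, 4.2, tolerance = 1e-9)
  expect_equal(flat@slope, 0, tolerance = 1e-9)

  expect_error(extrapolateDGToTemperature(c(1, 2), c(293, 300)), ">= 3")
})

test_that("planted extrapolation slope is covered by the 95% interval", {
  hits <- vapply(1:100, function(seed) {
    Tc <- c(20, 22, 23, 28, 32)
    truth <- 10 - 0.2 * Tc
    set.seed(seed)
    est <- extrapolateDGToTemperature(truth + rnorm(5, sd = 0.15),
                                      Tc + 273.15, target = 310.15)
    est@predictionInterval[1] <= 2.60 && 2.60 <= est@predictionInterval[2]
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("rate extrapolation inverts exact log-linear tables", {
  temps <- c(289.15, 295.15, 301.15)
  lkw <- c(-6, -5.4, -4.8)        # planted log10 k_u in water
  mku <- 0.5
  tab <- do.call(rbind, lapply(seq_along(temps), function(i)
    data.frame(temperature_K = temps[i], urea_M = 1:4,
               ku = 10^(lkw[i] + mku * (1:4)))))
  ext <- extrapolateRate(tab, target = 310.15)
  expect_equal(unname(ext@logKuWater), lkw, tolerance = 1e-10)
  expect_equal(unname(ext@mKu), rep(mku, 3), tolerance = 1e-10)
  # planted temperature line: slope 0.1 /K from 289.15 K
  expect_equal(log10(ext@kuTarget), -6 + 0.1 * (310.15 - 289.15),
               tolerance = 1e-9)

  # doubling every rate shifts log k_u by log10(2) and dG by -RT ln 2
  tab2 <- tab
  tab2$ku <- tab2$ku * 2
  ext2 <- extrapolateRate(tab2, target = 310.15)
  expect_equal(unname(ext2@logKuWater - ext@logKuWater), rep(log10(2), 3),
               tolerance = 1e-10)
  expect_equal(ext2@dGactBare - ext@dGactBare,
               -GAS_CONSTANT_KCAL * 310.15 * log(2), tolerance = 1e-9)
})

test_that("bare and Eyring activation energies differ by RT ln(kB T/h)", {
  # k_u(37 C) = 1e-4 /s: bare form gives -RT ln(1e-4) = 5.67 kcal/mol
  tab <- data.frame(temperature_K = rep(c(293.15, 303.15), each = 3),
                    urea_M = rep(1:3, 2),
                    ku = 10^(c(-5, -4.5, -4, -4.6, -4.1, -3.6)))
  ext <- extrapolateRate(tab, target = 310.15)
  expect_equal(ext@dGactBare, -GAS_CONSTANT_KCAL * 310.15 * log(ext@kuTarget),
               tolerance = 1e-12)
  expect_equal(-GAS_CONSTANT_KCAL * 310.15 * log(1e-4), 5.67,
               tolerance = 5e-3)
  gap <- GAS_CONSTANT_KCAL * 310.15 *
    log(BOLTZMANN_J_PER_K * 310.15 / PLANCK_J_S)
  expect_equal(ext@dGactEyring - ext@dGactBare, gap, tolerance = 1e-9)
})

test_that("Boltzmann melt fit recovers the planted midpoint", {
  spec <- stabilitySimSpec(dG0 = 5, mValue = 1.5, dGSlopeT = -0.25,
                           noiseSd = 0, seed = 1)
  tm_planted_C <- 20 + 5 / 0.25  # dG crosses 0 at 40 C
  cv <- simulateUnfoldingCurve(spec, seq(293.15, 353.15, by = 2),
                               axisKind = "temperature_kelvin")
  fit <- fitMelt(cv)
  expect_equal(fit@tm, tm_planted_C, tolerance = 0.05)

  # equivariance: shifting the temperature axis shifts T_m by the shift
  cv_shift <- UnfoldingCurve("temperature_kelvin", cv@axisValues + 5,
                             cv@signal)
  expect_equal(fitMelt(cv_shift)@tm, fit@tm + 5, tolerance = 1e-6)

  # flat signal has no inflection
  flat <- UnfoldingCurve("temperature_kelvin", seq(293, 353, by = 10),
                         matrix(1, 7, 1))
  expect_error(fitMelt(flat), "inflection|flat")
})

test_that("T_m recovery within 0.3 C at 1% noise (median, 100 seeds)", {
  errs <- vapply(1:100, function(seed) {
    cv <- simulateUnfoldingCurve(
      stabilitySimSpec(dG0 = 5, mValue = 1.5, dGSlopeT = -0.25,
                       noiseSd = 0.01, seed = seed),
      seq(293.15, 353.15, by = 1.5), axisKind = "temperature_kelvin")
    fit <- tryCatch(fitMelt(cv), error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    abs(fit@tm - 40)
  }, 0)
  expect_lte(median(errs, na.rm = TRUE), 0.3)
})
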