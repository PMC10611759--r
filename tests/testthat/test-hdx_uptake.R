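test_that("noiseless uptake fits invert the model to solver tolerance", {
  s <- simulateUptake(uptakeSimSpec(A0 = 10, amplitudes = 60, rates = 0.01,
                                    noiseSd = 0, seed = 1,
                                    timepoints = c(10, 60, 240, 1200)))
  fit <- fitUptake(s, order = 1)
  expect_true(fit@converged)
  expect_equal(fit@A0, 10, tolerance = 1e-6)
  expect_equal(fit@amplitudes, 60, tolerance = 1e-6)
  expect_equal(fit@rates, 0.01, tolerance = 1e-6)

  # noiseless biexponential, 5-point schedule
  s2 <- simulateUptake(uptakeSimSpec(
    A0 = 5, amplitudes = c(30, 40), rates = c(0.05, 0.002), noiseSd = 0,
    timepoints = c(10, 60, 240, 1200, 3600), seed = 1))
  fit2 <- fitUptake(s2, order = 2)
  expect_true(fit2@converged)
  expect_equal(fit2@rates, c(0.05, 0.002), tolerance = 1e-4)
  expect_equal(fit2@amplitudes, c(30, 40), tolerance = 1e-3)
  expect_gt(fit2@rates[1], fit2@rates[2])
})

test_that("biexponential rates recover within 15% at 1 %D noise", {
  s <- simulateUptake(uptakeSimSpec(
    A0 = 5, amplitudes = c(30, 40), rates = c(0.05, 0.002), noiseSd = 1,
    timepoints = c(10, 60, 240, 1200, 3600), nReplicates = 3, seed = 1))
  fit <- fitUptake(s, order = 2)
  expect_true(fit@converged)
  expect_lt(abs(fit@rates[1] / 0.05 - 1), 0.15)
  expect_lt(abs(fit@rates[2] / 0.002 - 1), 0.15)
})

test_that("constant series yields near-zero amplitude and unidentifiable rate", {
  s <- UptakeSeries(make_peptide(), c(10, 240, 1200),
                    matrix(50, 3, 3), temperature = 310.15)
  fit <- fitUptake(s, order = 1)
  expect_true(fit@converged)
  expect_identical(fit@modelOrder, 1L)
  expect_lt(fit@amplitudes, 0.5)
  expect_false(fit@rateIdentifiable[1])
  expect_error(ddGFromRates(fit, fit), "unidentifiable")
})

test_that("rate recovery: median error <= 10% over seeded mono simulations", {
  errs <- vapply(1:100, function(seed) {
    s <- simulateUptake(uptakeSimSpec(
      A0 = 10, amplitudes = 60, rates = 0.005, noiseSd = 1.5,
      timepoints = c(10, 240, 1200), nReplicates = 3, seed = seed))
    fit <- fitUptake(s, order = 1)
    abs(fit@rates[1] / 0.005 - 1)
  }, 0)
  expect_lte(median(errs), 0.10)
})

test_that("model order selection prefers the true order-1 model", {
  picks <- vapply(1:40, function(seed) {
    s <- simulateUptake(uptakeSimSpec(
      A0 = 10, amplitudes = 60, rates = 0.005, noiseSd = 2,
      timepoints = c(10, 60, 240, 1200, 3600), nReplicates = 3,
      seed = seed))
    fitUptake(s, order = "auto")@modelOrder
  }, 0L)
  expect_gte(mean(picks == 1L), 0.9)
})

test_that("differential map handles identity, shifts and n-guards", {
  panel <- make_state_panel("WT", 4, noise = 1, seed0 = 0)
  # identical states: delta 0 everywhere, p = 1 by the degenerate rule
  m0 <- differentialMap(panel, panel)
  expect_true(all(m0@table$delta_percentD == 0))
  expect_true(all(m0@table$p_value == 1))

  # planted +10 %D shift is recovered with significance
  shifted <- make_state_panel("MUT", 4, shift = 10, noise = 1, seed0 = 50)
  m1 <- differentialMap(panel, shifted)
  expect_equal(mean(m1@table$delta_percentD), 10, tolerance = 2)
  expect_gt(mean(m1@table$p_value < 0.05), 0.9)

  # single-replicate state: delta reported, p marked unavailable
  one_rep <- lapply(panel, function(s)
    UptakeSeries(PeptideRecord("ONE", s@peptide@start, s@peptide@end),
                 timepoints(s), percentD(s)[, 1, drop = FALSE]))
  m2 <- differentialMap(panel, one_rep)
  expect_true(all(is.na(m2@table$p_value)))
  expect_false(any(is.na(m2@table$delta_percentD)))

  # unmatched peptides are reported, not dropped
  extra <- c(panel, list(simulateUptake(uptakeSimSpec(10, 55, 0.008, seed = 9),
                                        PeptideRecord("WT", 900L, 909L))))
  m3 <- differentialMap(extra, shifted)
  expect_identical(nrow(m3@unmatched), 1L)
  expect_identical(m3@unmatched$start, 900L)

  expect_error(
    differentialMap(panel, list(simulateUptake(
      uptakeSimSpec(10, 55, 0.008, seed = 1),
      PeptideRecord("X", 500L, 509L)))),
    "no common peptides")
})

test_that("planted shift recovery holds across many seeds", {
  hits <- 0L
  deltas <- numeric(50)
  for (r in 1:50) {
    a <- simulateUptake(uptakeSimSpec(10, 55, 0.008, noiseSd = 1,
                                      seed = 1000 + r), make_peptide("A"))
    b <- simulateUptake(uptakeSimSpec(20, 55, 0.008, noiseSd = 1,
                                      seed = 2000 + r), make_peptide("B"))
    m <- differentialMap(list(a), list(b))
    deltas[r] <- mean(m@table$delta_percentD)
    hits <- hits + all(m@table$p_value < 0.05)
  }
  expect_equal(mean(deltas), 10, tolerance = 2)
  expect_gte(hits / 50, 0.95)
})

test_that("opening free-energy difference follows the rate-ratio law", {
  mkfit <- function(k) new("UptakeFit", peptide = make_peptide(),
                           modelOrder = 1L, A0 = 10, amplitudes = 60,
                           rates = k, rss = 0, aicc = NA_real_,
                           converged = TRUE, rateIdentifiable = TRUE,
                           temperature = 310.15)
  # equal rates: exactly zero
  expect_equal(ddGFromRates(mkfit(0.01), mkfit(0.01))@ddG, 0)
  # ratio 10 at 310.15 K: R*T*ln(10) with R = 1.986e-3 kcal/(K mol)
  d <- ddGFromRates(mkfit(0.01), mkfit(0.001), temperature = 310.15)
  expect_equal(abs(d@ddG), 1.418, tolerance = 1e-3)
  expect_equal(d@ddG, -1.986e-3 * 310.15 * log(10), tolerance = 1e-12)
  # antisymmetry under state swap
  d_swap <- ddGFromRates(mkfit(0.001), mkfit(0.01), temperature = 310.15)
  expect_equal(d@ddG, -d_swap@ddG, tolerance = 1e-12)
  # the gas constant used is the conventional 1.986 cal/(K mol)
  expect_identical(GAS_CONSTANT_KCAL, 1.986e-3)
  # slow component of an order-2 fit is the one converted
  f2 <- new("UptakeFit", peptide = make_peptide(), modelOrder = 2L, A0 = 5,
            amplitudes = c(30, 40), rates = c(0.05, 0.001), rss = 0,
            aicc = NA_real_, converged = TRUE,
            rateIdentifiable = c(TRUE, TRUE), temperature = 310.15)
  d2 <- ddGFromRates(f2, mkfit(0.001), temperature = 310.15)
  expect_equal(d2@rateA, 0.001)
  expect_equal(d2@ddG, 0)
  expect_match(d2@note, "EX2 assumed")
})

test_that("differential map projects onto residues by covering-peptide mean", {
  tab_a <- list(
    simulateUptake(uptakeSimSpec(10, 50, 0.01, noiseSd = 0, seed = 1),
                   PeptideRecord("A", 1L, 10L)),
    simulateUptake(uptakeSimSpec(10, 50, 0.01, noiseSd = 0, seed = 1),
                   PeptideRecord("A", 6L, 15L)))
  tab_b <- list(
    simulateUptake(uptakeSimSpec(20, 50, 0.01, noiseSd = 0, seed = 1),
                   PeptideRecord("B", 1L, 10L)),
    simulateUptake(uptakeSimSpec(30, 50, 0.01, noiseSd = 0, seed = 1),
                   PeptideRecord("B", 6L, 15L)))
  m <- differentialMap(tab_a, tab_b)
  pr <- projectDifferentialMap(m, time_s = 240, residueIds = c(3, 8, 12, 20))
  expect_equal(unname(pr), c(10, 15, 20, NA))
})
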