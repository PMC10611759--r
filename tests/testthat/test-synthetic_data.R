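test_that("uptake generator inverts the exchange model exactly", {
  # direct evaluation: A0=10, A=60, k=0.01/s at t=240 s
  s <- simulateUptake(uptakeSimSpec(A0 = 10, amplitudes = 60, rates = 0.01,
                                    noiseSd = 0, seed = 1))
  expect_equal(percentD(s)[2, 1], 10 + 60 * (1 - exp(-0.01 * 240)),
               tolerance = 1e-12)
  expect_equal(round(percentD(s)[2, 1], 2), 64.56)

  # asymptote: t -> Inf gives A0 + A
  s_inf <- simulateUptake(uptakeSimSpec(A0 = 10, amplitudes = 60,
                                        rates = 0.01, noiseSd = 0,
                                        timepoints = c(10, 1e7), seed = 1))
  expect_equal(percentD(s_inf)[2, 1], 70, tolerance = 1e-6)

  # determinism and seed isolation
  a <- simulateUptake(uptakeSimSpec(10, 60, 0.01, noiseSd = 2, seed = 7))
  b <- simulateUptake(uptakeSimSpec(10, 60, 0.01, noiseSd = 2, seed = 7))
  expect_identical(percentD(a), percentD(b))
  expect_true(all(percentD(a) >= 0 & percentD(a) <= 100))
})

test_that("uptake spec invariants are enforced", {
  expect_error(uptakeSimSpec(A0 = 50, amplitudes = 60, rates = 0.01),
               "<= 100")
  expect_error(uptakeSimSpec(A0 = 0, amplitudes = c(30, 30),
                             rates = c(0.001, 0.01)), "k_HX1 > k_HX2")
  expect_error(uptakeSimSpec(A0 = 0, amplitudes = 30, rates = -1),
               "rates must be > 0")
})

test_that("EX1 generator plants first-order folded-fraction decay", {
  # exp(-k_u t): k_u = 1e-3 /s at t = 693.1 s gives F_f = 0.50
  spec <- ex1SimSpec(ku = 1e-3, timepoints = c(0, 693.1), noiseSd = 0,
                     seed = 1)
  env <- simulateEx1Envelopes(spec)
  expect_equal(env@metadata$planted$Ff[2], 0.5, tolerance = 1e-4)

  # t = 0 is unimodal at the folded centroid
  e0 <- env@envelopes[[1]]
  expect_equal(unname(e0[which.max(e0[, 2]), 1]), spec@centroidFolded,
               tolerance = 4 * unname(diff(e0[1:2, 1])))
  # mass far beyond the unfolded centroid carries ~no folded signal at t=0
  expect_lt(e0[nrow(e0), 2] / max(e0[, 2]), 1e-4)

  # intensities are never negative, even at high noise
  noisy <- simulateEx1Envelopes(ex1SimSpec(ku = 1e-3, noiseSd = 1, seed = 3))
  expect_true(all(vapply(noisy@envelopes, function(e) all(e[, 2] >= 0),
                         TRUE)))
})

test_that("unfolding-curve generator has the planted midpoint", {
  # dG0 = 3.0, m = 1.5 -> f_u = 0.5 at C_m = 2.0 M
  spec <- stabilitySimSpec(dG0 = 3, mValue = 1.5, noiseSd = 0, seed = 1)
  cv <- simulateUnfoldingCurve(spec, seq(0, 6, by = 0.5),
                               temperature = 293.15)
  fu <- cv@metadata$planted$fractionUnfolded
  expect_equal(fu[cv@axisValues == 2], 0.5, tolerance = 1e-12)
  # [urea] = 0 with dG >> RT: essentially fully folded
  expect_lt(fu[1], 0.01)

  # thermal axis: signal crosses the baseline midpoint at the planted T_m
  tm_K <- spec@refTemperature - spec@dG0 / spec@dGSlopeT  # dG(T_m) = 0
  th <- simulateUnfoldingCurve(spec, seq(293.15, 353.15, by = 1),
                               axisKind = "temperature_kelvin")
  sig <- th@signal[, 1]
  mid <- (max(sig) + min(sig)) / 2
  crossing <- approx(sig, th@axisValues, xout = mid)$y
  expect_equal(crossing, tm_K, tolerance = 0.2)
})

test_that("trajectory generator plants correlation blocks and is seeded", {
  spec <- trajectorySimSpec(nResidues = 60, nFrames = 5000,
                            communities = list(1:30, 31:60),
                            intraCorr = 0.8, interCorr = 0,
                            fluctuationSd = 0.5, seed = 11)
  tr <- simulateTrajectory(spec)
  # sample-correlation oracle on raw displacements
  disp <- tr@frames[, , 1] - matrix(tr@reference[, 1], nFrames(tr), 60,
                                    byrow = TRUE)
  cc <- cor(disp)
  cross <- cc[1:30, 31:60]
  expect_lt(max(abs(cross)), 0.05)
  expect_gt(mean(cc[1:30, 1:30][upper.tri(diag(30))]), 0.75)

  # isotropic Gaussian closed form: per-residue RMSF ~ sigma * sqrt(3)
  sp0 <- trajectorySimSpec(nResidues = 8, nFrames = 5000,
                           communities = list(1:8), intraCorr = 2e-9,
                           interCorr = 1e-9, fluctuationSd = 0.5, seed = 3)
  tr0 <- simulateTrajectory(sp0)
  d0 <- sweep(tr0@frames, c(2, 3), tr0@reference)
  rmsf_raw <- sqrt(apply(d0^2, 2, function(m) mean(rowSums(m))))
  expect_equal(mean(rmsf_raw) / (0.5 * sqrt(3)), 1, tolerance = 0.03)

  # same seed -> identical frames
  tr_b <- simulateTrajectory(spec)
  expect_identical(tr@frames, tr_b@frames)
})

test_that("infeasible planted correlation matrices are rejected", {
  # many equicorrelated bridge-free blocks with strong negative implied
  # eigenvalues cannot arise from intra/inter in [0,1); force one via
  # bridge pairs that contradict the block structure
  spec <- trajectorySimSpec(nResidues = 9, nFrames = 10,
                            communities = list(1:3, 4:6, 7:9),
                            intraCorr = 0.99, interCorr = 0,
                            bridgePairs = cbind(c(1, 1, 4), c(4, 7, 7)),
                            bridgeCorr = 0.99, fluctuationSd = 0.5, seed = 1)
  expect_error(simulateTrajectory(spec), "smaller correlation contrasts")
})

test_that("contact loss displaces the listed residues after the set frame", {
  spec <- trajectorySimSpec(
    nResidues = 10, nFrames = 20, communities = list(1:10),
    intraCorr = 0.2, interCorr = 0.1, fluctuationSd = 0.3,
    contactLoss = list(residues = c(2, 5), afterFrame = 10,
                       offset = c(40, 0, 0)), seed = 2)
  tr <- simulateTrajectory(spec)
  jump <- mean(tr@frames[11:20, 2, 1]) - mean(tr@frames[1:10, 2, 1])
  expect_equal(jump, 40, tolerance = 1)
  stay <- mean(tr@frames[11:20, 3, 1]) - mean(tr@frames[1:10, 3, 1])
  expect_lt(abs(stay), 1)
})
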