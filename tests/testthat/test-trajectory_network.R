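test_that("RMSF is zero on static frames and invariant to rigid rotation", {
  ref <- lattice_ref <- simulateTrajectory(
    trajectorySimSpec(nResidues = 20, nFrames = 2, communities = list(1:20),
                      intraCorr = 0.2, interCorr = 0.1, seed = 1))@reference
  frames <- array(0, dim = c(12, 20, 3))
  for (f in 1:12) frames[f, , ] <- ref
  tr_static <- TrajectoryEnsemble(1:20, frames, ref)
  expect_equal(max(rmsf(tr_static)@rmsf), 0, tolerance = 1e-9)

  # jittered trajectory, then a global rotation of every frame
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 20, nFrames = 200, communities = list(1:20),
    intraCorr = 2e-9, interCorr = 1e-9, fluctuationSd = 0.4, seed = 3))
  theta <- 0.7
  Rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta), cos(theta), 0, 0, 0, 1), 3, byrow = TRUE)
  rot <- tr@frames
  for (f in seq_len(dim(rot)[1])) rot[f, , ] <- tr@frames[f, , ] %*% t(Rz)
  tr_rot <- TrajectoryEnsemble(1:20, rot, tr@reference)
  expect_equal(rmsf(tr_rot)@rmsf, rmsf(tr)@rmsf, tolerance = 1e-6)
})

test_that("RMSF matches the isotropic-Gaussian closed form", {
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 100, nFrames = 5000, communities = list(1:100),
    intraCorr = 2e-9, interCorr = 1e-9, fluctuationSd = 0.5, seed = 7))
  prof <- rmsf(tr)
  expect_equal(mean(prof@rmsf) / (0.5 * sqrt(3)), 1, tolerance = 0.03)
})

test_that("collinear references are rejected for superposition", {
  ref <- cbind(1:12, 0, 0)
  frames <- array(rnorm(10 * 12 * 3, sd = 0.1), dim = c(10, 12, 3))
  tr <- TrajectoryEnsemble(1:12, frames, ref)
  expect_error(rmsf(tr), "collinear")
})

test_that("native contacts: Q is exactly 1 on reference frames", {
  tr0 <- simulateTrajectory(trajectorySimSpec(
    nResidues = 30, nFrames = 2, communities = list(1:30),
    intraCorr = 0.2, interCorr = 0.1, seed = 1))
  frames <- array(0, dim = c(3, 30, 3))
  for (f in 1:3) frames[f, , ] <- tr0@reference
  tr <- TrajectoryEnsemble(1:30, frames, tr0@reference)
  nc <- nativeContacts(tr)
  expect_true(all(nc@Q == 1))
  expect_true(all(abs(nc@contacts[, 1] - nc@contacts[, 2]) > 3))
  expect_error(nativeContacts(tr, cutoff = 0.5), "increase the cutoff")
})

test_that("planted contact loss is recovered in the subset Q", {
  base <- simulateTrajectory(trajectorySimSpec(
    nResidues = 40, nFrames = 50, communities = list(1:40),
    intraCorr = 0.2, interCorr = 0.1, fluctuationSd = 0.05, seed = 5))
  nc0 <- nativeContacts(base, tolerance = 0.2)
  # subset: all native contacts of four residues; displace two of them
  probe <- c(10, 20, 28, 35)
  sub <- nc0@contacts[nc0@contacts[, 1] %in% probe |
                        nc0@contacts[, 2] %in% probe, ]
  lost_res <- c(10, 28)
  # a contact breaks only when exactly one endpoint is displaced (displacing
  # both by the same offset preserves their relative distance)
  broken <- xor(sub[, 1] %in% lost_res, sub[, 2] %in% lost_res)
  frac_kept <- 1 - mean(broken)
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 40, nFrames = 50, communities = list(1:40),
    intraCorr = 0.2, interCorr = 0.1, fluctuationSd = 0.05,
    contactLoss = list(residues = lost_res, afterFrame = 0,
                       offset = c(60, 60, 60)), seed = 5))
  nc <- nativeContacts(tr, subset = sub, tolerance = 0.2)
  expect_equal(mean(nc@subsetQ), frac_kept, tolerance = 0.02)
})

test_that("Q agrees with a brute-force recount over the explicit pair list", {
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 25, nFrames = 30, communities = list(1:25),
    intraCorr = 0.3, interCorr = 0.1, fluctuationSd = 0.8, seed = 13))
  nc <- nativeContacts(tr, cutoff = 8, tolerance = 0.1)
  # independent O(n^2) recount
  ref_d <- as.matrix(dist(tr@reference))
  q_brute <- vapply(seq_len(nFrames(tr)), function(f) {
    d <- as.matrix(dist(tr@frames[f, , ]))
    hits <- 0L; total <- 0L
    for (i in 1:24) for (j in (i + 1):25) {
      if (j - i <= 3 || ref_d[i, j] > 8) next
      total <- total + 1L
      if (d[i, j] <= 8 * 1.1) hits <- hits + 1L
    }
    hits / total
  }, 0)
  expect_equal(nc@Q, q_brute, tolerance = 1e-12)
})

test_that("generalized correlation obeys its dependence limits", {
  set.seed(21)
  n <- 5000
  x <- matrix(rnorm(n * 3), n)
  # independent: near zero
  y_ind <- matrix(rnorm(n * 3), n)
  expect_lt(generalizedCorrelationPair(x, y_ind), 0.1)
  # identical motions: near one
  expect_gte(generalizedCorrelationPair(x, x), 0.95)
  # jointly Gaussian, rho = 0.8 per coordinate: closed form r_MI = rho
  y_cor <- 0.8 * x + sqrt(1 - 0.64) * matrix(rnorm(n * 3), n)
  expect_equal(generalizedCorrelationPair(x, y_cor), 0.8, tolerance = 0.05)
})

test_that("correlation matrix op fills a valid symmetric unit-diagonal C", {
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 12, nFrames = 600, communities = list(1:6, 7:12),
    intraCorr = 0.7, interCorr = 0.05, fluctuationSd = 0.5, seed = 2))
  net <- generalizedCorrelation(tr)
  C <- correlationMatrix(net)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 12))
  expect_gt(mean(C[1:6, 1:6][upper.tri(diag(6))]), mean(C[1:6, 7:12]))
  expect_error(generalizedCorrelation(
    TrajectoryEnsemble(1:3, array(rnorm(5 * 3 * 3), c(5, 3, 3)),
                       matrix(0, 3, 3)), k = 6), "more frames than k")
})

test_that("network construction filters edges and maps C to distances", {
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 15, nFrames = 100, communities = list(1:15),
    intraCorr = 0.5, interCorr = 0.1, fluctuationSd = 0.3, seed = 4))
  C <- matrix(0.5, 15, 15)
  diag(C) <- 1
  C[1, 2] <- C[2, 1] <- 1      # perfectly coupled pair
  C[3, 4] <- C[4, 3] <- 0.001  # below floor
  net <- buildNetwork(C, tr)
  e12 <- net@edges[net@edges$i == 1 & net@edges$j == 2, ]
  expect_equal(e12$distance, 0)
  expect_false(any(net@edges$i == 3 & net@edges$j == 4))
  e_other <- net@edges$distance[net@edges$cij == 0.5]
  expect_equal(unique(round(e_other, 6)), round(log(2), 6))
  # occupancy monotonicity: stricter threshold never adds edges
  stricter <- suppressWarnings(buildNetwork(C, tr, occupancy = 0.95))
  looser <- suppressWarnings(buildNetwork(C, tr, occupancy = 0.5))
  key <- function(n) paste(n@edges$i, n@edges$j)
  expect_true(all(key(stricter) %in% key(looser)))
  expect_true(all(key(net) %in% key(looser)))
})

test_that("community analysis matches exhaustive small-graph expectations", {
  # two 5-node cliques joined by one edge: exactly 2 communities and the
  # bridge endpoints carry the top betweenness
  n <- 10
  C <- diag(n)
  for (i in 1:4) for (j in (i + 1):5) C[i, j] <- C[j, i] <- 0.8
  for (i in 6:9) for (j in (i + 1):10) C[i, j] <- C[j, i] <- 0.8
  C[5, 6] <- C[6, 5] <- 0.4
  edges <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
  net <- new("CorrelationNetwork", residueIds = 1:10, correlation = C,
             edges = data.frame(i = edges[, 1], j = edges[, 2],
                                cij = C[edges],
                                distance = -log(C[edges])))
  part <- communities(net)
  expect_identical(length(unique(part@membership)), 2L)
  expect_identical(part@membership[1:5], rep(part@membership[1], 5))
  expect_identical(part@membership[6:10], rep(part@membership[6], 5))
  top2 <- order(part@betweenness, decreasing = TRUE)[1:2]
  expect_setequal(top2, c(5, 6))
  # single inter-community pair with the bridge correlation as coupling
  expect_identical(nrow(part@coupling), 1L)
  expect_equal(part@coupling$coupling, 0.4)
  expect_equal(part@coupling$one_minus_coupling, 0.6)

  # path graph A-B-C: middle node has maximal betweenness
  Cp <- diag(3)
  Cp[1, 2] <- Cp[2, 1] <- 0.5
  Cp[2, 3] <- Cp[3, 2] <- 0.5
  ep <- data.frame(i = c(1, 2), j = c(2, 3), cij = 0.5, distance = log(2))
  netp <- new("CorrelationNetwork", residueIds = 1:3, correlation = Cp,
              edges = ep)
  pp <- communities(netp)
  expect_identical(which.max(pp@betweenness), 2L)
})

test_that("planted two-community trajectories are recovered (ARI >= 0.9)", {
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 60, nFrames = 800, communities = list(1:30, 31:60),
    intraCorr = 0.8, interCorr = 0.1, fluctuationSd = 0.5, seed = 17))
  C <- generalizedCorrelation(tr)
  net <- buildNetwork(C, tr)
  part <- communities(net)
  expect_gte(adjusted_rand(part@membership,
                           tr@metadata$planted$communities), 0.9)
  expect_true(all(part@coupling$coupling >= 0 & part@coupling$coupling <= 1))
})

test_that("trajectory quantities are invariant under global rigid motion", {
  tr <- simulateTrajectory(trajectorySimSpec(
    nResidues = 20, nFrames = 60, communities = list(1:20),
    intraCorr = 0.3, interCorr = 0.1, fluctuationSd = 0.4, seed = 6))
  shift <- c(10, -5, 3)
  moved <- tr@frames
  for (ax in 1:3) moved[, , ax] <- moved[, , ax] + shift[ax]
  tr_m <- TrajectoryEnsemble(1:20, moved, tr@reference)
  expect_equal(nativeContacts(tr_m)@Q, nativeContacts(tr)@Q)
  expect_equal(rmsf(tr_m)@rmsf, rmsf(tr)@rmsf, tolerance = 1e-8)
})
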