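## Synthetic-data generators. Each generator is the documented inverse of the
## model its consumer fits, and stores its planted parameters in the result's
## metadata so recovery tests can compare against ground truth. All
## randomness flows through the spec's seed; the caller's RNG state is left
## untouched.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

## ---------------------------------------------------------------------------
## Spec classes
## ---------------------------------------------------------------------------

#' Simulation specification classes
#'
#' Parameter bundles for the synthetic-data generators, with validity checks
#' enforcing the generative-model invariants. Construct via [uptakeSimSpec()],
#' [ex1SimSpec()], [stabilitySimSpec()], [trajectorySimSpec()].
#'
#' @name SimSpecs
#' @aliases UptakeSimSpec-class EX1SimSpec-class StabilitySimSpec-class
#'   TrajectorySimSpec-class
NULL

#' @export
setClass("UptakeSimSpec",
  slots = c(A0 = "numeric", amplitudes = "numeric", rates = "numeric",
            noiseSd = "numeric", timepoints = "numeric",
            nReplicates = "integer", seed = "integer",
            temperature = "numeric"))

setValidity("UptakeSimSpec", function(object) {
  msg <- character()
  if (object@A0 + sum(object@amplitudes) > 100 + 1e-9)
    msg <- c(msg, "A0 + sum(amplitudes) must be <= 100 %D")
  if (any(object@rates <= 0)) msg <- c(msg, "rates must be > 0")
  if (length(object@rates) != length(object@amplitudes))
    msg <- c(msg, "one rate per amplitude required")
  if (length(object@rates) == 2L && object@rates[1] <= object@rates[2])
    msg <- c(msg, "biexponential spec needs k_HX1 > k_HX2")
  if (object@noiseSd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @export
setClass("EX1SimSpec",
  slots = c(ku = "numeric", centroidFolded = "numeric",
            centroidUnfolded = "numeric", width = "numeric",
            nPoints = "integer", timepoints = "numeric",
            noiseSd = "numeric", seed = "integer"))

setValidity("EX1SimSpec", function(object) {
  msg <- character()
  if (object@centroidUnfolded <= object@centroidFolded)
    msg <- c(msg, "unfolded centroid must exceed folded centroid")
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (object@ku <= 0) msg <- c(msg, "k_u must be > 0")
  if (length(msg)) msg else TRUE
})

#' @export
setClass("StabilitySimSpec",
  slots = c(dG0 = "numeric", mValue = "numeric", dGSlopeT = "numeric",
            baselines = "numeric", noiseSd = "numeric", seed = "integer",
            refTemperature = "numeric"))

setValidity("StabilitySimSpec", function(object) {
  if (object@mValue <= 0) "m_value must be > 0" else TRUE
})

#' @export
setClass("TrajectorySimSpec",
  slots = c(nResidues = "integer", nFrames = "integer",
            communities = "list", intraCorr = "numeric",
            interCorr = "numeric", bridgePairs = "matrix",
            bridgeCorr = "numeric", fluctuationSd = "numeric",
            contactLoss = "list", seed = "integer"))

setValidity("TrajectorySimSpec", function(object) {
  msg <- character()
  if (!(object@interCorr >= 0 && object@interCorr < object@intraCorr &&
        object@intraCorr < 1))
    msg <- c(msg, "need 0 <= inter_corr < intra_corr < 1")
  covered <- sort(unlist(object@communities))
  if (!identical(covered, seq_len(object@nResidues)))
    msg <- c(msg, "communities must partition residues 1..n exactly once")
  if (object@fluctuationSd <= 0) msg <- c(msg, "fluctuation_sd must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct simulation specs
#'
#' @param A0 burst-phase \%D.
#' @param amplitudes one (A) or two (A1, A2) exchanging amplitudes, \%D.
#' @param rates matching exchange rate(s), 1/s (two rates: k1 > k2).
#' @param noiseSd additive Gaussian noise sd, \%D (uptake) or fractional
#'   multiplicative intensity noise (envelopes) or fractional signal-span
#'   noise (curves).
#' @param timepoints labeling schedule, seconds; default the experimental
#'   schedule 10, 240, 1200 s.
#' @param nReplicates replicates per timepoint.
#' @param seed RNG seed; the same seed reproduces the output exactly.
#' @param temperature labeling temperature, kelvin.
#' @return the corresponding spec object.
#' @rdname simSpecs
#' @export
uptakeSimSpec <- function(A0, amplitudes, rates, noiseSd = 1,
                          timepoints = c(10, 240, 1200), nReplicates = 3,
                          seed = 1, temperature = 310.15) {
  new("UptakeSimSpec", A0 = A0, amplitudes = amplitudes, rates = rates,
      noiseSd = noiseSd, timepoints = as.numeric(timepoints),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed),
      temperature = temperature)
}

#' @param ku unfolding rate constant, 1/s.
#' @param centroidFolded,centroidUnfolded envelope component centroids, Da.
#' @param width shared Gaussian component sd, Da.
#' @param nPoints mass-grid points per envelope.
#' @rdname simSpecs
#' @export
ex1SimSpec <- function(ku, centroidFolded = 0, centroidUnfolded = 6,
                       width = 1, nPoints = 64,
                       timepoints = c(0, 60, 240, 600, 1200),
                       noiseSd = 0.02, seed = 1) {
  new("EX1SimSpec", ku = ku, centroidFolded = centroidFolded,
      centroidUnfolded = centroidUnfolded, width = width,
      nPoints = as.integer(nPoints), timepoints = as.numeric(timepoints),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' @param dG0 unfolding free energy at the reference temperature, kcal/mol.
#' @param mValue denaturant dependence, kcal/mol/M (> 0).
#' @param dGSlopeT linear temperature dependence of dG0, kcal/mol/degree C.
#' @param baselines named numeric: `folded`, `unfolded` signal levels plus
#'   optional `foldedSlope`, `unfoldedSlope` per axis unit.
#' @param refTemperature temperature at which `dG0` holds, kelvin.
#' @rdname simSpecs
#' @export
stabilitySimSpec <- function(dG0, mValue, dGSlopeT = -0.2,
                             baselines = c(folded = 1, unfolded = 0,
                                           foldedSlope = 0,
                                           unfoldedSlope = 0),
                             noiseSd = 0, seed = 1,
                             refTemperature = 293.15) {
  full <- c(folded = 1, unfolded = 0, foldedSlope = 0, unfoldedSlope = 0)
  full[names(baselines)] <- baselines
  new("StabilitySimSpec", dG0 = dG0, mValue = mValue, dGSlopeT = dGSlopeT,
      baselines = full, noiseSd = noiseSd, seed = as.integer(seed),
      refTemperature = refTemperature)
}

#' @param nResidues,nFrames trajectory dimensions.
#' @param communities list of integer vectors partitioning 1..nResidues.
#' @param intraCorr,interCorr planted within-/between-community motion
#'   correlation, 0 <= inter < intra < 1.
#' @param bridgePairs 2-column matrix of residue pairs given elevated
#'   cross-community correlation `bridgeCorr`.
#' @param bridgeCorr correlation planted on bridge pairs.
#' @param fluctuationSd per-coordinate displacement sd, angstrom.
#' @param contactLoss NULL or list(residues=, afterFrame=, offset=) breaking
#'   the listed residues' native contacts from `afterFrame + 1` on by
#'   displacing them by `offset` (a 3-vector, angstrom).
#' @rdname simSpecs
#' @export
trajectorySimSpec <- function(nResidues, nFrames,
                              communities = list(seq_len(nResidues)),
                              intraCorr = 0.8, interCorr = 0.1,
                              bridgePairs = matrix(integer(), ncol = 2),
                              bridgeCorr = 0.7, fluctuationSd = 0.5,
                              contactLoss = list(), seed = 1) {
  new("TrajectorySimSpec", nResidues = as.integer(nResidues),
      nFrames = as.integer(nFrames), communities = communities,
      intraCorr = intraCorr, interCorr = interCorr,
      bridgePairs = bridgePairs, bridgeCorr = bridgeCorr,
      fluctuationSd = fluctuationSd, contactLoss = contactLoss,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Generators
## ---------------------------------------------------------------------------

# noiseless uptake model: D(t) = A0 + sum_i Ai (1 - exp(-k_i t))
uptake_model <- function(t, A0, amplitudes, rates) {
  A0 + rowSums(vapply(seq_along(rates),
                      function(i) amplitudes[i] * (1 - exp(-rates[i] * t)),
                      numeric(length(t))))
}

#' Simulate a deuterium uptake time course
#'
#' Evaluates the mono- or biexponential uptake model at the spec's schedule
#' and adds independent Gaussian noise per replicate, clipping to [0, 100].
#' The planted parameters are stored in the result's metadata.
#'
#' @param spec an `UptakeSimSpec` from [uptakeSimSpec()].
#' @param peptide optional [PeptideRecord-class] identity for the series.
#' @return an [UptakeSeries-class].
#' @examples
#' s <- simulateUptake(uptakeSimSpec(A0 = 10, amplitudes = 60, rates = 0.01,
#'                                   noiseSd = 0, seed = 7))
#' percentD(s)[2, 1]  # 64.56 %D at t = 240 s
#' @export
simulateUptake <- function(spec, peptide = PeptideRecord("sim", 1L, 10L)) {
  validObject(spec)
  mu <- uptake_model(spec@timepoints, spec@A0, spec@amplitudes, spec@rates)
  mat <- with_seed(spec@seed, {
    noise <- matrix(stats::rnorm(length(mu) * spec@nReplicates,
                                 sd = spec@noiseSd),
                    nrow = length(mu))
    pmin(pmax(mu + noise, 0), 100)
  })
  UptakeSeries(peptide = peptide, timepoints = spec@timepoints,
               percentD = mat, temperature = spec@temperature,
               metadata = list(planted = list(
                 A0 = spec@A0, amplitudes = spec@amplitudes,
                 rates = spec@rates, noiseSd = spec@noiseSd,
                 seed = spec@seed)))
}

#' Simulate EX1 bimodal isotope envelopes
#'
#' At labeling time t the envelope is the mixture
#' `F_f(t) N(centroidFolded, width) + (1 - F_f(t)) N(centroidUnfolded,
#' width)` with `F_f(t) = exp(-k_u t)`, sampled on a regular mass-offset
#' grid. Noise is multiplicative (intensities stay naturally non-negative);
#' any residual negative value is clipped to 0.
#'
#' @param spec an `EX1SimSpec` from [ex1SimSpec()].
#' @param peptide optional peptide identity.
#' @return an [EnvelopeSeries-class] with planted `ku` and per-timepoint
#'   `Ff` in its metadata.
#' @export
simulateEx1Envelopes <- function(spec,
                                 peptide = PeptideRecord("sim", 1L, 10L)) {
  validObject(spec)
  grid <- seq(spec@centroidFolded - 4 * spec@width,
              spec@centroidUnfolded + 4 * spec@width,
              length.out = spec@nPoints)
  Ff <- exp(-spec@ku * spec@timepoints)
  envs <- with_seed(spec@seed, {
    lapply(seq_along(spec@timepoints), function(i) {
      dens <- Ff[i] * stats::dnorm(grid, spec@centroidFolded, spec@width) +
        (1 - Ff[i]) * stats::dnorm(grid, spec@centroidUnfolded, spec@width)
      noisy <- dens * (1 + stats::rnorm(length(grid), sd = spec@noiseSd))
      cbind(mass_offset_Da = grid, intensity = pmax(noisy, 0))
    })
  })
  EnvelopeSeries(peptide = peptide, timepoints = spec@timepoints,
                 envelopes = envs,
                 metadata = list(planted = list(ku = spec@ku, Ff = Ff,
                                                seed = spec@seed)))
}

#' Simulate a two-state equilibrium unfolding curve
#'
#' The planted free energy is `dG(urea, T) = dG0 - m [urea] + dGSlopeT
#' (T - refTemperature in C)`; the fraction unfolded is
#' `f_u = 1 / (1 + exp(dG / RT))` and the observed signal interpolates the
#' (optionally sloped) folded and unfolded baselines, plus Gaussian noise
#' scaled to the baseline span. For a thermal axis pass
#' `axisKind = "temperature_kelvin"` and axis values in kelvin; the planted
#' midpoint (dG = 0) is at `T_m = refTemperature - dG0 / dGSlopeT` (in C).
#'
#' @param spec a `StabilitySimSpec` from [stabilitySimSpec()].
#' @param axisValues denaturant molarities or temperatures (kelvin).
#' @param axisKind "denaturant_molar" or "temperature_kelvin".
#' @param temperature experiment temperature (kelvin) for denaturant curves.
#' @param nReplicates replicate signals per axis point.
#' @return an [UnfoldingCurve-class] with planted parameters in metadata.
#' @export
simulateUnfoldingCurve <- function(spec, axisValues,
                                   axisKind = c("denaturant_molar",
                                                "temperature_kelvin"),
                                   temperature = spec@refTemperature,
                                   nReplicates = 1) {
  validObject(spec)
  axisKind <- match.arg(axisKind)
  if (axisKind == "denaturant_molar") {
    urea <- axisValues
    Tk <- temperature
  } else {
    urea <- 0
    Tk <- axisValues
  }
  dG <- spec@dG0 - spec@mValue * urea +
    spec@dGSlopeT * (Tk - spec@refTemperature)
  fu <- 1 / (1 + exp(dG / (GAS_CONSTANT_KCAL * Tk)))
  b <- spec@baselines
  bf <- b["folded"] + b["foldedSlope"] * axisValues
  bu <- b["unfolded"] + b["unfoldedSlope"] * axisValues
  mu <- bf + fu * (bu - bf)
  span <- abs(b["unfolded"] - b["folded"])
  sig <- with_seed(spec@seed, {
    matrix(mu, nrow = length(axisValues), ncol = nReplicates) +
      matrix(stats::rnorm(length(axisValues) * nReplicates,
                          sd = spec@noiseSd * span),
             nrow = length(axisValues))
  })
  UnfoldingCurve(axisKind = axisKind, axisValues = axisValues, signal = sig,
                 temperature = if (axisKind == "denaturant_molar") Tk
                               else NA_real_,
                 metadata = list(planted = list(
                   dG0 = spec@dG0, mValue = spec@mValue,
                   dGSlopeT = spec@dGSlopeT,
                   refTemperature = spec@refTemperature,
                   fractionUnfolded = fu, seed = spec@seed)))
}

# reference coordinates on a boustrophedon path through a cubic lattice, so
# that sequence neighbours (and community blocks) are in spatial contact
lattice_reference <- function(n, spacing = 3.8) {
  side <- ceiling(n^(1 / 3))
  coords <- matrix(0, n, 3)
  i <- 0L
  for (z in seq_len(side)) {
    for (y in seq_len(side)) {
      xs <- seq_len(side)
      if (y %% 2L == 0L) xs <- rev(xs)
      if (z %% 2L == 0L) xs <- rev(xs)
      for (x in xs) {
        i <- i + 1L
        if (i > n) return(coords * spacing)
        coords[i, ] <- c(x, y, z)
      }
    }
  }
  coords * spacing
}

# planted residue-residue correlation matrix with community block structure
planted_correlation <- function(spec) {
  n <- spec@nResidues
  R <- matrix(spec@interCorr, n, n)
  for (comm in spec@communities)
    R[comm, comm] <- spec@intraCorr
  if (nrow(spec@bridgePairs)) {
    for (r in seq_len(nrow(spec@bridgePairs))) {
      i <- spec@bridgePairs[r, 1L]; j <- spec@bridgePairs[r, 2L]
      R[i, j] <- R[j, i] <- spec@bridgeCorr
    }
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  clipped <- FALSE
  if (min(ev$values) < 1e-6) {
    if (min(ev$values) < -0.1)
      stop("planted correlation matrix is far from positive definite; ",
           "use smaller correlation contrasts")
    vals <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    clipped <- TRUE
  }
  list(R = R, clipped = clipped)
}

#' Simulate a residue trajectory with planted correlation structure
#'
#' Residue displacements are drawn from a zero-mean multivariate Gaussian
#' (independently per coordinate axis) whose residue-residue correlation
#' matrix has `intraCorr` within communities, `interCorr` between, and
#' `bridgeCorr` on the listed bridge pairs. Positive definiteness is
#' enforced by eigenvalue clipping with re-normalisation (echoed in the
#' metadata). The reference structure is a boustrophedon walk on a cubic
#' lattice (3.8 angstrom spacing) so that sequence neighbours are in spatial
#' contact. Optional contact loss displaces the listed residues by a fixed
#' offset after a given frame, breaking their native contacts.
#'
#' @param spec a `TrajectorySimSpec` from [trajectorySimSpec()].
#' @return a [TrajectoryEnsemble-class]; metadata holds the planted
#'   community labels, the (possibly clipped) correlation matrix and the
#'   contact-loss description.
#' @export
simulateTrajectory <- function(spec) {
  validObject(spec)
  n <- spec@nResidues
  reference <- lattice_reference(n)
  pc <- planted_correlation(spec)
  L <- chol(pc$R)  # upper triangular: t(L) %*% z has correlation R
  nf <- spec@nFrames
  frames <- with_seed(spec@seed, {
    fr <- array(0, dim = c(nf, n, 3))
    for (ax in 1:3) {
      z <- matrix(stats::rnorm(n * nf), nrow = n)
      disp <- spec@fluctuationSd * crossprod(L, z)  # n x nf
      fr[, , ax] <- t(disp) + matrix(reference[, ax], nf, n, byrow = TRUE)
    }
    fr
  })
  if (length(spec@contactLoss)) {
    cl <- spec@contactLoss
    offset <- if (is.null(cl$offset)) c(50, 50, 50) else cl$offset
    after <- if (is.null(cl$afterFrame)) 0L else cl$afterFrame
    if (after < nf)
      for (ax in 1:3)
        frames[(after + 1L):nf, cl$residues, ax] <-
          frames[(after + 1L):nf, cl$residues, ax] + offset[ax]
  }
  labels <- integer(n)
  for (ci in seq_along(spec@communities)) labels[spec@communities[[ci]]] <- ci
  TrajectoryEnsemble(
    residueIds = seq_len(n), frames = frames, reference = reference,
    metadata = list(planted = list(
      communities = labels, correlation = pc$R,
      correlationClipped = pc$clipped, fluctuationSd = spec@fluctuationSd,
      contactLoss = spec@contactLoss, seed = spec@seed)))
}
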