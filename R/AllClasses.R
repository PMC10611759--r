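#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' PeptideRecord: identity of one proteolytic peptide
#'
#' Residue numbering is 1-based and inclusive on both ends, matching the
#' conventional peptide naming in HDX-MS work (e.g. "a.a. 1033-1043").
#'
#' @slot state protein state label (e.g. "WT", "6SS").
#' @slot start,end first and last residue index (1-based, inclusive).
#' @slot sequence amino-acid sequence; may be empty ("") when unknown.
#' @slot charge precursor charge state; NA when unknown.
#' @export
setClass("PeptideRecord",
  slots = c(state = "character", start = "integer", end = "integer",
            sequence = "character", charge = "integer"),
  prototype = prototype(state = "", sequence = "", charge = NA_integer_))

setValidity("PeptideRecord", function(object) {
  msg <- character()
  if (length(object@start) != 1L || length(object@end) != 1L)
    msg <- c(msg, "start and end must be single integers")
  else {
    if (object@start > object@end)
      msg <- c(msg, "start must be <= end")
    if (nzchar(object@sequence) &&
        nchar(object@sequence) != object@end - object@start + 1L)
      msg <- c(msg, sprintf(
        "sequence length (%d) does not match end - start + 1 (%d)",
        nchar(object@sequence), object@end - object@start + 1L))
  }
  if (!is.na(object@charge) && object@charge < 1L)
    msg <- c(msg, "charge must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' UptakeSeries: deuterium uptake time course for one peptide/state
#'
#' Percent deuteration (%D) is expressed relative to the peptide's
#' theoretical maximum, uncorrected for back-exchange. Replicates may be
#' missing (NA); downstream statistics use the per-timepoint replicate count.
#'
#' @slot peptide a [PeptideRecord-class].
#' @slot temperature labeling temperature, kelvin.
#' @slot timepoints labeling times, seconds, strictly increasing.
#' @slot percentD matrix timepoint x replicate, in [0, 100] (NA allowed).
#' @slot metadata free-form list (e.g. planted simulation parameters).
#' @export
setClass("UptakeSeries",
  slots = c(peptide = "PeptideRecord", temperature = "numeric",
            timepoints = "numeric", percentD = "matrix", metadata = "list"),
  prototype = prototype(temperature = 310.15, metadata = list()))

setValidity("UptakeSeries", function(object) {
  msg <- character()
  tp <- object@timepoints
  if (length(tp) < 1L) msg <- c(msg, "need >= 1 timepoint")
  if (length(tp) > 1L && any(diff(tp) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (nrow(object@percentD) != length(tp))
    msg <- c(msg, "percentD must have one row per timepoint")
  if (any(rowSums(!is.na(object@percentD)) < 1L))
    msg <- c(msg, "every timepoint needs >= 1 non-missing replicate")
  v <- object@percentD[!is.na(object@percentD)]
  if (length(v) && (any(v < 0) || any(v > 100)))
    msg <- c(msg, "percentD values must lie in [0, 100]")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (kelvin)")
  if (length(msg)) msg else TRUE
})

#' EnvelopeSeries: isotope-envelope intensity distributions over time
#'
#' One mass spectrum ("envelope") per labeling timepoint, each a two-column
#' matrix of mass offset (Da) and non-negative intensity.
#'
#' @slot peptide a [PeptideRecord-class].
#' @slot timepoints labeling times, seconds.
#' @slot envelopes list of 2-column matrices (mass_offset_Da, intensity).
#' @slot metadata free-form list.
#' @export
setClass("EnvelopeSeries",
  slots = c(peptide = "PeptideRecord", timepoints = "numeric",
            envelopes = "list", metadata = "list"),
  prototype = prototype(metadata = list()))

setValidity("EnvelopeSeries", function(object) {
  msg <- character()
  if (length(object@envelopes) != length(object@timepoints))
    msg <- c(msg, "one envelope per timepoint required")
  for (i in seq_along(object@envelopes)) {
    e <- object@envelopes[[i]]
    if (!is.matrix(e) || ncol(e) != 2L) {
      msg <- c(msg, sprintf("envelope %d is not a 2-column matrix", i))
      next
    }
    if (nrow(e) < 5L)
      msg <- c(msg, sprintf("envelope %d has < 5 points", i))
    if (any(diff(e[, 1L]) <= 0))
      msg <- c(msg, sprintf("envelope %d mass offsets not strictly increasing", i))
    if (any(e[, 2L] < 0))
      msg <- c(msg, sprintf("envelope %d has negative intensities", i))
  }
  if (length(msg)) msg else TRUE
})

#' UnfoldingCurve: equilibrium unfolding signal vs denaturant or temperature
#'
#' @slot axisKind "denaturant_molar" (urea, M) or "temperature_kelvin".
#' @slot axisValues strictly increasing axis, >= 6 points.
#' @slot signal matrix axis x replicate; CD ellipticity or fluorescence,
#'   arbitrary units.
#' @slot temperature experiment temperature in kelvin (denaturant curves).
#' @slot metadata free-form list.
#' @export
setClass("UnfoldingCurve",
  slots = c(axisKind = "character", axisValues = "numeric",
            signal = "matrix", temperature = "numeric", metadata = "list"),
  prototype = prototype(temperature = NA_real_, metadata = list()))

setValidity("UnfoldingCurve", function(object) {
  msg <- character()
  if (!object@axisKind %in% c("denaturant_molar", "temperature_kelvin"))
    msg <- c(msg, "axisKind must be 'denaturant_molar' or 'temperature_kelvin'")
  if (length(object@axisValues) < 6L)
    msg <- c(msg, "need >= 6 axis points")
  if (any(diff(object@axisValues) <= 0))
    msg <- c(msg, "axis values must be strictly increasing")
  if (nrow(object@signal) != length(object@axisValues))
    msg <- c(msg, "signal must have one row per axis value")
  if (identical(object@axisKind, "denaturant_molar") &&
      (is.na(object@temperature) || object@temperature <= 0))
    msg <- c(msg, "denaturant curves need a positive temperature (kelvin)")
  if (length(msg)) msg else TRUE
})

#' TrajectoryEnsemble: per-frame residue coordinates plus reference
#'
#' Coordinates are in angstrom; one point per residue (C-alpha level).
#'
#' @slot residueIds ordered residue identifiers (integer).
#' @slot frames numeric array [frame x residue x 3].
#' @slot reference matrix residue x 3, the native/reference coordinates.
#' @slot frameSpacing time between frames (metadata only; arbitrary units).
#' @slot metadata free-form list (e.g. planted community labels).
#' @export
setClass("TrajectoryEnsemble",
  slots = c(residueIds = "integer", frames = "array", reference = "matrix",
            frameSpacing = "numeric", metadata = "list"),
  prototype = prototype(frameSpacing = 1, metadata = list()))

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "frames must be a [frame x residue x 3] array")
  else {
    if (d[1] < 2L) msg <- c(msg, "need >= 2 frames")
    if (d[2] != nrow(object@reference))
      msg <- c(msg, "frame residue count must match reference")
    if (d[2] != length(object@residueIds))
      msg <- c(msg, "residueIds length must match residue count")
  }
  if (ncol(object@reference) != 3L)
    msg <- c(msg, "reference must be a residue x 3 matrix")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## HDX uptake results
## ---------------------------------------------------------------------------

#' UptakeFit: mono- or biexponential fit of a deuterium uptake time course
#'
#' Model: D(t) = A0 + sum_i Ai (1 - exp(-k_i t)), with one (order 1) or two
#' (order 2, k1 > k2) exchanging amplitudes. A0 is the burst-phase %D.
#'
#' @slot peptide the fitted peptide.
#' @slot modelOrder 1 or 2.
#' @slot A0 burst-phase amplitude, %D.
#' @slot amplitudes A (order 1) or c(A1, A2) (order 2), %D.
#' @slot rates k_HX (order 1) or c(k_HX1, k_HX2) with k_HX1 > k_HX2, 1/s.
#' @slot rss residual sum of squares (weighted, on replicate means).
#' @slot aicc small-sample-corrected information criterion (NA if undefined).
#' @slot converged did any start converge.
#' @slot rateIdentifiable per-rate flag; FALSE when the exponential moves
#'   < 5% by the last timepoint or is > 99% complete at the first.
#' @slot temperature kelvin.
#' @export
setClass("UptakeFit",
  slots = c(peptide = "PeptideRecord", modelOrder = "integer", A0 = "numeric",
            amplitudes = "numeric", rates = "numeric", rss = "numeric",
            aicc = "numeric", converged = "logical",
            rateIdentifiable = "logical", temperature = "numeric"))

setValidity("UptakeFit", function(object) {
  msg <- character()
  if (!object@modelOrder %in% c(1L, 2L))
    msg <- c(msg, "modelOrder must be 1 or 2")
  if (object@converged) {
    if (any(object@amplitudes < 0) || object@A0 < 0)
      msg <- c(msg, "amplitudes must be >= 0")
    if (any(object@rates <= 0))
      msg <- c(msg, "rates must be > 0")
    if (object@modelOrder == 2L && length(object@rates) == 2L &&
        object@rates[1] <= object@rates[2])
      msg <- c(msg, "order-2 fits require k_HX1 > k_HX2")
  }
  if (length(msg)) msg else TRUE
})

#' DifferentialMap: per-peptide, per-timepoint differential deuteration
#'
#' Holds delta %D (state B minus state A) with Welch two-tailed t-test
#' p-values. The p-value is NA where either state has < 2 replicates.
#'
#' @slot stateA,stateB state labels.
#' @slot table data.frame with columns start, end, sequence, time_s,
#'   mean_A, mean_B, delta_percentD, p_value, p_adjusted, n_A, n_B.
#' @slot unmatched data.frame of peptides present in only one state.
#' @export
setClass("DifferentialMap",
  slots = c(stateA = "character", stateB = "character",
            table = "data.frame", unmatched = "data.frame"))

setValidity("DifferentialMap", function(object) {
  msg <- character()
  need <- c("start", "end", "sequence", "time_s", "mean_A", "mean_B",
            "delta_percentD", "p_value", "n_A", "n_B")
  miss <- setdiff(need, names(object@table))
  if (length(miss))
    msg <- c(msg, paste("table missing columns:", paste(miss, collapse = ", ")))
  else if (any(abs(object@table$delta_percentD) > 100, na.rm = TRUE))
    msg <- c(msg, "|delta_percentD| cannot exceed 100")
  if (length(msg)) msg else TRUE
})

#' DifferentialEnergetics: opening free-energy difference from rate ratio
#'
#' ddG_open = -R T ln(rate_A / rate_B) in kcal/mol (R = 1.986e-3
#' kcal/(K mol)). With this A-minus-B convention the value is negative when
#' state B exchanges slower (is more protected) than state A. Values are
#' approximate: EX2 exchange is assumed and the labeling used a
#' temperature-jump protocol.
#'
#' @slot peptide the peptide compared.
#' @slot ddG kcal/mol.
#' @slot rateA,rateB exchange rates used, 1/s.
#' @slot temperature kelvin.
#' @slot note kinetics-regime caveat string.
#' @export
setClass("DifferentialEnergetics",
  slots = c(peptide = "PeptideRecord", ddG = "numeric", rateA = "numeric",
            rateB = "numeric", temperature = "numeric", note = "character"))

setValidity("DifferentialEnergetics", function(object) {
  expect <- -GAS_CONSTANT_KCAL * object@temperature *
    log(object@rateA / object@rateB)
  if (abs(object@ddG - expect) > 1e-12 * max(1, abs(expect)))
    "ddG must equal -R*T*ln(rateA/rateB) for the stored rates"
  else TRUE
})

## ---------------------------------------------------------------------------
## EX1 kinetics results
## ---------------------------------------------------------------------------

#' BimodalFit: folded/unfolded deconvolution of isotope envelopes
#'
#' Two-Gaussian mixture with centroids and widths shared across timepoints
#' (joint fit) and a per-timepoint folded fraction F_f.
#'
#' @slot timepoints seconds.
#' @slot Ff folded fraction per timepoint, in [0, 1].
#' @slot centroidFolded,centroidUnfolded Da; unfolded > folded.
#' @slot widthFolded,widthUnfolded Gaussian sd, Da.
#' @slot residual total sum of squared residuals on unit-area envelopes.
#' @slot shared TRUE for the joint (shared-shape) fit.
#' @export
setClass("BimodalFit",
  slots = c(timepoints = "numeric", Ff = "numeric",
            centroidFolded = "numeric", centroidUnfolded = "numeric",
            widthFolded = "numeric", widthUnfolded = "numeric",
            residual = "numeric", shared = "logical"))

setValidity("BimodalFit", function(object) {
  msg <- character()
  if (any(object@Ff < 0 | object@Ff > 1))
    msg <- c(msg, "F_f must lie in [0, 1]")
  if (any(object@centroidUnfolded <= object@centroidFolded))
    msg <- c(msg, "unfolded centroid must exceed folded centroid")
  if (length(msg)) msg else TRUE
})

#' UnfoldingKineticsFit: EX1 unfolding rate and Eyring activation energy
#'
#' ln F_f = -k_u t fitted through the origin; dG_act = R T ln(k_B T / (h k_u))
#' (Eyring inversion) in kcal/mol.
#'
#' @slot ku unfolding rate constant, 1/s.
#' @slot temperature kelvin.
#' @slot dGact kcal/mol.
#' @slot nPoints timepoints used in the ln-fit.
#' @slot rss residual sum of squares of the origin-constrained ln-fit.
#' @export
setClass("UnfoldingKineticsFit",
  slots = c(ku = "numeric", temperature = "numeric", dGact = "numeric",
            nPoints = "integer", rss = "numeric"))

setValidity("UnfoldingKineticsFit", function(object) {
  msg <- character()
  if (object@ku <= 0) msg <- c(msg, "k_u must be > 0")
  expect <- GAS_CONSTANT_KCAL * object@temperature *
    log(BOLTZMANN_J_PER_K * object@temperature / PLANCK_J_S / object@ku)
  if (abs(object@dGact - expect) > 1e-9)
    msg <- c(msg, "dGact must equal R*T*ln(kB*T/(h*k_u)) for the stored k_u")
  if (length(msg)) msg else TRUE
})

#' ActivationDifference: unfolding activation energy difference
#'
#' ddG_act = -R T ln(k_u(B) / k_u(A)); positive when state B unfolds slower.
#'
#' @slot ddGact kcal/mol.
#' @slot kuA,kuB rates, 1/s.
#' @slot temperature kelvin.
#' @export
setClass("ActivationDifference",
  slots = c(ddGact = "numeric", kuA = "numeric", kuB = "numeric",
            temperature = "numeric"))

setValidity("ActivationDifference", function(object) {
  expect <- -GAS_CONSTANT_KCAL * object@temperature *
    log(object@kuB / object@kuA)
  if (abs(object@ddGact - expect) > 1e-12 * max(1, abs(expect)))
    "ddGact must equal -R*T*ln(kuB/kuA)" else TRUE
})

## ---------------------------------------------------------------------------
## Equilibrium stability results
## ---------------------------------------------------------------------------

#' UreaUnfoldingFit: two-state analysis of one urea titration
#'
#' @slot dG0 unfolding free energy in water at the curve's temperature,
#'   kcal/mol.
#' @slot mValue kcal/mol/M (positive).
#' @slot temperature kelvin.
#' @slot pointwise data.frame (urea_M, fraction_unfolded, dG) of the points
#'   entering the linear fit (f_u restricted to [0.05, 0.95]).
#' @slot baselines fitted baseline coefficients (folded/unfolded
#'   intercepts and slopes).
#' @slot rss residual sum of squares of the global sigmoid fit.
#' @export
setClass("UreaUnfoldingFit",
  slots = c(dG0 = "numeric", mValue = "numeric", temperature = "numeric",
            pointwise = "data.frame", baselines = "numeric", rss = "numeric"))

#' StabilityEstimate: linear temperature extrapolation of dG0 to a target
#'
#' @slot dG0Water extrapolated unfolding free energy at the target
#'   temperature, kcal/mol.
#' @slot mValue representative m-value (mean of per-curve fits), kcal/mol/M.
#' @slot temperatures kelvin, the per-curve temperatures.
#' @slot dG0PerTemperature kcal/mol at each temperature.
#' @slot slope,intercept regression of dG0 on temperature (kelvin).
#' @slot predictionInterval 95% prediction interval at the target, kcal/mol.
#' @slot targetTemperature kelvin.
#' @export
setClass("StabilityEstimate",
  slots = c(dG0Water = "numeric", mValue = "numeric",
            temperatures = "numeric", dG0PerTemperature = "numeric",
            slope = "numeric", intercept = "numeric",
            predictionInterval = "numeric", targetTemperature = "numeric"))

#' RateExtrapolation: unfolding rates extrapolated to water and 37 C
#'
#' Per temperature, log10(k_u) is fit linearly in [urea]; the zero-urea
#' intercepts are then extrapolated linearly in temperature to the target.
#' Two activation energies are reported: the bare -R T ln(k_u) form and the
#' Eyring form R T ln(k_B T/(h k_u)); their difference is exactly
#' R T ln(k_B T/h).
#'
#' @slot logKuWater log10 unfolding rate in water per temperature.
#' @slot mKu per-temperature log10-rate slope vs [urea], 1/M.
#' @slot temperatures kelvin.
#' @slot kuTarget extrapolated k_u at the target temperature, 1/s.
#' @slot dGactBare -R T ln(k_u) at target, kcal/mol.
#' @slot dGactEyring Eyring activation energy at target, kcal/mol.
#' @slot predictionInterval 95% prediction interval for log10 k_u at target.
#' @slot targetTemperature kelvin.
#' @export
setClass("RateExtrapolation",
  slots = c(logKuWater = "numeric", mKu = "numeric", temperatures = "numeric",
            kuTarget = "numeric", dGactBare = "numeric",
            dGactEyring = "numeric", predictionInterval = "numeric",
            targetTemperature = "numeric"))

#' MeltCurveFit: Boltzmann sigmoid fit of a thermal melt
#'
#' @slot tm melting temperature, degrees Celsius.
#' @slot slopeFactor transition slope factor (kelvin).
#' @slot baselinePre,baselinePost pre-/post-transition signal levels.
#' @slot rss residual sum of squares.
#' @export
setClass("MeltCurveFit",
  slots = c(tm = "numeric", slopeFactor = "numeric", baselinePre = "numeric",
            baselinePost = "numeric", rss = "numeric"))

## ---------------------------------------------------------------------------
## Trajectory network results
## ---------------------------------------------------------------------------

#' FluctuationProfile: per-residue RMSF about the mean structure
#'
#' @slot residueIds residue identifiers.
#' @slot rmsf angstrom, >= 0.
#' @export
setClass("FluctuationProfile",
  slots = c(residueIds = "integer", rmsf = "numeric"))

setValidity("FluctuationProfile", function(object) {
  if (length(object@rmsf) != length(object@residueIds))
    "one RMSF value per residue required"
  else if (any(object@rmsf < 0)) "RMSF must be >= 0" else TRUE
})

#' NativeContactProfile: native contacts and per-frame Q
#'
#' Native contacts are residue pairs (|i - j| > 3) whose reference C-alpha
#' distance is within the cutoff; Q is the per-frame fraction preserved.
#'
#' @slot contacts 2-column matrix of residue ids in native contact.
#' @slot Q per-frame fraction of native contacts, in [0, 1].
#' @slot subsetQ per-frame Q restricted to a pair subset (length 0 if none).
#' @slot subsetContacts the native contacts in the subset.
#' @slot cutoff angstrom.
#' @slot tolerance fractional slack on the cutoff when counting frames.
#' @export
setClass("NativeContactProfile",
  slots = c(contacts = "matrix", Q = "numeric", subsetQ = "numeric",
            subsetContacts = "matrix", cutoff = "numeric",
            tolerance = "numeric"))

setValidity("NativeContactProfile", function(object) {
  if (any(object@Q < 0 | object@Q > 1)) "Q must lie in [0, 1]" else TRUE
})

#' CorrelationNetwork: generalized-correlation residue network
#'
#' C holds the mutual-information generalized correlation r_MI in [0, 1];
#' edges are residue pairs passing the persistent-contact filter, with
#' graph distance -log(C_ij) so that highly coupled residues are close.
#'
#' @slot residueIds residue identifiers (nodes).
#' @slot C symmetric correlation matrix, diagonal 1.
#' @slot edges data.frame (i, j, cij, distance); i < j, residue ids.
#' @slot params list of filter parameters used.
#' @export
setClass("CorrelationNetwork",
  slots = c(residueIds = "integer", correlation = "matrix", edges = "data.frame",
            params = "list"),
  prototype = prototype(params = list()))

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  if (nrow(object@correlation) != length(object@residueIds) ||
      ncol(object@correlation) != length(object@residueIds))
    msg <- c(msg, "C must be square with one row per residue")
  else {
    if (max(abs(object@correlation - t(object@correlation))) > 1e-8)
      msg <- c(msg, "C must be symmetric")
    if (any(abs(diag(object@correlation) - 1) > 1e-8))
      msg <- c(msg, "diag(C) must be 1")
  }
  if (nrow(object@edges)) {
    if (any(object@edges$i == object@edges$j))
      msg <- c(msg, "no self-loops allowed")
    if (any(object@edges$distance < 0))
      msg <- c(msg, "edge distances must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' CommunityPartition: community decomposition of a correlation network
#'
#' @slot residueIds node identifiers.
#' @slot membership community id per node.
#' @slot betweenness node betweenness centrality on the weighted graph.
#' @slot coupling data.frame (community_a, community_b, coupling,
#'   one_minus_coupling): mean inter-community C_ij over retained edges.
#' @slot modularity modularity of the chosen partition.
#' @slot note diagnostic note (e.g. single community at max modularity).
#' @export
setClass("CommunityPartition",
  slots = c(residueIds = "integer", membership = "integer",
            betweenness = "numeric", coupling = "data.frame",
            modularity = "numeric", note = "character"),
  prototype = prototype(note = ""))

setValidity("CommunityPartition", function(object) {
  msg <- character()
  if (length(object@membership) != length(object@residueIds))
    msg <- c(msg, "one community id per node required")
  if (any(is.na(object@membership)))
    msg <- c(msg, "partition must cover all nodes")
  if (nrow(object@coupling) &&
      any(object@coupling$coupling < 0 | object@coupling$coupling > 1))
    msg <- c(msg, "coupling scores must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
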