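#' Accessors for DomainCoupling classes
#'
#' Slot accessors for the package's S4 containers: `peptide()`,
#' `timepoints()`, `percentD()` for uptake/envelope data; `residueIds()`,
#' `nFrames()`, `referenceCoords()` for trajectories; `rates()` for uptake
#' fits; `foldedFraction()` for bimodal fits; `membership()` and
#' `correlationMatrix()` for network results.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("peptide", "UptakeSeries", function(x) x@peptide)

#' @rdname accessors
#' @export
setMethod("peptide", "EnvelopeSeries", function(x) x@peptide)

#' @rdname accessors
#' @export
setMethod("timepoints", "UptakeSeries", function(x) x@timepoints)

#' @rdname accessors
#' @export
setMethod("timepoints", "EnvelopeSeries", function(x) x@timepoints)

#' @rdname accessors
#' @export
setMethod("percentD", "UptakeSeries", function(x) x@percentD)

#' @rdname accessors
#' @export
setMethod("residueIds", "TrajectoryEnsemble", function(x) x@residueIds)

#' @rdname accessors
#' @export
setMethod("residueIds", "CorrelationNetwork", function(x) x@residueIds)

#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(x) dim(x@frames)[1L])

#' @rdname accessors
#' @export
setMethod("referenceCoords", "TrajectoryEnsemble", function(x) x@reference)

#' @rdname accessors
#' @export
setMethod("rates", "UptakeFit", function(x) x@rates)

#' @rdname accessors
#' @export
setMethod("foldedFraction", "BimodalFit", function(x) x@Ff)

#' @rdname accessors
#' @export
setMethod("membership", "CommunityPartition",
          function(x) setNames(x@membership, x@residueIds))

#' @rdname accessors
#' @export
setMethod("correlationMatrix", "CorrelationNetwork", function(x) x@correlation)

## show methods ---------------------------------------------------------------

setMethod("show", "PeptideRecord", function(object) {
  cat(sprintf("PeptideRecord %s %d-%d %s\n", object@state, object@start,
              object@end,
              if (nzchar(object@sequence)) object@sequence else "<no sequence>"))
})

setMethod("show", "UptakeSeries", function(object) {
  cat(sprintf(
    "UptakeSeries: %s %d-%d | %d timepoints (%g-%g s) x %d replicates | %.2f K\n",
    object@peptide@state, object@peptide@start, object@peptide@end,
    length(object@timepoints), min(object@timepoints), max(object@timepoints),
    ncol(object@percentD), object@temperature))
})

setMethod("show", "EnvelopeSeries", function(object) {
  cat(sprintf("EnvelopeSeries: %s %d-%d | %d envelopes, %d-%d points each\n",
              object@peptide@state, object@peptide@start, object@peptide@end,
              length(object@envelopes),
              min(vapply(object@envelopes, nrow, 0L)),
              max(vapply(object@envelopes, nrow, 0L))))
})

setMethod("show", "UnfoldingCurve", function(object) {
  cat(sprintf("UnfoldingCurve (%s): %d points, axis %g-%g\n",
              object@axisKind, length(object@axisValues),
              min(object@axisValues), max(object@axisValues)))
})

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@frames)
  cat(sprintf("TrajectoryEnsemble: %d residues x %d frames\n", d[2], d[1]))
})

setMethod("show", "UptakeFit", function(object) {
  if (!object@converged) {
    cat("UptakeFit: <not converged>\n")
    return(invisible(NULL))
  }
  cat(sprintf("UptakeFit (order %d): A0 = %.2f %%D\n", object@modelOrder,
              object@A0))
  for (i in seq_along(object@rates))
    cat(sprintf("  A%d = %.2f %%D, k_HX%s = %.3g /s%s\n", i,
                object@amplitudes[i],
                if (object@modelOrder == 2L) as.character(i) else "",
                object@rates[i],
                if (!object@rateIdentifiable[i]) " [unidentifiable]" else ""))
})

setMethod("show", "DifferentialMap", function(object) {
  cat(sprintf("DifferentialMap %s vs %s: %d peptide-timepoint rows, %d unmatched peptides\n",
              object@stateB, object@stateA, nrow(object@table),
              nrow(object@unmatched)))
})

setMethod("show", "DifferentialEnergetics", function(object) {
  cat(sprintf("ddG_open(A-B) = %.3f kcal/mol at %.2f K (%s)\n",
              object@ddG, object@temperature, object@note))
})

setMethod("show", "BimodalFit", function(object) {
  cat(sprintf("BimodalFit: centroids %.2f / %.2f Da, widths %.2f / %.2f Da\n",
              object@centroidFolded, object@centroidUnfolded,
              object@widthFolded, object@widthUnfolded))
  cat("  F_f:", paste(sprintf("%.3f", object@Ff), collapse = " "), "\n")
})

setMethod("show", "UnfoldingKineticsFit", function(object) {
  cat(sprintf("k_u = %.4g /s; dG_act = %.2f kcal/mol at %.2f K (%d points)\n",
              object@ku, object@dGact, object@temperature, object@nPoints))
})

setMethod("show", "ActivationDifference", function(object) {
  cat(sprintf("ddG_act(B-A) = %.3f kcal/mol at %.2f K\n",
              object@ddGact, object@temperature))
})

setMethod("show", "UreaUnfoldingFit", function(object) {
  cat(sprintf("UreaUnfoldingFit: dG0 = %.3f kcal/mol, m = %.3f kcal/mol/M at %.2f K\n",
              object@dG0, object@mValue, object@temperature))
})

setMethod("show", "StabilityEstimate", function(object) {
  cat(sprintf("StabilityEstimate: dG0(water, %.2f K) = %.3f kcal/mol [%.3f, %.3f]\n",
              object@targetTemperature, object@dG0Water,
              object@predictionInterval[1], object@predictionInterval[2]))
})

setMethod("show", "RateExtrapolation", function(object) {
  cat(sprintf("RateExtrapolation: k_u(%.2f K) = %.4g /s; dG_act = %.2f (bare) / %.2f (Eyring) kcal/mol\n",
              object@targetTemperature, object@kuTarget, object@dGactBare,
              object@dGactEyring))
})

setMethod("show", "MeltCurveFit", function(object) {
  cat(sprintf("MeltCurveFit: T_m = %.2f C\n", object@tm))
})

setMethod("show", "FluctuationProfile", function(object) {
  cat(sprintf("FluctuationProfile: %d residues, RMSF %.3f-%.3f A\n",
              length(object@rmsf), min(object@rmsf), max(object@rmsf)))
})

setMethod("show", "NativeContactProfile", function(object) {
  cat(sprintf("NativeContactProfile: %d native contacts, mean Q = %.3f\n",
              nrow(object@contacts), mean(object@Q)))
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf("CorrelationNetwork: %d residues, %d retained edges\n",
              length(object@residueIds), nrow(object@edges)))
})

setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d communities, modularity %.3f%s\n",
              length(unique(object@membership)), object@modularity,
              if (nzchar(object@note)) paste0(" (", object@note, ")") else ""))
})
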