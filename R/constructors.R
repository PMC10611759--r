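#' Construct a PeptideRecord
#'
#' @param state protein state label.
#' @param start,end 1-based inclusive residue bounds.
#' @param sequence amino-acid sequence ("" when unknown).
#' @param charge optional positive charge state.
#' @return a [PeptideRecord-class].
#' @examples
#' PeptideRecord("WT", 1033, 1043, "LQARRRQSVLN")
#' @export
PeptideRecord <- function(state, start, end, sequence = "", charge = NA) {
  new("PeptideRecord", state = as.character(state),
      start = as.integer(start), end = as.integer(end),
      sequence = as.character(sequence), charge = as.integer(charge))
}

#' Construct an UptakeSeries
#'
#' @param peptide a [PeptideRecord-class].
#' @param timepoints labeling times in seconds, strictly increasing.
#' @param percentD matrix (timepoint x replicate) or vector of %D values.
#' @param temperature labeling temperature in kelvin (default 310.15, i.e.
#'   37 degrees C).
#' @param metadata optional list.
#' @return an [UptakeSeries-class].
#' @export
UptakeSeries <- function(peptide, timepoints, percentD,
                         temperature = 310.15, metadata = list()) {
  if (!is.matrix(percentD)) percentD <- matrix(percentD, ncol = 1L)
  new("UptakeSeries", peptide = peptide, timepoints = as.numeric(timepoints),
      percentD = percentD, temperature = temperature, metadata = metadata)
}

#' Construct an EnvelopeSeries
#'
#' @param peptide a [PeptideRecord-class].
#' @param timepoints labeling times in seconds.
#' @param envelopes list of 2-column matrices (mass_offset_Da, intensity).
#' @param metadata optional list.
#' @return an [EnvelopeSeries-class].
#' @export
EnvelopeSeries <- function(peptide, timepoints, envelopes, metadata = list()) {
  envelopes <- lapply(envelopes, function(e) {
    e <- as.matrix(e)
    colnames(e) <- c("mass_offset_Da", "intensity")
    e
  })
  new("EnvelopeSeries", peptide = peptide, timepoints = as.numeric(timepoints),
      envelopes = envelopes, metadata = metadata)
}

#' Construct an UnfoldingCurve
#'
#' @param axisKind "denaturant_molar" or "temperature_kelvin".
#' @param axisValues strictly increasing axis values (>= 6).
#' @param signal matrix (axis x replicate) or vector.
#' @param temperature kelvin; required for denaturant curves.
#' @param metadata optional list.
#' @return an [UnfoldingCurve-class].
#' @export
UnfoldingCurve <- function(axisKind, axisValues, signal,
                           temperature = NA_real_, metadata = list()) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1L)
  new("UnfoldingCurve", axisKind = axisKind,
      axisValues = as.numeric(axisValues), signal = signal,
      temperature = temperature, metadata = metadata)
}

#' Construct a TrajectoryEnsemble
#'
#' @param residueIds ordered residue identifiers.
#' @param frames array [frame x residue x 3], angstrom.
#' @param reference matrix residue x 3, angstrom.
#' @param frameSpacing time between frames (metadata only).
#' @param metadata optional list.
#' @return a [TrajectoryEnsemble-class].
#' @export
TrajectoryEnsemble <- function(residueIds, frames, reference,
                               frameSpacing = 1, metadata = list()) {
  new("TrajectoryEnsemble", residueIds = as.integer(residueIds),
      frames = frames, reference = as.matrix(reference),
      frameSpacing = frameSpacing, metadata = metadata)
}
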