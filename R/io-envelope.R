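#' Read isotope envelopes via a manifest
#'
#' The manifest is a CSV with columns `file, state, start, end, sequence,
#' time_s` binding one two-column envelope text file (columns
#' `mass_offset_Da, intensity`, whitespace separated, header line) to each
#' peptide/timepoint. Relative `file` paths are resolved against the
#' manifest's directory.
#'
#' @param manifestPath manifest CSV path.
#' @return list of [EnvelopeSeries-class], one per (state, peptide), with
#'   timepoints sorted increasing.
#' @seealso [writeEnvelopeSeries()]
#' @export
readEnvelopeManifest <- function(manifestPath) {
  mf <- utils::read.csv(manifestPath, stringsAsFactors = FALSE)
  need <- c("file", "state", "start", "end", "sequence", "time_s")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("envelope manifest format error: missing column(s) ",
         paste(miss, collapse = ", "))
  base <- dirname(manifestPath)
  mf$sequence <- as.character(mf$sequence)
  mf$sequence[is.na(mf$sequence)] <- ""
  key <- interaction(mf$state, mf$start, mf$end, mf$sequence, drop = TRUE)
  lapply(split(mf, key), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    envs <- lapply(g$file, function(f) {
      fp <- if (file.exists(f)) f else file.path(base, f)
      e <- as.matrix(utils::read.table(fp, header = TRUE))
      if (ncol(e) != 2L)
        stop("envelope file ", f, " must have exactly two columns")
      if (any(e[, 2L] < 0))
        stop("envelope file ", f, " has negative intensities")
      e
    })
    EnvelopeSeries(
      peptide = PeptideRecord(g$state[1L], g$start[1L], g$end[1L],
                              g$sequence[1L]),
      timepoints = g$time_s, envelopes = envs)
  })
}

#' Write an EnvelopeSeries as per-timepoint text files plus a manifest
#'
#' @param env an [EnvelopeSeries-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix for the envelope files.
#' @return the manifest path, invisibly.
#' @export
writeEnvelopeSeries <- function(env, dir, prefix = "envelope") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- env@peptide
  files <- character(length(env@timepoints))
  for (i in seq_along(env@timepoints)) {
    files[i] <- sprintf("%s_%s_%d-%d_t%g.txt", prefix, p@state, p@start,
                        p@end, env@timepoints[i])
    e <- env@envelopes[[i]]
    utils::write.table(
      data.frame(mass_offset_Da = sprintf("%.10g", e[, 1L]),
                 intensity = sprintf("%.10g", e[, 2L])),
      file.path(dir, files[i]), row.names = FALSE, quote = FALSE)
  }
  manifest <- file.path(dir, paste0(prefix, "_manifest.csv"))
  write_table_deterministic(
    data.frame(file = files, state = p@state, start = p@start, end = p@end,
               sequence = p@sequence, time_s = env@timepoints), manifest)
  invisible(manifest)
}

#' Read and write equilibrium unfolding curves
#'
#' CSV layout: columns `axis_value, signal` and optional `replicate`.
#' The axis kind (denaturant molarity or temperature in kelvin) and, for
#' denaturant curves, the experiment temperature are not part of the table
#' and are passed explicitly (or recovered from the `axis_kind` /
#' `temperature_K` columns when present).
#'
#' @param path CSV path.
#' @param axisKind "denaturant_molar" or "temperature_kelvin"; overridden by
#'   an `axis_kind` column if present.
#' @param temperature experiment temperature (kelvin) for denaturant curves.
#' @return an [UnfoldingCurve-class].
#' @export
readUnfoldingCurve <- function(path, axisKind = "denaturant_molar",
                               temperature = NA_real_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("axis_value", "signal"), names(df))
  if (length(miss))
    stop("unfolding curve format error: missing column(s) ",
         paste(miss, collapse = ", "))
  if ("axis_kind" %in% names(df)) axisKind <- df$axis_kind[1L]
  if ("temperature_K" %in% names(df)) temperature <- df$temperature_K[1L]
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  ax <- sort(unique(df$axis_value))
  reps <- sort(unique(df$replicate))
  sig <- matrix(NA_real_, length(ax), length(reps))
  sig[cbind(match(df$axis_value, ax), match(df$replicate, reps))] <- df$signal
  UnfoldingCurve(axisKind = axisKind, axisValues = ax, signal = sig,
                 temperature = temperature)
}

#' @rdname readUnfoldingCurve
#' @param curve an [UnfoldingCurve-class] to write.
#' @export
writeUnfoldingCurve <- function(curve, path) {
  idx <- which(!is.na(curve@signal), arr.ind = TRUE)
  df <- data.frame(axis_value = curve@axisValues[idx[, 1L]],
                   replicate = idx[, 2L], signal = curve@signal[idx],
                   axis_kind = curve@axisKind,
                   temperature_K = curve@temperature)
  df <- df[order(df$axis_value, df$replicate), ]
  write_table_deterministic(df, path)
  invisible(path)
}
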