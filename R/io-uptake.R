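#' Read a peptide-level HDX uptake table
#'
#' Expected CSV layout (UTF-8, comma separated, header required): columns
#' `state, start, end, sequence, time_s, replicate, percentD`, one row per
#' peptide/timepoint/replicate. Optional columns: `charge`,
#' `temperature_K` (default 310.15 K). Rows are grouped by
#' (state, start, end, sequence) into one [UptakeSeries-class] per peptide
#' and state. Readers reject, never repair: any %D outside [0, 100] is an
#' error naming the offending row.
#'
#' @param path CSV file path.
#' @param values "replicates" (default) when rows are individual replicate
#'   measurements, "means" when the table holds replicate means at export
#'   time (the `replicate` column is then optional and ignored).
#' @return list of [UptakeSeries-class], one per (state, peptide).
#' @seealso [writeUptakeTable()]
#' @export
readUptakeTable <- function(path, values = c("replicates", "means")) {
  values <- match.arg(values)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("state", "start", "end", "sequence", "time_s", "percentD")
  if (values == "replicates") need <- c(need, "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("uptake table format error: missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(!is.na(df$percentD) & (df$percentD < 0 | df$percentD > 100))
  if (length(bad))
    stop("uptake table validation error: percentD outside [0, 100] at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  bad <- which(is.na(df$percentD) | is.na(df$time_s) | is.na(df$start) |
                 is.na(df$end))
  if (length(bad))
    stop("uptake table validation error: missing required value at row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "))
  if (!"temperature_K" %in% names(df)) df$temperature_K <- 310.15
  if (!"charge" %in% names(df)) df$charge <- NA_integer_
  df$sequence <- as.character(df$sequence)
  df$sequence[is.na(df$sequence)] <- ""
  if (values == "means") df$replicate <- 1L

  key <- interaction(df$state, df$start, df$end, df$sequence, drop = TRUE)
  lapply(split(df, key), function(g) {
    tp <- sort(unique(g$time_s))
    reps <- sort(unique(g$replicate))
    mat <- matrix(NA_real_, nrow = length(tp), ncol = length(reps))
    mat[cbind(match(g$time_s, tp), match(g$replicate, reps))] <- g$percentD
    UptakeSeries(
      peptide = PeptideRecord(g$state[1L], g$start[1L], g$end[1L],
                              g$sequence[1L], g$charge[1L]),
      timepoints = tp, percentD = mat, temperature = g$temperature_K[1L])
  })
}

#' Write UptakeSeries objects to the standard uptake CSV
#'
#' Inverse of [readUptakeTable()]; reading the written file back yields the
#' same series up to floating-point formatting.
#'
#' @param seriesList list of [UptakeSeries-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeUptakeTable <- function(seriesList, path) {
  if (is(seriesList, "UptakeSeries")) seriesList <- list(seriesList)
  rows <- lapply(seriesList, function(s) {
    p <- s@peptide
    m <- s@percentD
    idx <- which(!is.na(m), arr.ind = TRUE)
    data.frame(state = p@state, start = p@start, end = p@end,
               sequence = p@sequence, time_s = s@timepoints[idx[, 1L]],
               replicate = idx[, 2L], percentD = m[idx],
               temperature_K = s@temperature, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$state, df$start, df$end, df$time_s, df$replicate), ]
  write_table_deterministic(df, path)
  invisible(path)
}

# fixed-precision CSV writer so that (config, seed) -> byte-identical output
write_table_deterministic <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) {
    x <- df[[j]]
    if (is.integer(x)) next
    df[[j]] <- ifelse(is.na(x), "NA", sprintf("%.10g", x))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}
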