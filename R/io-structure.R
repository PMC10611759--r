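#' Read a single-model reference structure (C-alpha level)
#'
#' Reads a standard PDB file through [bio3d::read.pdb()] and extracts one
#' C-alpha coordinate triple per residue, preserving file order. Multi-model
#' files are rejected (use [readTrajectory()] for those), as is any residue
#' lacking a C-alpha atom.
#'
#' @param path PDB file path.
#' @return list with `reference` (residue x 3 coordinate matrix, angstrom)
#'   and `residueIds` (integer residue numbers in file order).
#' @export
readReferenceStructure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (nrow(pdb$xyz) > 1L)
    stop("multi-model PDB: this is a trajectory; use readTrajectory()")
  atoms <- pdb$atom
  res_order <- unique(atoms$resno)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(res_order, ca$resno)
  if (length(missing_ca))
    stop("residue(s) lacking a C-alpha atom: ",
         paste(missing_ca, collapse = ", "))
  ca <- ca[match(res_order, ca$resno), , drop = FALSE]
  reference <- as.matrix(ca[, c("x", "y", "z")])
  dimnames(reference) <- NULL
  list(reference = reference, residueIds = as.integer(res_order))
}

#' Read a residue-coordinate trajectory
#'
#' Accepts a multi-model PDB (one C-alpha per residue per MODEL, read via
#' bio3d) or a plain per-frame coordinate CSV with columns
#' `frame, residue, x, y, z`. Binary trajectory dialects are out of scope.
#'
#' @param path trajectory file.
#' @param reference optional residue x 3 matrix used as the reference
#'   structure; defaults to the first frame.
#' @param format "auto" (by extension), "pdb" or "csv".
#' @param frameSpacing time between frames (metadata only).
#' @return a [TrajectoryEnsemble-class].
#' @export
readTrajectory <- function(path, reference = NULL,
                           format = c("auto", "pdb", "csv"),
                           frameSpacing = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "pdb"
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    ca_idx <- which(pdb$atom$elety == "CA")
    if (!length(ca_idx)) stop("no C-alpha atoms found")
    rid <- as.integer(pdb$atom$resno[ca_idx])
    xyz_cols <- as.vector(rbind(3 * ca_idx - 2, 3 * ca_idx - 1, 3 * ca_idx))
    xyz <- pdb$xyz[, xyz_cols, drop = FALSE]
    n_frames <- nrow(xyz)
    n_res <- length(rid)
    frames <- aperm(array(t(xyz), dim = c(3, n_res, n_frames)), c(3, 2, 1))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("frame", "residue", "x", "y", "z"), names(df))
    if (length(miss))
      stop("trajectory CSV format error: missing column(s) ",
           paste(miss, collapse = ", "))
    fr <- sort(unique(df$frame))
    rid <- sort(unique(df$residue))
    n_frames <- length(fr)
    n_res <- length(rid)
    if (nrow(df) != n_frames * n_res)
      stop("trajectory CSV must contain every residue in every frame")
    frames <- array(NA_real_, dim = c(n_frames, n_res, 3))
    fi <- match(df$frame, fr)
    ri <- match(df$residue, rid)
    frames[cbind(fi, ri, 1L)] <- df$x
    frames[cbind(fi, ri, 2L)] <- df$y
    frames[cbind(fi, ri, 3L)] <- df$z
    rid <- as.integer(rid)
  }
  if (is.null(reference)) reference <- frames[1L, , ]
  TrajectoryEnsemble(residueIds = rid, frames = frames,
                     reference = as.matrix(reference),
                     frameSpacing = frameSpacing)
}

#' Write a trajectory
#'
#' `writeTrajectoryCSV` writes the plain per-frame coordinate table that
#' [readTrajectory()] reads; `writeTrajectoryPDB` emits a minimal
#' multi-model C-alpha PDB (MODEL/ENDMDL records) readable by bio3d and any
#' structure viewer.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path) {
  d <- dim(traj@frames)
  df <- data.frame(
    frame = rep(seq_len(d[1L]), each = d[2L]),
    residue = rep(traj@residueIds, times = d[1L]),
    x = as.vector(t(traj@frames[, , 1L])),
    y = as.vector(t(traj@frames[, , 2L])),
    z = as.vector(t(traj@frames[, , 3L])))
  write_table_deterministic(df, path)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
writeTrajectoryPDB <- function(traj, path) {
  d <- dim(traj@frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1L])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(format_ca_atoms(traj@frames[f, , , drop = TRUE],
                               traj@residueIds), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# fixed-format C-alpha ATOM records (PDB v3.3 columns)
format_ca_atoms <- function(coords, residueIds, b = NULL) {
  coords <- matrix(coords, ncol = 3L)
  if (is.null(b)) b <- rep(0, nrow(coords))
  sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          seq_len(nrow(coords)), residueIds,
          coords[, 1L], coords[, 2L], coords[, 3L], 1.00, b)
}

#' Project per-residue scalar values onto a structure
#'
#' Writes a C-alpha PDB with the scalar in the B-factor column (fixed
#' \%6.2f format, values clipped to the writable range) plus a sidecar CSV
#' (`<path>.csv`) holding the unclipped values. Missing values get the
#' configured sentinel in the B-factor column and NA in the CSV. This is the
#' standard vehicle for pseudo-colour projection of differential deuteration
#' or RMSF onto a structure.
#'
#' @param reference residue x 3 coordinate matrix (or the list returned by
#'   [readReferenceStructure()]).
#' @param values numeric, one value per residue (NA allowed).
#' @param path output PDB path.
#' @param residueIds residue numbers; taken from `reference` when it is a
#'   [readReferenceStructure()] result.
#' @param sentinel B-factor written for missing values (default -1).
#' @param clip length-2 range the B-factor column is clipped to.
#' @return `path`, invisibly.
#' @export
writeResidueProjection <- function(reference, values, path,
                                   residueIds = NULL, sentinel = -1,
                                   clip = c(-99.99, 999.99)) {
  if (is.list(reference) && !is.null(reference$reference)) {
    if (is.null(residueIds)) residueIds <- reference$residueIds
    reference <- reference$reference
  }
  if (is.null(residueIds)) residueIds <- seq_len(nrow(reference))
  if (length(values) != nrow(reference))
    stop("value count (", length(values), ") does not match residue count (",
         nrow(reference), ")")
  b <- pmin(pmax(values, clip[1L]), clip[2L])
  b[is.na(values)] <- sentinel
  writeLines(c(format_ca_atoms(reference, residueIds, b = b), "END"), path)
  write_table_deterministic(
    data.frame(residue = residueIds, value = values), paste0(path, ".csv"))
  invisible(path)
}
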