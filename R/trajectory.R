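## Trajectory analysis: RMSF, fraction of native contacts, mutual-information
## generalized-correlation networks, Girvan-Newman communities, betweenness
## centrality and inter-community coupling.

# flatten [frame x residue x 3] to the frames x 3N layout bio3d uses
frames_to_xyz <- function(frames) {
  d <- dim(frames)
  out <- matrix(0, d[1L], d[2L] * 3L)
  for (ax in 1:3) out[, seq(ax, d[2L] * 3L, by = 3L)] <- frames[, , ax]
  out
}

xyz_to_frames <- function(xyz, n_res) {
  n_frames <- nrow(xyz)
  fr <- array(0, dim = c(n_frames, n_res, 3))
  for (ax in 1:3) fr[, , ax] <- xyz[, seq(ax, n_res * 3L, by = 3L)]
  fr
}

# least-squares rigid-body superposition of every frame onto the reference
superpose_frames <- function(traj, fitSubset = NULL) {
  n_res <- length(traj@residueIds)
  sv <- svd(scale(traj@reference, scale = FALSE))
  if (sum(sv$d > 1e-8 * max(sv$d)) < 2L)
    stop("degenerate (collinear) reference: rigid-body superposition ",
         "is underdetermined")
  fixed <- as.vector(t(traj@reference))
  mobile <- frames_to_xyz(traj@frames)
  idx <- if (is.null(fitSubset)) seq_len(n_res)
         else match(fitSubset, traj@residueIds)
  xyz_inds <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = mobile,
                           fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  xyz_to_frames(fitted, n_res)
}

#' Per-residue root mean square fluctuation
#'
#' Frames are superposed onto the reference by least-squares rigid-body
#' fitting (over all residues, or `fitSubset`); RMSF_i is the root mean
#' square displacement of residue i about its mean position, in angstrom.
#' For isotropic Gaussian jitter of per-coordinate sd sigma the expected
#' RMSF is sigma * sqrt(3).
#'
#' @param traj a [TrajectoryEnsemble-class] with >= 10 frames.
#' @param fitSubset optional residue ids used for the superposition.
#' @return a [FluctuationProfile-class].
#' @export
rmsf <- function(traj, fitSubset = NULL) {
  if (nFrames(traj) < 10L) stop("need >= 10 frames for RMSF")
  fr <- superpose_frames(traj, fitSubset)
  n_res <- length(traj@residueIds)
  vals <- vapply(seq_len(n_res), function(i) {
    x <- fr[, i, , drop = TRUE]
    mu <- colMeans(x)
    sqrt(mean(rowSums((x - matrix(mu, nrow(x), 3, byrow = TRUE))^2)))
  }, 0)
  new("FluctuationProfile", residueIds = traj@residueIds, rmsf = vals)
}

# 2-column matrix of native-contact pairs (residue ids) on the reference
native_contact_pairs <- function(traj, cutoff, minSeqSep = 3L) {
  D <- as.matrix(stats::dist(traj@reference))
  rid <- traj@residueIds
  sep <- abs(outer(rid, rid, "-"))
  keep <- upper.tri(D) & sep > minSeqSep & D <= cutoff
  idx <- which(keep, arr.ind = TRUE)
  cbind(i = rid[idx[, 1L]], j = rid[idx[, 2L]])
}

#' Fraction of native contacts per frame
#'
#' Native contacts are residue pairs with sequence separation > 3 whose
#' reference C-alpha distance is <= `cutoff` (default 8 angstrom). Per
#' frame, Q is the fraction of native pairs with distance <=
#' `cutoff * (1 + tolerance)` (hard count; `soft = TRUE` switches to the
#' smooth logistic count `1 / (1 + exp(beta (d - lambda d0)))` with the
#' native pair distance d0). `subset` restricts an additional Q trace to the
#' native contacts within an explicit pair set (e.g. one loop against the
#' rest of the protein).
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param subset optional 2-column matrix of residue-id pairs.
#' @param cutoff native-contact distance cutoff, angstrom.
#' @param tolerance fractional slack when counting a contact as preserved.
#' @param soft logistic soft counting instead of the hard count.
#' @param beta,lambda soft-count parameters (1/angstrom, unitless).
#' @return a [NativeContactProfile-class].
#' @export
nativeContacts <- function(traj, subset = NULL, cutoff = 8, tolerance = 0,
                           soft = FALSE, beta = 5, lambda = 1.2) {
  contacts <- native_contact_pairs(traj, cutoff)
  if (!nrow(contacts))
    stop("empty native contact set; increase the cutoff")
  rid <- traj@residueIds
  ci <- match(contacts[, 1L], rid)
  cj <- match(contacts[, 2L], rid)
  d0 <- sqrt(rowSums((traj@reference[ci, , drop = FALSE] -
                        traj@reference[cj, , drop = FALSE])^2))
  pair_dist <- function(f)
    sqrt(rowSums((traj@frames[f, ci, , drop = TRUE] -
                    traj@frames[f, cj, , drop = TRUE])^2))
  qval <- function(d, sel) {
    if (!any(sel)) return(NA_real_)
    if (soft) mean(1 / (1 + exp(beta * (d[sel] - lambda * d0[sel]))))
    else mean(d[sel] <= cutoff * (1 + tolerance))
  }
  sub_sel <- rep(FALSE, nrow(contacts))
  sub_contacts <- matrix(integer(), ncol = 2L)
  if (!is.null(subset)) {
    subset <- as.matrix(subset)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    sub_sel <- key(contacts[, 1L], contacts[, 2L]) %in%
      key(subset[, 1L], subset[, 2L])
    sub_contacts <- contacts[sub_sel, , drop = FALSE]
  }
  nf <- nFrames(traj)
  Q <- numeric(nf)
  subQ <- if (any(sub_sel)) numeric(nf) else numeric(0)
  for (f in seq_len(nf)) {
    d <- pair_dist(f)
    Q[f] <- qval(d, rep(TRUE, length(d)))
    if (length(subQ)) subQ[f] <- qval(d, sub_sel)
  }
  new("NativeContactProfile", contacts = contacts, Q = Q, subsetQ = subQ,
      subsetContacts = sub_contacts, cutoff = cutoff, tolerance = tolerance)
}

#' Generalized correlation matrix from residue motions
#'
#' Computes the mutual-information generalized correlation of every residue
#' pair's 3-D displacement fluctuations (after rigid-body superposition):
#' `r_MI = sqrt(1 - exp(-2 I / 3))`, clipped to [0, 1], diagonal 1, where I
#' is estimated with the Kraskov k-nearest-neighbour estimator (Chebyshev
#' norm; `k` defaults to 6). For jointly Gaussian motions with
#' per-coordinate correlation rho the closed form is I = -(3/2) ln(1 -
#' rho^2), i.e. r_MI = rho. Frames beyond `maxFrames` are subsampled on a
#' deterministic stride to bound the O(frames^2) estimator cost.
#'
#' Frames are assumed already aligned (merged-and-aligned trajectories are
#' the standard input to this analysis); set `superpose = TRUE` to
#' rigid-body fit them onto the reference here instead. Note that
#' superposition removes the common-mode component of motion and therefore
#' redistributes correlation among residues.
#'
#' @param traj a [TrajectoryEnsemble-class].
#' @param k nearest-neighbour order of the estimator.
#' @param maxFrames frame budget for the estimator (deterministic stride).
#' @param superpose rigid-body fit frames onto the reference first.
#' @return a [CorrelationNetwork-class] holding the matrix; its edge set is
#'   empty until [buildNetwork()] applies the contact filter.
#' @export
generalizedCorrelation <- function(traj, k = 6, maxFrames = 2000,
                                   superpose = FALSE) {
  nf <- nFrames(traj)
  if (nf <= k) stop("need more frames than k = ", k)
  if (nf < 500) warning("fewer than 500 frames; r_MI estimates will be noisy")
  fr <- if (superpose) superpose_frames(traj) else traj@frames
  if (nf > maxFrames) {
    stride <- seq(1L, nf, length.out = maxFrames)
    fr <- fr[unique(round(stride)), , , drop = FALSE]
  }
  n_res <- length(traj@residueIds)
  # displacement fluctuations about the mean, packed per residue
  coords <- matrix(0, nrow = dim(fr)[1L], ncol = 3L * n_res)
  for (r in seq_len(n_res))
    for (ax in 1:3)
      coords[, 3L * (r - 1L) + ax] <- fr[, r, ax] - mean(fr[, r, ax])
  I <- .ksg_mi_matrix(coords, n_res, as.integer(k))
  C <- sqrt(pmin(pmax(1 - exp(-2 * I / 3), 0), 1))
  diag(C) <- 1
  new("CorrelationNetwork", residueIds = traj@residueIds, correlation = C,
      edges = data.frame(i = integer(), j = integer(), cij = numeric(),
                         distance = numeric()),
      params = list(k = k, estimator = "KSG-1"))
}

#' Generalized correlation of one residue pair
#'
#' @param x,y n x 3 displacement matrices.
#' @param k nearest-neighbour order.
#' @return r_MI in [0, 1].
#' @rdname generalizedCorrelation
#' @export
generalizedCorrelationPair <- function(x, y, k = 6) {
  I <- .ksg_mi_pair(as.matrix(x), as.matrix(y), as.integer(k))
  sqrt(max(0, min(1, 1 - exp(-2 * I / 3))))
}

#' Build the correlation network with a persistent-contact filter
#'
#' Edges are retained for residue pairs that are in persistent spatial
#' contact (C-alpha distance <= `contactCutoff` in at least `occupancy` of
#' frames; default 10 angstrom in >= 75%) and whose generalized correlation
#' exceeds `floor`. The edge distance is `-log(C_ij)`, so highly coupled
#' residues are close in the graph. Raising the occupancy threshold can
#' only remove edges, never add them.
#'
#' @param C a [CorrelationNetwork-class] from [generalizedCorrelation()] (or
#'   a bare correlation matrix).
#' @param traj the underlying [TrajectoryEnsemble-class].
#' @param contactCutoff angstrom.
#' @param occupancy minimum fraction of frames in contact.
#' @param floor minimum C_ij for a retained edge.
#' @return a [CorrelationNetwork-class] with the edge table filled in; a
#'   disconnected graph triggers a warning with a component report.
#' @export
buildNetwork <- function(C, traj, contactCutoff = 10, occupancy = 0.75,
                         floor = 0.01) {
  mat <- if (is(C, "CorrelationNetwork")) C@correlation else C
  rid <- traj@residueIds
  n <- length(rid)
  nf <- nFrames(traj)
  occ <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    D <- as.matrix(stats::dist(traj@frames[f, , , drop = TRUE]))
    occ <- occ + (D <= contactCutoff)
  }
  occ <- occ / nf
  keep <- upper.tri(occ) & occ >= occupancy & mat >= floor
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(i = rid[idx[, 1L]], j = rid[idx[, 2L]],
                      cij = mat[idx],
                      distance = -log(pmin(mat[idx], 1)))
  edges <- edges[order(edges$i, edges$j), ]
  rownames(edges) <- NULL
  net <- new("CorrelationNetwork", residueIds = rid, correlation = mat, edges = edges,
             params = list(contactCutoff = contactCutoff,
                           occupancy = occupancy, floor = floor))
  g <- network_graph(net)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    warning("network is disconnected: ", comp$no, " components of sizes ",
            paste(comp$csize, collapse = ", "))
  net
}

# igraph representation; edge attributes cij (similarity) and distance
network_graph <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net@edges$i),
               to = as.character(net@edges$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net@residueIds)))
  igraph::E(g)$cij <- net@edges$cij
  # betweenness on zero-length edges (C_ij = 1) needs a positive floor
  igraph::E(g)$distance <- pmax(net@edges$distance, 1e-12)
  g
}

#' Community decomposition of a correlation network
#'
#' Girvan-Newman divisive clustering: edges are removed in decreasing order
#' of (distance-weighted) edge betweenness, ties broken deterministically by
#' the lexicographically smallest endpoint pair; the partition with maximal
#' modularity (computed on the full graph with C_ij as edge weights) is
#' returned. Node betweenness centrality is computed on the weighted full
#' graph. The coupling score of a community pair is the mean C_ij over the
#' retained edges joining them (reported alongside `1 - coupling`, the
#' edge-thickness convention of community diagrams).
#'
#' @param net a [CorrelationNetwork-class] with edges (see [buildNetwork()]).
#' @return a [CommunityPartition-class]; when maximal modularity yields a
#'   single community the partition is returned with a note.
#' @export
communities <- function(net) {
  if (length(net@residueIds) < 3L || nrow(net@edges) < 1L)
    stop("need a network with >= 3 nodes and >= 1 edge")
  g0 <- network_graph(net)
  g <- g0
  # divisive edge-removal sequence
  best_mod <- -Inf
  best_mem <- igraph::components(g)$membership
  repeat {
    if (igraph::ecount(g) == 0L) break
    eb <- igraph::edge_betweenness(g, weights = igraph::E(g)$distance)
    mx <- max(eb)
    cand <- which(eb >= mx - 1e-12)
    if (length(cand) > 1L) {
      ends <- igraph::ends(g, cand)
      ord <- order(as.integer(ends[, 1L]), as.integer(ends[, 2L]))
      cand <- cand[ord[1L]]
    }
    g <- igraph::delete_edges(g, cand)
    mem <- igraph::components(g)$membership
    mod <- igraph::modularity(g0, mem, weights = igraph::E(g0)$cij)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_mem <- mem
    }
  }
  # initial (uncut) partition competes too
  mem0 <- igraph::components(g0)$membership
  mod0 <- igraph::modularity(g0, mem0, weights = igraph::E(g0)$cij)
  if (mod0 > best_mod + 1e-12) {
    best_mod <- mod0
    best_mem <- mem0
  }
  note <- if (length(unique(best_mem)) < 2L)
    "single community at maximal modularity" else ""
  btw <- igraph::betweenness(g0, weights = igraph::E(g0)$distance)
  # inter-community coupling over retained edges
  mem_of <- best_mem[as.character(net@residueIds)]
  ei <- mem_of[as.character(net@edges$i)]
  ej <- mem_of[as.character(net@edges$j)]
  inter <- ei != ej
  coupling <- if (any(inter)) {
    ca <- pmin(ei[inter], ej[inter])
    cb <- pmax(ei[inter], ej[inter])
    agg <- stats::aggregate(net@edges$cij[inter],
                            by = list(community_a = ca, community_b = cb),
                            FUN = mean)
    data.frame(community_a = agg$community_a, community_b = agg$community_b,
               coupling = agg$x, one_minus_coupling = 1 - agg$x)
  } else {
    data.frame(community_a = integer(), community_b = integer(),
               coupling = numeric(), one_minus_coupling = numeric())
  }
  new("CommunityPartition", residueIds = net@residueIds,
      membership = as.integer(mem_of),
      betweenness = as.numeric(btw[as.character(net@residueIds)]),
      coupling = coupling, modularity = best_mod, note = note)
}

#' Export network results as tidy CSVs
#'
#' `writeNetworkEdges` writes the edge list (i, j, cij, distance);
#' `writeCommunityTable` writes per-residue community ids and betweenness.
#'
#' @param net a [CorrelationNetwork-class].
#' @param partition a [CommunityPartition-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkEdges <- function(net, path) {
  write_table_deterministic(net@edges, path)
  invisible(path)
}

#' @rdname writeNetworkEdges
#' @export
writeCommunityTable <- function(partition, path) {
  write_table_deterministic(
    data.frame(residue = partition@residueIds,
               community = partition@membership,
               betweenness = partition@betweenness), path)
  invisible(path)
}
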