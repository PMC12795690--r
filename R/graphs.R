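#' Construct a geometric graph object
#'
#' Container for graphs over point clouds: node positions, node features,
#' a directed edge index storing both directions of every undirected edge,
#' and optional per-edge attributes (distance in Angstrom, dihedral in
#' radians).
#'
#' @param pos N x 3 node positions.
#' @param edge_index E x 2 integer matrix of directed edges (1-based,
#'   columns `from`, `to`); each undirected edge appears in both
#'   directions.
#' @param x Optional N x F node feature matrix.
#' @param edge_attr Optional data frame with one row per directed edge.
#' @param method Builder tag ("schull", "radius", "knn", "complete").
#' @return Object of class `geometric_graph`.
#' @export
geometric_graph <- function(pos, edge_index, x = NULL, edge_attr = NULL,
                            method = "custom") {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  edge_index <- matrix(as.integer(edge_index), ncol = 2)
  colnames(edge_index) <- c("from", "to")
  if (nrow(edge_index) > 0) {
    stopifnot(all(edge_index >= 1), all(edge_index <= n))
    if (any(edge_index[, 1] == edge_index[, 2]))
      stop("self-loops are not stored in a geometric_graph")
    key <- paste(edge_index[, 1], edge_index[, 2])
    rev_key <- paste(edge_index[, 2], edge_index[, 1])
    if (anyDuplicated(key)) stop("duplicate directed edges")
    if (!all(rev_key %in% key))
      stop("every edge (i,j) must have its mirror (j,i)")
  }
  structure(list(pos = pos, x = x, edge_index = edge_index,
                 edge_attr = edge_attr),
            method = method, class = "geometric_graph")
}

#' @export
print.geometric_graph <- function(x, ...) {
  cat(sprintf("<geometric_graph:%s> %d nodes, %d undirected edges\n",
              attr(x, "method"), nrow(x$pos), nrow(x$edge_index) / 2L))
  invisible(x)
}

#' Number of undirected edges of a geometric graph
#' @param graph A [geometric_graph()].
#' @return Integer count.
#' @export
n_undirected_edges <- function(graph) nrow(graph$edge_index) %/% 2L

#' Is the graph a single connected component?
#' @param graph A [geometric_graph()].
#' @return Logical.
#' @export
is_connected_graph <- function(graph) {
  n <- nrow(graph$pos)
  if (n <= 1) return(TRUE)
  if (nrow(graph$edge_index) == 0) return(FALSE)
  # breadth-first search over the adjacency list
  adj <- split(graph$edge_index[, 2], graph$edge_index[, 1])
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    nb <- unlist(adj[as.character(queue)], use.names = FALSE)
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    queue <- unique(nb)
  }
  all(seen)
}

# undirected pair list (i < j) -> directed both ways
symmetrize_edges <- function(pairs) {
  if (length(pairs) == 0 || nrow(pairs) == 0)
    return(matrix(integer(0), 0, 2))
  und <- unique(cbind(pmin(pairs[, 1], pairs[, 2]),
                      pmax(pairs[, 1], pairs[, 2])))
  rbind(und, und[, 2:1, drop = FALSE])
}

#' Spherical convex hull (SCHull) graph construction
#'
#' Projects the points onto a unit sphere centred at their centroid, takes
#' the 3-D convex hull of the projections, and connects two original points
#' iff the hull contains the edge between their projections. The result is
#' a connected graph whose undirected edge count is at most `3N - 6`,
#' without any distance or neighbour-count hyperparameter. Near-coincident
#' projections (closer than `dedup_tol` on the unit sphere) are collapsed,
#' keeping the point farthest from the centroid; collapsed points are
#' re-attached to their representative's edges.
#'
#' @param points N x 3 numeric matrix (N >= 4 for a proper hull; smaller
#'   inputs fall back to the complete graph with a warning).
#' @param x Optional node features to store on the graph.
#' @param dedup_tol Chord-distance tolerance for coincident projections.
#' @param jitter_retry If the projections are degenerate (coplanar through
#'   the centroid), retry once with a seeded 1e-6 Angstrom jitter instead of
#'   failing.
#' @return A [geometric_graph()] with hull metadata (used by
#'   [edge_features()]) stored in attribute `hull`.
#' @export
build_schull <- function(points, x = NULL, dedup_tol = 1e-8,
                         jitter_retry = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 4) {
    warning("fewer than 4 points: falling back to the complete graph")
    pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(integer(0), 0, 2)
    return(geometric_graph(points, symmetrize_edges(pairs), x = x,
                           method = "complete"))
  }
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  r <- sqrt(rowSums(cen^2))
  if (all(r < 1e-12)) stop_ptppi("ptppi_degenerate_geometry",
                                 "all points coincide with the centroid")
  proj <- cen / pmax(r, 1e-12)

  # deduplicate near-coincident projections, keeping the farthest point
  ord <- order(-r)
  keep <- integer(0)
  group_of <- integer(n)
  for (i in ord) {
    assigned <- FALSE
    if (length(keep)) {
      d2 <- colSums((t(proj[keep, , drop = FALSE]) - proj[i, ])^2)
      hit <- which(d2 < dedup_tol^2)
      if (length(hit)) { group_of[i] <- keep[hit[1]]; assigned <- TRUE }
    }
    if (!assigned) { keep <- c(keep, i); group_of[i] <- i }
  }
  keep <- sort(keep)
  sub <- proj[keep, , drop = FALSE]

  faces <- tryCatch(.convex_hull_faces(sub),
                    error = function(e) e)
  if (inherits(faces, "error")) {
    if (jitter_retry) {
      jit <- with_seed(20240811L, matrix(rnorm(3 * n, sd = 1e-6), n, 3))
      return(build_schull(points + jit, x = x, dedup_tol = dedup_tol,
                          jitter_retry = FALSE))
    }
    stop_ptppi("ptppi_degenerate_geometry",
               paste0("degenerate projection geometry: ",
                      conditionMessage(faces),
                      " (set jitter_retry = TRUE to perturb and retry)"))
  }
  faces_orig <- matrix(keep[faces], ncol = 3)

  pairs <- rbind(faces_orig[, c(1, 2)], faces_orig[, c(2, 3)],
                 faces_orig[, c(3, 1)])
  ei <- symmetrize_edges(pairs)

  # re-attach deduplicated points to their representative
  dropped <- setdiff(seq_len(n), keep)
  if (length(dropped)) {
    extra <- cbind(dropped, group_of[dropped])
    ei <- rbind(ei, extra, extra[, 2:1, drop = FALSE])
  }
  g <- geometric_graph(points, ei, x = x, method = "schull")
  attr(g, "hull") <- list(faces = faces_orig, proj = proj, centroid = ctr)
  g
}

#' Edge distance and dihedral features for SCHull graphs
#'
#' Per directed edge: the Euclidean distance between the original points,
#' and the interior dihedral angle (radians, in \[0, pi\]) between the two
#' hull faces sharing the projected edge. Edges incident to fewer than two
#' hull faces (deduplicated re-attachments, degenerate hulls) get dihedral
#' `pi`; the count is attached as attribute `no_face_count`.
#'
#' @param graph A graph built by [build_schull()].
#' @param points Optional point matrix (defaults to `graph$pos`).
#' @return Data frame with columns `dist`, `dihedral`, one row per directed
#'   edge of `graph`.
#' @export
edge_features <- function(graph, points = graph$pos) {
  hull <- attr(graph, "hull")
  if (is.null(hull)) stop("edge_features() needs a graph built by build_schull()")
  ei <- graph$edge_index
  d <- sqrt(rowSums((points[ei[, 1], , drop = FALSE] -
                       points[ei[, 2], , drop = FALSE])^2))

  faces <- hull$faces
  proj <- hull$proj
  fnorm <- face_normals(proj, faces)

  # map undirected edge key -> adjacent face rows
  fe <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  fid <- rep(seq_len(nrow(faces)), 3)
  key <- paste(pmin(fe[, 1], fe[, 2]), pmax(fe[, 1], fe[, 2]))
  by_edge <- split(fid, key)

  ekey <- paste(pmin(ei[, 1], ei[, 2]), pmax(ei[, 1], ei[, 2]))
  dihedral <- rep(pi, nrow(ei))
  nf <- 0L
  hit <- by_edge[ekey]
  for (row in seq_len(nrow(ei))) {
    fs <- hit[[row]]
    if (is.null(fs) || length(fs) < 2) { nf <- nf + 1L; next }
    cosang <- sum(fnorm[fs[1], ] * fnorm[fs[2], ])
    cosang <- min(1, max(-1, cosang))
    dihedral[row] <- pi - acos(cosang)
  }
  out <- data.frame(dist = d, dihedral = dihedral)
  attr(out, "no_face_count") <- nf %/% 2L
  out
}

# outward unit normals of oriented hull faces
face_normals <- function(pts, faces) {
  a <- pts[faces[, 1], , drop = FALSE]
  b <- pts[faces[, 2], , drop = FALSE]
  c_ <- pts[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  nrm / sqrt(rowSums(nrm^2))
}

#' Radius-cutoff graph builder
#'
#' Connects two points iff `0 < dist <= r`. Isolated nodes are permitted;
#' their count is attached as attribute `isolated`.
#'
#' @param points N x 3 matrix.
#' @param r Cutoff radius (Angstrom), positive.
#' @param x Optional node features.
#' @return A [geometric_graph()].
#' @export
build_radius_graph <- function(points, r, x = NULL) {
  stopifnot(r > 0)
  points <- as.matrix(points)
  n <- nrow(points)
  d2 <- cross_dist2(points, points)
  adj <- d2 <= r^2 & d2 > 0
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  g <- geometric_graph(points, symmetrize_edges(idx), x = x, method = "radius")
  deg <- tabulate(g$edge_index[, 1], n)
  attr(g, "isolated") <- sum(deg == 0)
  g
}

#' k-nearest-neighbour graph builder
#'
#' Directed edges from each node to its `k` nearest neighbours (distance
#' ties broken by lower index), then symmetrised by union.
#'
#' @param points N x 3 matrix.
#' @param k Neighbour count, `1 <= k < N`.
#' @param x Optional node features.
#' @return A [geometric_graph()].
#' @export
build_knn_graph <- function(points, k, x = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1 || k >= n)
    stop_ptppi("ptppi_parameter_error", "need 1 <= k < number of points")
  d2 <- cross_dist2(points, points)
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
  pairs <- cbind(rep(seq_len(n), each = k), as.integer(t(nn)))
  geometric_graph(points, symmetrize_edges(pairs), x = x, method = "knn")
}
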