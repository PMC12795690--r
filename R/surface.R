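#' Surface sampler configuration
#'
#' Parameters of the on-the-fly molecular surface sampler. The surface is
#' the level set \eqn{f(x) = o} of a smooth-min distance field over the
#' atoms,
#' \deqn{f(x) = -s \log \sum_k \exp(-(\|x - a_k\| - r_k)/s),}
#' where \eqn{r_k} is the per-element atomic radius, \eqn{s} the smoothing
#' width and \eqn{o} the level-set offset. Seed points are scattered around
#' every atom and converged onto the level set by damped Newton descent
#' along the analytic field gradient; surviving points are thinned so that
#' no two are closer than `subsample_spacing`.
#'
#' @param atom_radius_map Named numeric vector of per-element radii
#'   (Angstrom); defaults to van der Waals values.
#' @param level_set_offset Offset of the sampled level set above the atomic
#'   radii (Angstrom).
#' @param seeds_per_atom Number of random seed points per atom.
#' @param descent_steps Maximum descent iterations.
#' @param descent_step_size Damping factor of the Newton step.
#' @param subsample_spacing Minimum distance between retained surface
#'   points (Angstrom).
#' @param smoothing_sigma Smooth-min temperature `s` (Angstrom).
#' @param k_chem Number of nearest atoms used by the chemical features.
#' @param rng_seed Seed for the (fully deterministic) sampler.
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(atom_radius_map = default_atom_radii(),
                           level_set_offset = 1.05,
                           seeds_per_atom = 20L,
                           descent_steps = 50L,
                           descent_step_size = 1.0,
                           subsample_spacing = 1.0,
                           smoothing_sigma = 1.0,
                           k_chem = 16L,
                           rng_seed = 1L) {
  stopifnot(level_set_offset > 0, seeds_per_atom >= 1, descent_steps > 0,
            descent_step_size > 0, subsample_spacing > 0,
            smoothing_sigma > 0, k_chem >= 1, all(atom_radius_map > 0))
  structure(list(atom_radius_map = atom_radius_map,
                 level_set_offset = level_set_offset,
                 seeds_per_atom = as.integer(seeds_per_atom),
                 descent_steps = as.integer(descent_steps),
                 descent_step_size = descent_step_size,
                 subsample_spacing = subsample_spacing,
                 smoothing_sigma = smoothing_sigma,
                 k_chem = as.integer(k_chem),
                 rng_seed = as.integer(rng_seed)),
            class = "sampler_config")
}

#' Smooth-min distance field and its gradient
#'
#' Evaluates the soft distance field underlying the surface sampler at a set
#' of query points, returning field values and (optionally) analytic
#' gradients.
#'
#' @param x Numeric matrix of query points (m x 3).
#' @param cloud An [atom_cloud()].
#' @param cfg A [sampler_config()].
#' @param gradient Also return the m x 3 gradient matrix?
#' @return List with `value` (length m) and, if requested, `grad` (m x 3).
#' @export
distance_field <- function(x, cloud, cfg = sampler_config(), gradient = FALSE) {
  x <- matrix(as.double(x), ncol = 3)
  s <- cfg$smoothing_sigma
  radii <- cfg$atom_radius_map[cloud$elements]
  d2 <- cross_dist2(x, cloud$coords)
  d <- sqrt(d2)
  z <- -(sweep(d, 2, radii)) / s          # m x A
  zmax <- apply(z, 1, max)
  e <- exp(z - zmax)
  sum_e <- rowSums(e)
  val <- -s * (log(sum_e) + zmax)
  out <- list(value = as.numeric(val))
  if (gradient) {
    p <- e / sum_e                         # softmax weights, m x A
    # grad = sum_k p_k (x - a_k)/d_k, expressed as one mat-vec per axis
    W <- p / pmax(d, 1e-12)
    out$grad <- x * rowSums(W) - W %*% cloud$coords
  }
  out
}

#' Sample an oriented surface point cloud
#'
#' Generates surface points on the smooth-min distance level set of an atom
#' cloud and their outward unit normals (the normalised field gradient).
#' Fully deterministic given `cfg$rng_seed`.
#'
#' @param cloud An [atom_cloud()].
#' @param cfg A [sampler_config()].
#' @param tolerance Convergence tolerance on `|f - offset|` (Angstrom).
#' @return List with `points` (N x 3) and `normals` (N x 3, unit rows).
#' @export
sample_surface <- function(cloud, cfg = sampler_config(), tolerance = 1e-4) {
  A <- nrow(cloud$coords)
  radii <- cfg$atom_radius_map[cloud$elements]
  seeds <- with_seed(cfg$rng_seed, {
    m <- A * cfg$seeds_per_atom
    dir <- matrix(rnorm(3 * m), m, 3)
    dir <- dir / sqrt(rowSums(dir^2))
    rad <- rep(radii, each = cfg$seeds_per_atom) + cfg$level_set_offset +
      runif(m, -0.3, 0.3)
    cloud$coords[rep(seq_len(A), each = cfg$seeds_per_atom), , drop = FALSE] +
      dir * rad
  })

  x <- seeds
  target <- cfg$level_set_offset
  active <- seq_len(nrow(x))
  for (it in seq_len(cfg$descent_steps)) {
    f <- distance_field(x[active, , drop = FALSE], cloud, cfg,
                        gradient = TRUE)
    err <- f$value - target
    gn2 <- pmax(rowSums(f$grad^2), 1e-8)
    x[active, ] <- x[active, , drop = FALSE] -
      cfg$descent_step_size * (err / gn2) * f$grad
    active <- active[abs(err) >= tolerance]
    if (!length(active)) break
  }
  fin <- distance_field(x, cloud, cfg)
  ok <- abs(fin$value - target) <= max(tolerance, 1e-3)
  if (mean(ok) < 0.5)
    stop_ptppi("ptppi_sampling_failure",
               sprintf("surface descent converged for only %.0f%% of %d seeds",
                       100 * mean(ok), nrow(x)),
               converged_fraction = mean(ok))
  x <- x[ok, , drop = FALSE]

  keep <- .poisson_subsample(x, cfg$subsample_spacing)
  x <- x[keep, , drop = FALSE]
  g <- distance_field(x, cloud, cfg, gradient = TRUE)$grad
  normals <- g / sqrt(rowSums(g^2))
  list(points = x, normals = normals)
}

#' Pre-network chemical features of surface points
#'
#' For every surface point, the inverse-distance-weighted average of the
#' one-hot element vectors of its `k_chem` nearest atoms (weights normalised
#' to sum to one). The learnable 22-to-22 chemical MLP of the network acts
#' on these vectors downstream.
#'
#' @param points Surface points (N x 3).
#' @param cloud An [atom_cloud()].
#' @param k_chem Number of nearest atoms to aggregate.
#' @return N x 22 matrix with columns named after [element_vocabulary()].
#' @export
compute_chemical_features <- function(points, cloud, k_chem = 16L) {
  vocab <- element_vocabulary()
  A <- nrow(cloud$coords)
  k <- min(as.integer(k_chem), A)
  d2 <- cross_dist2(points, cloud$coords)
  N <- nrow(points)
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  if (k == 1) nn <- matrix(nn, ncol = 1)
  rows <- rep(seq_len(N), each = k)
  cols_atom <- as.integer(t(nn))
  d <- sqrt(d2[cbind(rows, cols_atom)])
  w <- 1 / pmax(d, 1e-6)
  wsum <- rowsum(w, rows)[, 1]
  w <- w / wsum[rows]
  elem_idx <- match(cloud$elements, vocab)[cols_atom]
  chem <- as.matrix(Matrix::sparseMatrix(i = rows, j = elem_idx, x = w,
                                         dims = c(N, length(vocab))))
  colnames(chem) <- vocab
  chem
}

#' Multi-scale curvature features
#'
#' Estimates a 2 x 2 shape operator per point and Gaussian window by a
#' weighted quadric fit in the tangent plane and returns its determinant and
#' trace per scale. The sign convention makes convex regions (normals
#' diverging) have positive trace. Points with fewer than 6 usable
#' neighbours at a scale get 0 there; the count is attached as attribute
#' `low_support`.
#'
#' @param points Surface points (N x 3).
#' @param normals Unit normals (N x 3).
#' @param scales Gaussian window radii in Angstrom.
#' @return N x (2 * length(scales)) matrix, columns `curv_det_<s>` then
#'   `curv_trace_<s>`.
#' @export
compute_curvatures <- function(points, normals, scales = c(1, 2, 3, 5, 10)) {
  stopifnot(length(scales) >= 1)
  res <- .curvature_features(as.matrix(points), as.matrix(normals),
                             as.numeric(scales))
  out <- res$features
  colnames(out) <- c(paste0("curv_det_", scales), paste0("curv_trace_", scales))
  attr(out, "low_support") <- res$low_support
  out
}

#' Featurise an atom cloud into an oriented surface point cloud
#'
#' Runs the surface sampler, chemical featuriser and multi-scale curvature
#' estimator and fuses the results into the 32-dimensional per-point feature
#' matrix (22 chemical + 10 curvature channels).
#'
#' @param cloud An [atom_cloud()].
#' @param cfg A [sampler_config()].
#' @param scales Curvature scales (Angstrom).
#' @return Object of class `surface_point_cloud` with fields `points`,
#'   `normals`, `chem`, `curv`, `features`.
#' @export
featurize <- function(cloud, cfg = sampler_config(),
                      scales = c(1, 2, 3, 5, 10)) {
  surf <- sample_surface(cloud, cfg)
  chem <- compute_chemical_features(surf$points, cloud, cfg$k_chem)
  curv <- compute_curvatures(surf$points, surf$normals, scales)
  features <- cbind(chem, curv)
  structure(list(points = surf$points, normals = surf$normals,
                 chem = chem, curv = curv, features = features),
            class = "surface_point_cloud")
}

#' @export
print.surface_point_cloud <- function(x, ...) {
  cat(sprintf("<surface_point_cloud> %d points, %d feature channels\n",
              nrow(x$points), ncol(x$features)))
  invisible(x)
}

#' Write a surface point cloud as a tab-separated table
#'
#' Columns: x, y, z, nx, ny, nz, then the 32 feature columns.
#'
#' @param surf A `surface_point_cloud`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_tsv <- function(surf, path) {
  df <- data.frame(x = surf$points[, 1], y = surf$points[, 2],
                   z = surf$points[, 3], nx = surf$normals[, 1],
                   ny = surf$normals[, 2], nz = surf$normals[, 3])
  df <- cbind(df, as.data.frame(surf$features))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
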