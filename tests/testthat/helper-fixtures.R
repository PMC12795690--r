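# Shared fixtures and independent oracles, all built in code.

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- caching (expensive fixtures shared across test files) -----------------
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# ---- tiny hand-written PDB fixtures ----------------------------------------
write_mini_pdb <- function(path, atoms) {
  # atoms: data.frame(x, y, z, element, chain, resno)
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("ATOM  %5d  %-3s ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, substr(a$element, 1, 3), a$chain, a$resno,
            a$x, a$y, a$z, toupper(a$element))
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

# ---- platonic / simple point sets ------------------------------------------
tetrahedron_points <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
}
octahedron_points <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

sphere_cloud <- function(n, R = 1, seed = 1) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  list(points = R * u, normals = u)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# canonical sorted key set of undirected edges
edge_key_set <- function(edge_index) {
  sort(unique(paste(pmin(edge_index[, 1], edge_index[, 2]),
                    pmax(edge_index[, 1], edge_index[, 2]))))
}

# ---- independent convex-hull oracles ---------------------------------------

# brute-force O(n^3) hull by face enumeration; fine for n <= ~30
brute_hull <- function(P, eps = 1e-9) {
  n <- nrow(P)
  faces <- list()
  edges <- character(0)
  ctr <- colMeans(P)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    nrm <- pracma::cross(P[j, ] - P[i, ], P[k, ] - P[i, ])
    if (sqrt(sum(nrm^2)) < eps) next
    d <- as.numeric((P - matrix(P[i, ], n, 3, byrow = TRUE)) %*% nrm)
    if (all(d <= eps) || all(d >= -eps)) {
      # orient outward relative to the centroid
      if (sum((P[i, ] - ctr) * nrm) < 0) nrm <- -nrm
      faces[[length(faces) + 1]] <- list(idx = c(i, j, k),
                                         normal = nrm / sqrt(sum(nrm^2)))
      edges <- c(edges, paste(c(i, j, i), c(j, k, k)))
    }
  }
  list(faces = faces, edges = sort(unique(edges)))
}

# scipy.spatial.ConvexHull on many clouds in a single python call
scipy_hull_edges <- function(clouds) {
  td <- tempfile("hulls")
  dir.create(td)
  for (i in seq_along(clouds))
    write.table(clouds[[i]], file.path(td, sprintf("c%04d.csv", i)),
                row.names = FALSE, col.names = FALSE, sep = ",")
  script <- file.path(td, "hull.py")
  writeLines(c(
    "import sys, glob, os",
    "import numpy as np",
    "from scipy.spatial import ConvexHull",
    "d = sys.argv[1]",
    "for f in sorted(glob.glob(os.path.join(d, 'c*.csv'))):",
    "    P = np.loadtxt(f, delimiter=',')",
    "    h = ConvexHull(P)",
    "    es = set()",
    "    for s in h.simplices:",
    "        for a in range(3):",
    "            i, j = int(s[a]) + 1, int(s[(a + 1) % 3]) + 1",
    "            es.add((min(i, j), max(i, j)))",
    "    with open(f + '.edges', 'w') as out:",
    "        for i, j in sorted(es):",
    "            out.write(f'{i} {j}\\n')"), script)
  status <- system2("python", c(script, td), stdout = TRUE, stderr = TRUE)
  lapply(seq_along(clouds), function(i) {
    ed <- read.table(file.path(td, sprintf("c%04d.csv.edges", i)))
    sort(paste(ed[, 1], ed[, 2]))
  })
}

# ---- small random graph pairs for network-level tests ----------------------
chain_graph <- function(n, f = 5, seed = 1) {
  set.seed(seed)
  pos <- matrix(rnorm(3 * n), n, 3)
  und <- cbind(1:(n - 1), 2:n)
  geometric_graph(pos, rbind(und, und[, 2:1]),
                  x = matrix(rnorm(n * f), n, f))
}

toy_pair <- function(label, seed = 1, n1 = 5, n2 = 4, f = 5, sdim = 12) {
  set.seed(seed)
  list(lig_graph = chain_graph(n1, f, seed), rec_graph = chain_graph(n2, f, seed + 1),
       seq_embed_l = rnorm(sdim), seq_embed_r = rnorm(sdim),
       label = label, id = sprintf("toy%d", seed))
}

toy_cfg <- function(H = 8, ...) {
  model_config(hidden_dim = H, dropout = 0, num_pt_layers = 2,
               seq_embed_dim = 12, in_feature_dim = 5, rng_seed = 3, ...)
}

toy_pairs <- function(n, seed = 1) {
  lapply(seq_len(n), function(i) toy_pair(i %% 2, seed = seed * 1000 + i))
}

# dense loop re-implementation of the attention layer (independent oracle)
dense_pt_oracle <- function(h, pos, edge_index, params, cfg, layer = 1) {
  H <- cfg$hidden_dim
  N <- nrow(h)
  mlp <- function(x, W1, b1, W2, b2) {
    a <- pmax(x %*% W1 + matrix(b1, nrow(x), length(b1), byrow = TRUE), 0)
    a %*% W2 + matrix(b2, nrow(a), length(b2), byrow = TRUE)
  }
  g <- function(nm) params[[sprintf("l%d_%s", layer, nm)]]
  out <- matrix(0, N, H)
  for (i in 1:N) {
    nbr <- c(edge_index[edge_index[, 2] == i, 1], i)
    logits <- matrix(0, length(nbr), H)
    vals <- matrix(0, length(nbr), H)
    for (t in seq_along(nbr)) {
      j <- nbr[t]
      d <- matrix(pos[i, ] - pos[j, ], 1)
      delta <- mlp(d, g("P1"), g("p1"), g("P2"), g("p2"))
      u <- matrix(h[i, ], 1) %*% g("W1") - matrix(h[j, ], 1) %*% g("W2") + delta
      logits[t, ] <- mlp(u, g("G1"), g("g1"), g("G2"), g("g2"))
      vals[t, ] <- matrix(h[j, ], 1) %*% g("W3") + matrix(g("b3"), 1) + delta
    }
    al <- apply(logits, 2, function(cc) exp(cc - max(cc)) / sum(exp(cc - max(cc))))
    if (length(nbr) == 1) al <- matrix(al, 1)
    out[i, ] <- pmax(colSums(al * vals), 0)
  }
  out
}

# ---- shared synthetic datasets (generated once per test run) ---------------
small_spec <- function(strength, seed) {
  synthetic_spec(n_pairs = 90L, residues_per_chain = c(35L, 80L),
                 complementarity_strength = strength,
                 sequence_signal_strength = strength, rng_seed = seed)
}

small_dataset <- function(strength, seed = 7) {
  cached(sprintf("ds_s%s_%d", strength, seed),
         generate_synthetic_dataset(small_spec(strength, seed)))
}

train_eval_auroc <- function(ds, seed, epochs = 12L, H = 16L,
                             patience = epochs) {
  folds <- make_splits(ds, k = 5L, seed = seed)
  mc <- model_config(hidden_dim = H, num_pt_layers = 2L,
                     rng_seed = derive_seed_public(seed, 1))
  tc <- train_config(learning_rate = 1e-3, max_epochs = epochs,
                     patience = patience, rng_seed = seed)
  m <- ptppi_train(ds[folds > 2], ds[folds == 2], mc, tc)
  evaluate_pairs(m, ds[folds == 1])$auroc
}

derive_seed_public <- function(seed, index) ptppi:::derive_seed(seed, index)
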