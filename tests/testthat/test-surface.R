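# Structure parsing and surface featurisation.

test_that("hand-written PDB files parse with vocabulary filtering", {
  tf <- tempfile(fileext = ".pdb")
  write_mini_pdb(tf, data.frame(x = c(0, 1.5, 2.0), y = c(0, 0, 1.4),
                                z = 0, element = c("C", "N", "O"),
                                chain = "A", resno = 1:3))
  cl <- read_structure(tf, "pdb")
  expect_s3_class(cl, "atom_cloud")
  expect_equal(nrow(cl$coords), 3)
  expect_equal(length(unique(cl$chain_id)), 1)
  expect_equal(attr(cl, "dropped"), 0L)

  # an out-of-vocabulary element is dropped and counted
  tf2 <- tempfile(fileext = ".pdb")
  write_mini_pdb(tf2, data.frame(x = c(0, 1.5, 2.0), y = c(0, 0, 1.4),
                                 z = 0, element = c("C", "X", "O"),
                                 chain = "A", resno = 1:3))
  cl2 <- read_structure(tf2, "pdb")
  expect_equal(nrow(cl2$coords), 2)
  expect_equal(attr(cl2, "dropped"), 1L)

  # degenerate-chain error is available on demand
  expect_error(read_structure(tf2, "pdb", min_atoms_per_chain = 4),
               class = "ptppi_degenerate_chain")
  expect_error(read_structure(tempfile(), "pdb"), class = "ptppi_format_error")
})

test_that("mmCIF parsing yields the same atoms as the PDB route", {
  tf <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test", "loop_", "_atom_site.group_PDB", "_atom_site.id",
    "_atom_site.type_symbol", "_atom_site.label_atom_id",
    "_atom_site.label_alt_id", "_atom_site.label_comp_id",
    "_atom_site.label_asym_id", "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.500 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 2.000 1.400 0.000 1.00 10.00 ? 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 1.200 2.300 0.300 1.00 10.00 ? 1 ALA A O 1"),
    tf)
  cl <- read_structure(tf, "mmcif")
  expect_equal(nrow(cl$coords), 4)
  expect_equal(cl$elements, c("N", "C", "C", "O"))
})

test_that("two-chain clouds round-trip exactly through the tabular dump", {
  set.seed(5)
  cl <- atom_cloud(matrix(round(rnorm(30, sd = 5), 3), 10, 3),
                   sample(c("C", "N", "O", "S"), 10, replace = TRUE),
                   rep(c("A", "B"), each = 5), rep(1:5, 2))
  tf <- tempfile(fileext = ".tsv")
  write_atom_cloud(cl, tf)
  cl2 <- read_atom_cloud(tf)
  expect_identical(cl2$chain_id, cl$chain_id)
  expect_identical(cl2$residue_index, cl$residue_index)
  expect_identical(cl2$elements, cl$elements)
  expect_equal(cl2$coords, cl$coords)
})

test_that("surface points sit on the level set with unit analytic normals", {
  # four well-separated atoms behave like isolated spheres
  cl <- atom_cloud(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0), c(0, 0, 30)),
                   rep("C", 4), rep("A", 4), 1:4)
  cfg <- sampler_config(rng_seed = 7)
  s <- sample_surface(cl, cfg)
  expect_gt(nrow(s$points), 10)
  d1 <- sqrt(rowSums(s$points^2))
  near1 <- d1 < 10
  expect_true(any(near1))
  # carbon radius 1.70 + offset 1.05
  expect_lt(max(abs(d1[near1] - 2.75)), 2e-3)
  # normals are unit and radial for the isolated-sphere patch
  expect_lt(max(abs(sqrt(rowSums(s$normals^2)) - 1)), 1e-6)
  cosang <- rowSums(s$normals[near1, ] * s$points[near1, ]) / d1[near1]
  expect_lt(max(abs(cosang - 1)), 1e-4)

  # determinism: identical input and seed give bitwise-identical output
  expect_identical(s, sample_surface(cl, cfg))

  # minimum spacing respected
  dd <- as.matrix(dist(s$points))
  diag(dd) <- Inf
  expect_gte(min(dd), cfg$subsample_spacing)
})

test_that("normals agree with central finite differences of the field", {
  set.seed(21)
  cl <- atom_cloud(matrix(rnorm(36, sd = 3), 12, 3),
                   sample(c("C", "N", "O"), 12, replace = TRUE),
                   rep("A", 12), 1:12)
  cfg <- sampler_config(rng_seed = 3)
  s <- sample_surface(cl, cfg)
  h <- 1e-5
  for (i in c(1, 5, 9)) {
    x0 <- s$points[i, , drop = FALSE]
    fd <- vapply(1:3, function(k) {
      xp <- x0; xm <- x0
      xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
      (distance_field(xp, cl, cfg)$value -
         distance_field(xm, cl, cfg)$value) / (2 * h)
    }, numeric(1))
    an <- distance_field(x0, cl, cfg, gradient = TRUE)$grad[1, ]
    expect_lt(sqrt(sum((fd - an)^2)) / sqrt(sum(fd^2)), 1e-3)
  }
})

test_that("sampling failure raises a diagnostic error", {
  cl <- atom_cloud(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2)),
                   rep("C", 4), rep("A", 4), 1:4)
  cfg <- sampler_config(rng_seed = 1, descent_steps = 1,
                        descent_step_size = 1e-6)
  expect_error(sample_surface(cl, cfg), class = "ptppi_sampling_failure")
})

test_that("chemical features are normalised inverse-distance one-hot mixes", {
  # single-carbon neighbourhood: everything lands in the C channel
  cl <- atom_cloud(rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0), c(0, 0, 40)),
                   rep("C", 4), rep("A", 4), 1:4)
  s <- sample_surface(cl, sampler_config(rng_seed = 2))
  chem <- compute_chemical_features(s$points, cl, k_chem = 2)
  expect_equal(ncol(chem), 22)
  expect_equal(unname(chem[, "C"]), rep(1, nrow(chem)))
  expect_equal(rowSums(chem), rep(1, nrow(chem)), tolerance = 1e-6)

  # mixed elements still sum to one
  set.seed(8)
  cl2 <- atom_cloud(matrix(rnorm(150, sd = 4), 50, 3),
                    sample(c("C", "N", "O", "S", "Fe"), 50, replace = TRUE),
                    rep("A", 50), 1:50)
  pts <- matrix(rnorm(60, sd = 5), 20, 3)
  chem2 <- compute_chemical_features(pts, cl2, k_chem = 16)
  expect_equal(rowSums(chem2), rep(1, 20), tolerance = 1e-6)
})

test_that("spatial-index neighbours match exhaustive nearest-neighbour search", {
  set.seed(13)
  cl <- atom_cloud(matrix(rnorm(150, sd = 4), 50, 3),
                   sample(c("C", "N", "O"), 50, replace = TRUE),
                   rep("A", 50), 1:50)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  k <- 7
  chem <- compute_chemical_features(pts, cl, k_chem = k)
  vocab <- element_vocabulary()
  for (i in 1:10) {
    d <- sqrt(colSums((t(cl$coords) - pts[i, ])^2))
    nn <- order(d)[1:k]
    w <- (1 / d[nn]) / sum(1 / d[nn])
    expected <- vapply(vocab, function(e) sum(w[cl$elements[nn] == e]),
                       numeric(1))
    expect_equal(unname(chem[i, ]), unname(expected), tolerance = 1e-10)
  }
})

test_that("curvature recovers the analytic sphere and plane", {
  for (seed in 1:5) {
    sp <- sphere_cloud(2500, R = 5, seed = seed)
    cv <- compute_curvatures(sp$points, sp$normals, scales = 1)
    expect_lt(abs(mean(cv[, 1]) - 1 / 25) / (1 / 25), 0.15)
    expect_lt(abs(mean(cv[, 2]) - 2 / 5) / (2 / 5), 0.15)
  }
  gx <- as.matrix(expand.grid(seq(-8, 8, 0.5), seq(-8, 8, 0.5)))
  plane <- cbind(gx, 0)
  nrm <- cbind(0 * gx[, 1], 0 * gx[, 1], 1)
  cp <- compute_curvatures(plane, nrm)
  expect_lt(max(abs(cp)), 1e-2)
})

test_that("default scales give ten curvature columns, det then trace", {
  sp <- sphere_cloud(300, R = 5, seed = 2)
  cv <- compute_curvatures(sp$points, sp$normals)
  expect_equal(ncol(cv), 10)
  expect_identical(colnames(cv),
                   c(paste0("curv_det_", c(1, 2, 3, 5, 10)),
                     paste0("curv_trace_", c(1, 2, 3, 5, 10))))
})

test_that("curvature is invariant under rigid motion", {
  sp <- sphere_cloud(800, R = 4, seed = 3)
  base <- compute_curvatures(sp$points, sp$normals)
  for (seed in 1:3) {
    A <- random_rotation(seed)
    tv <- c(3, -7, 2) * seed
    moved <- compute_curvatures(sp$points %*% t(A) +
                                  matrix(tv, 800, 3, byrow = TRUE),
                                sp$normals %*% t(A))
    expect_lt(max(abs(base - moved)), 1e-3)
  }
})

test_that("featurize fuses 22 chemical and 10 curvature channels into 32", {
  set.seed(30)
  cl <- atom_cloud(matrix(rnorm(60, sd = 3), 20, 3),
                   sample(c("C", "N", "O", "S"), 20, replace = TRUE),
                   rep("A", 20), 1:20)
  surf <- featurize(cl, sampler_config(rng_seed = 4))
  expect_equal(ncol(surf$chem), 22)
  expect_equal(ncol(surf$curv), 10)
  expect_equal(ncol(surf$features), 32)
  expect_equal(surf$features[, 1:22], surf$chem, ignore_attr = TRUE)
  expect_equal(surf$features[, 23:32], surf$curv, ignore_attr = TRUE)
  expect_lt(max(abs(sqrt(rowSums(surf$normals^2)) - 1)), 1e-6)

  tf <- tempfile(fileext = ".tsv")
  write_surface_tsv(surf, tf)
  tab <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(ncol(tab), 38)
  expect_equal(nrow(tab), nrow(surf$points))
})
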