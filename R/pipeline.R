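#' Pair filters of the dataset construction
#'
#' A ligand/receptor pair is accepted iff the minimum inter-chain
#' residue-residue distance (minimum over all atom pairs of the two chains)
#' is strictly below `contact_distance` and both sequence lengths lie in
#' `length_range` (bounds inclusive).
#'
#' @param lig_cloud,rec_cloud [atom_cloud()]s of the two chains.
#' @param lig_seq,rec_seq [sequence_record()]s of the two chains.
#' @param contact_distance Contact threshold in Angstrom (default 8,
#'   strict).
#' @param length_range Inclusive sequence-length bounds.
#' @return List with `accept` (logical), `reason` (`"ok"`,
#'   `"length-out-of-range"` or `"no-contact"`), and `min_distance`.
#' @export
filter_pair <- function(lig_cloud, rec_cloud, lig_seq, rec_seq,
                        contact_distance = 8, length_range = c(35L, 300L)) {
  if (is.null(lig_seq) || is.null(rec_seq))
    stop_ptppi("ptppi_validation_error", "both chains need sequences")
  len_l <- nchar(lig_seq$sequence)
  len_r <- nchar(rec_seq$sequence)
  mind <- sqrt(min(cross_dist2(lig_cloud$coords, rec_cloud$coords)))
  if (len_l < length_range[1] || len_l > length_range[2] ||
      len_r < length_range[1] || len_r > length_range[2])
    return(list(accept = FALSE, reason = "length-out-of-range",
                min_distance = mind))
  if (!(mind < contact_distance))
    return(list(accept = FALSE, reason = "no-contact", min_distance = mind))
  list(accept = TRUE, reason = "ok", min_distance = mind)
}

#' Sample random negative pairs
#'
#' Draws `n` distinct unordered chain pairs from `pool`, excluding known
#' interacting pairs (the stand-in for a database cross-check: the
#' exclusion set is supplied by the caller) and self-pairs. Deterministic
#' given `seed`.
#'
#' @param pool Character vector of chain identifiers.
#' @param known_pairs Two-column matrix / data frame of excluded unordered
#'   pairs (may be empty).
#' @param n Number of pairs to draw.
#' @param seed RNG seed.
#' @return Data frame with columns `id_1`, `id_2`.
#' @export
sample_negatives <- function(pool, known_pairs = NULL, n, seed = 1L) {
  pool <- unique(as.character(pool))
  excl <- character(0)
  if (!is.null(known_pairs) && NROW(known_pairs) > 0) {
    if (is.data.frame(known_pairs)) {
      a <- as.character(known_pairs[[1]]); b <- as.character(known_pairs[[2]])
    } else {
      a <- as.character(known_pairs[, 1]); b <- as.character(known_pairs[, 2])
    }
    excl <- paste(pmin(a, b), pmax(a, b))
  }
  npool <- length(pool)
  n_excl_in_pool <- sum(excl %in% {
    # exclusions only reduce availability if both ids are in the pool
    cp <- utils::combn(pool, 2)
    paste(pmin(cp[1, ], cp[2, ]), pmax(cp[1, ], cp[2, ]))
  })
  if (choose(npool, 2) - n_excl_in_pool < n)
    stop_ptppi("ptppi_sampling_exhausted",
               "pool too small for the requested number of negative pairs")
  with_seed(seed, {
    chosen <- character(0)
    out <- matrix(character(0), 0, 2)
    guard <- 0L
    while (nrow(out) < n) {
      pr <- sort(sample(pool, 2))
      key <- paste(pr[1], pr[2])
      if (key %in% excl || key %in% chosen) {
        guard <- guard + 1L
        if (guard > 1e6) stop_ptppi("ptppi_sampling_exhausted",
                                    "negative sampling did not terminate")
        next
      }
      chosen <- c(chosen, key)
      out <- rbind(out, pr)
    }
    data.frame(id_1 = out[, 1], id_2 = out[, 2], stringsAsFactors = FALSE)
  })
}

#' Specification of the synthetic dimer generator
#'
#' Defines the conditions the generator emulates: paired compact atom
#' clouds in interface contact, with chain sizes matching the dataset
#' filters, optional geometric complementarity at the interface (a convex
#' boss on the ligand matched by a concave pocket on the receptor) and
#' optional correlated sequence motifs.
#'
#' @param n_pairs Number of pairs the derived dataset will contain.
#' @param positive_fraction Fraction of interacting pairs; labels are
#'   allocated deterministically so the balance is exact.
#' @param residues_per_chain Inclusive range of residues per chain.
#' @param interface_contact_distance Interface atoms of a generated pair
#'   lie within this distance (Angstrom, default 8).
#' @param complementarity_strength Amplitude of the boss/pocket geometry on
#'   positive pairs (0 = none).
#' @param sequence_signal_strength Probability that a positive pair carries
#'   the correlated sequence motifs (0 = none).
#' @param rng_seed Base seed; each sample index derives its own sub-seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pairs = 200L, positive_fraction = 0.5,
                           residues_per_chain = c(35L, 300L),
                           interface_contact_distance = 8,
                           complementarity_strength = 1,
                           sequence_signal_strength = 1,
                           rng_seed = 1L) {
  stopifnot(n_pairs >= 1, positive_fraction >= 0, positive_fraction <= 1,
            residues_per_chain[1] >= 1,
            residues_per_chain[2] >= residues_per_chain[1],
            interface_contact_distance > 0,
            complementarity_strength >= 0, sequence_signal_strength >= 0)
  if (residues_per_chain[1] < 35 || residues_per_chain[2] > 300)
    stop_ptppi("ptppi_validation_error",
               "residues_per_chain must lie within [35, 300]")
  structure(list(n_pairs = as.integer(n_pairs),
                 positive_fraction = positive_fraction,
                 residues_per_chain = as.integer(residues_per_chain),
                 interface_contact_distance = interface_contact_distance,
                 complementarity_strength = complementarity_strength,
                 sequence_signal_strength = sequence_signal_strength,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Desk-scale sampler preset of the synthetic pipeline
#'
#' A coarser surface sampling resolution than the per-structure default,
#' sized for training experiments on hundreds of synthetic dimers.
#'
#' @param rng_seed Sampler seed.
#' @return A [sampler_config()].
#' @export
pipeline_sampler_config <- function(rng_seed = 1L) {
  sampler_config(seeds_per_atom = 4L, descent_steps = 30L,
                 subsample_spacing = 5.0, rng_seed = rng_seed)
}

aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
motif_ligand <- "WCWHHKCYWCWM"
motif_receptor <- "MYFFDDRNEEFM"

# compact blob of n atoms with >= 2 A separation inside a ball
synth_blob <- function(n) {
  R <- 2.0 * n^(1 / 3)
  m <- 25 * n
  pts <- matrix(runif(3 * m, -R, R), m, 3)
  pts <- pts[rowSums(pts^2) <= R^2, , drop = FALSE]
  keep <- .poisson_subsample(pts, 2.0)
  if (length(keep) < n) keep <- seq_len(min(nrow(pts), n))
  list(coords = pts[keep[seq_len(min(n, length(keep)))], , drop = FALSE],
       radius = R)
}

synth_elements <- function(n) {
  sample(c("C", "N", "O", "S"), n, replace = TRUE,
         prob = c(0.55, 0.16, 0.24, 0.05))
}

#' Generate one synthetic ligand-receptor complex
#'
#' Positives get a convex boss on the ligand facing a concave pocket dented
#' into the receptor (amplitude `complementarity_strength`) and, with
#' probability `sequence_signal_strength`, correlated sequence motifs;
#' negatives are independently generated chains placed in contact range
#' without complementarity. Every generated pair passes [filter_pair()].
#' Deterministic given `(spec$rng_seed, index)`.
#'
#' @param spec A [synthetic_spec()].
#' @param index Sample index (1-based); also decides the label through the
#'   deterministic balance allocation.
#' @param sampler A [sampler_config()] for the surface featurisation.
#' @param graph_method `"schull"`, `"radius"` or `"knn"`.
#' @param r,k Parameters of the baseline graph builders.
#' @return Object of class `pair_sample`: atom clouds, surface point
#'   clouds, geometric graphs, sequence records, pooled sequence
#'   embeddings, `label` and `id`.
#' @export
generate_synthetic_complex <- function(spec, index,
                                       sampler = pipeline_sampler_config(),
                                       graph_method = c("schull", "radius",
                                                        "knn"),
                                       r = 10, k = 8) {
  graph_method <- match.arg(graph_method)
  f <- spec$positive_fraction
  label <- as.integer(floor(index * f) - floor((index - 1) * f) >= 1)
  q <- spec$complementarity_strength

  sd_i <- derive_seed(spec$rng_seed, index)
  built <- with_seed(sd_i, {
    n_l <- sample(spec$residues_per_chain[1]:spec$residues_per_chain[2], 1)
    n_r <- sample(spec$residues_per_chain[1]:spec$residues_per_chain[2], 1)
    lig <- synth_blob(n_l)
    rec <- synth_blob(n_r)
    lig_el <- synth_elements(nrow(lig$coords))
    rec_el <- synth_elements(nrow(rec$coords))
    lig_res <- seq_len(nrow(lig$coords))
    rec_res <- seq_len(nrow(rec$coords))

    if (label == 1 && q > 0) {
      # convex boss on the ligand, pointing +x
      nb <- 10L
      tip <- c(lig$radius + 2.5 * q, 0, 0)
      boss <- matrix(rnorm(3 * nb, sd = 1.2), nb, 3) +
        matrix(tip, nb, 3, byrow = TRUE)
      boss[, 1] <- pmax(boss[, 1], lig$radius * 0.8)
      near <- apply(cross_dist2(boss, lig$coords), 1, which.min)
      lig$coords <- rbind(lig$coords, boss)
      lig_el <- c(lig_el, synth_elements(nb))
      lig_res <- c(lig_res, lig_res[near])
      # concave pocket dented into the receptor's -x face
      u <- rec$coords / pmax(sqrt(rowSums(rec$coords^2)), 1e-9)
      facing <- u[, 1] < -0.75
      depth <- 3.0 * q * pmax(-u[facing, 1] - 0.75, 0) / 0.25
      rec$coords[facing, ] <- rec$coords[facing, ] * (1 - depth /
        pmax(sqrt(rowSums(rec$coords[facing, , drop = FALSE]^2)), 1e-9))
    }

    # place the receptor along +x so the chains touch but do not overlap
    shift0 <- lig$radius + rec$radius + 4.5
    rec$coords[, 1] <- rec$coords[, 1] + shift0
    mind <- sqrt(min(cross_dist2(lig$coords, rec$coords)))
    target <- min(spec$interface_contact_distance - 2, 6)
    rec$coords[, 1] <- rec$coords[, 1] + (target - mind)

    seq_l <- paste(sample(aa_letters, n_l, replace = TRUE), collapse = "")
    seq_r <- paste(sample(aa_letters, n_r, replace = TRUE), collapse = "")
    if (label == 1 && runif(1) < spec$sequence_signal_strength) {
      seq_l <- inject_motif(seq_l, motif_ligand)
      seq_r <- inject_motif(seq_r, motif_receptor)
    }
    list(lig = lig, rec = rec, lig_el = lig_el, rec_el = rec_el,
         lig_res = lig_res, rec_res = rec_res, seq_l = seq_l, seq_r = seq_r)
  })

  lig_cloud <- atom_cloud(built$lig$coords, built$lig_el,
                          rep("L", nrow(built$lig$coords)), built$lig_res)
  rec_cloud <- atom_cloud(built$rec$coords, built$rec_el,
                          rep("R", nrow(built$rec$coords)), built$rec_res)

  scfg_l <- sampler; scfg_l$rng_seed <- derive_seed(sd_i, 1L, salt = 11L)
  scfg_r <- sampler; scfg_r$rng_seed <- derive_seed(sd_i, 2L, salt = 11L)
  lig_surf <- featurize(lig_cloud, scfg_l)
  rec_surf <- featurize(rec_cloud, scfg_r)

  build <- function(surf) {
    switch(graph_method,
           schull = build_schull(surf$points, x = surf$features,
                                 jitter_retry = TRUE),
           radius = build_radius_graph(surf$points, r = r, x = surf$features),
           knn = build_knn_graph(surf$points, k = k, x = surf$features))
  }
  lig_graph <- build(lig_surf)
  rec_graph <- build(rec_surf)

  sl <- sequence_record(sprintf("pair%05d_L", index), built$seq_l)
  sr <- sequence_record(sprintf("pair%05d_R", index), built$seq_r)
  structure(list(lig_cloud = lig_cloud, rec_cloud = rec_cloud,
                 lig_surf = lig_surf, rec_surf = rec_surf,
                 lig_graph = lig_graph, rec_graph = rec_graph,
                 seq_l = sl, seq_r = sr,
                 seq_embed_l = embed(sl)$pooled,
                 seq_embed_r = embed(sr)$pooled,
                 label = label, id = sprintf("pair%05d", index)),
            class = "pair_sample")
}

inject_motif <- function(s, motif) {
  L <- nchar(s)
  m <- nchar(motif)
  if (m >= L) return(substr(motif, 1, L))
  at <- max(1L, (L - m) %/% 2L)
  paste0(substr(s, 1, at - 1), motif, substr(s, at + m, L))
}

#' @export
print.pair_sample <- function(x, ...) {
  cat(sprintf("<pair_sample> %s label=%d | L: %d atoms/%d pts, R: %d atoms/%d pts\n",
              x$id, x$label, nrow(x$lig_cloud$coords), nrow(x$lig_surf$points),
              nrow(x$rec_cloud$coords), nrow(x$rec_surf$points)))
  invisible(x)
}

#' Generate a synthetic paired dataset
#'
#' @param spec A [synthetic_spec()].
#' @param sampler Surface sampler preset.
#' @param graph_method,r,k Graph construction (see
#'   [generate_synthetic_complex()]).
#' @param progress Print a dot every 25 pairs?
#' @return List of `pair_sample`s of length `spec$n_pairs`.
#' @export
generate_synthetic_dataset <- function(spec,
                                       sampler = pipeline_sampler_config(),
                                       graph_method = "schull", r = 10, k = 8,
                                       progress = FALSE) {
  out <- vector("list", spec$n_pairs)
  for (i in seq_len(spec$n_pairs)) {
    out[[i]] <- generate_synthetic_complex(spec, i, sampler = sampler,
                                           graph_method = graph_method,
                                           r = r, k = k)
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' Rebuild the graphs of pair samples with another builder
#'
#' Swaps the graph construction method while leaving surface points and
#' node features untouched (the baseline-comparison harness).
#'
#' @param pairs List of `pair_sample`s.
#' @param method `"schull"`, `"radius"` or `"knn"`.
#' @param r,k Builder parameters.
#' @return The modified list of pairs.
#' @export
rebuild_pair_graphs <- function(pairs, method = c("schull", "radius", "knn"),
                                r = 10, k = 8) {
  method <- match.arg(method)
  build <- function(surf) {
    switch(method,
           schull = build_schull(surf$points, x = surf$features,
                                 jitter_retry = TRUE),
           radius = build_radius_graph(surf$points, r = r, x = surf$features),
           knn = build_knn_graph(surf$points, k = k, x = surf$features))
  }
  lapply(pairs, function(p) {
    p$lig_graph <- build(p$lig_surf)
    p$rec_graph <- build(p$rec_surf)
    p
  })
}

#' Assign samples to cross-validation folds
#'
#' Disjoint, exhaustive folds of near-equal size (sizes differ by at most
#' one); deterministic given `seed`.
#'
#' @param samples List (or vector) of samples.
#' @param k Number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_splits <- function(samples, k = 3L, seed = 1L) {
  n <- length(samples)
  k <- as.integer(k)
  if (k < 2 || k > n)
    stop_ptppi("ptppi_parameter_error", "need 2 <= k <= number of samples")
  with_seed(seed, {
    perm <- sample.int(n)
    folds <- integer(n)
    folds[perm] <- rep_len(seq_len(k), n)
    folds
  })
}

#' Write a synthetic pair as PDB + FASTA files
#'
#' Emits the two chains of a pair as a standard PDB file (chains L and R)
#' plus a FASTA file with both sequences, so that the real structure and
#' sequence readers can be exercised end to end.
#'
#' @param pair A `pair_sample`.
#' @param dir Output directory.
#' @return Named character vector with the `pdb` and `fasta` paths.
#' @export
write_pair_files <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, paste0(pair$id, ".pdb"))
  fa_path <- file.path(dir, paste0(pair$id, ".fasta"))
  coords <- rbind(pair$lig_cloud$coords, pair$rec_cloud$coords)
  elem <- c(pair$lig_cloud$elements, pair$rec_cloud$elements)
  chain <- c(pair$lig_cloud$chain_id, pair$rec_cloud$chain_id)
  resno <- c(pair$lig_cloud$residue_index, pair$rec_cloud$residue_index)
  bio3d::write.pdb(file = pdb_path, xyz = as.numeric(t(coords)),
                   resno = resno, chain = chain,
                   resid = rep("ALA", length(elem)),
                   elety = elem, elesy = elem,
                   eleno = seq_along(elem))
  bio3d::write.fasta(seqs = rbind(strsplit(pair$seq_l$sequence, "")[[1]]),
                     ids = pair$seq_l$id, file = fa_path)
  # append the receptor record
  cat(sprintf(">%s\n%s\n", pair$seq_r$id, pair$seq_r$sequence),
      file = fa_path, append = TRUE)
  c(pdb = pdb_path, fasta = fa_path)
}
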