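# Network building blocks and the paired forward pass.

test_that("node encoding maps zero to zero and respects the shape contract", {
  for (H in c(8, 64)) {
    cfg <- toy_cfg(H = H)
    params <- init_ptppi_params(cfg)
    x <- rbind(rep(0, 5), rnorm(5))
    out <- encode_nodes(x, params, cfg)
    expect_equal(dim(out), c(2L, H))
    expect_equal(out[1, ], rep(0, H))
    # evaluation mode is deterministic
    expect_identical(out, encode_nodes(x, params, cfg))
  }
  cfg <- toy_cfg()
  expect_error(encode_nodes(matrix(0, 2, 7), init_ptppi_params(cfg), cfg),
               class = "ptppi_shape_error")
})

test_that("positional encoding depends only on displacements", {
  cfg <- toy_cfg()
  params <- init_ptppi_params(cfg)
  und <- rbind(c(1, 2), c(2, 3), c(1, 3))
  ei <- rbind(und, und[, 2:1])

  # identical positions: every node receives hTheta(0)
  pos0 <- matrix(1.5, 3, 3)
  out0 <- positional_encoding(pos0, ei, params, cfg)
  expect_equal(out0[1, ], out0[2, ])
  expect_equal(out0[2, ], out0[3, ])
  h0 <- as.numeric(pmax(matrix(params$pe_b1, 1), 0) %*% params$pe_A2 +
                     params$pe_b2)
  expect_equal(out0[1, ], h0)

  # translation invariance
  set.seed(6)
  pos <- matrix(rnorm(9), 3, 3)
  out <- positional_encoding(pos, ei, params, cfg)
  shifted <- positional_encoding(pos + matrix(c(4, -2, 9), 3, 3, byrow = TRUE),
                                 ei, params, cfg)
  expect_equal(out, shifted, tolerance = 1e-12)

  # node-order permutation permutes rows (checked against explicit loop)
  perm <- c(3, 1, 2)
  inv <- order(perm)
  pos_p <- pos[perm, ]
  ei_p <- matrix(inv[ei], ncol = 2)
  out_p <- positional_encoding(pos_p, ei_p, params, cfg)
  expect_equal(out_p[inv, ], out, tolerance = 1e-12)

  # a node with no incident edge receives hTheta(0)
  out_iso <- positional_encoding(rbind(pos, c(9, 9, 9)), ei, params, cfg)
  expect_equal(out_iso[4, ], h0)
})

test_that("pt_layer equals the dense loop oracle on small graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    N <- sample(4:10, 1)
    cfg <- toy_cfg(H = 8)
    cfg$rng_seed <- seed
    params <- init_ptppi_params(cfg)
    pos <- matrix(rnorm(3 * N), N, 3)
    h <- matrix(rnorm(N * 8), N, 8)
    und <- cbind(1:(N - 1), 2:N)
    extra <- if (N > 3) rbind(c(1, N)) else NULL
    ei <- rbind(und, extra)
    ei <- rbind(ei, ei[, 2:1])
    out <- pt_layer(h, pos, ei, params, cfg, layer = 1)
    oracle <- dense_pt_oracle(h, pos, ei, params, cfg, layer = 1)
    expect_lt(max(abs(out - oracle)), 1e-5)
  }
})

test_that("attention is a one-element softmax for an isolated node", {
  cfg <- toy_cfg()
  params <- init_ptppi_params(cfg)
  h <- matrix(rnorm(8), 1, 8)
  pos <- matrix(0, 1, 3)
  ei <- matrix(integer(0), 0, 2)
  at <- pt_attention(h, pos, ei, params, cfg)
  expect_equal(as.numeric(at$alpha), rep(1, 8))
  out <- pt_layer(h, pos, ei, params, cfg)
  g <- function(nm) params[[paste0("l1_", nm)]]
  delta <- as.numeric(pmax(matrix(g("p1"), 1), 0) %*% g("P2") + g("p2"))
  expect_equal(out[1, ],
               pmax(as.numeric(h %*% g("W3")) + g("b3") + delta, 0),
               tolerance = 1e-12)
})

test_that("attention weights sum to one per channel over each neighbourhood", {
  set.seed(44)
  cfg <- toy_cfg()
  params <- init_ptppi_params(cfg)
  N <- 9
  pos <- matrix(rnorm(3 * N), N, 3)
  h <- matrix(rnorm(N * 8), N, 8)
  und <- cbind(1:(N - 1), 2:N)
  ei <- rbind(und, und[, 2:1])
  at <- pt_attention(h, pos, ei, params, cfg)
  sums <- rowsum(at$alpha, at$dst)
  expect_lt(max(abs(sums - 1)), 1e-6)
})

test_that("chain pooling is an exact per-chain mean", {
  h <- matrix(rnorm(80), 10, 8)
  chain <- rep(1:2, c(6, 4))
  pooled <- pool_chain(h, chain)
  loop1 <- colSums(h[1:6, ]) / 6
  loop2 <- colSums(h[7:10, ]) / 4
  expect_equal(pooled[1, ], loop1)
  expect_equal(pooled[2, ], loop2)
  # pooling one chain ignores the other's nodes entirely
  h2 <- h
  h2[7:10, ] <- 99
  expect_equal(pool_chain(h2, chain)[1, ], loop1)
  # constant embeddings pool to that constant
  v <- rnorm(8)
  expect_equal(pool_chain(matrix(v, 10, 8, byrow = TRUE), chain)[2, ], v)
  expect_error(pool_chain(h, rep(c(1, 3), 5)), class = "ptppi_pooling_error")
})

test_that("sequence projection is a deterministic two-layer map to H", {
  cfg <- toy_cfg()
  params <- init_ptppi_params(cfg)
  params$sq_s1[] <- 0
  params$sq_s2[] <- 0
  expect_equal(project_sequence(rep(0, 12), params, cfg), rep(0, 8))
  s <- rnorm(12)
  out <- project_sequence(s, params, cfg)
  expect_length(out, 8)
  expect_identical(out, project_sequence(s, params, cfg))
  expect_error(project_sequence(rep(0, 11), params, cfg),
               class = "ptppi_shape_error")
})

test_that("forward_pair outputs probabilities and honours ablation flags", {
  cfg <- toy_cfg()
  params <- init_ptppi_params(cfg)
  pairs <- toy_pairs(4, seed = 2)
  probs <- forward_pair(pairs, params, cfg)
  expect_length(probs, 4)
  expect_true(all(probs > 0 & probs < 1))

  # batch permutation permutes outputs identically
  perm <- c(3, 1, 4, 2)
  expect_equal(forward_pair(pairs[perm], params, cfg), probs[perm],
               tolerance = 1e-12)

  # dropping the sequence branch halves the fused width
  cfg_ns <- toy_cfg(use_sequence = FALSE)
  params_ns <- init_ptppi_params(cfg_ns)
  expect_equal(nrow(params_ns$hd_U1), 2 * cfg$hidden_dim)
  expect_equal(nrow(params$hd_U1), 4 * cfg$hidden_dim)
  probs_ns <- forward_pair(pairs, params_ns, cfg_ns)
  expect_true(all(probs_ns > 0 & probs_ns < 1))

  # MLP ablation and positional-encoder ablation still run end to end
  for (cfg_ab in list(toy_cfg(use_pt_block = FALSE),
                      toy_cfg(use_positional_encoder = FALSE))) {
    p_ab <- forward_pair(pairs, init_ptppi_params(cfg_ab), cfg_ab)
    expect_true(all(p_ab > 0 & p_ab < 1))
  }

  # width inconsistencies are configuration errors
  bad <- toy_cfg()
  bad$in_feature_dim <- 9L
  expect_error(forward_pair(pairs, params, bad), class = "ptppi_config_error")
})

test_that("gradients reach every trainable tensor and match finite differences", {
  cfg <- toy_cfg()
  params <- init_ptppi_params(cfg)
  pack <- pack_pairs(toy_pairs(2, seed = 5))
  lg <- ptppi:::nn_loss_grad(params, cfg, pack, train = FALSE)
  groups <- c("W_in", "ln_gamma", "pe_A1", "pe_A2", "l1_W1", "l1_W2",
              "l1_W3", "l1_P1", "l1_G1", "l2_W3", "l2_G2", "sq_S1",
              "sq_S2", "hd_U1", "hd_U2")
  for (nm in groups) {
    g <- lg$grads[[nm]]
    expect_true(all(is.finite(g)), info = nm)
    expect_gt(sum(abs(g)), 0)
  }
  set.seed(1)
  for (nm in groups) {
    p <- params[[nm]]
    for (ii in sample(length(p), min(3, length(p)))) {
      h <- 1e-5
      pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + h
      pm <- params; pm[[nm]][ii] <- pm[[nm]][ii] - h
      fd <- (ptppi:::nn_loss_grad(pp, cfg, pack, train = FALSE)$loss -
               ptppi:::nn_loss_grad(pm, cfg, pack, train = FALSE)$loss) /
        (2 * h)
      an <- lg$grads[[nm]][ii]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd), abs(an)), 1e-4)
    }
  }
})

test_that("evaluation-mode forward passes are deterministic under fixed weights", {
  cfg <- toy_cfg()
  cfg$dropout <- 0.2
  params <- init_ptppi_params(cfg)
  pairs <- toy_pairs(3, seed = 9)
  p1 <- forward_pair(pairs, params, cfg, train = FALSE)
  p2 <- forward_pair(pairs, params, cfg, train = FALSE)
  expect_identical(p1, p2)
})
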