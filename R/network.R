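#' Model configuration for the PT-PPI network
#'
#' @param hidden_dim Hidden width H of all node / pooled embeddings.
#' @param num_pt_layers Number of Point Transformer layers (1 to 5).
#' @param dropout Dropout rate applied after the input encoding and after
#'   every transformer layer (inert in evaluation mode).
#' @param use_sequence Fuse pooled sequence embeddings into the head?
#' @param use_positional_encoder Add the learned encoding of inter-point
#'   displacements to the initial node embeddings?
#' @param use_pt_block If `FALSE`, the transformer stack is replaced by a
#'   two-layer perceptron on node features (ablation).
#' @param seq_embed_dim Width of the pooled sequence embeddings.
#' @param in_feature_dim Width of the surface point features (22 chemical +
#'   10 curvature channels).
#' @param rng_seed Seed used for weight initialisation.
#' @return Object of class `model_config`.
#' @export
model_config <- function(hidden_dim = 64L, num_pt_layers = 2L, dropout = 0.2,
                         use_sequence = TRUE, use_positional_encoder = TRUE,
                         use_pt_block = TRUE, seq_embed_dim = 1024L,
                         in_feature_dim = 32L, rng_seed = 1L) {
  stopifnot(hidden_dim > 0, num_pt_layers >= 1, num_pt_layers <= 5,
            dropout >= 0, dropout < 1, seq_embed_dim > 0, in_feature_dim > 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 num_pt_layers = as.integer(num_pt_layers),
                 dropout = dropout,
                 use_sequence = isTRUE(use_sequence),
                 use_positional_encoder = isTRUE(use_positional_encoder),
                 use_pt_block = isTRUE(use_pt_block),
                 seq_embed_dim = as.integer(seq_embed_dim),
                 in_feature_dim = as.integer(in_feature_dim),
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

rand_mat <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)

#' Initialise network parameters
#'
#' @param cfg A [model_config()].
#' @return Named list of weight matrices / bias vectors.
#' @export
init_ptppi_params <- function(cfg) {
  H <- cfg$hidden_dim
  with_seed(cfg$rng_seed, {
    p <- list(
      W_in = rand_mat(cfg$in_feature_dim, H),
      ln_gamma = rep(1, H), ln_beta = rep(0, H),
      pe_A1 = rand_mat(3, H), pe_b1 = rep(0, H),
      pe_A2 = rand_mat(H, H), pe_b2 = rep(0, H),
      sq_S1 = rand_mat(cfg$seq_embed_dim, H), sq_s1 = rep(0, H),
      sq_S2 = rand_mat(H, H), sq_s2 = rep(0, H),
      mlp_M1 = rand_mat(H, H), mlp_m1 = rep(0, H),
      mlp_M2 = rand_mat(H, H), mlp_m2 = rep(0, H)
    )
    for (l in seq_len(cfg$num_pt_layers)) {
      p[[sprintf("l%d_W1", l)]] <- rand_mat(H, H)
      p[[sprintf("l%d_W2", l)]] <- rand_mat(H, H)
      p[[sprintf("l%d_W3", l)]] <- rand_mat(H, H)
      p[[sprintf("l%d_b3", l)]] <- rep(0, H)
      p[[sprintf("l%d_P1", l)]] <- rand_mat(3, H)
      p[[sprintf("l%d_p1", l)]] <- rep(0, H)
      p[[sprintf("l%d_P2", l)]] <- rand_mat(H, H)
      p[[sprintf("l%d_p2", l)]] <- rep(0, H)
      p[[sprintf("l%d_G1", l)]] <- rand_mat(H, H)
      p[[sprintf("l%d_g1", l)]] <- rep(0, H)
      p[[sprintf("l%d_G2", l)]] <- rand_mat(H, H)
      p[[sprintf("l%d_g2", l)]] <- rep(0, H)
    }
    din <- if (cfg$use_sequence) 4L * H else 2L * H
    p$hd_U1 <- rand_mat(din, H); p$hd_u1 <- rep(0, H)
    p$hd_U2 <- rand_mat(H, 1); p$hd_u2 <- 0
    p
  })
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# segment sum of the rows of M by group index (1..n); returns n x ncol(M)
seg_sum <- function(M, idx, n) {
  rs <- rowsum(M, idx)
  out <- matrix(0, n, ncol(M))
  out[as.integer(rownames(rs)), ] <- rs
  out
}

drop_mask <- function(nr, nc, p, train) {
  if (!train || p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}
apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

add_bias <- function(M, b) sweep(M, 2, b, "+")

# ---------------------------------------------------------------------------
# forward pieces (each returns output + cache needed for backprop)

ln_forward <- function(Z, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(Z)
  xc <- Z - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat, 2, gamma, "*")
  y <- sweep(y, 2, beta, "+")
  list(out = y, xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, gamma) {
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dZ <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dZ = dZ, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

mlp2_forward <- function(X, W1, b1, W2, b2) {
  a1 <- add_bias(X %*% W1, b1)
  h1 <- relu(a1)
  out <- add_bias(h1 %*% W2, b2)
  list(out = out, a1 = a1, h1 = h1, X = X)
}

mlp2_backward <- function(dout, cache, W1, W2) {
  dh1 <- dout %*% t(W2)
  da1 <- dh1 * (cache$a1 > 0)
  list(dX = da1 %*% t(W1),
       dW1 = crossprod(cache$X, da1), db1 = colSums(da1),
       dW2 = crossprod(cache$h1, dout), db2 = colSums(dout))
}

# ---------------------------------------------------------------------------
# full batched forward; pack is built by pack_pairs()

nn_forward <- function(params, cfg, pack, train = FALSE, keep_cache = FALSE) {
  H <- cfg$hidden_dim
  N <- nrow(pack$X)
  cache <- list()

  # Input feature encoding: dropout(relu(LayerNorm(X W_in)))
  Z0 <- pack$X %*% params$W_in
  ln <- ln_forward(Z0, params$ln_gamma, params$ln_beta)
  Rin <- relu(ln$out)
  mask0 <- drop_mask(N, H, cfg$dropout, train)
  h <- apply_mask(Rin, mask0)
  if (keep_cache) cache$enc <- list(ln = ln, Rin = Rin, mask0 = mask0)

  # Node-level positional encoding: mean over in-neighbourhood of
  # hTheta(p_i - p_j)
  if (cfg$use_positional_encoder) {
    d <- pack$pos[pack$dst, , drop = FALSE] - pack$pos[pack$src, , drop = FALSE]
    pe <- mlp2_forward(d, params$pe_A1, params$pe_b1,
                       params$pe_A2, params$pe_b2)
    cnt <- tabulate(pack$dst, N)
    S <- seg_sum(pe$out, pack$dst, N)
    mean_pe <- S / pmax(cnt, 1)
    if (any(cnt == 0)) {
      h0row <- as.numeric(add_bias(relu(matrix(params$pe_b1, 1)) %*%
                                     params$pe_A2, params$pe_b2))
      mean_pe[cnt == 0, ] <- matrix(h0row, sum(cnt == 0), H, byrow = TRUE)
    }
    h <- h + mean_pe
    if (keep_cache) cache$pe <- list(pe = pe, cnt = cnt)
  }

  if (cfg$use_pt_block) {
    src_all <- c(pack$src, seq_len(N))
    dst_all <- c(pack$dst, seq_len(N))
    dall <- pack$pos[dst_all, , drop = FALSE] - pack$pos[src_all, , drop = FALSE]
    selfpos <- length(pack$src) + seq_len(N)
    cache$layers <- vector("list", cfg$num_pt_layers)
    for (l in seq_len(cfg$num_pt_layers)) {
      g <- function(nm) params[[sprintf("l%d_%s", l, nm)]]
      dm <- mlp2_forward(dall, g("P1"), g("p1"), g("P2"), g("p2"))
      delta <- dm$out
      q <- h %*% g("W1")
      kk <- h %*% g("W2")
      v <- add_bias(h %*% g("W3"), g("b3"))
      u <- q[dst_all, , drop = FALSE] - kk[src_all, , drop = FALSE] + delta
      gm <- mlp2_forward(u, g("G1"), g("g1"), g("G2"), g("g2"))
      logit <- gm$out
      sh <- logit - logit[selfpos[dst_all], , drop = FALSE]
      clamped <- sh > 80
      sh[clamped] <- 80
      ex <- exp(sh)
      denom <- seg_sum(ex, dst_all, N)
      alpha <- ex / denom[dst_all, , drop = FALSE]
      w <- v[src_all, , drop = FALSE] + delta
      msg <- alpha * w
      out <- seg_sum(msg, dst_all, N)
      Rl <- relu(out)
      maskl <- drop_mask(N, H, cfg$dropout, train)
      h_new <- apply_mask(Rl, maskl)
      if (keep_cache)
        cache$layers[[l]] <- list(h = h, dm = dm, gm = gm, alpha = alpha,
                                  w = w, out = out, maskl = maskl,
                                  clamped = clamped)
      h <- h_new
    }
    if (keep_cache) cache$edges <- list(src_all = src_all, dst_all = dst_all,
                                        dall = dall, selfpos = selfpos)
  } else {
    # ablation: two-layer perceptron instead of the transformer stack
    a1 <- add_bias(h %*% params$mlp_M1, params$mlp_m1)
    r1 <- relu(a1)
    mask1 <- drop_mask(N, H, cfg$dropout, train)
    h1 <- apply_mask(r1, mask1)
    a2 <- add_bias(h1 %*% params$mlp_M2, params$mlp_m2)
    r2 <- relu(a2)
    mask2 <- drop_mask(N, H, cfg$dropout, train)
    h_new <- apply_mask(r2, mask2)
    if (keep_cache) cache$mlp <- list(h = h, a1 = a1, h1 = h1, a2 = a2,
                                      mask1 = mask1, mask2 = mask2)
    h <- h_new
  }

  # per-chain mean pooling
  C <- pack$n_chain
  cntc <- tabulate(pack$chain, C)
  if (any(cntc == 0)) stop_ptppi("ptppi_pooling_error", "empty chain in batch")
  G <- seg_sum(h, pack$chain, C) / cntc

  GL <- G[pack$pair_chains[, 1], , drop = FALSE]
  GR <- G[pack$pair_chains[, 2], , drop = FALSE]
  if (cfg$use_sequence) {
    sl <- mlp2_forward(pack$seq_l, params$sq_S1, params$sq_s1,
                       params$sq_S2, params$sq_s2)
    sr <- mlp2_forward(pack$seq_r, params$sq_S1, params$sq_s1,
                       params$sq_S2, params$sq_s2)
    z <- cbind(GL, GR, sl$out, sr$out)
    if (keep_cache) cache$seq <- list(sl = sl, sr = sr)
  } else {
    z <- cbind(GL, GR)
  }
  hd <- mlp2_forward(z, params$hd_U1, params$hd_u1, params$hd_U2, params$hd_u2)
  prob <- as.numeric(sigmoid(hd$out))

  if (keep_cache) {
    cache$h_final <- h
    cache$cntc <- cntc
    cache$hd <- hd
    cache$z <- z
  }
  list(prob = prob, h = h, pooled = G, cache = if (keep_cache) cache)
}

# backward pass; returns gradients for every parameter (same names)
nn_backward <- function(params, cfg, pack, fw, dlogit_head) {
  H <- cfg$hidden_dim
  N <- nrow(pack$X)
  cache <- fw$cache
  gr <- list()

  # head
  hb <- mlp2_backward(matrix(dlogit_head, ncol = 1), cache$hd,
                      params$hd_U1, params$hd_U2)
  gr$hd_U1 <- hb$dW1; gr$hd_u1 <- hb$db1
  gr$hd_U2 <- hb$dW2; gr$hd_u2 <- hb$db2
  dz <- hb$dX
  dGL <- dz[, 1:H, drop = FALSE]
  dGR <- dz[, H + 1:H, drop = FALSE]
  if (cfg$use_sequence) {
    dsl <- dz[, 2 * H + 1:H, drop = FALSE]
    dsr <- dz[, 3 * H + 1:H, drop = FALSE]
    bl <- mlp2_backward(dsl, cache$seq$sl, params$sq_S1, params$sq_S2)
    br <- mlp2_backward(dsr, cache$seq$sr, params$sq_S1, params$sq_S2)
    gr$sq_S1 <- bl$dW1 + br$dW1; gr$sq_s1 <- bl$db1 + br$db1
    gr$sq_S2 <- bl$dW2 + br$dW2; gr$sq_s2 <- bl$db2 + br$db2
  }

  # pooling: dG (C x H) -> dh
  C <- pack$n_chain
  dG <- matrix(0, C, H)
  dG <- dG + seg_sum(dGL, pack$pair_chains[, 1], C)
  dG <- dG + seg_sum(dGR, pack$pair_chains[, 2], C)
  dG <- dG / cache$cntc
  dh <- dG[pack$chain, , drop = FALSE]

  if (cfg$use_pt_block) {
    e <- cache$edges
    E <- length(e$src_all)
    for (l in rev(seq_len(cfg$num_pt_layers))) {
      g <- function(nm) params[[sprintf("l%d_%s", l, nm)]]
      cl <- cache$layers[[l]]
      dR <- apply_mask(dh, cl$maskl)
      dout <- dR * (cl$out > 0)
      dmsg <- dout[e$dst_all, , drop = FALSE]
      dalpha <- dmsg * cl$w
      dw <- dmsg * cl$alpha
      # softmax backward (shift-invariant, so the self-loop shift adds 0)
      ssum <- seg_sum(cl$alpha * dalpha, e$dst_all, N)
      dlogit <- cl$alpha * (dalpha - ssum[e$dst_all, , drop = FALSE])
      dlogit[cl$clamped] <- 0
      gb <- mlp2_backward(dlogit, cl$gm, g("G1"), g("G2"))
      gr[[sprintf("l%d_G1", l)]] <- gb$dW1
      gr[[sprintf("l%d_g1", l)]] <- gb$db1
      gr[[sprintf("l%d_G2", l)]] <- gb$dW2
      gr[[sprintf("l%d_g2", l)]] <- gb$db2
      du <- gb$dX
      ddelta <- du + dw
      db <- mlp2_backward(ddelta, cl$dm, g("P1"), g("P2"))
      gr[[sprintf("l%d_P1", l)]] <- db$dW1
      gr[[sprintf("l%d_p1", l)]] <- db$db1
      gr[[sprintf("l%d_P2", l)]] <- db$dW2
      gr[[sprintf("l%d_p2", l)]] <- db$db2
      dq <- seg_sum(du, e$dst_all, N)
      dkk <- -seg_sum(du, e$src_all, N)
      dv <- seg_sum(dw, e$src_all, N)
      gr[[sprintf("l%d_W1", l)]] <- crossprod(cl$h, dq)
      gr[[sprintf("l%d_W2", l)]] <- crossprod(cl$h, dkk)
      gr[[sprintf("l%d_W3", l)]] <- crossprod(cl$h, dv)
      gr[[sprintf("l%d_b3", l)]] <- colSums(dv)
      dh <- dq %*% t(g("W1")) + dkk %*% t(g("W2")) + dv %*% t(g("W3"))
    }
  } else {
    cm <- cache$mlp
    dr2 <- apply_mask(dh, cm$mask2)
    da2 <- dr2 * (cm$a2 > 0)
    gr$mlp_M2 <- crossprod(cm$h1, da2); gr$mlp_m2 <- colSums(da2)
    dh1 <- da2 %*% t(params$mlp_M2)
    dr1 <- apply_mask(dh1, cm$mask1)
    da1 <- dr1 * (cm$a1 > 0)
    gr$mlp_M1 <- crossprod(cm$h, da1); gr$mlp_m1 <- colSums(da1)
    dh <- da1 %*% t(params$mlp_M1)
  }

  # positional encoder
  if (cfg$use_positional_encoder) {
    pe <- cache$pe
    dmean <- dh  # positional term was added to h0
    dsum <- dmean[pack$dst, , drop = FALSE] /
      pmax(pe$cnt, 1)[pack$dst]
    pb <- mlp2_backward(dsum, pe$pe, params$pe_A1, params$pe_A2)
    gr$pe_A1 <- pb$dW1; gr$pe_b1 <- pb$db1
    gr$pe_A2 <- pb$dW2; gr$pe_b2 <- pb$db2
  }

  # input encoding
  enc <- cache$enc
  dRin <- apply_mask(dh, enc$mask0)
  dln <- dRin * (enc$ln$out > 0)
  lb <- ln_backward(dln, enc$ln, params$ln_gamma)
  gr$ln_gamma <- lb$dgamma; gr$ln_beta <- lb$dbeta
  gr$W_in <- crossprod(pack$X, lb$dZ)
  gr
}

# binary cross-entropy loss + full gradient for a packed batch
nn_loss_grad <- function(params, cfg, pack, train = TRUE) {
  fw <- nn_forward(params, cfg, pack, train = train, keep_cache = TRUE)
  p <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
  y <- pack$y
  B <- length(y)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dlogit <- (fw$prob - y) / B
  grads <- nn_backward(params, cfg, pack, fw, dlogit)
  list(loss = loss, prob = fw$prob, grads = grads)
}

# ---------------------------------------------------------------------------
# exported module operations (thin wrappers around the batched core)

#' Encode node features into the hidden space
#'
#' `dropout(ReLU(LayerNorm(W_in x)))`, the input feature encoding of the
#' network. Dropout is inert unless `train = TRUE`.
#'
#' @param x N x `in_feature_dim` feature matrix.
#' @param params Parameters from [init_ptppi_params()].
#' @param cfg A [model_config()].
#' @param train Training mode (enables dropout)?
#' @return N x H matrix.
#' @export
encode_nodes <- function(x, params, cfg, train = FALSE) {
  if (ncol(x) != cfg$in_feature_dim)
    stop_ptppi("ptppi_shape_error",
               sprintf("expected %d input features, got %d",
                       cfg$in_feature_dim, ncol(x)))
  Z0 <- x %*% params$W_in
  ln <- ln_forward(Z0, params$ln_gamma, params$ln_beta)
  apply_mask(relu(ln$out), drop_mask(nrow(x), cfg$hidden_dim, cfg$dropout,
                                     train))
}

#' Node-level positional encoding
#'
#' Applies the two-layer perceptron `hTheta` to every displacement
#' `p_i - p_j` along the graph edges and aggregates per node by the mean
#' over its in-neighbourhood. Nodes without incident edges receive
#' `hTheta(0)`.
#'
#' @param pos N x 3 positions.
#' @param edge_index E x 2 directed edge matrix (`from`, `to`).
#' @param params,cfg As in [encode_nodes()].
#' @return N x H matrix of additive positional terms.
#' @export
positional_encoding <- function(pos, edge_index, params, cfg) {
  N <- nrow(pos)
  H <- cfg$hidden_dim
  src <- edge_index[, 1]; dst <- edge_index[, 2]
  d <- pos[dst, , drop = FALSE] - pos[src, , drop = FALSE]
  pe <- mlp2_forward(d, params$pe_A1, params$pe_b1, params$pe_A2, params$pe_b2)
  cnt <- tabulate(dst, N)
  out <- seg_sum(pe$out, dst, N) / pmax(cnt, 1)
  if (any(cnt == 0)) {
    h0row <- as.numeric(add_bias(relu(matrix(params$pe_b1, 1)) %*%
                                   params$pe_A2, params$pe_b2))
    out[cnt == 0, ] <- matrix(h0row, sum(cnt == 0), H, byrow = TRUE)
  }
  out
}

#' One Point Transformer layer
#'
#' Vector attention over graph neighbourhoods,
#' \deqn{x_i' = \sum_{j \in N(i)} \alpha_{ij} \odot (W_3 x_j + \delta_{ij}),}
#' with \eqn{\alpha_{ij} = \mathrm{softmax}_j(\gamma(W_1 x_i - W_2 x_j +
#' \delta_{ij}))} normalised per channel over `N(i)`, followed by
#' `dropout(ReLU(.))`. Self-loops are added internally so every node has a
#' non-empty neighbourhood.
#'
#' @param h N x H node embeddings.
#' @param pos N x 3 positions.
#' @param edge_index E x 2 directed edges.
#' @param params,cfg As in [encode_nodes()].
#' @param layer Which layer's weights to use (1-based).
#' @param train Training mode (enables dropout)?
#' @return N x H updated embeddings.
#' @export
pt_layer <- function(h, pos, edge_index, params, cfg, layer = 1L,
                     train = FALSE) {
  N <- nrow(h)
  pack <- list(X = matrix(0, N, cfg$in_feature_dim), pos = pos,
               src = edge_index[, 1], dst = edge_index[, 2])
  cfg1 <- cfg
  cfg1$num_pt_layers <- 1L
  # run the single-layer core directly on h
  src_all <- c(pack$src, seq_len(N))
  dst_all <- c(pack$dst, seq_len(N))
  dall <- pos[dst_all, , drop = FALSE] - pos[src_all, , drop = FALSE]
  selfpos <- length(pack$src) + seq_len(N)
  g <- function(nm) params[[sprintf("l%d_%s", layer, nm)]]
  delta <- mlp2_forward(dall, g("P1"), g("p1"), g("P2"), g("p2"))$out
  q <- h %*% g("W1"); kk <- h %*% g("W2")
  v <- add_bias(h %*% g("W3"), g("b3"))
  u <- q[dst_all, , drop = FALSE] - kk[src_all, , drop = FALSE] + delta
  logit <- mlp2_forward(u, g("G1"), g("g1"), g("G2"), g("g2"))$out
  sh <- logit - logit[selfpos[dst_all], , drop = FALSE]
  sh[sh > 80] <- 80
  ex <- exp(sh)
  alpha <- ex / seg_sum(ex, dst_all, N)[dst_all, , drop = FALSE]
  out <- seg_sum(alpha * (v[src_all, , drop = FALSE] + delta), dst_all, N)
  apply_mask(relu(out), drop_mask(N, cfg$hidden_dim, cfg$dropout, train))
}

#' Attention weights of a Point Transformer layer
#'
#' Returns the per-channel attention coefficients over the self-loop
#' augmented edge set, mainly for testing and interpretation.
#'
#' @inheritParams pt_layer
#' @return List with `alpha` (E+N x H), `src`, `dst`.
#' @export
pt_attention <- function(h, pos, edge_index, params, cfg, layer = 1L) {
  N <- nrow(h)
  src_all <- c(edge_index[, 1], seq_len(N))
  dst_all <- c(edge_index[, 2], seq_len(N))
  dall <- pos[dst_all, , drop = FALSE] - pos[src_all, , drop = FALSE]
  selfpos <- nrow(edge_index) + seq_len(N)
  g <- function(nm) params[[sprintf("l%d_%s", layer, nm)]]
  delta <- mlp2_forward(dall, g("P1"), g("p1"), g("P2"), g("p2"))$out
  q <- h %*% g("W1"); kk <- h %*% g("W2")
  u <- q[dst_all, , drop = FALSE] - kk[src_all, , drop = FALSE] + delta
  logit <- mlp2_forward(u, g("G1"), g("g1"), g("G2"), g("g2"))$out
  sh <- logit - logit[selfpos[dst_all], , drop = FALSE]
  sh[sh > 80] <- 80
  ex <- exp(sh)
  alpha <- ex / seg_sum(ex, dst_all, N)[dst_all, , drop = FALSE]
  list(alpha = alpha, src = src_all, dst = dst_all)
}

#' Mean-pool node embeddings per chain
#'
#' @param h N x H node embeddings.
#' @param chain Integer vector assigning each node to a chain (1-based).
#' @return `max(chain)` x H matrix of per-chain means.
#' @export
pool_chain <- function(h, chain) {
  C <- max(chain)
  cnt <- tabulate(chain, C)
  if (any(cnt == 0)) stop_ptppi("ptppi_pooling_error", "empty chain")
  seg_sum(h, chain, C) / cnt
}

#' Project a pooled sequence embedding into the hidden space
#'
#' Two-layer perceptron `seq_embed_dim -> H -> H` with ReLU between the
#' layers.
#'
#' @param s Numeric vector of length `seq_embed_dim`, or a matrix with that
#'   many columns.
#' @param params,cfg As in [encode_nodes()].
#' @return H-vector (or matrix with H columns).
#' @export
project_sequence <- function(s, params, cfg) {
  if (is.null(dim(s))) s <- matrix(s, 1)
  if (ncol(s) != cfg$seq_embed_dim)
    stop_ptppi("ptppi_shape_error",
               sprintf("expected %d-wide sequence embedding, got %d",
                       cfg$seq_embed_dim, ncol(s)))
  out <- mlp2_forward(s, params$sq_S1, params$sq_s1,
                      params$sq_S2, params$sq_s2)$out
  if (nrow(out) == 1) as.numeric(out) else out
}

#' Forward pass over a batch of ligand-receptor pairs
#'
#' Runs the full network (input encoding, positional encoding, transformer
#' stack or its MLP ablation, per-chain pooling, sequence projection,
#' fusion and prediction head) and returns one interaction probability per
#' pair.
#'
#' @param batch A packed batch from [pack_pairs()], or a list of pair
#'   samples (see [generate_synthetic_complex()]).
#' @param params,cfg As in [encode_nodes()].
#' @param train Training mode (enables dropout)?
#' @return Numeric vector of probabilities in (0, 1).
#' @export
forward_pair <- function(batch, params, cfg, train = FALSE) {
  if (is.null(batch$X)) batch <- pack_pairs(batch)
  if (ncol(batch$X) != cfg$in_feature_dim)
    stop_ptppi("ptppi_config_error", "node feature width mismatch")
  if (cfg$use_sequence && ncol(batch$seq_l) != cfg$seq_embed_dim)
    stop_ptppi("ptppi_config_error", "sequence embedding width mismatch")
  nn_forward(params, cfg, batch, train = train)$prob
}

#' Pack pair samples into a batched graph
#'
#' Concatenates the ligand and receptor graphs of many pairs into one
#' block-diagonal graph with per-node chain ids, ready for the batched
#' network core.
#'
#' @param pairs List of `pair_sample` objects.
#' @return A pack: list with `X`, `pos`, `src`, `dst`, `chain`, `n_chain`,
#'   `pair_chains`, `seq_l`, `seq_r`, `y`, `ids`.
#' @export
pack_pairs <- function(pairs) {
  Xs <- list(); poss <- list(); srcs <- list(); dsts <- list()
  chains <- list()
  B <- length(pairs)
  pair_chains <- matrix(0L, B, 2)
  seq_l <- NULL; seq_r <- NULL
  y <- numeric(B); ids <- character(B)
  off <- 0L; chain_id <- 0L
  for (b in seq_len(B)) {
    p <- pairs[[b]]
    for (side in c("lig", "rec")) {
      gph <- p[[paste0(side, "_graph")]]
      n <- nrow(gph$pos)
      chain_id <- chain_id + 1L
      Xs[[length(Xs) + 1L]] <- gph$x
      poss[[length(poss) + 1L]] <- gph$pos
      srcs[[length(srcs) + 1L]] <- gph$edge_index[, 1] + off
      dsts[[length(dsts) + 1L]] <- gph$edge_index[, 2] + off
      chains[[length(chains) + 1L]] <- rep(chain_id, n)
      pair_chains[b, if (side == "lig") 1 else 2] <- chain_id
      off <- off + n
    }
    if (is.null(seq_l)) {
      seq_l <- matrix(0, B, length(p$seq_embed_l))
      seq_r <- matrix(0, B, length(p$seq_embed_r))
    }
    seq_l[b, ] <- p$seq_embed_l
    seq_r[b, ] <- p$seq_embed_r
    y[b] <- p$label
    ids[b] <- p$id %||% as.character(b)
  }
  list(X = do.call(rbind, Xs), pos = do.call(rbind, poss),
       src = unlist(srcs), dst = unlist(dsts),
       chain = unlist(chains), n_chain = chain_id,
       pair_chains = pair_chains, seq_l = seq_l, seq_r = seq_r,
       y = y, ids = ids)
}
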