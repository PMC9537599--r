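# Minimal reverse-mode automatic differentiation engine.
#
# Values are dense arrays; batched image tensors use dim (H, W, C, N) in
# native column-major order so the Rcpp convolution kernels can alias them
# without copying. A node records its value, its parents and a backward
# closure mapping the incoming gradient to per-parent gradients. Creation
# ids increase monotonically, so sorting reachable nodes by decreasing id
# yields a valid reverse topological order.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_node <- function(v, parents = list(), bw = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  .ad$counter <- .ad$counter + 1L
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$param <- param
  e$id <- .ad$counter
  class(e) <- "adnode"
  e
}

ad_const <- function(v) ad_node(v)
ad_param <- function(v) ad_node(v, param = TRUE)

as_ad <- function(x) if (inherits(x, "adnode")) x else ad_const(x)

ad_accum <- function(node, g) {
  if (is.null(g)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar root. Gradients end up in node$grad; call
# ad_zero_grads() on parameters between steps.
ad_backward <- function(root, seed = 1) {
  stopifnot(inherits(root, "adnode"))
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  nn <- 0L
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  root$grad <- seed
  for (nd in nodes[ord]) {
    if (is.null(nd$bw) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    for (i in seq_along(nd$parents)) ad_accum(nd$parents[[i]], gs[[i]])
    if (!nd$param && !identical(nd, root)) nd$grad <- NULL
  }
  invisible(root)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and arithmetic ops ----------------------------------------

op_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$v + b$v, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$v - b$v, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$v; bv <- b$v
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_smul <- function(a, k) {
  a <- as_ad(a)
  ad_node(a$v * k, list(a), function(g) list(g * k))
}

op_lrelu <- function(a, alpha = 0.2) {
  a <- as_ad(a)
  m <- ifelse(a$v > 0, 1, alpha)
  ad_node(a$v * m, list(a), function(g) list(g * m))
}

op_silu <- function(a) {
  a <- as_ad(a)
  av <- a$v
  if (is.null(dim(av))) {
    s <- 1 / (1 + exp(-av))
    return(ad_node(av * s, list(a),
                   function(g) list(g * s * (1 + av * (1 - s)))))
  }
  ad_node(silu_fwd(av), list(a), function(g) {
    dim(g) <- dim(av)
    list(silu_bwd(av, g))
  })
}

op_tanh <- function(a) {
  a <- as_ad(a)
  t <- tanh(a$v)
  ad_node(t, list(a), function(g) list(g * (1 - t^2)))
}

# Hard clip; zero subgradient outside the active range.
op_clip <- function(a, lo, hi) {
  a <- as_ad(a)
  m <- (a$v >= lo) & (a$v <= hi)
  ad_node(pmin(pmax(a$v, lo), hi), list(a), function(g) list(g * m))
}

op_mean <- function(a) {
  a <- as_ad(a)
  n <- length(a$v)
  ad_node(mean(a$v), list(a), function(g) {
    gr <- array(g / n, dim = if (is.null(dim(a$v))) length(a$v) else dim(a$v))
    list(gr)
  })
}

# Mean absolute difference (L1).
op_l1 <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- a$v - b$v
  n <- length(d)
  ad_node(mean(abs(d)), list(a, b), function(g) {
    s <- sign(d) * (g / n)
    dm <- if (is.null(dim(d))) s else array(s, dim = dim(d))
    list(dm, -dm)
  })
}

op_mse <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- a$v - b$v
  n <- length(d)
  ad_node(mean(d^2), list(a, b), function(g) {
    s <- 2 * d * (g / n)
    list(s, -s)
  })
}

# ---- structured ops ---------------------------------------------------------

# 2-D convolution with per-output-channel bias. x: (H, W, Cin, N),
# w: (kh, kw, Cin, Cout), b: (Cout).
op_conv <- function(x, w, b, stride = 1L, pad = 1L) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  out <- conv2d_fwd(x$v, w$v, as.integer(stride), as.integer(pad))
  d <- dim(out)
  out <- out + rep(b$v, each = d[1] * d[2])
  xd <- dim(x$v); wd <- dim(w$v)
  ad_node(out, list(x, w, b), function(g) {
    dim(g) <- d
    gm <- matrix(g, nrow = d[1] * d[2])
    db <- rowSums(matrix(colSums(gm), nrow = d[3]))
    list(conv2d_bwd_input(g, w$v, as.integer(stride), as.integer(pad),
                          as.integer(xd[1]), as.integer(xd[2])),
         conv2d_bwd_weight(x$v, g, as.integer(stride), as.integer(pad),
                           as.integer(wd[1]), as.integer(wd[2])),
         db)
  })
}

# Per-sample channel bias: x (H, W, C, N) + b (C, N), broadcast over space.
op_bias_cn <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  d <- dim(x$v)
  stopifnot(nrow(b$v) == d[3], ncol(b$v) == d[4])
  hw <- d[1] * d[2]
  ad_node(bias_cn_fwd(x$v, b$v), list(x, b), function(g) {
    db <- matrix(colSums(matrix(g, nrow = hw)), nrow = d[3])
    list(g, db)
  })
}

# Group normalization over (H, W, channels-in-group), per sample.
op_group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_ad(x); gamma <- as_ad(gamma); beta <- as_ad(beta)
  d <- dim(x$v)
  stopifnot(d[3] %% groups == 0)
  fw <- gn_fwd(x$v, gamma$v, beta$v, as.integer(groups), eps)
  ad_node(fw$out, list(x, gamma, beta), function(g) {
    dim(g) <- d
    bw <- gn_bwd(x$v, g, gamma$v, fw$mu, fw$istd, as.integer(groups))
    list(bw$dx, bw$dgamma, bw$dbeta)
  })
}

# Nearest-neighbour 2x upsampling.
op_upsample2 <- function(x) {
  x <- as_ad(x)
  d <- dim(x$v)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  out <- x$v[ri, ci, , , drop = FALSE]
  ad_node(out, list(x), function(g) {
    dim(g) <- c(2 * d[1], 2 * d[2], d[3], d[4])
    gs <- g[seq(1, 2 * d[1], 2), , , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), , , , drop = FALSE]
    gs <- gs[, seq(1, 2 * d[2], 2), , , drop = FALSE] +
      gs[, seq(2, 2 * d[2], 2), , , drop = FALSE]
    list(gs)
  })
}

op_concat_c <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  da <- dim(a$v); db <- dim(b$v)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a$v
  out[, , da[3] + seq_len(db[3]), ] <- b$v
  ad_node(out, list(a, b), function(g) {
    dim(g) <- dim(out)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Global average pool: (H, W, C, N) -> (C, N).
op_gap <- function(x) {
  x <- as_ad(x)
  d <- dim(x$v)
  hw <- d[1] * d[2]
  out <- matrix(colMeans(matrix(x$v, nrow = hw)), nrow = d[3])
  ad_node(out, list(x), function(g) {
    gfull <- rep(as.vector(g) / hw, each = hw)
    list(array(gfull, d))
  })
}

# Dense layer on column-sample matrices: x (F, N), w (F, O), b (O) -> (O, N).
op_linear <- function(x, w, b) {
  x <- as_ad(x); w <- as_ad(w); b <- as_ad(b)
  out <- crossprod(w$v, x$v) + b$v
  ad_node(out, list(x, w, b), function(g) {
    dim(g) <- dim(out)
    list(w$v %*% g, x$v %*% t(g), rowSums(g))
  })
}

op_reshape <- function(x, dims) {
  x <- as_ad(x)
  old <- dim(x$v)
  ad_node(array(x$v, dims), list(x), function(g) list(array(g, old)))
}

# Single-head spatial self-attention. x: (H, W, C, N); wq/wk/wv/wo: (C, C).
# Tokens are the H*W spatial positions.
op_attention <- function(x, wq, wk, wv, wo) {
  x <- as_ad(x); wq <- as_ad(wq); wk <- as_ad(wk); wv <- as_ad(wv); wo <- as_ad(wo)
  d <- dim(x$v)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  sc <- 1 / sqrt(C)
  Ts <- As <- Qs <- Ks <- Vs <- vector("list", N)
  out <- array(0, d)
  for (n in seq_len(N)) {
    Tm <- matrix(x$v[, , , n], hw, C)
    Q <- Tm %*% wq$v; K <- Tm %*% wk$v; V <- Tm %*% wv$v
    S <- tcrossprod(Q, K) * sc
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    out[, , , n] <- array((A %*% V) %*% wo$v, c(d[1], d[2], C))
    Ts[[n]] <- Tm; As[[n]] <- A; Qs[[n]] <- Q; Ks[[n]] <- K; Vs[[n]] <- V
  }
  ad_node(out, list(x, wq, wk, wv, wo), function(g) {
    dim(g) <- d
    dx <- array(0, d)
    dwq <- matrix(0, C, C); dwk <- matrix(0, C, C)
    dwv <- matrix(0, C, C); dwo <- matrix(0, C, C)
    for (n in seq_len(N)) {
      Gm <- matrix(g[, , , n], hw, C)
      A <- As[[n]]; Tm <- Ts[[n]]
      dO <- Gm %*% t(wo$v)                    # grad wrt A %*% V
      dwo <- dwo + crossprod(A %*% Vs[[n]], Gm)
      dA <- tcrossprod(dO, Vs[[n]])
      dV <- crossprod(A, dO)
      dS <- A * (dA - rowSums(dA * A)) * sc   # softmax backward, rowwise
      dQ <- dS %*% Ks[[n]]
      dK <- crossprod(dS, Qs[[n]])
      dT <- dQ %*% t(wq$v) + dK %*% t(wk$v) + dV %*% t(wv$v)
      dwq <- dwq + crossprod(Tm, dQ)
      dwk <- dwk + crossprod(Tm, dK)
      dwv <- dwv + crossprod(Tm, dV)
      dx[, , , n] <- array(dT, c(d[1], d[2], C))
    }
    list(dx, dwq, dwk, dwv, dwo)
  })
}

# Softmax cross-entropy over logits (K, N) with integer labels in 1..K.
op_softmax_ce <- function(logits, labels) {
  logits <- as_ad(logits)
  L <- logits$v
  L <- L - rep(apply(L, 2, max), each = nrow(L))
  P <- exp(L)
  P <- P / rep(colSums(P), each = nrow(P))
  N <- ncol(P)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  ad_node(loss, list(logits), function(g) {
    dP <- P
    dP[idx] <- dP[idx] - 1
    list(dP * (g / N))
  })
}

# ---- optimizer --------------------------------------------------------------

# Decoupled-weight-decay Adam over a flat list of parameter nodes.
adamw_init <- function(params) {
  for (p in params) {
    p$m <- p$v * 0
    p$v2 <- p$m
  }
  list(t = 0L)
}

adamw_step <- function(params, state, lr = 1e-4, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(dim(p$v))) g <- as.vector(g) else dim(g) <- dim(p$v)
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v2 <- beta2 * p$v2 + (1 - beta2) * g^2
    p$v <- p$v - lr * ((p$m / c1) / (sqrt(p$v2 / c2) + eps) + weight_decay * p$v)
  }
  state
}
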