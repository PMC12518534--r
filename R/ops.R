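# Differentiable array operations.
#
# Layout conventions, fixed package-wide:
#   * feature maps ("grids"): (H, W, C, B) column-major arrays
#   * token matrices: (N, C, B) with token n = w + W*(h-1), i.e. row-major
#     raster scan of the grid, channels-last per token
#   * channel gates: (C, B)
# Backward closures return one gradient per parent (NULL for constants).

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- broadcasting helpers (pure functions, used in both directions) ----

expand_mid <- function(m, cols) {
  # (r, B) -> (r, cols, B)
  d <- dim(m)
  aperm(array(m, c(d[1], d[2], cols)), c(1, 3, 2))
}

expand_front <- function(m, n) {
  # (d, B) -> (n, d, B)
  d <- dim(m)
  aperm(array(m, c(d[1], d[2], n)), c(3, 1, 2))
}

expand_grid_cb <- function(m, H, W) {
  # (C, B) -> (H, W, C, B)
  array(rep(as.vector(m), each = H * W), c(H, W, dim(m)[1], dim(m)[2]))
}

# ---- elementwise ----

op_add <- function(a, b) {
  ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

op_sub <- function(a, b) {
  ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

op_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

op_const_mul <- function(a, s) {
  ad_op(a$value * s, list(a), function(g) list(g * s))
}

op_scalar_mul <- function(x, s) {
  # s: length-1 tensor (e.g. a learnable branch weight)
  xv <- x$value; sv <- as.numeric(s$value)
  ad_op(xv * sv, list(x, s),
        function(g) list(g * sv, array(sum(g * xv), dim = dim(s$value))))
}

op_gelu <- function(x) {
  xv <- x$value
  ad_op(xv * stats::pnorm(xv), list(x),
        function(g) list(g * (stats::pnorm(xv) + xv * stats::dnorm(xv))))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  ad_op(y, list(x), function(g) list(g * y * (1 - y)))
}

# ---- scale / bias along one margin ----

# expand a per-channel vector to the full array shape for margin `dim`
margin_expand <- function(v, d, dim) {
  inner <- prod(d[seq_len(dim - 1L)])
  outer <- prod(d[seq_along(d) > dim])
  rep(rep(v, each = inner), times = outer)
}

margin_sum <- function(a, d, dim) {
  if (dim == length(d)) return(colSums(a, dims = dim - 1L))
  if (dim == length(d) - 1L) {
    s <- colSums(a, dims = dim - 1L) # (C, B)
    return(rowSums(s))
  }
  apply(a, dim, sum)
}

op_scale_dim <- function(x, gamma, dim) {
  xv <- x$value; gv <- as.vector(gamma$value)
  d <- dim(xv)
  ge <- margin_expand(gv, d, dim)
  ad_op(xv * ge, list(x, gamma), function(g) {
    dg <- margin_sum(g * xv, d, dim)
    list(g * ge, array(dg, dim = dim(gamma$value)))
  })
}

op_bias_dim <- function(x, b, dim) {
  bv <- as.vector(b$value)
  d <- dim(x$value)
  ad_op(x$value + margin_expand(bv, d, dim), list(x, b), function(g) {
    list(g, array(margin_sum(g, d, dim), dim = dim(b$value)))
  })
}

# ---- matrix products ----

op_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), t(av) %*% g))
}

op_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  # batched matmul over third dim; optional transposes of the 2D slices
  av <- a$value; bv <- b$value
  da <- dim(av); db_ <- dim(bv)
  nb <- da[3]
  m <- if (ta) da[2] else da[1]
  n <- if (tb) db_[1] else db_[2]
  y <- array(0, c(m, n, nb))
  for (i in seq_len(nb)) {
    A <- av[, , i, drop = FALSE]; dim(A) <- da[1:2]
    B <- bv[, , i, drop = FALSE]; dim(B) <- db_[1:2]
    if (ta) A <- t(A)
    if (tb) B <- t(B)
    y[, , i] <- A %*% B
  }
  ad_op(y, list(a, b), function(g) {
    ga <- array(0, da); gb <- array(0, db_)
    for (i in seq_len(nb)) {
      G <- g[, , i, drop = FALSE]; dim(G) <- c(m, n)
      A <- av[, , i, drop = FALSE]; dim(A) <- da[1:2]
      B <- bv[, , i, drop = FALSE]; dim(B) <- db_[1:2]
      Ai <- if (ta) t(A) else A
      Bi <- if (tb) t(B) else B
      gA <- G %*% t(Bi)
      gB <- t(Ai) %*% G
      ga[, , i] <- if (ta) t(gA) else gA
      gb[, , i] <- if (tb) t(gB) else gB
    }
    list(ga, gb)
  })
}

op_token_linear <- function(x, W, b = NULL) {
  # x: (N, C, B); W: (C, M); b: (M) or NULL
  xv <- x$value; Wv <- W$value
  d <- dim(xv); N <- d[1]; C <- d[2]; B <- d[3]; M <- dim(Wv)[2]
  xm <- aperm(xv, c(1, 3, 2)); dim(xm) <- c(N * B, C)
  ym <- xm %*% Wv
  if (!is.null(b)) ym <- sweep(ym, 2, as.vector(b$value), "+")
  y <- ym; dim(y) <- c(N, B, M); y <- aperm(y, c(1, 3, 2))
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  ad_op(y, parents, function(g) {
    gm <- aperm(g, c(1, 3, 2)); dim(gm) <- c(N * B, M)
    gx <- gm %*% t(Wv); dim(gx) <- c(N, B, C); gx <- aperm(gx, c(1, 3, 2))
    gW <- t(xm) %*% gm
    out <- list(gx, gW)
    if (!is.null(b)) out[[3]] <- array(colSums(gm), dim = dim(b$value))
    out
  })
}

# ---- convolution ----

op_conv2d <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L),
                      groups = 1L) {
  xv <- x$value; wv <- w$value
  xd <- as.integer(dim(xv)); wd <- as.integer(dim(wv))
  bias <- if (is.null(b)) numeric(0) else as.vector(b$value)
  y <- cpp_conv2d_fwd(as.vector(xv), xd, as.vector(wv), wd, bias,
                      as.integer(stride), as.integer(pad), as.integer(groups))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_op(y, parents, function(g) {
    r <- cpp_conv2d_bwd(as.vector(xv), xd, as.vector(wv), wd, as.vector(g),
                        as.integer(stride), as.integer(pad),
                        as.integer(groups), !is.null(b))
    out <- list(r$dx, r$dw)
    if (!is.null(b)) out[[3]] <- array(r$db, dim = dim(b$value))
    out
  })
}

# ---- normalization ----

op_layernorm <- function(x, gamma, beta, dim, eps = 1e-6) {
  # normalize over margin `dim` (the channel axis), affine per channel
  xv <- x$value
  d <- dim(xv); C <- d[dim]
  perm <- c(dim, setdiff(seq_along(d), dim))
  xm <- aperm(xv, perm); dim(xm) <- c(C, prod(d) / C)
  K <- ncol(xm)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = C)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = C)
  gv <- as.vector(gamma$value); bv <- as.vector(beta$value)
  ym <- xhat * gv + bv # column recycling over channels
  y <- ym; dim(y) <- d[perm]; y <- aperm(y, order(perm))
  ad_op(y, list(x, gamma, beta), function(g) {
    gm <- aperm(g, perm); dim(gm) <- c(C, prod(d) / C)
    dgamma <- rowSums(gm * xhat)
    dbeta <- rowSums(gm)
    dxhat <- gm * gv
    t1 <- colSums(dxhat)
    t2 <- colSums(dxhat * xhat)
    dxm <- (dxhat - rep(t1 / C, each = C) - xhat * rep(t2 / C, each = C)) *
      rep(istd, each = C)
    dx <- dxm; dim(dx) <- d[perm]; dx <- aperm(dx, order(perm))
    list(dx, array(dgamma, dim = dim(gamma$value)),
         array(dbeta, dim = dim(beta$value)))
  })
}

# ---- softmax over rows of (r, c, B) slices, with optional fixed mask ----

op_softmax_rows <- function(x, mask = NULL) {
  xv <- x$value
  d <- dim(xv)
  xa <- xv
  if (!is.null(mask)) xa[!mask] <- -Inf
  slice <- function(a, j) matrix(a[, j, ], d[1], d[3])
  mx <- slice(xa, 1L)
  if (d[2] > 1L) for (j in 2:d[2]) mx <- pmax(mx, slice(xa, j))
  e <- array(0, d)
  s <- matrix(0, d[1], d[3])
  for (j in seq_len(d[2])) {
    ej <- exp(slice(xa, j) - mx)
    e[, j, ] <- ej
    s <- s + ej
  }
  y <- e
  for (j in seq_len(d[2])) y[, j, ] <- slice(e, j) / s
  ad_op(y, list(x), function(g) {
    dot <- matrix(0, d[1], d[3])
    for (j in seq_len(d[2])) dot <- dot + slice(g, j) * slice(y, j)
    dx <- array(0, d)
    for (j in seq_len(d[2])) dx[, j, ] <- slice(y, j) * (slice(g, j) - dot)
    list(dx)
  })
}

# ---- l2 normalization of token-matrix columns (channel vectors) ----

op_l2norm_cols <- function(x, eps = 1e-12) {
  xv <- x$value
  d <- dim(xv)
  nrm <- sqrt(colSums(xv^2, dims = 1) + eps)
  dim(nrm) <- d[2:3]
  y <- xv / expand_front(nrm, d[1])
  ad_op(y, list(x), function(g) {
    dot <- colSums(g * y, dims = 1)
    dim(dot) <- d[2:3]
    list((g - y * expand_front(dot, d[1])) / expand_front(nrm, d[1]))
  })
}

# ---- layout conversions ----

op_to_tokens <- function(x) {
  xv <- x$value
  d <- dim(xv) # (H, W, C, B)
  y <- aperm(xv, c(2, 1, 3, 4)); dim(y) <- c(d[1] * d[2], d[3], d[4])
  ad_op(y, list(x), function(g) {
    dim(g) <- c(d[2], d[1], d[3], d[4])
    list(aperm(g, c(2, 1, 3, 4)))
  })
}

op_to_grid <- function(x, H, W) {
  xv <- x$value
  d <- dim(xv) # (N, C, B)
  y <- xv; dim(y) <- c(W, H, d[2], d[3]); y <- aperm(y, c(2, 1, 3, 4))
  ad_op(y, list(x), function(g) {
    g <- aperm(g, c(2, 1, 3, 4)); dim(g) <- d
    list(g)
  })
}

op_split_heads <- function(x, heads) {
  # (N, C, B) -> (N, C/heads, heads*B); head h of sample b at slice h+(b-1)*heads
  xv <- x$value
  d <- dim(xv); dh <- d[2] / heads
  y <- xv; dim(y) <- c(d[1], dh, heads * d[3])
  ad_op(y, list(x), function(g) { dim(g) <- d; list(g) })
}

op_merge_heads <- function(x, heads) {
  xv <- x$value
  d <- dim(xv) # (N, dh, heads*B)
  y <- xv; dim(y) <- c(d[1], d[2] * heads, d[3] / heads)
  ad_op(y, list(x), function(g) { dim(g) <- d; list(g) })
}

# ---- channel concat / slice / shuffle (grid layout, channel dim = 3) ----

op_concat_channels <- function(a, b) {
  av <- a$value; bv <- b$value
  da <- dim(av); db_ <- dim(bv)
  y <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
  y[, , seq_len(da[3]), ] <- av
  y[, , da[3] + seq_len(db_[3]), ] <- bv
  ad_op(y, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db_[3]), , drop = FALSE])
  })
}

op_index_channels <- function(x, idx) {
  xv <- x$value
  d <- dim(xv)
  y <- xv[, , idx, , drop = FALSE]
  ad_op(y, list(x), function(g) {
    gx <- array(0, d)
    gx[, , idx, ] <- gx[, , idx, , drop = FALSE] + g
    list(gx)
  })
}

op_channel_shuffle <- function(x, groups) {
  d <- dim(x$value); C <- d[3]
  # output channel -> input channel: interleave the `groups` contiguous blocks
  idx <- as.vector(matrix(seq_len(C), nrow = groups, byrow = TRUE))
  inv <- order(idx)
  y <- x$value[, , idx, , drop = FALSE]
  ad_op(y, list(x), function(g) list(g[, , inv, , drop = FALSE]))
}

# ---- pooling / resampling ----

op_global_avgpool <- function(x) {
  xv <- x$value
  d <- dim(xv)
  y <- colSums(xv, dims = 2) / (d[1] * d[2]) # (C, B)
  dim(y) <- d[3:4]
  ad_op(y, list(x), function(g) {
    list(expand_grid_cb(g / (d[1] * d[2]), d[1], d[2]))
  })
}

op_gate_channels <- function(x, gate) {
  # x: (H, W, C, B); gate: (C, B)
  xv <- x$value; gv <- gate$value
  d <- dim(xv)
  ge <- expand_grid_cb(gv, d[1], d[2])
  ad_op(xv * ge, list(x, gate), function(g) {
    dg <- colSums(g * xv, dims = 2); dim(dg) <- d[3:4]
    list(g * ge, dg)
  })
}

op_resample <- function(x, Mh, Mw) {
  # y[a,b,c,d] = sum_{h,w} Mh[a,h] Mw[b,w] x[h,w,c,d]
  xv <- x$value
  d <- dim(xv)
  H2 <- nrow(Mh); W2 <- nrow(Mw)
  contract <- function(z, A, B_) {
    dz <- dim(z)
    zm <- z; dim(zm) <- c(dz[1], prod(dz[-1]))
    zm <- A %*% zm; dim(zm) <- c(nrow(A), dz[-1])
    zm <- aperm(zm, c(2, 1, 3, 4))
    dz2 <- dim(zm); dim(zm) <- c(dz2[1], prod(dz2[-1]))
    zm <- B_ %*% zm; dim(zm) <- c(nrow(B_), dz2[-1])
    aperm(zm, c(2, 1, 3, 4))
  }
  y <- contract(xv, Mh, Mw)
  ad_op(y, list(x), function(g) list(contract(g, t(Mh), t(Mw))))
}

interp_matrix <- function(n_out, n_in) {
  # bilinear interpolation weights, align_corners = FALSE convention
  M <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * s - 0.5
    lo <- floor(src)
    f <- src - lo
    i0 <- min(max(lo + 1, 1), n_in)
    i1 <- min(max(lo + 2, 1), n_in)
    M[i, i0] <- M[i, i0] + (1 - f)
    M[i, i1] <- M[i, i1] + f
  }
  M
}

avgpool_matrix <- function(n_out, n_in) {
  # adaptive average pooling bins (contiguous, floor/ceil boundaries)
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- floor((i - 1) * n_in / n_out) + 1
    b <- ceiling(i * n_in / n_out)
    M[i, a:b] <- 1 / (b - a + 1)
  }
  M
}

# ---- pixel shuffle (patch expanding rearrangement) ----

pixel_shuffle_index <- function(H, W, C, r) {
  # output (rH, rW, C/r^2); returns in-slice index vector: out_flat = in_flat[idx]
  C2 <- C / (r * r)
  Ho <- H * r; Wo <- W * r
  ho <- rep(seq_len(Ho), times = Wo * C2)
  wo <- rep(rep(seq_len(Wo), each = Ho), times = C2)
  co <- rep(seq_len(C2), each = Ho * Wo)
  h <- (ho - 1L) %/% r + 1L; dh <- (ho - 1L) %% r
  w <- (wo - 1L) %/% r + 1L; dw <- (wo - 1L) %% r
  ci <- (co - 1L) * r * r + dh * r + dw + 1L
  h + H * (w - 1L) + H * W * (ci - 1L)
}

op_pixel_shuffle <- function(x, r, idx = NULL) {
  xv <- x$value
  d <- dim(xv)
  if (is.null(idx)) idx <- pixel_shuffle_index(d[1], d[2], d[3], r)
  inv <- integer(length(idx)); inv[idx] <- seq_along(idx)
  xm <- xv; dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  y <- xm[idx, , drop = FALSE]
  dim(y) <- c(d[1] * r, d[2] * r, d[3] / (r * r), d[4])
  ad_op(y, list(x), function(g) {
    gm <- g; dim(gm) <- c(length(idx), d[4])
    gx <- gm[inv, , drop = FALSE]; dim(gx) <- d
    list(gx)
  })
}

# ---- reductions ----

op_token_mean <- function(x) {
  # (N, C, B) -> (C, B)
  xv <- x$value
  d <- dim(xv)
  y <- colSums(xv, dims = 1) / d[1]; dim(y) <- d[2:3]
  ad_op(y, list(x), function(g) list(expand_front(g, d[1]) / d[1]))
}

op_reshape <- function(x, dims) {
  d <- dim(x$value)
  y <- x$value; dim(y) <- dims
  ad_op(y, list(x), function(g) { dim(g) <- d; list(g) })
}

op_head_scale <- function(x, logtau, heads, mode = c("div", "mul")) {
  # x: (r, c, heads*B), slice i belongs to head ((i-1) %% heads) + 1;
  # scales each slice by exp(+-logtau[head]) with gradient to logtau
  mode <- match.arg(mode)
  xv <- x$value
  d <- dim(xv)
  h_of <- ((seq_len(d[3]) - 1L) %% heads) + 1L
  s <- exp(if (mode == "div") -as.vector(logtau$value) else as.vector(logtau$value))
  sv <- s[h_of]
  y <- xv * rep(sv, each = d[1] * d[2])
  ad_op(y, list(x, logtau), function(g) {
    gy <- g * y
    per_slice <- colSums(gy, dims = 2)
    dlt <- vapply(seq_len(heads), function(h) sum(per_slice[h_of == h]),
                  numeric(1))
    if (mode == "div") dlt <- -dlt
    list(g * rep(sv, each = d[1] * d[2]), array(dlt, dim = dim(logtau$value)))
  })
}

op_weighted_sum <- function(xs, alpha) {
  # sum_i alpha[i] * xs[[i]] with learnable weights alpha
  av <- as.vector(alpha$value)
  vals <- lapply(xs, function(x) x$value)
  y <- av[1] * vals[[1]]
  for (i in seq_along(xs)[-1]) y <- y + av[i] * vals[[i]]
  ad_op(y, c(xs, list(alpha)), function(g) {
    out <- lapply(seq_along(xs), function(i) g * av[i])
    out[[length(xs) + 1L]] <-
      array(vapply(vals, function(v) sum(g * v), numeric(1)),
            dim = dim(alpha$value))
    out
  })
}

op_mean_all <- function(x) {
  xv <- x$value
  ad_op(array(mean(xv), 1L), list(x),
        function(g) list(array(as.numeric(g) / length(xv), dim = dim(xv))))
}
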