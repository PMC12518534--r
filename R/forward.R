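# Forward passes through the module tree, plus the pure functional forms of
# the attention primitives (useful on their own and as test oracles for the
# module versions).

ln_grid <- function(m, x) op_layernorm(x, m$gamma, m$beta, 3L)
ln_tok <- function(m, x) op_layernorm(x, m$gamma, m$beta, 2L)

fwd_conv <- function(m, x) {
  op_conv2d(x, m$w, m$b, m$meta$stride, m$meta$pad, m$meta$groups)
}

fwd_linear <- function(m, x) op_token_linear(x, m$w, m$b)

# row-wise top-k threshold per slice of a (r, c, S) array; ties at the
# k-th largest value are kept (>= comparison). `sorted` optionally carries
# the descending row sort (dims (c, r, S)) so several k share one sort.
topk_mask_slices <- function(Sv, k, sorted = NULL) {
  d <- dim(Sv)
  if (is.null(sorted)) {
    sorted <- apply(Sv, c(1, 3), sort.int, decreasing = TRUE, method = "quick")
  }
  th <- matrix(sorted[k, , ], d[1], d[3])
  Sv >= expand_mid(th, d[2])
}

fwd_xca <- function(m, tok) {
  heads <- m$meta$heads
  q <- op_split_heads(fwd_linear(m$q, tok), heads)
  k <- op_split_heads(fwd_linear(m$k, tok), heads)
  v <- op_split_heads(fwd_linear(m$v, tok), heads)
  qn <- op_l2norm_cols(q)
  kn <- op_l2norm_cols(k)
  S <- op_head_scale(op_bmm(qn, kn, ta = TRUE), m$logtau, heads, "div")
  A <- op_softmax_rows(S) # rows index output channels; weights sum to 1
  out <- op_bmm(v, A, tb = TRUE)
  fwd_linear(m$proj, op_merge_heads(out, heads))
}

fwd_tksa <- function(m, tok) {
  heads <- m$meta$heads
  q <- op_split_heads(fwd_linear(m$q, tok), heads)
  k <- op_split_heads(fwd_linear(m$k, tok), heads)
  v <- op_split_heads(fwd_linear(m$v, tok), heads)
  S <- op_head_scale(op_bmm(q, k, ta = TRUE), m$logtau, heads, "mul")
  sorted <- apply(S$value, c(1, 3), sort.int, decreasing = TRUE,
                  method = "quick")
  branches <- lapply(m$meta$ks, function(ki) {
    mask <- topk_mask_slices(S$value, ki, sorted)
    A <- op_softmax_rows(S, mask)
    op_bmm(v, A, tb = TRUE)
  })
  out <- op_weighted_sum(branches, m$alpha)
  fwd_linear(m$proj, op_merge_heads(out, heads))
}

fwd_mixffn <- function(m, tok) {
  hw <- m$meta$hw
  h1 <- fwd_linear(m$fc1, tok)
  g <- op_to_grid(h1, hw[1], hw[2])
  d <- op_to_tokens(fwd_conv(m$dw, g))
  h <- op_gelu(ln_tok(m$ln, op_add(d, h1)))
  fwd_linear(m$fc2, h)
}

fwd_casa <- function(m, x) {
  hw <- m$meta$hw
  tok <- op_to_tokens(x)
  att <- function(a, t) if (a$type == "xca") fwd_xca(a, t) else fwd_tksa(a, t)
  if (m$meta$order == "parallel") {
    both <- op_const_mul(op_add(att(m$att1, ln_tok(m$ln1, tok)),
                                att(m$att2, ln_tok(m$ln3, tok))), 0.5)
    tok <- op_add(tok, both)
    tok <- op_add(tok, fwd_mixffn(m$ffn1, ln_tok(m$ln2, tok)))
  } else {
    tok <- op_add(tok, att(m$att1, ln_tok(m$ln1, tok)))
    tok <- op_add(tok, fwd_mixffn(m$ffn1, ln_tok(m$ln2, tok)))
    if (!is.null(m$att2)) {
      tok <- op_add(tok, att(m$att2, ln_tok(m$ln3, tok)))
      tok <- op_add(tok, fwd_mixffn(m$ffn2, ln_tok(m$ln4, tok)))
    }
  }
  op_to_grid(tok, hw[1], hw[2])
}

fwd_conv_block <- function(m, x) {
  op_add(x, fwd_conv(m$c2, op_gelu(fwd_conv(m$c1, ln_grid(m$ln, x)))))
}

cpca_gate <- function(m, x) {
  pooled <- op_reshape(op_global_avgpool(x), c(1L, m$meta$C, dim(x$value)[4]))
  h <- op_gelu(fwd_linear(m$ca_fc1, pooled))
  op_reshape(op_sigmoid(fwd_linear(m$ca_fc2, h)),
             c(m$meta$C, dim(x$value)[4]))
}

fwd_cpca <- function(m, x) {
  gate <- cpca_gate(m, x)
  xg <- op_gate_channels(x, gate)
  s <- NULL
  for (pair in m$strips) {
    y <- fwd_conv(pair$b, fwd_conv(pair$a, xg))
    s <- if (is.null(s)) y else op_add(s, y)
  }
  a <- fwd_conv(m$mixer, s)
  op_add(x, op_mul(a, xg))
}

fwd_stem <- function(m, x) ln_grid(m$ln, fwd_conv(m$conv, x))
fwd_down <- function(m, x) ln_grid(m$ln, fwd_conv(m$conv, x))

fwd_patch_expand <- function(m, x) {
  op_pixel_shuffle(fwd_conv(m$conv, x), 2L, m$meta$idx)
}

fwd_scsa <- function(m, x) {
  D <- m$meta$D
  ng <- length(m$meta$kernels)
  Cg <- D %/% ng
  feats <- NULL
  for (g in seq_len(ng)) {
    idx <- (g - 1L) * Cg + seq_len(Cg)
    xg <- op_index_channels(x, idx)
    y <- fwd_conv(m$smsa[[g]]$b, fwd_conv(m$smsa[[g]]$a, xg))
    feats <- if (is.null(feats)) y else op_concat_channels(feats, y)
  }
  # the shuffle mixes the gate features across groups; the identity path is
  # untouched so saturated gates reduce the block to the identity
  feats <- op_channel_shuffle(feats, m$meta$groups)
  x1 <- op_mul(x, op_sigmoid(feats))
  pooled <- op_to_tokens(op_resample(x1, m$meta$Ph, m$meta$Pw))
  heads <- m$meta$heads
  q <- op_split_heads(fwd_linear(m$q, pooled), heads)
  k <- op_split_heads(fwd_linear(m$k, pooled), heads)
  v <- op_split_heads(fwd_linear(m$v, pooled), heads)
  S <- op_const_mul(op_bmm(q, k, ta = TRUE), 1 / sqrt(D / heads))
  out <- op_merge_heads(op_bmm(v, op_softmax_rows(S), tb = TRUE), heads)
  gate <- op_sigmoid(op_token_mean(out))
  op_gate_channels(x1, gate)
}

fwd_liteffn <- function(m, x) {
  fwd_conv(m$c2, op_gelu(fwd_conv(m$dw, fwd_conv(m$c1, x))))
}

fwd_sscf <- function(m, x1, x2) {
  xc <- if (m$meta$aggregation == "concat") op_concat_channels(x1, x2)
        else op_add(x1, x2)
  if (m$meta$main_module == "scsa_block") {
    xs <- op_add(xc, op_scale_dim(fwd_scsa(m$scsa, ln_grid(m$ln_a, xc)),
                                  m$gamma1, 3L))
    xf <- op_add(xs, op_scale_dim(fwd_liteffn(m$liteffn, ln_grid(m$ln_b, xs)),
                                  m$gamma2, 3L))
  } else {
    xf <- fwd_scsa(m$scsa, xc)
  }
  if (m$meta$aggregation != "concat") return(xf)
  if (m$meta$compression == "dwconv") {
    fwd_conv(m$comp_pw, fwd_conv(m$comp_dw, xf))
  } else {
    fwd_conv(m$comp_pw, xf)
  }
}

fwd_plain_fusion <- function(m, x1, x2) {
  fwd_conv(m$comp_pw, op_concat_channels(x1, x2))
}

fwd_head <- function(m, x) {
  op_resample(fwd_conv(m$conv, x), m$meta$Mh, m$meta$Mw)
}

fwd_unit <- function(m, x) {
  switch(m$type,
         casa = fwd_casa(m, x),
         conv_block = fwd_conv_block(m, x),
         cpca = fwd_cpca(m, x),
         stop("no forward for unit type ", m$type))
}

#' Run the encoder, returning the multi-scale feature pyramid
#'
#' @param model a built model with allocated weights.
#' @param x input array `(H, W, C_in, B)` (a grayscale `(H, W)` matrix or
#'   `(H, W, C_in)` array is promoted).
#' @return list of feature arrays at scales 1/4, 1/8, 1/16 of the input
#'   (or the configured pyramid), each `(H_s, W_s, C_s, B)`.
#' @export
encoder_forward <- function(model, x) {
  x <- promote_input(model$cfg, x)
  ad_no_grad({
    feats <- encoder_pass(model, ad_tensor(x))
    lapply(feats, ad_value)
  })
}

promote_input <- function(cfg, x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) dim(x) <- c(dim(x) %||% length(x), 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[1] != cfg$img_size || d[2] != cfg$img_size) {
    stop("input spatial size ", d[1], "x", d[2], " does not match the ",
         "configured img_size ", cfg$img_size, call. = FALSE)
  }
  if (d[3] != cfg$in_channels) {
    stop("input has ", d[3], " channels, model expects ", cfg$in_channels,
         call. = FALSE)
  }
  x
}

encoder_pass <- function(model, xt) {
  z <- fwd_stem(model$stem, xt)
  feats <- list()
  for (s in seq_along(model$stages)) {
    if (s > 1L) z <- fwd_down(model$downs[[s - 1L]], z)
    for (blk in model$stages[[s]]) z <- fwd_unit(blk, z)
    feats[[s]] <- z
  }
  feats
}

model_forward_tensor <- function(model, xt) {
  feats <- encoder_pass(model, xt)
  ns <- length(feats)
  z <- feats[[ns]]
  for (blk in model$bottleneck) z <- fwd_unit(blk, z)
  for (i in seq_along(model$decoder)) {
    st <- model$decoder[[i]]
    z <- fwd_patch_expand(st$expand, z)
    if (!is.null(st$adapt)) z <- fwd_conv(st$adapt, z)
    skip <- feats[[ns - i]]
    z <- if (st$fuse$type == "sscf") fwd_sscf(st$fuse, skip, z)
         else fwd_plain_fusion(st$fuse, skip, z)
    for (blk in st$blocks) z <- fwd_unit(blk, z)
  }
  fwd_head(model$head, z)
}

#' Full forward pass to segmentation logits
#'
#' @param model a built model with allocated weights.
#' @param x input array `(H, W, C_in, B)`; `H = W = img_size`.
#' @return logits array `(H, W, num_classes, B)` at the input resolution.
#' @export
dcf_forward <- function(model, x) {
  x <- promote_input(model$cfg, x)
  ad_no_grad(ad_value(model_forward_tensor(model, ad_tensor(x))))
}

#' Predict integer label masks
#'
#' @inheritParams dcf_forward
#' @return integer array `(H, W, B)` of argmax class indices in
#'   `0..num_classes-1`.
#' @export
predict_masks <- function(model, x) {
  logits <- dcf_forward(model, x)
  d <- dim(logits)
  am <- apply(logits, c(1, 2, 4), which.max) - 1L
  array(as.integer(am), d[c(1, 2, 4)])
}

# ---- pure functional attention primitives ----------------------------------

#' Cross-covariance attention on a single token matrix triple
#'
#' Computes `V %*% Softmax(K^T Q / tau)` with the query and key channel
#' columns l2-normalized first, so every entry of the `d x d`
#' cross-covariance matrix lies in `(-1, 1)`. The softmax normalizes over
#' the key-channel axis: each output channel's mixture weights over input
#' channels sum to one.
#'
#' @param Q,K,V numeric `N x d` token matrices of identical shape.
#' @param tau positive temperature.
#' @return `N x d` output token matrix.
#' @export
xca_attention <- function(Q, K, V, tau = 1) {
  if (!all(dim(Q) == dim(K)) || !all(dim(Q) == dim(V))) {
    stop("xca_attention: Q, K, V must share the same N x d shape", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0) {
    stop("xca_attention: tau must be a positive scalar", call. = FALSE)
  }
  nq <- sqrt(colSums(Q^2) + 1e-12)
  nk <- sqrt(colSums(K^2) + 1e-12)
  Qn <- sweep(Q, 2, nq, "/")
  Kn <- sweep(K, 2, nk, "/")
  S <- t(Qn) %*% Kn / tau # rows index output (query) channels
  A <- softmax_rows_matrix(S)
  V %*% t(A)
}

softmax_rows_matrix <- function(S) {
  m <- apply(S, 1, max)
  e <- exp(S - m)
  e[S == -Inf] <- 0
  e / rowSums(e)
}

#' Top-k sparsification mask
#'
#' Per row, entries greater than or equal to the k-th largest row value are
#' kept; all others are replaced by `-Inf` so they vanish under a subsequent
#' softmax. Ties at the threshold are all kept.
#'
#' @param S numeric matrix.
#' @param k number of entries to keep per row, `1 <= k <= ncol(S)`.
#' @return matrix of the same shape with suppressed entries at `-Inf`.
#' @export
topk_mask <- function(S, k) {
  if (k < 1 || k > ncol(S)) {
    stop("topk_mask: k must be between 1 and the row length ", ncol(S),
         call. = FALSE)
  }
  th <- apply(S, 1, function(r) sort(r, decreasing = TRUE)[k])
  out <- S
  out[S < th] <- -Inf
  out
}

#' Top-k sparse attention (functional form)
#'
#' The transposed-attention similarity `S = (Q^T K) * tau` is computed per
#' head from `Q = K = V = X`, sparsified with [topk_mask()] at
#' `k_i = max(1, round(f_i * C_head))` for each configured fraction,
#' softmax-normalized row-wise, applied to `V`, and the branches combined
#' with the configured branch weights.
#'
#' @param X numeric `N x C` token matrix; `C` divisible by the head count.
#' @param cfg a [casa_config()] providing heads, fractions, temperature and
#'   branch weights.
#' @return `N x C` output token matrix.
#' @export
tksa_attention <- function(X, cfg = casa_config()) {
  C <- ncol(X)
  heads <- cfg$num_heads
  if (C %% heads != 0) {
    stop("tksa_attention: C not divisible by num_heads", call. = FALSE)
  }
  dh <- C %/% heads
  ks <- pmax(1L, as.integer(round(cfg$k_fractions * dh)))
  if (any(round(cfg$k_fractions * dh) < 1)) {
    stop("tksa_attention: a k_fraction rounds to zero channels", call. = FALSE)
  }
  alpha <- rep(cfg$branch_weight_init, length.out = length(ks))
  out <- matrix(0, nrow(X), C)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    Xh <- X[, cols, drop = FALSE]
    S <- (t(Xh) %*% Xh) * cfg$temperature_init
    acc <- matrix(0, nrow(X), dh)
    for (i in seq_along(ks)) {
      A <- softmax_rows_matrix(topk_mask(S, ks[i]))
      acc <- acc + alpha[i] * (Xh %*% t(A))
    }
    out[, cols] <- acc
  }
  out
}

#' Concatenate two feature maps along channels
#'
#' @param x1,x2 arrays `(H, W, C, B)` with identical batch and spatial dims.
#' @return array `(H, W, C1 + C2, B)` with `x1`'s channels first.
#' @export
concat_features <- function(x1, x2) {
  d1 <- dim(x1); d2 <- dim(x2)
  if (!all(d1[c(1, 2, 4)] == d2[c(1, 2, 4)])) {
    stop("concat_features: spatial/batch dimensions disagree", call. = FALSE)
  }
  y <- array(0, c(d1[1], d1[2], d1[3] + d2[3], d1[4]))
  y[, , seq_len(d1[3]), ] <- x1
  y[, , d1[3] + seq_len(d2[3]), ] <- x2
  y
}
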