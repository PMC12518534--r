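# Layer and block constructors. A module is a named list with a `type`
# field, parameter tensors (environments), child modules, and a `meta` list
# that records geometry and the exact multiply-accumulate (MAC) count of the
# layer at its build-time spatial size. With `alloc = FALSE` parameters are
# shape-only descriptors, so model budgets can be computed without touching
# memory for weights.

param_new <- function(dims, init = "zeros", alloc = TRUE, sd = NULL, val = NULL) {
  dims <- as.integer(dims)
  if (!alloc) {
    return(structure(list(dims = dims, n = prod(dims)), class = "dcf_paramspec"))
  }
  n <- prod(dims)
  v <- switch(init,
    zeros = rep(0, n),
    ones = rep(1, n),
    const = rep(val, n),
    trunc_normal = pmin(pmax(stats::rnorm(n, 0, 0.02), -0.04), 0.04),
    normal = stats::rnorm(n, 0, sd),
    stop("unknown init: ", init)
  )
  ad_tensor(array(v, dims), param = TRUE)
}

is_param <- function(x) {
  is_tensor(x) && isTRUE(x$param) || inherits(x, "dcf_paramspec")
}

is_module <- function(x) is.list(x) && !is.null(x$type) && !inherits(x, "dcf_paramspec")

# depth-first walk over all parameters (fn(path, param)), descending into
# arbitrarily nested plain lists (stage lists, block lists, ...)
walk_params <- function(mod, fn, path = "") {
  descend <- function(el, p) {
    if (is_param(el)) {
      fn(p, el)
    } else if (is_module(el)) {
      walk_params(el, fn, p)
    } else if (is.list(el)) {
      nms <- names(el) %||% rep("", length(el))
      for (i in seq_along(el)) {
        tag <- if (nzchar(nms[i])) paste0(p, "/", nms[i])
               else paste0(p, "[", i, "]")
        descend(el[[i]], tag)
      }
    }
  }
  for (nm in setdiff(names(mod), c("meta", "cfg"))) {
    descend(mod[[nm]], paste0(path, "/", nm))
  }
}

walk_modules <- function(mod, fn) {
  fn(mod)
  descend <- function(el) {
    if (is_module(el)) {
      walk_modules(el, fn)
    } else if (is.list(el) && !is_param(el)) {
      for (el2 in el) descend(el2)
    }
  }
  for (nm in setdiff(names(mod), c("meta", "cfg"))) descend(mod[[nm]])
}

conv_out_hw <- function(hw, k, stride, pad) {
  (hw + 2L * pad - k) %/% stride + 1L
}

nn_conv <- function(cin, cout, k, hw, stride = c(1L, 1L), pad = c(0L, 0L),
                    groups = 1L, bias = TRUE, alloc = TRUE) {
  k <- rep(as.integer(k), length.out = 2)
  stride <- rep(as.integer(stride), length.out = 2)
  pad <- rep(as.integer(pad), length.out = 2)
  fan_in <- prod(k) * cin / groups
  out_hw <- conv_out_hw(hw, k, stride, pad)
  list(
    type = "conv",
    w = param_new(c(k, cin / groups, cout), "normal", alloc, sd = sqrt(2 / fan_in)),
    b = if (bias) param_new(cout, "zeros", alloc),
    meta = list(stride = stride, pad = pad, groups = groups,
                hw_in = hw, hw_out = out_hw,
                macs = prod(out_hw) * cout * prod(k) * cin / groups)
  )
}

nn_linear <- function(cin, cout, n_tokens, bias = TRUE, alloc = TRUE) {
  list(
    type = "linear",
    w = param_new(c(cin, cout), "trunc_normal", alloc),
    b = if (bias) param_new(cout, "zeros", alloc),
    meta = list(macs = n_tokens * cin * cout)
  )
}

nn_layernorm <- function(C, alloc = TRUE) {
  list(type = "layernorm",
       gamma = param_new(C, "ones", alloc),
       beta = param_new(C, "zeros", alloc),
       meta = list(macs = 0))
}

# ---- attention blocks -------------------------------------------------------

nn_xca <- function(C, heads, N, temperature_init = 1, alloc = TRUE) {
  dh <- C / heads
  list(
    type = "xca",
    q = nn_linear(C, C, N, alloc = alloc),
    k = nn_linear(C, C, N, alloc = alloc),
    v = nn_linear(C, C, N, alloc = alloc),
    proj = nn_linear(C, C, N, alloc = alloc),
    logtau = param_new(heads, "const", alloc, val = log(temperature_init)),
    meta = list(heads = heads, N = N, C = C,
                macs = 2 * N * C * dh) # the two d x d attention products
  )
}

nn_tksa <- function(C, heads, k_fractions, N, temperature_init = 1,
                    branch_weight_init = 1, alloc = TRUE) {
  dh <- C / heads
  ks <- pmax(1L, as.integer(round(k_fractions * dh)))
  list(
    type = "tksa",
    q = nn_linear(C, C, N, alloc = alloc),
    k = nn_linear(C, C, N, alloc = alloc),
    v = nn_linear(C, C, N, alloc = alloc),
    proj = nn_linear(C, C, N, alloc = alloc),
    logtau = param_new(heads, "const", alloc, val = log(temperature_init)),
    alpha = param_new(length(k_fractions), "const", alloc,
                      val = branch_weight_init),
    meta = list(heads = heads, N = N, C = C, ks = ks,
                k_fractions = k_fractions,
                macs = (1 + length(ks)) * N * C * dh)
  )
}

nn_mixffn <- function(C, expansion, hw, alloc = TRUE) {
  E <- C * expansion
  N <- prod(hw)
  list(
    type = "mixffn",
    fc1 = nn_linear(C, E, N, alloc = alloc),
    dw = nn_conv(E, E, 3, hw, pad = c(1L, 1L), groups = E, alloc = alloc),
    ln = nn_layernorm(E, alloc),
    fc2 = nn_linear(E, C, N, alloc = alloc),
    meta = list(hw = hw, macs = 0)
  )
}

#' Construct a CASA decoder block
#'
#' Channel-Adaptive Sparse Attention: a four-stage residual cascade
#' LN-XCA, LN-MixFFN, LN-TKSA, LN-MixFFN (the channel-first ordering).
#' Alternative orderings (`sparse_pre`, `parallel`, `channel_only`,
#' `sparse_only`) are supported for ablation-style configurations.
#'
#' @param C channel count of the block.
#' @param hw spatial size `c(H, W)` of the feature map it operates on.
#' @param casa list of CASA hyperparameters, see [casa_config()].
#' @param order cascade ordering.
#' @param alloc allocate parameters (`FALSE` builds a shape-only module).
#' @return a module list.
#' @export
nn_casa <- function(C, hw, casa = casa_config(), order = "channel_pre",
                    alloc = TRUE) {
  if (C %% casa$num_heads != 0) {
    stop("casa: channels (", C, ") not divisible by num_heads (",
         casa$num_heads, ")", call. = FALSE)
  }
  dh <- C / casa$num_heads
  if (any(round(casa$k_fractions * dh) < 1)) {
    stop("casa: a k_fraction rounds to zero channels at head width ", dh,
         call. = FALSE)
  }
  N <- prod(hw)
  m <- list(type = "casa", meta = list(C = C, hw = hw, order = order, macs = 0))
  mk_ffn <- function() nn_mixffn(C, casa$ffn_expansion, hw, alloc)
  mk_xca <- function() nn_xca(C, casa$num_heads, N, casa$temperature_init, alloc)
  mk_tksa <- function() nn_tksa(C, casa$num_heads, casa$k_fractions, N,
                                casa$temperature_init,
                                casa$branch_weight_init, alloc)
  if (order %in% c("channel_pre", "sparse_pre")) {
    m$ln1 <- nn_layernorm(C, alloc); m$att1 <-
      if (order == "channel_pre") mk_xca() else mk_tksa()
    m$ln2 <- nn_layernorm(C, alloc); m$ffn1 <- mk_ffn()
    m$ln3 <- nn_layernorm(C, alloc); m$att2 <-
      if (order == "channel_pre") mk_tksa() else mk_xca()
    m$ln4 <- nn_layernorm(C, alloc); m$ffn2 <- mk_ffn()
  } else if (order == "parallel") {
    m$ln1 <- nn_layernorm(C, alloc); m$att1 <- mk_xca()
    m$ln3 <- nn_layernorm(C, alloc); m$att2 <- mk_tksa()
    m$ln2 <- nn_layernorm(C, alloc); m$ffn1 <- mk_ffn()
  } else if (order == "channel_only") {
    m$ln1 <- nn_layernorm(C, alloc); m$att1 <- mk_xca()
    m$ln2 <- nn_layernorm(C, alloc); m$ffn1 <- mk_ffn()
  } else if (order == "sparse_only") {
    m$ln1 <- nn_layernorm(C, alloc); m$att1 <- mk_tksa()
    m$ln2 <- nn_layernorm(C, alloc); m$ffn1 <- mk_ffn()
  } else {
    stop("unknown casa order: ", order, call. = FALSE)
  }
  m
}

# plain convolutional residual block (no-CASA ablation decoder unit)
nn_conv_block <- function(C, hw, alloc = TRUE) {
  list(type = "conv_block",
       ln = nn_layernorm(C, alloc),
       c1 = nn_conv(C, C, 3, hw, pad = c(1L, 1L), alloc = alloc),
       c2 = nn_conv(C, C, 3, hw, pad = c(1L, 1L), alloc = alloc),
       meta = list(hw = hw, macs = 0))
}

# ---- encoder units ----------------------------------------------------------

#' Construct a CPCA encoder block
#'
#' Channel-prior convolutional attention: a global-average-pool channel gate
#' (bottleneck MLP, sigmoid), followed by multi-scale depthwise strip
#' convolutions (1xk / kx1 pairs, k in 5, 7, 11, 21) and a pointwise mixer
#' producing a spatial attention map, with an outer residual connection.
#' The internals mirror the published channel-prior attention design and are
#' isolated behind this constructor.
#'
#' @inheritParams nn_casa
#' @param reduction channel reduction of the gate MLP.
#' @return a module list.
#' @export
nn_cpca <- function(C, hw, reduction = 4, alloc = TRUE) {
  Cr <- max(4L, as.integer(C %/% reduction))
  strips <- lapply(c(5L, 7L, 11L, 21L), function(k) {
    list(type = "strip_pair",
         a = nn_conv(C, C, c(1L, k), hw, pad = c(0L, (k - 1L) %/% 2L),
                     groups = C, alloc = alloc),
         b = nn_conv(C, C, c(k, 1L), hw, pad = c((k - 1L) %/% 2L, 0L),
                     groups = C, alloc = alloc),
         meta = list(macs = 0))
  })
  list(type = "cpca",
       ca_fc1 = nn_linear(C, Cr, 1, alloc = alloc),
       ca_fc2 = nn_linear(Cr, C, 1, alloc = alloc),
       strips = strips,
       mixer = nn_conv(C, C, 1, hw, alloc = alloc),
       meta = list(C = C, hw = hw, macs = 0))
}

nn_stem <- function(in_ch, C, stride, hw, alloc = TRUE) {
  conv <- if (stride == 4L) {
    nn_conv(in_ch, C, 7, hw, stride = c(4L, 4L), pad = c(3L, 3L), alloc = alloc)
  } else {
    nn_conv(in_ch, C, stride, hw, stride = c(stride, stride), alloc = alloc)
  }
  list(type = "stem", conv = conv, ln = nn_layernorm(C, alloc),
       meta = list(hw_out = conv$meta$hw_out, macs = 0))
}

nn_down <- function(cin, cout, hw, alloc = TRUE) {
  conv <- nn_conv(cin, cout, 2, hw, stride = c(2L, 2L), alloc = alloc)
  list(type = "down", conv = conv, ln = nn_layernorm(cout, alloc),
       meta = list(hw_out = conv$meta$hw_out, macs = 0))
}

#' Construct a patch-expanding upsampler
#'
#' Pointwise linear expansion to `2C` channels followed by a 2x pixel
#' rearrangement, so a `(B, 2C, H, W)` input becomes `(B, C, 2H, 2W)`:
#' channels halve while each spatial dimension doubles.
#'
#' @inheritParams nn_casa
#' @return a module list.
#' @export
nn_patch_expand <- function(C, hw, alloc = TRUE) {
  if (C %% 2L != 0L) {
    stop("patch_expand: channel count must be even, got ", C, call. = FALSE)
  }
  list(type = "patch_expand",
       conv = nn_conv(C, 2L * C, 1, hw, alloc = alloc),
       meta = list(C = C, hw = hw, hw_out = hw * 2L,
                   idx = pixel_shuffle_index(hw[1], hw[2], 2L * C, 2L),
                   macs = 0))
}

# ---- fusion blocks ----------------------------------------------------------

nn_scsa <- function(D, hw, kernels = c(3L, 5L, 7L, 9L), pcsa_heads = 4L,
                    shuffle_groups = 4L, alloc = TRUE) {
  ng <- length(kernels)
  if (D %% (2L * ng) != 0L || D %% shuffle_groups != 0L) {
    stop("scsa: channels (", D, ") must be divisible by 2*length(kernels) and ",
         "by the shuffle group count", call. = FALSE)
  }
  if (D %% pcsa_heads != 0L) {
    stop("scsa: channels not divisible by pcsa_heads", call. = FALSE)
  }
  Cg <- D %/% ng
  smsa <- lapply(kernels, function(k) {
    p <- (k - 1L) %/% 2L
    list(type = "strip_pair",
         a = nn_conv(Cg, Cg, c(k, 1L), hw, pad = c(p, 0L), groups = Cg,
                     alloc = alloc),
         b = nn_conv(Cg, Cg, c(1L, k), hw, pad = c(0L, p), groups = Cg,
                     alloc = alloc),
         meta = list(macs = 0))
  })
  ph <- min(7L, hw[1]); pw <- min(7L, hw[2])
  Np <- ph * pw
  dh <- D / pcsa_heads
  list(type = "scsa",
       smsa = smsa,
       q = nn_linear(D, D, Np, alloc = alloc),
       k = nn_linear(D, D, Np, alloc = alloc),
       v = nn_linear(D, D, Np, alloc = alloc),
       meta = list(D = D, hw = hw, kernels = kernels, heads = pcsa_heads,
                   groups = shuffle_groups,
                   Ph = avgpool_matrix(ph, hw[1]), Pw = avgpool_matrix(pw, hw[2]),
                   macs = 2 * Np * D * dh))
}

nn_liteffn <- function(D, hw, expansion = 2L, alloc = TRUE) {
  E <- D * expansion
  list(type = "liteffn",
       c1 = nn_conv(D, E, 1, hw, alloc = alloc),
       dw = nn_conv(E, E, 3, hw, pad = c(1L, 1L), groups = E, alloc = alloc),
       c2 = nn_conv(E, D, 1, hw, alloc = alloc),
       meta = list(hw = hw, macs = 0))
}

#' Construct an SSCF skip-fusion block
#'
#' Synergistic skip-connection and cross-layer fusion: encoder and decoder
#' features at the same scale are aggregated (channel concatenation by
#' default), refined by a dual-residual SCSA-Block (gamma-scaled SCSA
#' attention and Lite-FFN branches on layer-normalized input), and
#' compressed back to `C` channels (depthwise 3x3 + pointwise by default,
#' or a pure linear projection).
#'
#' @param C channel count of each input feature map.
#' @param hw spatial size `c(H, W)`.
#' @param fusion list of fusion hyperparameters, see [fusion_config()].
#' @param alloc allocate parameters.
#' @return a module list.
#' @export
nn_sscf <- function(C, hw, fusion = fusion_config(), alloc = TRUE) {
  D <- if (fusion$aggregation == "concat") 2L * C else C
  m <- list(type = "sscf",
            meta = list(C = C, D = D, hw = hw,
                        aggregation = fusion$aggregation,
                        main_module = fusion$main_module,
                        compression = fusion$compression,
                        macs = 0))
  m$scsa <- nn_scsa(D, hw, fusion$smsa_kernel_sizes, fusion$pcsa_heads,
                    fusion$group_count, alloc)
  if (fusion$main_module == "scsa_block") {
    m$ln_a <- nn_layernorm(D, alloc)
    m$gamma1 <- param_new(D, "const", alloc, val = fusion$gamma_init)
    m$ln_b <- nn_layernorm(D, alloc)
    m$liteffn <- nn_liteffn(D, hw, alloc = alloc)
    m$gamma2 <- param_new(D, "const", alloc, val = fusion$gamma_init)
  }
  if (fusion$aggregation == "concat") {
    if (fusion$compression == "dwconv") {
      m$comp_dw <- nn_conv(D, D, 3, hw, pad = c(1L, 1L), groups = D,
                           alloc = alloc)
      m$comp_pw <- nn_conv(D, C, 1, hw, alloc = alloc)
    } else {
      m$comp_pw <- nn_conv(D, C, 1, hw, alloc = alloc)
    }
  }
  m
}

nn_head <- function(C, num_classes, hw, img_size, alloc = TRUE) {
  list(type = "head",
       conv = nn_conv(C, num_classes, 1, hw, alloc = alloc),
       meta = list(hw = hw, img_size = img_size,
                   Mh = interp_matrix(img_size, hw[1]),
                   Mw = interp_matrix(img_size, hw[2]),
                   macs = 0))
}
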