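# Model configuration and assembly.
#
# Default channel widths were fixed once by a budget calibration (see
# tools/calibrate.R) so that the full model carries about 42M trainable
# parameters and about 18.5 GMACs for one 224 x 224 forward pass.

#' CASA hyperparameters
#'
#' @param num_heads attention heads for both XCA and TKSA.
#' @param temperature_init initial value of the learnable per-head
#'   temperature (stored log-parameterized).
#' @param k_fractions strictly increasing sparsity fractions in `(0, 1]`;
#'   each branch keeps `round(f * C_head)` channels per similarity row.
#' @param branch_weight_init initial value of the learnable branch weights.
#' @param ffn_expansion Mix-FFN hidden expansion ratio.
#' @return list of class `casa_config`.
#' @export
casa_config <- function(num_heads = 4L,
                        temperature_init = 1,
                        k_fractions = c(1 / 2, 2 / 3, 3 / 4, 4 / 5),
                        branch_weight_init = 1,
                        ffn_expansion = 4L) {
  if (temperature_init <= 0) stop("temperature_init must be positive", call. = FALSE)
  if (any(k_fractions <= 0) || any(k_fractions > 1)) {
    stop("k_fractions must lie in (0, 1]", call. = FALSE)
  }
  if (length(k_fractions) > 1 && any(diff(k_fractions) <= 0)) {
    stop("k_fractions must be strictly increasing", call. = FALSE)
  }
  structure(list(num_heads = as.integer(num_heads),
                 temperature_init = temperature_init,
                 k_fractions = k_fractions,
                 branch_weight_init = branch_weight_init,
                 ffn_expansion = as.integer(ffn_expansion)),
            class = "casa_config")
}

#' SSCF fusion hyperparameters
#'
#' @param gamma_init initial value of the learnable channel-wise residual
#'   scales (small, in `(0, 0.1]`).
#' @param smsa_kernel_sizes odd kernel sizes of the multi-scale depthwise
#'   strip convolutions.
#' @param pcsa_heads heads of the pooled channel self-attention.
#' @param group_count channel-shuffle group count.
#' @param aggregation `"concat"` or `"addition"`.
#' @param main_module `"scsa_block"` (dual-residual refinement) or `"scsa"`
#'   (the bare attention module).
#' @param compression `"dwconv"` (depthwise 3x3 + pointwise) or `"linear"`.
#' @return list of class `fusion_config`.
#' @export
fusion_config <- function(gamma_init = 1e-2,
                          smsa_kernel_sizes = c(3L, 5L, 7L, 9L),
                          pcsa_heads = 4L,
                          group_count = 4L,
                          aggregation = c("concat", "addition"),
                          main_module = c("scsa_block", "scsa"),
                          compression = c("dwconv", "linear")) {
  if (gamma_init <= 0 || gamma_init > 0.1) {
    stop("gamma_init must be in (0, 0.1]", call. = FALSE)
  }
  if (any(smsa_kernel_sizes %% 2L == 0L)) {
    stop("smsa_kernel_sizes must be odd", call. = FALSE)
  }
  structure(list(gamma_init = gamma_init,
                 smsa_kernel_sizes = as.integer(smsa_kernel_sizes),
                 pcsa_heads = as.integer(pcsa_heads),
                 group_count = as.integer(group_count),
                 aggregation = match.arg(aggregation),
                 main_module = match.arg(main_module),
                 compression = match.arg(compression)),
            class = "fusion_config")
}

#' Encoder stage plan
#'
#' @param channels_per_stage strictly increasing channel widths, one per
#'   encoder stage (3 or 4 stages).
#' @param blocks_per_stage CPCA blocks per stage.
#' @param stem_stride downsampling factor of the stem (first pyramid scale
#'   denominator); 4 gives the 1/4, 1/8, 1/16 pyramid.
#' @return list of class `stage_plan`.
#' @export
stage_plan <- function(channels_per_stage = c(160L, 304L, 744L),
                       blocks_per_stage = rep(3L, length(channels_per_stage)),
                       stem_stride = 4L) {
  channels_per_stage <- as.integer(channels_per_stage)
  blocks_per_stage <- as.integer(blocks_per_stage)
  if (length(channels_per_stage) != length(blocks_per_stage)) {
    stop("stage_plan: channels_per_stage and blocks_per_stage lengths differ",
         call. = FALSE)
  }
  if (length(channels_per_stage) > 1 && any(diff(channels_per_stage) <= 0)) {
    stop("stage_plan: channels must be strictly increasing across stages",
         call. = FALSE)
  }
  ns <- length(channels_per_stage)
  structure(list(channels_per_stage = channels_per_stage,
                 blocks_per_stage = blocks_per_stage,
                 stem_stride = as.integer(stem_stride),
                 scales = 1 / (stem_stride * 2^(seq_len(ns) - 1))),
            class = "stage_plan")
}

#' Full model configuration
#'
#' @param stage_plan encoder plan, see [stage_plan()].
#' @param decoder_depths CASA blocks per decoder stage (length = encoder
#'   stages - 1), ordered from the bottleneck outwards.
#' @param casa CASA hyperparameters, see [casa_config()].
#' @param fusion SSCF hyperparameters, see [fusion_config()].
#' @param num_classes classes including background.
#' @param img_size square input size, divisible by 16 (and by the deepest
#'   pyramid denominator).
#' @param in_channels input image channels (1 grayscale, 3 RGB).
#' @param casa_order decoder attention cascade ordering.
#' @param use_cpca CNN encoder (`TRUE`) or pure-transformer encoder built
#'   from CASA blocks (`FALSE`).
#' @param use_casa CASA decoder blocks (`TRUE`) or plain convolutional
#'   decoder blocks (`FALSE`).
#' @param use_sscf SSCF skip fusion (`TRUE`) or plain concatenation +
#'   pointwise compression (`FALSE`).
#' @param bottleneck_depth attention blocks at the deepest scale.
#' @return list of class `model_config`.
#' @export
model_config <- function(stage_plan = dcfnet::stage_plan(),
                         decoder_depths = NULL,
                         casa = casa_config(),
                         fusion = fusion_config(),
                         num_classes = 9L,
                         img_size = 224L,
                         in_channels = 1L,
                         casa_order = c("channel_pre", "sparse_pre", "parallel",
                                        "channel_only", "sparse_only"),
                         use_cpca = TRUE,
                         use_casa = TRUE,
                         use_sscf = TRUE,
                         bottleneck_depth = 2L) {
  casa_order <- match.arg(casa_order)
  ns <- length(stage_plan$channels_per_stage)
  if (is.null(decoder_depths)) decoder_depths <- rep(2L, ns - 1L)
  decoder_depths <- as.integer(decoder_depths)
  if (length(decoder_depths) != ns - 1L) {
    stop("model_config: decoder_depths must have length ", ns - 1L,
         " (encoder stages - 1), got ", length(decoder_depths), call. = FALSE)
  }
  if (num_classes < 1L) stop("model_config: num_classes must be positive", call. = FALSE)
  max_denom <- stage_plan$stem_stride * 2^(ns - 1L)
  if (img_size %% 16L != 0L || img_size %% max_denom != 0L) {
    stop("model_config: img_size (", img_size, ") must be divisible by 16 ",
         "and by the deepest scale denominator (", max_denom, ")", call. = FALSE)
  }
  structure(list(stage_plan = stage_plan,
                 decoder_depths = decoder_depths,
                 casa = casa, fusion = fusion,
                 num_classes = as.integer(num_classes),
                 img_size = as.integer(img_size),
                 in_channels = as.integer(in_channels),
                 casa_order = casa_order,
                 use_cpca = isTRUE(use_cpca),
                 use_casa = isTRUE(use_casa),
                 use_sscf = isTRUE(use_sscf),
                 bottleneck_depth = as.integer(bottleneck_depth)),
            class = "model_config")
}

decoder_unit <- function(cfg, C, hw, alloc) {
  if (cfg$use_casa) nn_casa(C, hw, cfg$casa, cfg$casa_order, alloc)
  else nn_conv_block(C, hw, alloc)
}

plain_fusion <- function(C, hw, alloc) {
  # no-SSCF ablation: concatenate and compress pointwise
  list(type = "plain_fusion",
       comp_pw = nn_conv(2L * C, C, 1, hw, alloc = alloc),
       meta = list(C = C, hw = hw, macs = 0))
}

#' Build a DCF-Net model
#'
#' Assembles encoder, bottleneck, skip-fusion blocks, decoder stages and
#' segmentation head according to `cfg`. With `alloc = FALSE` the model
#' carries parameter shapes only (enough for [count_parameters()] and
#' [count_flops()]) without allocating weights.
#'
#' @param cfg a [model_config()].
#' @param alloc allocate and initialize weights.
#' @return a model object (nested module list) of class `dcf_model`.
#' @export
build_model <- function(cfg, alloc = TRUE) {
  stopifnot(inherits(cfg, "model_config"))
  sp <- cfg$stage_plan
  ch <- sp$channels_per_stage
  ns <- length(ch)
  hw0 <- c(cfg$img_size, cfg$img_size)
  model <- list(type = "dcfnet", cfg = cfg, meta = list(macs = 0))

  # encoder
  model$stem <- nn_stem(cfg$in_channels, ch[1], sp$stem_stride, hw0, alloc)
  hw <- model$stem$meta$hw_out
  stages <- list(); downs <- list()
  hws <- list()
  for (s in seq_len(ns)) {
    if (s > 1L) {
      downs[[s - 1L]] <- nn_down(ch[s - 1L], ch[s], hw, alloc)
      hw <- downs[[s - 1L]]$meta$hw_out
    }
    hws[[s]] <- hw
    stages[[s]] <- lapply(seq_len(sp$blocks_per_stage[s]), function(i) {
      if (cfg$use_cpca) nn_cpca(ch[s], hw, alloc = alloc)
      else nn_casa(ch[s], hw, cfg$casa, cfg$casa_order, alloc)
    })
  }
  model$stages <- stages
  model$downs <- downs

  # bottleneck on the deepest features
  model$bottleneck <- lapply(seq_len(cfg$bottleneck_depth), function(i) {
    decoder_unit(cfg, ch[ns], hws[[ns]], alloc)
  })

  # decoder: stage i fuses with encoder stage ns - i
  dec <- list()
  C_cur <- ch[ns]; hw_cur <- hws[[ns]]
  for (i in seq_len(ns - 1L)) {
    s_skip <- ns - i
    C_skip <- ch[s_skip]
    st <- list(type = "dec_stage", meta = list(macs = 0))
    st$expand <- nn_patch_expand(C_cur, hw_cur, alloc)
    hw_cur <- st$expand$meta$hw_out
    C_half <- C_cur %/% 2L
    if (C_half != C_skip) {
      st$adapt <- nn_conv(C_half, C_skip, 1, hw_cur, alloc = alloc)
    }
    st$fuse <- if (cfg$use_sscf) nn_sscf(C_skip, hw_cur, cfg$fusion, alloc)
               else plain_fusion(C_skip, hw_cur, alloc)
    st$blocks <- lapply(seq_len(cfg$decoder_depths[i]), function(j) {
      decoder_unit(cfg, C_skip, hw_cur, alloc)
    })
    dec[[i]] <- st
    C_cur <- C_skip
  }
  model$decoder <- dec
  model$head <- nn_head(C_cur, cfg$num_classes, hw_cur, cfg$img_size, alloc)
  class(model) <- c("dcf_model", "list")
  model
}

#' Count trainable parameters
#'
#' @param model a built model (weights allocated or shape-only).
#' @return exact number of trainable scalars.
#' @export
count_parameters <- function(model) {
  total <- 0
  walk_params(model, function(path, p) {
    total <<- total + if (inherits(p, "dcf_paramspec")) p$n else length(p$value)
  })
  total
}

#' Count forward-pass FLOPs
#'
#' Per-layer multiply-accumulate count of a single-sample forward pass at
#' the model's build size, with one MAC counted as one FLOP (the convention
#' of the common profilers). Convolutions, linear layers and attention
#' matrix products are counted; normalizations, activations and
#' interpolations are not.
#'
#' @param model a built model.
#' @return FLOPs in GFLOPs.
#' @export
count_flops <- function(model) {
  total <- 0
  walk_modules(model, function(m) {
    if (!is.null(m$meta$macs)) total <<- total + m$meta$macs
  })
  total / 1e9
}

#' Count modules of a given type
#' @param model a built model.
#' @param type module type string, e.g. `"casa"`.
#' @return integer count.
#' @export
count_blocks <- function(model, type) {
  n <- 0L
  walk_modules(model, function(m) if (identical(m$type, type)) n <<- n + 1L)
  n
}

#' Collect named parameter tensors of a model
#' @param model a built model with allocated weights.
#' @return named list of parameter tensors (path -> tensor).
#' @export
model_parameters <- function(model) {
  out <- list()
  walk_params(model, function(path, p) {
    if (is_tensor(p)) out[[path]] <<- p
  })
  out
}

#' Zero accumulated gradients of all parameters
#' @param model a built model.
#' @export
zero_grad <- function(model) {
  walk_params(model, function(path, p) if (is_tensor(p)) p$grad <- NULL)
  invisible(NULL)
}

#' Save model weights and configuration to a single file
#'
#' @param model a built model.
#' @param path output file.
#' @param extra optional list stored alongside (e.g. training state).
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  values <- list()
  walk_params(model, function(p_, p) if (is_tensor(p)) values[[p_]] <<- p$value)
  saveRDS(list(cfg = model$cfg, values = values, extra = extra), path)
  invisible(path)
}

#' Load a model from a checkpoint file
#'
#' @param path checkpoint written by [save_checkpoint()].
#' @return list with elements `model` and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$cfg, alloc = TRUE)
  walk_params(model, function(p_, p) {
    if (is_tensor(p)) {
      v <- ck$values[[p_]]
      if (is.null(v)) stop("checkpoint missing parameter ", p_, call. = FALSE)
      p$value <- v
    }
  })
  list(model = model, extra = ck$extra)
}
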