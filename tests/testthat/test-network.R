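# Whole-network assembly: shape contracts, determinism, batching, budgets
# and the configuration design space.

test_that("default-size model forward-passes a 224 input to full-resolution
           logits", {
  set.seed(51)
  m <- build_model(model_config())
  x <- array(stats::runif(224 * 224), c(224, 224, 1, 1))
  y <- dcf_forward(m, x)
  expect_identical(dim(y), c(224L, 224L, 9L, 1L))
  expect_true(all(is.finite(y)))
})

test_that("end-to-end shape contract holds across the divisible-by-16 grid", {
  set.seed(52)
  for (s in c(96L, 160L)) {
    m <- build_model(tiny_cfg(channels = c(8L, 16L, 24L), img_size = s,
                              num_classes = 3L))
    y <- dcf_forward(m, array(stats::runif(s * s), c(s, s, 1, 1)))
    expect_identical(dim(y), c(s, s, 3L, 1L))
  }
})

test_that("forward is deterministic and batch-equivariant", {
  set.seed(53)
  m <- build_model(tiny_cfg(img_size = 32L, channels = c(8L, 16L, 24L)))
  x <- array(stats::runif(32 * 32 * 2), c(32, 32, 1, 2))
  y1 <- dcf_forward(m, x)
  y2 <- dcf_forward(m, x)
  expect_identical(y1, y2) # bitwise under fixed weights
  ya <- dcf_forward(m, x[, , , 1, drop = FALSE])
  yb <- dcf_forward(m, x[, , , 2, drop = FALSE])
  expect_equal(y1[, , , 1], ya[, , , 1], tolerance = 1e-5)
  expect_equal(y1[, , , 2], yb[, , , 1], tolerance = 1e-5)
})

test_that("gradients reach every parameter group", {
  set.seed(54)
  m <- build_model(tiny_cfg(img_size = 32L, channels = c(8L, 16L, 24L),
                            num_classes = 2L))
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  lab <- array(sample(0:1, 32 * 32, TRUE), c(32, 32, 1))
  ad_record(TRUE)
  loss <- op_seg_loss(model_forward_tensor(m, ad_tensor(x)), lab, 0.4)
  ad_backward(loss)
  ad_record(FALSE)
  gn <- vapply(model_parameters(m),
               function(p) if (is.null(p$grad)) NA_real_ else sqrt(sum(p$grad^2)),
               0)
  expect_false(anyNA(gn))
  expect_true(all(is.finite(gn)))
  expect_true(all(gn > 0))
  zero_grad(m)
})

test_that("parameter counting is exact and monotone in the module set", {
  # a lone 3x3 conv, 4 -> 8 channels with bias
  conv <- nn_conv(4L, 8L, 3L, c(8L, 8L))
  expect_identical(length(conv$w$value) + length(conv$b$value), 296L)
  cfg <- tiny_cfg()
  full <- count_parameters(build_model(cfg, alloc = FALSE))
  nosscf <- count_parameters(build_model(
    tiny_cfg(use_sscf = FALSE), alloc = FALSE))
  expect_lt(nosscf, full)
})

test_that("the structural walker counts decoder and bottleneck blocks", {
  cfg <- tiny_cfg(decoder_depths = c(3L, 3L))
  m <- build_model(cfg, alloc = FALSE)
  expect_identical(count_blocks(m, "casa"), 2L + 3L + 3L)
  m2 <- build_model(tiny_cfg(use_casa = FALSE), alloc = FALSE)
  expect_identical(count_blocks(m2, "casa"), 0L)
  expect_identical(count_blocks(m2, "conv_block"), 2L + 2L + 2L)
})

test_that("flops counting: pointwise closed form and stem scaling law", {
  pw <- nn_conv(16L, 16L, 1L, c(12L, 12L))
  expect_identical(pw$meta$macs, 12 * 12 * 16 * 16)
  stem224 <- nn_stem(1L, 8L, 4L, c(224L, 224L))
  stem448 <- nn_stem(1L, 8L, 4L, c(448L, 448L))
  expect_equal(stem448$conv$meta$macs / stem224$conv$meta$macs, 4)
})

test_that("configuration validation raises named errors", {
  expect_error(model_config(decoder_depths = c(2L, 2L, 2L)), "decoder_depths")
  expect_error(model_config(img_size = 100L), "img_size")
  expect_error(stage_plan(c(32L, 16L, 48L)), "strictly increasing")
  expect_error(casa_config(k_fractions = c(0.5, 0.5)), "strictly increasing")
  expect_error(casa_config(k_fractions = c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(casa_config(temperature_init = 0), "positive")
  expect_error(nn_casa(10L, c(4L, 4L), casa_config(num_heads = 4L)),
               "divisible")
})

test_that("every ablation-space configuration builds and forward-passes", {
  set.seed(55)
  ch <- c(16L, 32L, 48L)
  x <- array(stats::runif(64 * 64), c(64, 64, 1, 1))
  run <- function(cfg) {
    m <- build_model(cfg)
    y <- dcf_forward(m, x)
    expect_identical(dim(y), c(64L, 64L, cfg$num_classes, 1L))
    expect_true(all(is.finite(y)))
  }
  # component on/off grid (pure-transformer encoder, conv decoder, plain skips)
  run(tiny_cfg(use_cpca = FALSE))
  run(tiny_cfg(use_casa = FALSE, use_sscf = FALSE))
  run(tiny_cfg(use_casa = FALSE))
  run(tiny_cfg(use_sscf = FALSE))
  # decoder stacking
  for (dd in list(c(1L, 1L), c(2L, 1L), c(3L, 3L))) {
    run(tiny_cfg(decoder_depths = dd))
  }
})
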