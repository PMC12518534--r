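# The tape engine: analytic gradients of every operator family agree with
# central finite differences, and the whole assembled network is
# differentiable end to end.

rt <- function(...) ad_tensor(array(stats::rnorm(prod(c(...))), c(...)),
                              param = TRUE)

test_that("convolution gradients match finite differences", {
  set.seed(101)
  expect_true(fd_grad_check(
    function() list(x = rt(6, 7, 4, 2), w = rt(3, 3, 2, 6), b = rt(6)),
    function(i) op_conv2d(i$x, i$w, i$b, c(2, 1), c(1, 1), 2)))
  expect_true(fd_grad_check( # depthwise fast path
    function() list(x = rt(5, 5, 4, 2), w = rt(3, 1, 1, 4), b = rt(4)),
    function(i) op_conv2d(i$x, i$w, i$b, c(1, 1), c(1, 0), 4)))
  expect_true(fd_grad_check( # pointwise fast path
    function() list(x = rt(5, 5, 4, 2), w = rt(1, 1, 4, 3), b = rt(3)),
    function(i) op_conv2d(i$x, i$w, i$b)))
})

test_that("normalization and attention op gradients match finite differences", {
  set.seed(102)
  expect_true(fd_grad_check(
    function() list(x = rt(5, 6, 2), g = rt(6), b = rt(6)),
    function(i) op_layernorm(i$x, i$g, i$b, 2L)))
  cmat <- ad_tensor(array(sin(1:60), c(4, 5, 3)))
  mask <- array(TRUE, c(4, 5, 3)); mask[, 4:5, ] <- FALSE
  expect_true(fd_grad_check(
    function() list(x = rt(4, 5, 3)),
    function(i) op_mul(op_softmax_rows(i$x, mask), cmat)))
  cmat2 <- ad_tensor(array(sin(1:48), c(6, 4, 2)))
  expect_true(fd_grad_check(
    function() list(x = rt(6, 4, 2)),
    function(i) op_mul(op_l2norm_cols(i$x), cmat2)))
  expect_true(fd_grad_check(
    function() list(a = rt(6, 4, 3), b = rt(6, 5, 3)),
    function(i) op_bmm(i$a, i$b, ta = TRUE)))
  expect_true(fd_grad_check(
    function() list(x = rt(3, 3, 8), lt = rt(4)),
    function(i) op_head_scale(i$x, i$lt, 4, "div")))
})

test_that("resampling / rearrangement gradients match finite differences", {
  set.seed(103)
  cmat <- ad_tensor(array(sin(1:288), c(12, 4, 3, 2)))
  expect_true(fd_grad_check(
    function() list(x = rt(6, 8, 3, 2)),
    function(i) op_mul(op_resample(i$x, interp_matrix(12, 6),
                                   avgpool_matrix(4, 8)), cmat)))
  cmat2 <- ad_tensor(array(sin(1:192), c(6, 8, 2, 2)))
  expect_true(fd_grad_check(
    function() list(x = rt(3, 4, 8, 2)),
    function(i) op_mul(op_pixel_shuffle(i$x, 2), cmat2)))
})

test_that("fused segmentation loss gradient matches finite differences", {
  set.seed(104)
  lab <- array(sample(0:2, 4 * 4 * 2, replace = TRUE), c(4, 4, 2))
  expect_true(fd_grad_check(
    function() list(x = rt(4, 4, 3, 2)),
    function(i) op_seg_loss(i$x, lab, 0.4)))
})

test_that("the assembled network is differentiable end to end", {
  set.seed(105)
  # dense attention (k fraction 1) keeps the loss smooth in every weight;
  # top-k selection is piecewise constant, so finite differences are only
  # valid away from mask-threshold crossings (masked-softmax gradients are
  # checked op-level with a fixed mask above)
  cfg <- tiny_cfg(channels = c(8L, 16L, 24L), img_size = 32L,
                  num_classes = 2L,
                  casa = casa_config(k_fractions = 1))
  m <- build_model(cfg)
  # keep logits away from softmax saturation: the loss clamps log(P) at
  # 1e-12 in the forward but backpropagates the unclamped (P - Y)/N signal,
  # so finite differences are only meaningful in the smooth region
  m$head$conv$w$value <- m$head$conv$w$value * 0.02
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  lab <- array(sample(0:1, 32 * 32, replace = TRUE), c(32, 32, 1))
  ad_record(TRUE)
  loss <- op_seg_loss(model_forward_tensor(m, ad_tensor(x)), lab, 0.4)
  ad_backward(loss)
  ad_record(FALSE)
  params <- model_parameters(m)
  some <- params[sample(length(params), 8)]
  eps <- 1e-4
  for (p in some) {
    i <- sample(length(p$value), 1)
    v0 <- p$value[i]
    p$value[i] <- v0 + eps
    lp <- as.numeric(ad_value(ad_no_grad(
      op_seg_loss(model_forward_tensor(m, ad_tensor(x)), lab, 0.4))))
    p$value[i] <- v0 - eps
    lm <- as.numeric(ad_value(ad_no_grad(
      op_seg_loss(model_forward_tensor(m, ad_tensor(x)), lab, 0.4))))
    p$value[i] <- v0
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - p$grad[i]), 5e-3 * max(1, abs(num)))
  }
  zero_grad(m)
})
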