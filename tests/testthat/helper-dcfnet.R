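# Shared fixtures: all data is generated in code at test time.

tiny_cfg <- function(channels = c(16L, 32L, 48L), img_size = 64L,
                     num_classes = 4L, ...) {
  model_config(stage_plan = stage_plan(channels), img_size = img_size,
               num_classes = num_classes, ...)
}

rand_grid <- function(H, W, C, B) array(stats::rnorm(H * W * C * B),
                                        c(H, W, C, B))

# zero every parameter of a module subtree (residual-identity fixtures)
zero_module <- function(m) {
  walk_params(m, function(p_, p) if (is_tensor(p)) p$value[] <- 0)
  invisible(m)
}

set_bias <- function(layer, value) {
  layer$b$value[] <- value
  invisible(layer)
}

# reference softmax over matrix rows, written independently of the package op
ref_row_softmax <- function(S) {
  t(apply(S, 1, function(r) {
    e <- exp(r - max(r[is.finite(r)]))
    e[r == -Inf] <- 0
    e / sum(e)
  }))
}

fd_grad_check <- function(make_inputs, f, n_entries = 6, eps = 1e-5,
                          tol = 1e-4) {
  ins <- make_inputs()
  ad_record(TRUE)
  loss <- op_mean_all(f(ins))
  ad_backward(loss)
  ad_record(FALSE)
  worst <- 0
  for (nm in names(ins)) {
    t <- ins[[nm]]
    if (!is_tensor(t)) next
    ga <- t$grad
    expect_false(is.null(ga), label = paste("gradient reaches", nm))
    idx <- sample(length(t$value), min(n_entries, length(t$value)))
    for (i in idx) {
      v0 <- t$value[i]
      t$value[i] <- v0 + eps
      lp <- mean(ad_value(ad_no_grad(f(ins))))
      t$value[i] <- v0 - eps
      lm <- mean(ad_value(ad_no_grad(f(ins))))
      t$value[i] <- v0
      num <- (lp - lm) / (2 * eps)
      worst <- max(worst, abs(num - ga[i]) / max(1, abs(num)))
    }
  }
  worst < tol
}
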