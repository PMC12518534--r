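# Optimizers and the training loop: SGD with momentum (the multi-organ /
# cardiac profile) or Adam (the lesion profile), with polynomial learning
# rate decay of power 0.9, the convention of the training protocols this
# architecture family follows.

#' Training configuration
#'
#' The two dataset profiles mirror the published protocols: SGD with
#' momentum 0.9, initial learning rate 3.4e-3, weight decay 1e-4, 400
#' epochs, batch 16 and loss weight `lam = 0.4` for the multi-organ and
#' cardiac regimes; Adam with learning rate 1e-4, 100 epochs, batch 4 and
#' `lam = 0.5` for the lesion regime.
#'
#' @param optimizer `"sgd_momentum"` or `"adam"`.
#' @param lr initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 weight decay.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lam cross-entropy weight of the hybrid loss, in `[0, 1]`.
#' @param seed RNG seed for shuffling and any augmentation.
#' @param lr_power polynomial decay power (`lr * (1 - t/T)^power`).
#' @return list of class `train_config`.
#' @export
train_config <- function(optimizer = c("sgd_momentum", "adam"),
                         lr = 3.4e-3, momentum = 0.9, weight_decay = 1e-4,
                         epochs = 400L, batch_size = 16L, lam = 0.4,
                         seed = 1L, lr_power = 0.9) {
  optimizer <- match.arg(optimizer)
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]", call. = FALSE)
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  structure(list(optimizer = optimizer, lr = lr, momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lam = lam,
                 seed = as.integer(seed), lr_power = lr_power),
            class = "train_config")
}

#' Built-in training profiles
#'
#' @param name `"synapse_like"`, `"acdc_like"` (SGD profile) or
#'   `"isic_like"` (Adam profile).
#' @param ... overrides passed to [train_config()].
#' @return a [train_config()].
#' @export
train_profile <- function(name = c("synapse_like", "acdc_like", "isic_like"),
                          ...) {
  name <- match.arg(name)
  args <- switch(name,
    synapse_like = ,
    acdc_like = list(optimizer = "sgd_momentum", lr = 3.4e-3, momentum = 0.9,
                     weight_decay = 1e-4, epochs = 400L, batch_size = 16L,
                     lam = 0.4),
    isic_like = list(optimizer = "adam", lr = 1e-4, epochs = 100L,
                     batch_size = 4L, lam = 0.5, weight_decay = 0)
  )
  do.call(train_config, utils::modifyList(args, list(...)))
}

make_optimizer <- function(model, cfg) {
  params <- model_parameters(model)
  state <- lapply(params, function(p) {
    list(v = array(0, dim(p$value)), m = array(0, dim(p$value)), t = 0L)
  })
  list(params = params, state = state, cfg = cfg)
}

optimizer_step <- function(opt, lr) {
  cfg <- opt$cfg
  for (nm in names(opt$params)) {
    p <- opt$params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (cfg$weight_decay > 0) g <- g + cfg$weight_decay * p$value
    st <- opt$state[[nm]]
    if (cfg$optimizer == "sgd_momentum") {
      st$v <- cfg$momentum * st$v + g
      p$value <- p$value - lr * st$v
    } else {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      st$t <- st$t + 1L
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mh <- st$m / (1 - b1^st$t)
      vh <- st$v / (1 - b2^st$t)
      p$value <- p$value - lr * mh / (sqrt(vh) + eps)
    }
    opt$state[[nm]] <- st
  }
  opt
}

as_batch <- function(images, masks, idx) {
  S <- nrow(images[[idx[1]]])
  x <- array(0, c(S, S, 1L, length(idx)))
  y <- array(0L, c(S, S, length(idx)))
  for (j in seq_along(idx)) {
    x[, , 1L, j] <- images[[idx[j]]]
    y[, , j] <- masks[[idx[j]]]
  }
  list(x = x, y = y)
}

#' Mean foreground Dice between predicted and true masks
#'
#' @param pred,truth lists of integer masks (or single masks).
#' @param num_classes class count including background.
#' @return mean over foreground classes of the mean per-image DSC.
#' @export
mean_fg_dsc <- function(pred, truth, num_classes) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  per_class <- vapply(seq_len(num_classes - 1L), function(cls) {
    mean(vapply(seq_along(pred),
                function(i) dsc_metric(pred[[i]], truth[[i]], cls), 0))
  }, 0)
  mean(per_class)
}

#' Evaluate a model on an image/mask list
#'
#' @param model built model.
#' @param images,masks lists of matrices.
#' @param batch_size forward batch size.
#' @return list with `mean_dsc` and the predicted mask list.
#' @export
evaluate_model <- function(model, images, masks, batch_size = 8L) {
  preds <- vector("list", length(images))
  i <- 1L
  while (i <= length(images)) {
    idx <- i:min(i + batch_size - 1L, length(images))
    b <- as_batch(images, masks, idx)
    pm <- predict_masks(model, b$x)
    for (j in seq_along(idx)) preds[[idx[j]]] <- pm[, , j]
    i <- i + batch_size
  }
  list(mean_dsc = mean_fg_dsc(preds, masks, model$cfg$num_classes),
       pred = preds)
}

#' Train a model
#'
#' Minimizes the hybrid Dice + cross-entropy loss with the configured
#' optimizer and polynomial learning-rate decay. Fully seeded: two runs with
#' the same seed and data produce identical parameters.
#'
#' @param model built model (modified in place; also returned).
#' @param images,masks training data as lists of matrices.
#' @param cfg a [train_config()].
#' @param steps optional cap on total optimizer steps (overrides epochs).
#' @param val_images,val_masks optional validation data.
#' @param eval_every evaluate validation DSC every this many steps.
#' @param augment_data apply random joint flips/rotations per sample.
#' @param checkpoint_dir if set, `last.ckpt` / `best.ckpt` are written here.
#' @param log_file if set, JSON-lines log rows are appended here.
#' @param start_epoch epoch counter offset (used when resuming).
#' @param verbose print progress lines.
#' @return list with `model`, `history` (data.frame) and `val_history`.
#' @export
train_model <- function(model, images, masks, cfg,
                        steps = NULL, val_images = NULL, val_masks = NULL,
                        eval_every = NULL, augment_data = FALSE,
                        checkpoint_dir = NULL, log_file = NULL,
                        start_epoch = 0L, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  set.seed(cfg$seed)
  n <- length(images)
  bs <- min(cfg$batch_size, n)
  steps_per_epoch <- max(1L, n %/% bs)
  total <- if (is.null(steps)) cfg$epochs * steps_per_epoch else steps
  opt <- make_optimizer(model, cfg)
  hist <- list(); vhist <- list()
  best_dsc <- -Inf
  step <- 0L
  epoch <- start_epoch
  while (step < total) {
    epoch <- epoch + 1L
    perm <- sample.int(n)
    for (bi in seq_len(steps_per_epoch)) {
      if (step >= total) break
      idx <- perm[((bi - 1L) * bs + 1L):(bi * bs)]
      b <- as_batch(images, masks, idx)
      if (augment_data) {
        for (j in seq_along(idx)) {
          a <- augment(b$x[, , 1L, j], b$y[, , j])
          b$x[, , 1L, j] <- a$image
          b$y[, , j] <- a$mask
        }
      }
      lr <- cfg$lr * (1 - step / total)^cfg$lr_power
      ad_record(TRUE)
      logits <- model_forward_tensor(model, ad_tensor(b$x))
      loss <- op_seg_loss(logits, b$y, cfg$lam)
      ad_backward(loss)
      ad_record(FALSE)
      opt <- optimizer_step(opt, lr)
      zero_grad(model)
      step <- step + 1L
      row <- list(step = step, epoch = epoch, lr = lr,
                  loss = as.numeric(loss$value),
                  ce = loss$aux$ce, dice_loss = loss$aux$dice)
      hist[[length(hist) + 1L]] <- row
      if (!is.null(log_file)) {
        cat(jsonlite::toJSON(row, auto_unbox = TRUE, digits = 8), "\n",
            file = log_file, append = TRUE)
      }
      if (verbose && step %% 10L == 0L) {
        message(sprintf("step %d/%d loss %.4f", step, total, row$loss))
      }
      if (!is.null(eval_every) && step %% eval_every == 0L &&
          !is.null(val_images)) {
        ev <- evaluate_model(model, val_images, val_masks)
        vhist[[length(vhist) + 1L]] <- list(step = step,
                                            val_dsc = ev$mean_dsc)
        if (!is.null(checkpoint_dir) && ev$mean_dsc > best_dsc) {
          best_dsc <- ev$mean_dsc
          save_checkpoint(model, file.path(checkpoint_dir, "best.ckpt"),
                          extra = list(step = step, epoch = epoch,
                                       val_dsc = ev$mean_dsc))
        }
      }
    }
    if (!is.null(checkpoint_dir)) {
      save_checkpoint(model, file.path(checkpoint_dir, "last.ckpt"),
                      extra = list(step = step, epoch = epoch))
    }
  }
  list(model = model,
       history = do.call(rbind, lapply(hist, as.data.frame)),
       val_history = if (length(vhist))
         do.call(rbind, lapply(vhist, as.data.frame)))
}
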