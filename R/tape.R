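#' @useDynLib dcfnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Reverse-mode autodiff tape.
#
# Every tensor is an environment holding `value` (a numeric array) and,
# after backward(), `grad`. Operations append nodes to a global tape while
# recording is on; ad_backward() replays the tape in reverse creation order.
# Parameters are leaf tensors kept off the tape whose gradients accumulate
# across the backward sweep (zeroed explicitly between optimizer steps).

.dcf <- new.env(parent = emptyenv())
.dcf$recording <- FALSE
.dcf$tape <- NULL
.dcf$n <- 0L

#' Turn gradient recording on or off
#'
#' While recording, every tensor operation appends a node to an internal
#' tape so that [ad_backward()] can later propagate gradients. Recording
#' is off by default; inference-only forward passes should leave it off so
#' intermediate values can be garbage collected.
#'
#' @param on logical; start (`TRUE`) or stop and clear (`FALSE`) the tape.
#' @return invisibly, the previous recording state.
#' @export
ad_record <- function(on = TRUE) {
  prev <- .dcf$recording
  .dcf$recording <- isTRUE(on)
  .dcf$tape <- if (isTRUE(on)) vector("list", 8192L) else NULL
  .dcf$n <- 0L
  invisible(prev)
}

tape_push <- function(node) {
  n <- .dcf$n + 1L
  if (n > length(.dcf$tape)) {
    .dcf$tape <- c(.dcf$tape, vector("list", length(.dcf$tape)))
  }
  .dcf$tape[[n]] <- node
  .dcf$n <- n
  node
}

#' Create a tensor leaf
#'
#' @param value numeric array (a `dim` attribute is added to bare vectors).
#' @param param logical; mark as a trainable parameter.
#' @return a tensor (environment with `value`, `grad`, `param`).
#' @export
ad_tensor <- function(value, param = FALSE) {
  if (is.null(dim(value))) dim(value) <- length(value)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$param <- isTRUE(param)
  class(node) <- "dcf_tensor"
  node
}

# Internal: result node of an operation. `backward` maps the node's gradient
# to a list of parent gradients (NULL entries allowed for constants).
ad_op <- function(value, parents, backward) {
  node <- ad_tensor(value)
  if (.dcf$recording) {
    node$parents <- parents
    node$backward <- backward
    tape_push(node)
  }
  node
}

is_tensor <- function(x) inherits(x, "dcf_tensor")

#' Extract the value array of a tensor
#' @param x tensor or plain array.
#' @return numeric array.
#' @export
ad_value <- function(x) if (is_tensor(x)) x$value else x

#' Backpropagate gradients from a scalar loss
#'
#' Replays the active tape in reverse, accumulating `grad` on every tensor
#' that participated in the computation, including parameter leaves.
#'
#' @param loss scalar tensor produced while recording.
#' @export
ad_backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$value) == 1L)
  if (!.dcf$recording) stop("ad_backward() requires an active tape", call. = FALSE)
  loss$grad <- array(1, dim = dim(loss$value))
  for (i in seq.int(.dcf$n, 1L)) {
    node <- .dcf$tape[[i]]
    if (is.null(node$grad) || is.null(node$backward)) next
    gs <- node$backward(node$grad)
    ps <- node$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      if (!is_tensor(p)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    node$grad <- NULL # free as we go
  }
  invisible(NULL)
}

#' Evaluate an expression without gradient recording
#' @param expr expression to evaluate.
#' @export
ad_no_grad <- function(expr) {
  prev <- .dcf$recording
  .dcf$recording <- FALSE
  on.exit(.dcf$recording <- prev)
  expr
}
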