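# Minimal reverse-mode automatic differentiation on dense R arrays.
#
# A "tensor" is an environment holding a numeric array (`value`), an
# accumulated gradient (`grad`), the parent tensors it was computed from,
# and a backward closure mapping the output gradient to a list of parent
# gradients. Nodes are stamped with a creation counter so the backward
# pass can run in reverse topological order without an explicit tape.

.tensor_env <- new.env(parent = emptyenv())
.tensor_env$counter <- 0L

#' Create an autodiff tensor
#'
#' Wraps a numeric array as a node in the computation graph. Users normally
#' only need this indirectly (model parameters and inputs are wrapped by the
#' layer constructors and `model_forward()`), but it is exported so the
#' individual blocks (HWD, MSAM) can be exercised standalone.
#'
#' @param value numeric array, conventionally `(H, W, C, N)` for feature maps.
#' @param requires_grad should gradients be accumulated for this node?
#' @param parents list of parent tensors.
#' @param backward function(grad) -> list of gradients, one per parent.
#' @return an object of class `hf_tensor`.
#' @export
tensor <- function(value, requires_grad = FALSE, parents = list(),
                   backward = NULL) {
  node <- new.env(parent = emptyenv())
  .tensor_env$counter <- .tensor_env$counter + 1L
  node$id <- .tensor_env$counter
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) isTRUE(p$requires_grad), logical(1)))
  class(node) <- "hf_tensor"
  node
}

is_tensor <- function(x) inherits(x, "hf_tensor")

as_tensor <- function(x) if (is_tensor(x)) x else tensor(x)

#' @export
print.hf_tensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<hf_tensor", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires_grad) "(grad)" else "", ">\n")
  invisible(x)
}

# Collect the subgraph reachable from `root` whose nodes require grad,
# ordered by descending creation id (a valid reverse topological order,
# since parents are always created before children).
.reachable_nodes <- function(root) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  stack <- list(root)
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(node$id)
    if (!is.null(seen[[key]]) || !node$requires_grad) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- node
    for (p in node$parents) stack[[length(stack) + 1L]] <- p
  }
  out[order(vapply(out, function(n) n$id, numeric(1)), decreasing = TRUE)]
}

.accumulate_grad <- function(node, g) {
  if (!node$requires_grad) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Backpropagate gradients from a tensor
#'
#' Seeds `root$grad` with `seed` (default: an array of ones, i.e. d(sum)/dx)
#' and propagates gradients to every ancestor with `requires_grad = TRUE`.
#'
#' @param root output tensor (typically a scalar loss node).
#' @param seed gradient of the objective with respect to `root$value`.
#' @export
backward <- function(root, seed = NULL) {
  if (is.null(seed)) seed <- array(1, dim = dim(root$value) %||% length(root$value))
  root$grad <- seed
  for (node in .reachable_nodes(root)) {
    if (is.null(node$backward) || is.null(node$grad)) next
    grads <- node$backward(node$grad)
    for (k in seq_along(node$parents)) {
      if (!is.null(grads[[k]])) .accumulate_grad(node$parents[[k]], grads[[k]])
    }
  }
  invisible(root)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
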