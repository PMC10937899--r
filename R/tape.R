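#' @useDynLib cryopick, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal reverse-mode automatic differentiation.
#
# A tape records nodes in creation order; each node holds its value, an
# accumulated gradient and a closure pushing gradients to its parents.
# Values are plain R arrays/matrices so all heavy lifting goes through
# BLAS (%*%) or the compiled kernels. With grad = FALSE the tape records
# nothing and ops become thin wrappers around the forward computation,
# which keeps inference memory flat.

tape_new <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$grad <- grad
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tp, value, parents = NULL, backward = NULL, cache = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (tp$grad) {
    nd$parents <- parents
    nd$backward <- backward
    nd$cache <- cache
    n <- tp$n + 1L
    if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[n]] <- nd
    tp$n <- n
  }
  nd
}

tp_leaf <- function(tp, value) tp_node(tp, value)

tp_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Reverse sweep from `loss` (a scalar node). Gradients of every leaf
# reachable from the loss end up in leaf$grad.
tp_backward <- function(tp, loss) {
  stopifnot(tp$grad)
  loss$grad <- 1
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
    # free the subgraph as we go; leaves keep their grads
    if (!is.null(nd$backward)) {
      nd$cache <- NULL
    }
  }
  invisible(NULL)
}
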