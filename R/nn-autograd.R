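# Reverse-mode automatic differentiation over a dynamically built tape.
# Feature-map values are numeric arrays with dim (H, W, C, N); scalars and
# matrices (for the attention MLP) are also allowed node values.

.ag_state <- new.env(parent = emptyenv())
.ag_state$next_id <- 0L

ag_next_id <- function() {
  .ag_state$next_id <- .ag_state$next_id + 1L
  .ag_state$next_id
}

#' @keywords internal
ag_node <- function(value, parents = list(), backward = NULL, param = FALSE) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backward <- backward
  n$grad <- NULL
  n$param <- param
  n$id <- ag_next_id()
  class(n) <- "ag_node"
  n
}

#' @keywords internal
ag_param <- function(value) ag_node(value, param = TRUE)

#' @keywords internal
ag_const <- function(value) ag_node(value)

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

# Topological order of the subgraph reachable from `root` (iterative DFS).
ag_topo <- function(root) {
  order <- vector("list", 0L)
  state <- new.env(parent = emptyenv())  # id -> TRUE once emitted
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(top$node$id)
    if (top$expanded) {
      order[[length(order) + 1L]] <- top$node
      next
    }
    if (!is.null(state[[key]])) next
    state[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = top$node, expanded = TRUE)
    for (p in top$node$parents)
      if (is.null(state[[as.character(p$id)]]))
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
  }
  order
}

# Back-propagate d(root)/d(node) into every node$grad reachable from root.
ag_backward <- function(root, grad = NULL) {
  order <- ag_topo(root)
  for (n in order) n$grad <- NULL
  if (is.null(grad)) {
    grad <- ag_value(root)
    grad[] <- 1
  }
  root$grad <- grad
  for (i in rev(seq_along(order))) {
    n <- order[[i]]
    if (is.null(n$grad) || is.null(n$backward)) next
    gs <- n$backward(n$grad)
    for (k in seq_along(n$parents)) {
      gk <- gs[[k]]
      if (is.null(gk)) next
      p <- n$parents[[k]]
      p$grad <- if (is.null(p$grad)) gk else p$grad + gk
    }
  }
  invisible(root)
}
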