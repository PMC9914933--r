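# Minimal reverse-mode autodiff tape for the forecasting network.
#
# Nodes are environments holding a value, an accumulated gradient, their
# parent nodes and a backward closure.  Graphs are built eagerly by the
# op_* constructors in nn_ops.R; ad_backward() topologically sorts the
# tape and propagates gradients.  Everything operates on plain numeric
# matrices so the heavy lifting stays in BLAS.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_node <- function(val, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  .ad_env$counter <- .ad_env$counter + 1L
  n$id <- .ad_env$counter
  n$val <- val
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  class(n) <- "ad_node"
  n
}

ad_const <- function(val) ad_node(val)

ad_param <- function(val) {
  n <- ad_node(val)
  n$is_param <- TRUE
  n
}

# Accumulate gradient g into node n.
.acc <- function(n, g) {
  n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

# Backpropagate from a scalar-valued root node.
ad_backward <- function(root) {
  topo <- vector("list", 1024L)
  k <- 0L
  visited <- new.env(parent = emptyenv())
  visit <- function(n) {
    key <- as.character(n$id)
    if (is.null(visited[[key]])) {
      visited[[key]] <- TRUE
      for (p in n$parents) visit(p)
      k <<- k + 1L
      if (k > length(topo)) length(topo) <<- 2L * k
      topo[[k]] <<- n
    }
  }
  visit(root)
  for (i in seq_len(k)) topo[[i]]$grad <- NULL
  root$grad <- 1
  for (i in rev(seq_len(k))) {
    n <- topo[[i]]
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n$grad)
  }
  invisible(NULL)
}

# ---- Adam optimizer over a flat named list of parameter nodes ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0),
       t = 0L)
}

adam_step <- function(params, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gn2 <- 0
  for (p in params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
  scale <- if (clip > 0 && sqrt(gn2) > clip) clip / sqrt(gn2) else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    p$val <- p$val - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
    p$grad <- NULL
  }
  state
}
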