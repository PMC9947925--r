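# Minimal reverse-mode automatic differentiation on dense matrices.
# Values are computed eagerly; every operation appends a node (an
# environment holding the value, accumulated gradient and a backward
# closure) to a tape, and nn_backward() replays the tape in reverse.
# All heavy lifting is matrix algebra, so gradients cost about two
# forward passes through BLAS.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", tp$n))
  tp$nodes[[tp$n]] <- nd
  nd
}

acc_grad <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

#' Create a trainable parameter
#'
#' @param value initial numeric matrix (or vector).
#' @param name parameter name (diagnostics).
#' @param trainable whether the optimizer may update it.
#' @return an environment of class `nn_param`.
#' @export
new_param <- function(value, name = "param", trainable = TRUE) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$name <- name
  p$trainable <- trainable
  p$m <- NULL      # Adam first moment
  p$v <- NULL      # Adam second moment
  class(p) <- "nn_param"
  p
}

# leaf node bound to a parameter: backward copies the gradient out
tp_leaf <- function(tp, param) {
  nd <- tp_push(tp, param$value)
  nd$param <- param
  nd
}

tp_const <- function(tp, x) tp_push(tp, x)

tp_matmul <- function(tp, a, b) {
  tp_push(tp, a$value %*% b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad %*% t(b$value))
    acc_grad(b, crossprod(a$value, nd$grad))
  })
}

tp_add <- function(tp, a, b) {
  tp_push(tp, a$value + b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, nd$grad)
  })
}

# a (n x k) + bias (length-k vector), broadcast over rows
tp_add_bias <- function(tp, a, b) {
  tp_push(tp, sweep(a$value, 2, b$value, "+"), list(a, b), function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, colSums(nd$grad))
  })
}

tp_mul <- function(tp, a, b) {
  tp_push(tp, a$value * b$value, list(a, b), function(nd) {
    acc_grad(a, nd$grad * b$value)
    acc_grad(b, nd$grad * a$value)
  })
}

# multiply by a constant numeric (no node)
tp_scale <- function(tp, a, k) {
  tp_push(tp, a$value * k, list(a), function(nd) acc_grad(a, nd$grad * k))
}

# scale each row of a (n x k) by column vector node s (n x 1)
tp_scale_rows <- function(tp, a, s) {
  sv <- as.numeric(s$value)
  tp_push(tp, a$value * sv, list(a, s), function(nd) {
    acc_grad(a, nd$grad * sv)
    acc_grad(s, matrix(rowSums(nd$grad * a$value), ncol = 1))
  })
}

# multiply rows by a constant 0/1 (or weight) vector
tp_mask_rows <- function(tp, a, mask) {
  tp_push(tp, a$value * mask, list(a), function(nd)
    acc_grad(a, nd$grad * mask))
}

tp_tanh <- function(tp, a) {
  y <- tanh(a$value)
  tp_push(tp, y, list(a), function(nd) acc_grad(a, nd$grad * (1 - y * y)))
}

tp_sigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-a$value))
  tp_push(tp, y, list(a), function(nd) acc_grad(a, nd$grad * y * (1 - y)))
}

tp_relu <- function(tp, a) {
  y <- a$value
  pos <- y > 0
  y[!pos] <- 0
  tp_push(tp, y, list(a), function(nd) acc_grad(a, nd$grad * pos))
}

tp_cbind <- function(tp, parts) {
  widths <- vapply(parts, function(p) ncol(p$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  tp_push(tp, do.call(cbind, lapply(parts, `[[`, "value")), parts,
          function(nd) {
            for (i in seq_along(parts))
              acc_grad(parts[[i]],
                       nd$grad[, starts[i]:ends[i], drop = FALSE])
          })
}

tp_cols <- function(tp, a, idx) {
  tp_push(tp, a$value[, idx, drop = FALSE], list(a), function(nd) {
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[, idx] <- nd$grad
    acc_grad(a, g)
  })
}

# gather rows (duplicates allowed); backward scatter-adds via rowsum
tp_rows <- function(tp, a, idx) {
  tp_push(tp, a$value[idx, , drop = FALSE], list(a), function(nd) {
    agg <- rowsum(nd$grad, group = idx)
    g <- matrix(0, nrow(a$value), ncol(a$value))
    g[as.integer(rownames(agg)), ] <- agg
    acc_grad(a, g)
  })
}

# append one all-zero row (out-of-range target for conv gathers)
tp_pad_zero_row <- function(tp, a) {
  tp_push(tp, rbind(a$value, 0), list(a), function(nd)
    acc_grad(a, nd$grad[-nrow(nd$grad), , drop = FALSE]))
}

# group-mean over rows: rows with the same group id (1..G) are averaged
# with per-group divisor (e.g. true site size); groups must cover 1..G
tp_group_mean <- function(tp, a, group, divisors) {
  sums <- rowsum(a$value, group = group)
  ord <- as.integer(rownames(sums))
  val <- matrix(0, length(divisors), ncol(a$value))
  val[ord, ] <- sums
  val <- val / divisors
  tp_push(tp, val, list(a), function(nd)
    acc_grad(a, (nd$grad / divisors)[group, , drop = FALSE]))
}

# row-wise softmax
tp_softmax <- function(tp, a) {
  z <- a$value - apply(a$value, 1, max)
  e <- exp(z)
  y <- e / rowSums(e)
  tp_push(tp, y, list(a), function(nd) {
    dot <- rowSums(nd$grad * y)
    acc_grad(a, (nd$grad - dot) * y)
  })
}

# per-row cross-entropy of logits against integer class targets (1..K);
# returns an n x 1 node of -log softmax(logits)[target]
tp_ce_rows <- function(tp, logits, target) {
  z <- logits$value - apply(logits$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), target)]
  tp_push(tp, matrix(-log(pmax(picked, 1e-12)), ncol = 1), list(logits),
          function(nd) {
            g <- p * as.numeric(nd$grad)
            g[cbind(seq_len(n), target)] <-
              g[cbind(seq_len(n), target)] - as.numeric(nd$grad)
            acc_grad(logits, g)
          })
}

# per-row squared error of row-softmax(logits) against one-hot targets
tp_mse_rows <- function(tp, logits, target) {
  z <- logits$value - apply(logits$value, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  n <- nrow(p)
  oh <- matrix(0, n, ncol(p))
  oh[cbind(seq_len(n), target)] <- 1
  diff <- p - oh
  tp_push(tp, matrix(rowSums(diff^2), ncol = 1), list(logits),
          function(nd) {
            gp <- 2 * diff * as.numeric(nd$grad)      # d/dp
            dot <- rowSums(gp * p)
            acc_grad(logits, (gp - dot) * p)          # through softmax
          })
}

# row-wise minimum of an n x k node; subgradient flows to the argmin entry
tp_row_min <- function(tp, a) {
  j <- max.col(-a$value, ties.method = "first")
  n <- nrow(a$value)
  tp_push(tp, matrix(a$value[cbind(seq_len(n), j)], ncol = 1), list(a),
          function(nd) {
            g <- matrix(0, n, ncol(a$value))
            g[cbind(seq_len(n), j)] <- nd$grad
            acc_grad(a, g)
          })
}

# sum of all elements -> 1 x 1 node
tp_sum <- function(tp, a) {
  tp_push(tp, matrix(sum(a$value), 1, 1), list(a), function(nd)
    acc_grad(a, matrix(as.numeric(nd$grad), nrow(a$value), ncol(a$value))))
}

#' Run backward pass over a tape
#'
#' Seeds the given scalar node's gradient with 1 and accumulates gradients
#' into every parameter leaf touched by the tape.
#' @param tp a tape from `new_tape()`.
#' @param loss_node the scalar (1 x 1) node to differentiate.
#' @keywords internal
nn_backward <- function(tp, loss_node) {
  loss_node$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
    if (!is.null(nd$grad) && !is.null(nd$param)) {
      if (is.null(nd$param$grad)) nd$param$grad <- nd$grad
      else nd$param$grad <- nd$param$grad + nd$grad
    }
  }
  invisible(NULL)
}

# one Adam update over a flat list of nn_param; clears gradients.
# clip rescales the joint gradient to a global L2 norm bound.
adam_step <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t = 1, clip = Inf) {
  if (is.finite(clip)) {
    sq <- 0
    for (p in params)
      if (p$trainable && !is.null(p$grad)) sq <- sq + sum(p$grad^2)
    gn <- sqrt(sq)
    if (gn > clip)
      for (p in params)
        if (p$trainable && !is.null(p$grad)) p$grad <- p$grad * (clip / gn)
  }
  for (p in params) {
    if (!p$trainable || is.null(p$grad)) { p$grad <- NULL; next }
    g <- p$grad
    if (is.null(p$m)) { p$m <- g * 0; p$v <- g * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

clear_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
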