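# Minimal reverse-mode automatic differentiation on dense matrices.
#
# Every tensor is a base-R double matrix; a tape records nodes in creation
# order and the backward pass walks it in reverse, accumulating gradients.
# This is deliberately small: just the operations the generator,
# discriminator and hybrid loss need. Gradient correctness is enforced by
# finite-difference checks in the test suite.

ag_tape <- function(capacity = 4096L) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", capacity)
  tp$n <- 0L
  tp
}

ag_node <- function(tp, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  n <- tp$n + 1L
  if (n > length(tp$nodes))
    tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd$id <- n
  nd
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ag_const <- function(tp, value) ag_node(tp, as_mat(value))
# parameters are leaves too; they differ only in that we read their $grad
ag_param <- function(tp, value) ag_node(tp, as_mat(value))

ag_acc <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(tp, root) {
  if (length(root$value) != 1L) stop("backward root must be scalar")
  for (i in seq_len(tp$n)) tp$nodes[[i]]$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(root$id))) {
    nd <- tp$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible(NULL)
}

ag_matmul <- function(tp, a, b) {
  ag_node(tp, a$value %*% b$value, function(g) {
    ag_acc(a, g %*% t(b$value))
    ag_acc(b, t(a$value) %*% g)
  })
}

ag_add <- function(tp, a, b) {
  ag_node(tp, a$value + b$value, function(g) {
    ag_acc(a, g)
    ag_acc(b, g)
  })
}

# a: n x k, bias: 1 x k broadcast over rows
ag_add_bias <- function(tp, a, bias) {
  v <- a$value + matrix(bias$value, nrow(a$value), ncol(a$value), byrow = TRUE)
  ag_node(tp, v, function(g) {
    ag_acc(a, g)
    ag_acc(bias, matrix(colSums(g), 1L))
  })
}

ag_sub <- function(tp, a, b) {
  ag_node(tp, a$value - b$value, function(g) {
    ag_acc(a, g)
    ag_acc(b, -g)
  })
}

ag_mul <- function(tp, a, b) {
  ag_node(tp, a$value * b$value, function(g) {
    ag_acc(a, g * b$value)
    ag_acc(b, g * a$value)
  })
}

# scale each row i of a (n x k) by s[i] (s: n x 1)
ag_scale_rows <- function(tp, a, s) {
  sv <- as.vector(s$value)
  ag_node(tp, a$value * sv, function(g) {
    ag_acc(a, g * sv)
    ag_acc(s, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

ag_smul <- function(tp, a, c) {
  ag_node(tp, a$value * c, function(g) ag_acc(a, g * c))
}

ag_oneminus <- function(tp, a) {
  ag_node(tp, 1 - a$value, function(g) ag_acc(a, -g))
}

ag_sigmoid <- function(tp, a) {
  v <- 1 / (1 + exp(-a$value))
  ag_node(tp, v, function(g) ag_acc(a, g * v * (1 - v)))
}

ag_tanh <- function(tp, a) {
  v <- tanh(a$value)
  ag_node(tp, v, function(g) ag_acc(a, g * (1 - v * v)))
}

ag_relu <- function(tp, a) {
  v <- a$value
  mask <- v > 0
  v[!mask] <- 0
  ag_node(tp, v, function(g) ag_acc(a, g * mask))
}

ag_abs <- function(tp, a) {
  ag_node(tp, abs(a$value), function(g) ag_acc(a, g * sign(a$value)))
}

ag_sqrt_shift <- function(tp, a, eps = 1e-12) {
  v <- sqrt(a$value + eps)
  ag_node(tp, v, function(g) ag_acc(a, g * 0.5 / v))
}

ag_mean <- function(tp, a) {
  n <- length(a$value)
  dm <- dim(a$value)
  ag_node(tp, matrix(mean(a$value), 1L, 1L), function(g) {
    ag_acc(a, matrix(g[1L] / n, dm[1L], dm[2L]))
  })
}

ag_rowsums <- function(tp, a) {
  dm <- dim(a$value)
  ag_node(tp, matrix(rowSums(a$value), ncol = 1L), function(g) {
    ag_acc(a, matrix(as.vector(g), dm[1L], dm[2L]))
  })
}

ag_rowmax <- function(tp, a) {
  idx <- max.col(a$value, ties.method = "first")
  v <- a$value[cbind(seq_len(nrow(a$value)), idx)]
  dm <- dim(a$value)
  ag_node(tp, matrix(v, ncol = 1L), function(g) {
    z <- matrix(0, dm[1L], dm[2L])
    z[cbind(seq_len(dm[1L]), idx)] <- as.vector(g)
    ag_acc(a, z)
  })
}

ag_max2 <- function(tp, a, b) {
  mask <- a$value >= b$value
  ag_node(tp, pmax(a$value, b$value), function(g) {
    ag_acc(a, g * mask)
    ag_acc(b, g * !mask)
  })
}

ag_cbind <- function(tp, nodes) {
  vals <- lapply(nodes, `[[`, "value")
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ag_node(tp, do.call(cbind, vals), function(g) {
    for (i in seq_along(nodes))
      ag_acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_col <- function(tp, a, j) {
  dm <- dim(a$value)
  ag_node(tp, a$value[, j, drop = FALSE], function(g) {
    z <- matrix(0, dm[1L], dm[2L])
    z[, j] <- g
    ag_acc(a, z)
  })
}

# first differences along columns, anchored: v[,1] = a[,1] - anchor,
# v[,j] = a[,j] - a[,j-1]; anchor is a constant n x 1 numeric
ag_coldiff_anchor <- function(tp, a, anchor) {
  av <- a$value
  H <- ncol(av)
  prev <- cbind(anchor, av[, -H, drop = FALSE])
  ag_node(tp, av - prev, function(g) {
    gg <- g
    if (H > 1L)
      gg[, -H] <- gg[, -H, drop = FALSE] - g[, -1L, drop = FALSE]
    ag_acc(a, gg)
  })
}

# mean over entries of stabilized sigmoid cross-entropy of logits vs labels
ag_sce_mean <- function(tp, logits, labels) {
  a <- logits$value
  b <- labels
  n <- length(a)
  v <- mean(pmax(a, 0) - a * b + log1p(exp(-abs(a))))
  ag_node(tp, matrix(v, 1L, 1L), function(g) {
    ag_acc(logits, g[1L] * (1 / (1 + exp(-a)) - b) / n)
  })
}
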