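# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The training objective composes matrix products, row-softmax attention,
# gating nonlinearities and indexed dot products; gradients are obtained by
# recording every operation on a tape and sweeping it backwards.  Scalars are
# 1x1 matrices throughout.  Only the operations the model needs are provided.

ad_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape
}

.ad_push <- function(tape, value, parents = integer(0), backfn = NULL) {
  id <- tape$n + 1L
  if (id > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  node <- list(id = id, value = value, parents = parents, backfn = backfn)
  tape$nodes[[id]] <- node
  tape$n <- id
  structure(list(id = id, tape = tape, value = value), class = "ad_node")
}

is_ad <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (is_ad(x)) x$value else x

.as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

ad_const <- function(tape, x) .ad_push(tape, .as_mat(x))

ad_param <- function(tape, x) .ad_push(tape, .as_mat(x))

#' @noRd
ad_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  .ad_push(a$tape, av %*% bv, c(a$id, b$id),
           function(g) list(g %*% t(bv), crossprod(av, g)))
}

# a + b where b may be a row vector broadcast over rows of a, or a scalar
ad_add <- function(a, b) {
  av <- a$value; bv <- b$value
  if (identical(dim(av), dim(bv))) {
    .ad_push(a$tape, av + bv, c(a$id, b$id), function(g) list(g, g))
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    .ad_push(a$tape, sweep(av, 2L, as.vector(bv), "+"), c(a$id, b$id),
             function(g) list(g, matrix(colSums(g), nrow = 1L)))
  } else if (length(bv) == 1L) {
    .ad_push(a$tape, av + bv[1L], c(a$id, b$id),
             function(g) list(g, matrix(sum(g), 1L, 1L)))
  } else stop("ad_add: incompatible shapes")
}

ad_sub <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  .ad_push(a$tape, a$value - b$value, c(a$id, b$id), function(g) list(g, -g))
}

# elementwise product (same shape)
ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  stopifnot(identical(dim(av), dim(bv)))
  .ad_push(a$tape, av * bv, c(a$id, b$id), function(g) list(g * bv, g * av))
}

# X (n x c) scaled per-row by a column-vector node v (n x 1)
ad_mul_colvec <- function(x, v) {
  xv <- x$value; vv <- as.vector(v$value)
  .ad_push(x$tape, xv * vv, c(x$id, v$id),
           function(g) list(g * vv, matrix(rowSums(g * xv), ncol = 1L)))
}

# multiply by a plain numeric scalar
ad_scale <- function(x, k) {
  .ad_push(x$tape, x$value * k, x$id, function(g) list(g * k))
}

# per-row scaling by a plain numeric vector (e.g. inverse degrees, 0^-1 := 0)
ad_rowscale <- function(x, s) {
  s <- as.vector(s)
  .ad_push(x$tape, x$value * s, x$id, function(g) list(g * s))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-x$value))
  .ad_push(x$tape, v, x$id, function(g) list(g * v * (1 - v)))
}

ad_relu <- function(x) {
  xv <- x$value
  .ad_push(x$tape, pmax(xv, 0), x$id, function(g) list(g * (xv > 0)))
}

# log(sigmoid(x)), numerically stable in both tails
ad_logsigmoid <- function(x) {
  xv <- x$value
  v <- ifelse(xv >= 0, -log1p(exp(-xv)), xv - log1p(exp(xv)))
  .ad_push(x$tape, v, x$id, function(g) list(g / (1 + exp(xv))))
}

# softmax over each row, with max-subtraction for overflow safety
ad_row_softmax <- function(x) {
  xv <- x$value
  e <- exp(xv - apply(xv, 1L, max))
  p <- e / rowSums(e)
  .ad_push(x$tape, p, x$id,
           function(g) list(p * (g - rowSums(g * p))))
}

ad_transpose <- function(x) {
  .ad_push(x$tape, t(x$value), x$id, function(g) list(t(g)))
}

ad_sum <- function(x) {
  d <- dim(x$value)
  .ad_push(x$tape, matrix(sum(x$value), 1L, 1L), x$id,
           function(g) list(matrix(g[1L], d[1L], d[2L])))
}

ad_sumsq <- function(x) {
  xv <- x$value
  .ad_push(x$tape, matrix(sum(xv^2), 1L, 1L), x$id,
           function(g) list(2 * g[1L] * xv))
}

ad_colmean <- function(x) {
  n <- nrow(x$value)
  .ad_push(x$tape, matrix(colMeans(x$value), nrow = 1L), x$id,
           function(g) list(matrix(rep(as.vector(g) / n, each = n), nrow = n)))
}

# rowSums(X * Y) as an n x 1 column
ad_rowdot <- function(x, y) {
  xv <- x$value; yv <- y$value
  stopifnot(identical(dim(xv), dim(yv)))
  .ad_push(x$tape, matrix(rowSums(xv * yv), ncol = 1L), c(x$id, y$id),
           function(g) {
             gv <- as.vector(g)
             list(gv * yv, gv * xv)
           })
}

# dot products of selected row pairs: out[k] = X[ri[k], ] . Y[ci[k], ]
ad_pair_dot <- function(x, y, ri, ci) {
  xv <- x$value; yv <- y$value
  val <- matrix(rowSums(xv[ri, , drop = FALSE] * yv[ci, , drop = FALSE]), ncol = 1L)
  .ad_push(x$tape, val, c(x$id, y$id), function(g) {
    gv <- as.vector(g)
    dx <- matrix(0, nrow(xv), ncol(xv))
    agg <- rowsum(gv * yv[ci, , drop = FALSE], group = ri)
    dx[as.integer(rownames(agg)), ] <- agg
    dy <- matrix(0, nrow(yv), ncol(yv))
    agg2 <- rowsum(gv * xv[ri, , drop = FALSE], group = ci)
    dy[as.integer(rownames(agg2)), ] <- agg2
    list(dx, dy)
  })
}

ad_permute_rows <- function(x, perm) {
  .ad_push(x$tape, x$value[perm, , drop = FALSE], x$id, function(g) {
    dx <- g
    dx[perm, ] <- g
    list(dx)
  })
}

ad_permute_cols <- function(x, perm) {
  .ad_push(x$tape, x$value[, perm, drop = FALSE], x$id, function(g) {
    dx <- g
    dx[, perm] <- g
    list(dx)
  })
}

# sum of the entries of an n x 1 column restricted to a logical mask
ad_masked_sum <- function(x, mask) {
  xv <- x$value
  .ad_push(x$tape, matrix(sum(xv[mask, 1L]), 1L, 1L), x$id, function(g) {
    dx <- matrix(0, nrow(xv), 1L)
    dx[mask, 1L] <- g[1L]
    list(dx)
  })
}

ad_cbind <- function(cols) {
  tape <- cols[[1L]]$tape
  val <- do.call(cbind, lapply(cols, `[[`, "value"))
  .ad_push(tape, val, vapply(cols, `[[`, integer(1), "id"),
           function(g) lapply(seq_along(cols), function(j) g[, j, drop = FALSE]))
}

ad_col <- function(x, j) {
  d <- dim(x$value)
  .ad_push(x$tape, x$value[, j, drop = FALSE], x$id, function(g) {
    dx <- matrix(0, d[1L], d[2L])
    dx[, j] <- g
    list(dx)
  })
}

# Backward sweep from `loss` (1x1); returns a function mapping node -> gradient
ad_backward <- function(loss) {
  tape <- loss$tape
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- matrix(1, 1L, 1L)
  for (id in seq(loss$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backfn)) next
    pg <- node$backfn(g)
    for (j in seq_along(node$parents)) {
      pid <- node$parents[[j]]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
  }
  function(node) {
    g <- grads[[node$id]]
    if (is.null(g)) matrix(0, nrow(node$value), ncol(node$value)) else g
  }
}
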