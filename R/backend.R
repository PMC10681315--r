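# A tiny operation table lets the same forward-pass code run either on plain
# numeric matrices (prediction, diagnostics) or on the autodiff tape
# (training).  Both tables expose the identical vocabulary.

.softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

.logsigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

ops_plain <- function() {
  list(
    wrap = function(x) if (is.matrix(x)) x else matrix(x, nrow = 1L),
    value = function(x) x,
    mm = `%*%`,
    add = function(a, b) {
      if (identical(dim(a), dim(b))) a + b
      else if (nrow(b) == 1L && ncol(b) == ncol(a)) sweep(a, 2L, as.vector(b), "+")
      else if (length(b) == 1L) a + b[1L]
      else stop("add: incompatible shapes")
    },
    sub = function(a, b) a - b,
    mul = function(a, b) a * b,
    mul_colvec = function(x, v) x * as.vector(v),
    scale = function(x, k) x * k,
    rowscale = function(x, s) x * as.vector(s),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    relu = function(x) pmax(x, 0),
    logsigmoid = .logsigmoid,
    row_softmax = .softmax_rows,
    transpose = t,
    sum = function(x) matrix(sum(x), 1L, 1L),
    sumsq = function(x) matrix(sum(x^2), 1L, 1L),
    colmean = function(x) matrix(colMeans(x), nrow = 1L),
    rowdot = function(x, y) matrix(rowSums(x * y), ncol = 1L),
    pair_dot = function(x, y, ri, ci)
      matrix(rowSums(x[ri, , drop = FALSE] * y[ci, , drop = FALSE]), ncol = 1L),
    permute_rows = function(x, p) x[p, , drop = FALSE],
    permute_cols = function(x, p) x[, p, drop = FALSE],
    masked_sum = function(x, m) matrix(sum(x[m, 1L]), 1L, 1L),
    cbind = function(cols) do.call(cbind, cols),
    col = function(x, j) x[, j, drop = FALSE]
  )
}

ops_ad <- function(tape) {
  list(
    wrap = function(x) ad_const(tape, x),
    value = ad_value,
    mm = ad_matmul,
    add = ad_add,
    sub = ad_sub,
    mul = ad_mul,
    mul_colvec = ad_mul_colvec,
    scale = ad_scale,
    rowscale = ad_rowscale,
    sigmoid = ad_sigmoid,
    relu = ad_relu,
    logsigmoid = ad_logsigmoid,
    row_softmax = ad_row_softmax,
    transpose = ad_transpose,
    sum = ad_sum,
    sumsq = ad_sumsq,
    colmean = ad_colmean,
    rowdot = ad_rowdot,
    pair_dot = ad_pair_dot,
    permute_rows = ad_permute_rows,
    permute_cols = ad_permute_cols,
    masked_sum = ad_masked_sum,
    cbind = ad_cbind,
    col = ad_col
  )
}
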