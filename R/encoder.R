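# Drug/entity representation learning: self-gated multi-branch hypergraph
# attention fused with a task-graph convolution.
#
# Each enabled branch x in {j, p, i, u} starts from a gated view of the
# shared drug table D0,
#     D0x = D0 . sigmoid(D0 Pg_x + Bg_x),
# and propagates it L times through its hypergraph incidence I_x:
#     D'   = rowsoftmax(I_x D_l D_l') D_l
#     D_l+1 = deg(I_x)^-1 relu(D' Pm_x + Bm_x),
# with the convention 0^-1 := 0 for isolated drugs.  Layers 0..L are
# averaged into the branch embedding Dx, and a per-drug softmax attention
# over branches fuses them into Ds.  A graph convolution over the task
# matrix R then interleaves drug and entity updates, and the final drug
# embedding is Ds plus the layer average of the fused drug states.
# Pair scores are inner products of the final drug and entity rows.

.branch_names <- c("j", "p", "i", "u")

#' Self-gating unit
#'
#' Elementwise modulation `X * sigmoid(X P + B)` producing a branch-specific
#' view of a shared embedding table.
#'
#' @param X numeric matrix (n x c).
#' @param P gate weight matrix (c x c).
#' @param B gate bias (length-c vector or 1 x c matrix), broadcast over rows.
#' @return gated matrix, same shape as `X`.
#' @export
self_gate <- function(X, P, B) {
  stopifnot(ncol(X) == nrow(P), ncol(P) == ncol(X))
  X * (1 / (1 + exp(-sweep(X %*% P, 2L, as.vector(B), "+"))))
}

#' One hypergraph attention propagation layer
#'
#' Computes `rowsoftmax(I D D') D`, applies the linear map and ReLU, and
#' normalizes rows by the hypergraph degree (zero-degree rows map to zero).
#' With `conv = TRUE` the softmax attention is replaced by plain
#' degree-normalized propagation `I D` (the hypergraph-convolution variant).
#'
#' @param I_x hypergraph incidence matrix (b x b, non-negative).
#' @param deg degree vector (row sums of `I_x`).
#' @param D_l current drug embeddings (b x c).
#' @param P_m,B_m propagation weights (c x c) and bias (length c).
#' @param conv logical; replace attention by convolution.
#' @param masked logical; restrict the row softmax to the nonzero entries of
#'   `I_x` instead of all b columns.
#' @return the propagated embeddings (b x c).
#' @export
hypergraph_attention_layer <- function(I_x, deg, D_l, P_m, B_m,
                                       conv = FALSE, masked = FALSE) {
  if (!all(is.finite(D_l))) stop("non-finite embeddings")
  Dp <- if (conv) {
    I_x %*% D_l
  } else {
    sc <- I_x %*% tcrossprod(D_l)
    if (masked) sc[I_x == 0] <- -1e30
    .softmax_rows(sc) %*% D_l
  }
  inv <- ifelse(deg > 0, 1 / deg, 0)
  pmax(sweep(Dp %*% P_m, 2L, as.vector(B_m), "+"), 0) * inv
}

#' Forward pass of one hypergraph branch
#'
#' Gates the shared drug table, applies `L` attention layers, and averages
#' the `L + 1` layer embeddings into the branch embedding.
#'
#' @inheritParams hypergraph_attention_layer
#' @param D0 shared drug embedding table (b x c).
#' @param P_g,B_g self-gate parameters.
#' @param L number of propagation layers (>= 1).
#' @return list with `mean` (the branch embedding) and `layers` (list of the
#'   `L + 1` per-layer embeddings).
#' @export
branch_forward <- function(I_x, deg, D0, P_g, B_g, P_m, B_m, L = 2L,
                           conv = FALSE, masked = FALSE) {
  stopifnot(L >= 1L)
  layers <- vector("list", L + 1L)
  layers[[1L]] <- self_gate(D0, P_g, B_g)
  for (l in seq_len(L)) {
    layers[[l + 1L]] <- hypergraph_attention_layer(I_x, deg, layers[[l]],
                                                   P_m, B_m, conv, masked)
  }
  list(mean = Reduce(`+`, layers) / (L + 1L), layers = layers)
}

#' Attention over branch embeddings
#'
#' Per drug, a softmax over the enabled branches of `a' (Dx Pa)` weighs the
#' branch embeddings into the fused drug embedding `Ds`.
#'
#' @param D_branches named list of branch embeddings (each b x c); only
#'   enabled branches are included.
#' @param a attention vector (length c).
#' @param P_a attention weight matrix (c x c).
#' @return list with `omega` (b x K matrix of weights, columns named by
#'   branch, rows summing to 1) and `Ds` (the fused b x c embedding).
#' @export
branch_attention <- function(D_branches, a, P_a) {
  K <- length(D_branches)
  if (K == 0L) stop("all hypergraph branches are disabled")
  logits <- vapply(D_branches, function(Dx) as.vector((Dx %*% P_a) %*% matrix(a, ncol = 1L)),
                   numeric(nrow(D_branches[[1L]])))
  logits <- matrix(logits, ncol = K, dimnames = list(NULL, names(D_branches)))
  omega <- .softmax_rows(logits)
  Ds <- Reduce(`+`, Map(function(Dx, k) Dx * omega[, k], D_branches, seq_len(K)))
  list(omega = omega, Ds = Ds)
}

#' Inner-product pair scores
#'
#' @param D drug embeddings (b x c).
#' @param M entity embeddings (t x c).
#' @param pairs two-column integer matrix (drug index, entity index).
#' @return numeric vector of scores `D[d, ] . M[i, ]`.
#' @export
score_pairs <- function(D, M, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (any(pairs[, 1L] < 1L | pairs[, 1L] > nrow(D)) ||
      any(pairs[, 2L] < 1L | pairs[, 2L] > nrow(M))) {
    stop("pair index out of range")
  }
  rowSums(D[pairs[, 1L], , drop = FALSE] * M[pairs[, 2L], , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Full forward pass, written once against an operation table so it can run
# either on plain matrices or on the autodiff tape.
#
# params: flat named list (tensors in backend form), see init_params().
# data:   list(I = named list of incidence matrices, deginv = named list of
#         inverse-degree vectors, R = task matrix, r_rowinv, r_colinv =
#         inverse row/column degree vectors of R).
# cfg:    list(L, branches = character subset of j/p/i/u, conv, masked).
# Returns backend tensors: D, M, Ds, omega (b x K), branch layers, fused
# per-layer drug states, entity layer states.
encoder_forward <- function(params, data, cfg, ops = ops_plain()) {
  L <- cfg$L
  branches <- cfg$branches
  b <- nrow(ops$value(params$D0))

  branch_layers <- list()
  branch_mean <- list()
  for (x in branches) {
    Ix <- ops$wrap(data$I[[x]])
    inv <- data$deginv[[x]]
    D0x <- ops$mul(params$D0,
                   ops$sigmoid(ops$add(ops$mm(params$D0, params[[paste0("Pg_", x)]]),
                                       params[[paste0("Bg_", x)]])))
    layers <- vector("list", L + 1L)
    layers[[1L]] <- D0x
    for (l in seq_len(L)) {
      Dl <- layers[[l]]
      Dp <- if (isTRUE(cfg$conv)) {
        ops$mm(Ix, Dl)
      } else {
        sc <- ops$mm(Ix, ops$mm(Dl, ops$transpose(Dl)))
        if (isTRUE(cfg$masked)) {
          sc <- ops$add(sc, ops$wrap(ifelse(data$I[[x]] == 0, -1e30, 0)))
        }
        ops$mm(ops$row_softmax(sc), Dl)
      }
      lin <- ops$add(ops$mm(Dp, params[[paste0("Pm_", x)]]),
                     params[[paste0("Bm_", x)]])
      layers[[l + 1L]] <- ops$rowscale(ops$relu(lin), inv)
    }
    branch_layers[[x]] <- layers
    branch_mean[[x]] <- ops$scale(Reduce(ops$add, layers), 1 / (L + 1L))
  }

  K <- length(branches)
  if (K > 0L) {
    logit_cols <- lapply(branch_mean, function(Dx)
      ops$mm(ops$mm(Dx, params$Pa), ops$transpose(params$a)))
    logits <- ops$cbind(logit_cols)
    omega <- ops$row_softmax(logits)
    omega_cols <- lapply(seq_len(K), function(k) ops$col(omega, k))
    names(omega_cols) <- branches
    Ds <- Reduce(ops$add, Map(function(x, k) ops$mul_colvec(branch_mean[[x]], omega_cols[[x]]),
                              branches, seq_len(K)))
  } else {
    omega <- NULL
    omega_cols <- list()
    Ds <- ops$wrap(matrix(0, b, ncol(ops$value(params$D0))))
  }

  # graph convolution over the task matrix R
  R <- ops$wrap(data$R)
  Rt <- ops$wrap(t(data$R))
  D0c <- ops$mul(params$D0,
                 ops$sigmoid(ops$add(ops$mm(params$D0, params$Pg_c), params$Bg_c)))
  Dc_layers <- vector("list", L + 1L)
  Dm_layers <- vector("list", L + 1L)
  M_layers <- vector("list", L + 1L)
  Dc_layers[[1L]] <- D0c
  M_layers[[1L]] <- params$M0
  fuse <- function(l) {
    half <- ops$scale(Dc_layers[[l]], 0.5)
    if (K == 0L) return(half)
    hyp <- Reduce(ops$add, lapply(branches, function(x)
      ops$mul_colvec(branch_layers[[x]][[l]], omega_cols[[x]])))
    ops$add(hyp, half)
  }
  Dm_layers[[1L]] <- fuse(1L)
  for (l in seq_len(L)) {
    Dc_layers[[l + 1L]] <- ops$rowscale(
      ops$relu(ops$add(ops$mm(ops$mm(R, M_layers[[l]]), params$Pm_c), params$Bm_c)),
      data$r_rowinv)
    M_layers[[l + 1L]] <- ops$rowscale(
      ops$relu(ops$add(ops$mm(ops$mm(Rt, Dm_layers[[l]]), params$Pt_c), params$bt_c)),
      data$r_colinv)
    Dm_layers[[l + 1L]] <- fuse(l + 1L)
  }

  D <- ops$add(Ds, ops$scale(Reduce(ops$add, Dm_layers), 1 / (L + 1L)))
  M <- ops$scale(Reduce(ops$add, M_layers), 1 / (L + 1L))

  list(D = D, M = M, Ds = Ds, omega = omega, omega_cols = omega_cols,
       branch_layers = branch_layers, branch_mean = branch_mean,
       Dc_layers = Dc_layers, Dm_layers = Dm_layers, M_layers = M_layers,
       branches = branches)
}

# encoder data block from incidences and the task matrix
encoder_data <- function(incid, R, branches) {
  I <- list(); deginv <- list()
  for (x in branches) {
    m <- incid$I[[x]]
    storage.mode(m) <- "double"
    I[[x]] <- m
    d <- incid$deg[[x]]
    deginv[[x]] <- ifelse(d > 0, 1 / d, 0)
  }
  Rd <- R; storage.mode(Rd) <- "double"
  rd <- rowSums(Rd); cd <- colSums(Rd)
  list(I = I, deginv = deginv, R = Rd,
       r_rowinv = ifelse(rd > 0, 1 / rd, 0),
       r_colinv = ifelse(cd > 0, 1 / cd, 0))
}

#' Initialize the trainable parameters
#'
#' Embedding tables are drawn uniformly from (-0.05, 0.05) scaled by
#' `1/sqrt(c)`; gate, propagation and attention weights use Xavier-style
#' uniform initialization; biases start at zero.
#'
#' @param b number of drugs.
#' @param t number of task entities.
#' @param c embedding dimension.
#' @param seed integer seed.
#' @param propagation_params if `FALSE`, the per-branch and convolution
#'   propagation maps are frozen at identity/zero (so the trainable set is
#'   embeddings, gates and attention only).
#' @return flat named list of parameter matrices with attributes
#'   `trainable` (names) and `dims` (b, t, c).
#' @export
init_params <- function(b, t, c, seed = 1L, propagation_params = TRUE) {
  rng <- .with_seed(seed)
  on.exit(rng())
  xavier <- function(nin, nout) {
    r <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -r, r), nin, nout)
  }
  emb <- function(n) matrix(stats::runif(n * c, -0.05, 0.05) / sqrt(c), n, c)
  p <- list(D0 = emb(b), M0 = emb(t))
  for (x in c(.branch_names, "c")) {
    p[[paste0("Pg_", x)]] <- xavier(c, c)
    p[[paste0("Bg_", x)]] <- matrix(0, 1L, c)
  }
  for (x in .branch_names) {
    p[[paste0("Psg_", x)]] <- xavier(c, c)
    p[[paste0("bsg_", x)]] <- matrix(0, 1L, c)
  }
  for (x in c(.branch_names, "c")) {
    p[[paste0("Pm_", x)]] <- if (propagation_params) xavier(c, c) else diag(c)
    p[[paste0("Bm_", x)]] <- matrix(0, 1L, c)
  }
  p$Pt_c <- if (propagation_params) xavier(c, c) else diag(c)
  p$bt_c <- matrix(0, 1L, c)
  p$a <- xavier(1L, c)
  p$Pa <- xavier(c, c)
  frozen <- if (propagation_params) character(0) else
    c(paste0("Pm_", c(.branch_names, "c")), paste0("Bm_", c(.branch_names, "c")),
      "Pt_c", "bt_c")
  attr(p, "trainable") <- setdiff(names(p), frozen)
  attr(p, "dims") <- c(b = b, t = t, c = c)
  p
}
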