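# Training objective: Bayesian personalized ranking over sampled triples,
# plus a hierarchical self-supervised mutual-information term per hypergraph
# branch (node vs sub-hypergraph vs whole-graph summaries against
# permutation-corrupted negatives), combined as L = L_bpr + lambda * L_self.

#' Sample BPR training triples
#'
#' Draws `(d, i, j)` triples: `(d, i)` uniformly from the observed training
#' edges and `j` uniformly from the entities unobserved for `d`.  Drugs whose
#' row is fully observed are skipped (resampled).
#'
#' @param R_train binary training task matrix (drugs x entities).
#' @param n number of triples.
#' @param seed integer seed.
#' @return integer matrix with columns `d`, `i`, `j`.
#' @export
sample_triples <- function(R_train, n, seed = 1L) {
  stopifnot(n >= 0L)
  if (n == 0L) return(matrix(integer(0), 0L, 3L, dimnames = list(NULL, c("d", "i", "j"))))
  rng <- .with_seed(seed)
  on.exit(rng())
  edges <- which(R_train == 1L, arr.ind = TRUE)
  if (!nrow(edges)) stop("no positive edges to sample from")
  open_row <- rowSums(R_train == 0L) > 0L
  if (any(!open_row[unique(edges[, 1L])])) {
    edges <- edges[open_row[edges[, 1L]], , drop = FALSE]
    if (!nrow(edges)) stop("every drug row is fully observed")
  }
  pick <- sample.int(nrow(edges), n, replace = TRUE)
  d <- edges[pick, 1L]
  i <- edges[pick, 2L]
  j <- vapply(d, function(dd) {
    neg <- which(R_train[dd, ] == 0L)
    neg[sample.int(length(neg), 1L)]
  }, integer(1))
  cbind(d = unname(d), i = unname(i), j = unname(j))
}

#' Bayesian personalized ranking loss
#'
#' `sum(-log sigmoid(s_di - s_dj)) + delta * ||theta||^2`, where scores are
#' inner products of drug and entity embedding rows and the L2 regularizer
#' runs over all trainable parameter blocks.
#'
#' @param D,M drug and entity embeddings.
#' @param triples matrix from [sample_triples()].
#' @param params optional parameter list entering the regularizer (its
#'   `trainable` attribute, when present, selects the blocks).
#' @param delta L2 regularization strength.
#' @return scalar loss.
#' @export
bpr_loss <- function(D, M, triples, params = NULL, delta = 0) {
  s_pos <- score_pairs(D, M, triples[, c(1L, 2L), drop = FALSE])
  s_neg <- score_pairs(D, M, triples[, c(1L, 3L), drop = FALSE])
  if (!all(is.finite(s_pos)) || !all(is.finite(s_neg))) stop("non-finite scores")
  loss <- -sum(.logsigmoid(s_pos - s_neg))
  if (!is.null(params) && delta > 0) {
    nms <- attr(params, "trainable")
    if (is.null(nms)) nms <- names(params)
    loss <- loss + delta * sum(vapply(params[nms], function(m) sum(m^2), numeric(1)))
  }
  loss
}

#' Sub-hypergraph readout
#'
#' Summarizes, for every drug `d`, its hyperedge row `q_d` of the incidence
#' matrix into `s_d = (sum_v q_dv x_v) / |{v : q_dv > 0}|` (weights kept in
#' the numerator, the divisor counts the nonzero members).  Drugs with an
#' empty row yield the zero vector.
#'
#' @param D_ssl gated drug table (b x c).
#' @param I_x hypergraph incidence matrix (b x b).
#' @return b x c matrix of sub-hypergraph summaries.
#' @export
subhypergraph_readout <- function(D_ssl, I_x) {
  cnt <- rowSums(I_x > 0)
  (I_x %*% D_ssl) * ifelse(cnt > 0, 1 / cnt, 0)
}

#' Permutation corruption of a summary table
#'
#' Applies a random row permutation followed by a random column permutation;
#' the multiset of entries is preserved.
#'
#' @param S numeric matrix.
#' @param seed integer seed.
#' @return corrupted matrix of the same shape.
#' @export
corrupt <- function(S, seed = 1L) {
  rng <- .with_seed(seed)
  on.exit(rng())
  S[sample.int(nrow(S)), , drop = FALSE][, sample.int(ncol(S)), drop = FALSE]
}

# shared permutations so the tape and the plain path corrupt identically
.corrupt_perms <- function(b, c, seed) {
  rng <- .with_seed(seed)
  on.exit(rng())
  list(rows = sample.int(b), cols = sample.int(c))
}

#' Self-supervised mutual-information loss
#'
#' For each enabled branch, gates the final drug table, reads out the
#' drug-centred sub-hypergraph summaries and the whole-hypergraph summary
#' (mean of the non-empty summaries), corrupts the summary table by row and
#' column shuffling, and scores agreement with an inner-product
#' discriminator through a pairwise ranking loss:
#' `-sum_d [ log sig(f(d_d, s_d) - f(d_d, s~_d)) + log sig(f(s_d, g) - f(s~_d, g)) ]`.
#' Drugs with an empty hyperedge row are excluded.
#'
#' @param D final drug embeddings (b x c).
#' @param params parameter list holding the per-branch SSL gates
#'   (`Psg_x`, `bsg_x`).
#' @param I_list named list of incidence matrices for the enabled branches.
#' @param seed integer seed for the corruption permutations.
#' @return scalar loss (strictly positive).
#' @export
ssl_loss <- function(D, params, I_list, seed = 1L) {
  total <- 0
  for (x in names(I_list)) {
    I_x <- I_list[[x]]
    D_ssl <- self_gate(D, params[[paste0("Psg_", x)]], params[[paste0("bsg_", x)]])
    S <- subhypergraph_readout(D_ssl, I_x)
    valid <- rowSums(I_x > 0) > 0
    if (!any(valid)) next
    g <- colMeans(S[valid, , drop = FALSE])
    perms <- .corrupt_perms(nrow(S), ncol(S), seed + match(x, .branch_names))
    St <- S[perms$rows, , drop = FALSE][, perms$cols, drop = FALSE]
    t1 <- rowSums(D_ssl * S) - rowSums(D_ssl * St)
    t2 <- as.vector(S %*% g) - as.vector(St %*% g)
    total <- total - sum(.logsigmoid(t1[valid])) - sum(.logsigmoid(t2[valid]))
  }
  total
}

#' Total training objective
#'
#' @param L_s ranking (BPR) loss including its regularizer.
#' @param L_self self-supervised loss.
#' @param lambda weight of the auxiliary task.
#' @return `L_s + lambda * L_self`.
#' @export
total_loss <- function(L_s, L_self, lambda) L_s + lambda * L_self

# ---------------------------------------------------------------------------
# Tape-side objective, mirroring the plain functions above on the autodiff
# backend.  Returns nodes for the components so the trace can be recorded.
loss_forward <- function(params, enc, data, triples, delta, lambda, ssl_seed, ops) {
  D <- enc$D; M <- enc$M
  s_pos <- ops$pair_dot(D, M, triples[, 1L], triples[, 2L])
  s_neg <- ops$pair_dot(D, M, triples[, 1L], triples[, 3L])
  rank_term <- ops$scale(ops$sum(ops$logsigmoid(ops$sub(s_pos, s_neg))), -1)
  nms <- attr(params, "trainable_names")
  reg <- NULL
  if (delta > 0 && length(nms)) {
    sq <- lapply(params[nms], ops$sumsq)
    reg <- ops$scale(Reduce(ops$add, sq), delta)
  }
  L_s <- if (is.null(reg)) rank_term else ops$add(rank_term, reg)

  L_self <- NULL
  if (lambda > 0 && length(enc$branches)) {
    parts <- list()
    for (x in enc$branches) {
      I_x <- data$I[[x]]
      cnt <- rowSums(I_x > 0)
      valid <- cnt > 0
      if (!any(valid)) next
      D_ssl <- ops$mul(D, ops$sigmoid(ops$add(ops$mm(D, params[[paste0("Psg_", x)]]),
                                              params[[paste0("bsg_", x)]])))
      S <- ops$rowscale(ops$mm(ops$wrap(I_x), D_ssl), ifelse(valid, 1 / cnt, 0))
      gsel <- matrix(ifelse(valid, 1 / sum(valid), 0), nrow = 1L)
      g <- ops$mm(ops$wrap(gsel), S)  # 1 x c mean over non-empty rows
      perms <- .corrupt_perms(nrow(I_x), ncol(ops$value(D)), ssl_seed + match(x, .branch_names))
      St <- ops$permute_cols(ops$permute_rows(S, perms$rows), perms$cols)
      t1 <- ops$sub(ops$rowdot(D_ssl, S), ops$rowdot(D_ssl, St))
      t2 <- ops$sub(ops$mm(S, ops$transpose(g)), ops$mm(St, ops$transpose(g)))
      term <- ops$add(ops$masked_sum(ops$logsigmoid(t1), valid),
                      ops$masked_sum(ops$logsigmoid(t2), valid))
      parts[[x]] <- term
    }
    if (length(parts)) L_self <- ops$scale(Reduce(ops$add, parts), -1)
  }

  total <- if (is.null(L_self)) L_s else ops$add(L_s, ops$scale(L_self, lambda))
  list(total = total, L_s = L_s, L_self = L_self)
}

# note: ssl_loss() above uses seed per branch offset through .corrupt_perms
# with the same convention as loss_forward so both paths agree when compared.

# ---------------------------------------------------------------------------
# Adam optimizer over the flat parameter list.
.adam_new <- function(params, trainable) {
  list(m = lapply(params[trainable], function(x) x * 0),
       v = lapply(params[trainable], function(x) x * 0),
       t = 0L, b1 = 0.9, b2 = 0.999, eps = 1e-8)
}

.adam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$b1^state$t
  bc2 <- 1 - state$b2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$b1 * state$m[[nm]] + (1 - state$b1) * g
    state$v[[nm]] <- state$b2 * state$v[[nm]] + (1 - state$b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(state = state, params = params)
}

# One full training run; params0 from init_params().  Returns final params
# and the per-epoch loss trace.
train_loop <- function(params0, data, cfg, control, seed) {
  params <- params0
  trainable <- attr(params0, "trainable")
  lambda <- if (identical(control$ablation, "no_ssl")) 0 else control$lambda
  adam <- .adam_new(params, trainable)
  trace <- data.frame(epoch = integer(0), loss_bpr = numeric(0),
                      loss_ssl = numeric(0), loss_total = numeric(0))
  if (control$epochs == 0L) return(list(params = params, trace = trace))

  R <- data$R
  n_pos <- sum(R == 1)
  rng <- .with_seed(seed)
  on.exit(rng())
  for (epoch in seq_len(control$epochs)) {
    triple_seed <- sample.int(.Machine$integer.max, 1L)
    triples <- sample_triples(R, n_pos, triple_seed)
    ord <- sample.int(nrow(triples))
    triples <- triples[ord, , drop = FALSE]
    nb <- max(1L, ceiling(nrow(triples) / control$batch))
    ep <- c(bpr = 0, ssl = 0, total = 0)
    for (batch in seq_len(nb)) {
      lo <- (batch - 1L) * control$batch + 1L
      hi <- min(batch * control$batch, nrow(triples))
      tb <- triples[lo:hi, , drop = FALSE]
      ssl_seed <- sample.int(.Machine$integer.max / 2, 1L)

      tape <- ad_tape()
      ops <- ops_ad(tape)
      pt <- params
      for (nm in names(pt)) pt[[nm]] <- ad_param(tape, params[[nm]])
      attr(pt, "trainable_names") <- trainable
      enc <- encoder_forward(pt, data, cfg, ops)
      losses <- loss_forward(pt, enc, data, tb, control$reg, lambda, ssl_seed, ops)
      tot <- ad_value(losses$total)[1L]
      if (!is.finite(tot)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", batch)
      }
      grad_of <- ad_backward(losses$total)
      grads <- lapply(pt[trainable], grad_of)
      st <- .adam_step(adam, params, grads, control$lr)
      adam <- st$state
      params <- st$params
      ep["total"] <- ep["total"] + tot
      ep["bpr"] <- ep["bpr"] + ad_value(losses$L_s)[1L]
      ep["ssl"] <- ep["ssl"] + if (is.null(losses$L_self)) 0 else ad_value(losses$L_self)[1L]
    }
    trace <- rbind(trace, data.frame(epoch = epoch, loss_bpr = ep[["bpr"]],
                                     loss_ssl = ep[["ssl"]],
                                     loss_total = ep[["total"]]))
  }
  list(params = params, trace = trace)
}
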