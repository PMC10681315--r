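# Independent reference implementations used as test oracles.  Everything
# here is deliberately written at scalar-loop level (explicit index loops,
# no reuse of the package's vectorized code paths).

# ---- scalar matrix helpers -------------------------------------------------

smm <- function(A, B) {
  n <- nrow(A); m <- ncol(B); k <- ncol(A)
  out <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    acc <- 0
    for (l in seq_len(k)) acc <- acc + A[i, l] * B[l, j]
    out[i, j] <- acc
  }
  out
}

srow_softmax <- function(X) {
  out <- X
  for (i in seq_len(nrow(X))) {
    mx <- max(X[i, ])
    e <- exp(X[i, ] - mx)
    out[i, ] <- e / sum(e)
  }
  out
}

ssigmoid <- function(x) 1 / (1 + exp(-x))

# ---- scalar-loop encoder (Eqs: gate, attention layer, branch fusion, GCN) --

ref_gate <- function(X, P, B) {
  out <- X
  lin <- smm(X, P)
  for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
    out[i, j] <- X[i, j] * ssigmoid(lin[i, j] + B[1L, j])
  }
  out
}

ref_attention_layer <- function(I_x, deg, D, P_m, B_m, conv = FALSE) {
  if (conv) {
    Dp <- smm(I_x, D)
  } else {
    Sc <- smm(I_x, smm(D, t(D)))
    Dp <- smm(srow_softmax(Sc), D)
  }
  lin <- smm(Dp, P_m)
  out <- lin
  for (i in seq_len(nrow(D))) for (j in seq_len(ncol(D))) {
    v <- max(lin[i, j] + B_m[1L, j], 0)
    out[i, j] <- if (deg[i] > 0) v / deg[i] else 0
  }
  out
}

ref_encoder_forward <- function(params, data, cfg) {
  L <- cfg$L
  branches <- cfg$branches
  b <- nrow(params$D0); cc <- ncol(params$D0)
  layers <- list(); mean_x <- list()
  for (x in branches) {
    I_x <- data$I[[x]]
    deg <- rowSums(I_x)
    Dl <- ref_gate(params$D0, params[[paste0("Pg_", x)]], params[[paste0("Bg_", x)]])
    ls <- list(Dl)
    for (l in seq_len(L)) {
      Dl <- ref_attention_layer(I_x, deg, Dl, params[[paste0("Pm_", x)]],
                                params[[paste0("Bm_", x)]], conv = isTRUE(cfg$conv))
      ls[[l + 1L]] <- Dl
    }
    layers[[x]] <- ls
    acc <- matrix(0, b, cc)
    for (M_ in ls) acc <- acc + M_
    mean_x[[x]] <- acc / (L + 1L)
  }

  K <- length(branches)
  omega <- NULL
  Ds <- matrix(0, b, cc)
  if (K > 0L) {
    logits <- matrix(0, b, K)
    for (k in seq_len(K)) {
      Dx <- mean_x[[branches[k]]]
      pr <- smm(Dx, params$Pa)
      for (d in seq_len(b)) {
        acc <- 0
        for (j in seq_len(cc)) acc <- acc + params$a[1L, j] * pr[d, j]
        logits[d, k] <- acc
      }
    }
    omega <- srow_softmax(logits)
    for (d in seq_len(b)) for (j in seq_len(cc)) {
      acc <- 0
      for (k in seq_len(K)) acc <- acc + omega[d, k] * mean_x[[branches[k]]][d, j]
      Ds[d, j] <- acc
    }
  }

  R <- data$R
  t_ <- ncol(R)
  rdeg <- rowSums(R); cdeg <- colSums(R)
  Dc <- list(ref_gate(params$D0, params$Pg_c, params$Bg_c))
  Ml <- list(params$M0)
  fuse <- function(l) {
    out <- 0.5 * Dc[[l]]
    if (K > 0L) {
      for (k in seq_len(K)) {
        out <- out + omega[, k] * layers[[branches[k]]][[l]]
      }
    }
    out
  }
  Dm <- list(fuse(1L))
  for (l in seq_len(L)) {
    lin <- smm(smm(R, Ml[[l]]), params$Pm_c)
    nxt <- lin
    for (i in seq_len(b)) for (j in seq_len(cc)) {
      v <- max(lin[i, j] + params$Bm_c[1L, j], 0)
      nxt[i, j] <- if (rdeg[i] > 0) v / rdeg[i] else 0
    }
    Dc[[l + 1L]] <- nxt
    lin2 <- smm(smm(t(R), Dm[[l]]), params$Pt_c)
    nxt2 <- lin2
    for (i in seq_len(t_)) for (j in seq_len(cc)) {
      v <- max(lin2[i, j] + params$bt_c[1L, j], 0)
      nxt2[i, j] <- if (cdeg[i] > 0) v / cdeg[i] else 0
    }
    Ml[[l + 1L]] <- nxt2
    Dm[[l + 1L]] <- fuse(l + 1L)
  }
  Dfin <- Ds
  accD <- matrix(0, b, cc); accM <- matrix(0, t_, cc)
  for (l in seq_len(L + 1L)) { accD <- accD + Dm[[l]]; accM <- accM + Ml[[l]] }
  list(D = Ds + accD / (L + 1L), M = accM / (L + 1L), omega = omega, Ds = Ds)
}

# ---- scalar loss references ------------------------------------------------

ref_bpr <- function(D, M, triples, delta = 0, params = NULL) {
  total <- 0
  for (r in seq_len(nrow(triples))) {
    d <- triples[r, 1L]; i <- triples[r, 2L]; j <- triples[r, 3L]
    si <- 0; sj <- 0
    for (k in seq_len(ncol(D))) {
      si <- si + D[d, k] * M[i, k]
      sj <- sj + D[d, k] * M[j, k]
    }
    total <- total - log(ssigmoid(si - sj))
  }
  if (!is.null(params) && delta > 0) {
    for (m in params) total <- total + delta * sum(m * m)
  }
  total
}

ref_readout <- function(D_ssl, I_x) {
  b <- nrow(I_x)
  out <- matrix(0, b, ncol(D_ssl))
  for (d in seq_len(b)) {
    nz <- 0
    for (v in seq_len(b)) {
      if (I_x[d, v] > 0) {
        nz <- nz + 1L
        out[d, ] <- out[d, ] + I_x[d, v] * D_ssl[v, ]
      }
    }
    if (nz > 0) out[d, ] <- out[d, ] / nz
  }
  out
}

# mirrors the package's corruption-permutation convention
ref_ssl <- function(D, params, I_list, seed) {
  branch_names <- c("j", "p", "i", "u")
  total <- 0
  for (x in names(I_list)) {
    I_x <- I_list[[x]]
    D_ssl <- ref_gate(D, params[[paste0("Psg_", x)]], params[[paste0("bsg_", x)]])
    S <- ref_readout(D_ssl, I_x)
    valid <- rowSums(I_x > 0) > 0
    if (!any(valid)) next
    g <- colMeans(S[valid, , drop = FALSE])
    perms <- hgdrug:::.corrupt_perms(nrow(S), ncol(S), seed + match(x, branch_names))
    St <- S[perms$rows, , drop = FALSE][, perms$cols, drop = FALSE]
    for (d in which(valid)) {
      t1 <- sum(D_ssl[d, ] * S[d, ]) - sum(D_ssl[d, ] * St[d, ])
      t2 <- sum(S[d, ] * g) - sum(St[d, ] * g)
      total <- total - log(ssigmoid(t1)) - log(ssigmoid(t2))
    }
  }
  total
}

# ---- brute-force metrics ---------------------------------------------------

brute_auroc <- function(pos, neg) {
  conc <- 0
  for (p in pos) for (n in neg) {
    if (p > n) conc <- conc + 1
    else if (p == n) conc <- conc + 0.5
  }
  conc / (length(pos) * length(neg))
}

brute_aupr <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (s in thr) {
    tp <- sum(pos >= s); fp <- sum(neg >= s)
    prec <- tp / (tp + fp)
    rec <- tp / length(pos)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# ---- random small heterogeneous networks for the motif oracle --------------

rand_small_dsmn <- function(seed) {
  set.seed(seed)
  b <- sample(4:12, 1L)
  nf <- sample(3:8, 1L)
  ne <- sample(2:8, 1L)
  dens <- runif(1, 0.2, 0.5)
  sym01 <- function(n) {
    m <- matrix(rbinom(n * n, 1L, dens), n, n)
    m[lower.tri(m, diag = TRUE)] <- 0L
    m <- m + t(m); mode(m) <- "integer"; m
  }
  bin <- function(n, m) {
    x <- matrix(rbinom(n * m, 1L, dens), n, m); mode(x) <- "integer"; x
  }
  Z <- bin(nf, nf); diag(Z) <- 0L
  structure(list(task_kind = "DTI",
                 S = sym01(b), Y = bin(b, nf), Z = Z,
                 W = bin(b, ne), G = bin(b, ne), V = bin(b, ne),
                 R = bin(b, ne)),
            class = "dsmn")
}

# ---- tiny planted fixture for quick training tests -------------------------

small_planted <- function(seed = 1L) {
  make_planted_network(planted_spec(b = 20L, t = 12L, n_blocks = 2L,
                                    p_in = 0.4, p_out = 0.05,
                                    frags_per_block = 4L, frag_noise = 1L,
                                    seed = seed))
}
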