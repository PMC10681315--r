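# Desk-scale synthetic inputs with the statistical structure the model
# exploits: drugs fall into blocks; task links concentrate within blocks;
# and each block shares a pool of fragments, so shared-substructure motifs
# carry signal about links.  This restates, as a generative assumption, the
# mechanism that drugs with the same basic structure tend to have similar
# pharmacological effects.

#' Specification of a planted-partition network
#'
#' @param b number of drugs (divisible by `n_blocks`).
#' @param t number of task entities (divisible by `n_blocks`).
#' @param n_blocks number of planted blocks.
#' @param p_in,p_out within/between-block edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param frags_per_block size of each block's fragment pool.
#' @param frag_noise number of additional random fragments per drug.
#' @param seed integer seed.
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(b = 60L, t = 40L, n_blocks = 2L, p_in = 0.25,
                         p_out = 0.02, frags_per_block = 6L, frag_noise = 1L,
                         seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1,
            b %% n_blocks == 0L, t %% n_blocks == 0L,
            frags_per_block >= 1L, frag_noise >= 0L)
  structure(list(b = as.integer(b), t = as.integer(t),
                 n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
                 frags_per_block = as.integer(frags_per_block),
                 frag_noise = as.integer(frag_noise), seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a planted-partition heterogeneous network
#'
#' Drugs and entities are assigned evenly to blocks.  Task edges are
#' Bernoulli(`p_in`) within a block and Bernoulli(`p_out`) across; the
#' drug-drug matrix S is drawn the same way over drug pairs.  Each drug is
#' linked to every fragment of its block's pool plus `frag_noise` random
#' extra fragments, and Z is a shallow tree (pool head -> other pool
#' members) so quadrilateral substructure motifs occur.  Every drug is
#' guaranteed at least one fragment and one task edge (a within-block edge
#' is added if a drug row comes out empty).
#'
#' @param spec a [planted_spec()].
#' @return a `dsmn` network (bipartite task in the drug-target slot, with S,
#'   Y, Z populated) carrying the block assignments as attributes
#'   `drug_block` and `entity_block`.
#' @export
make_planted_network <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  rng <- .with_seed(spec$seed)
  on.exit(rng())
  b <- spec$b; t_ <- spec$t; nb <- spec$n_blocks
  drug_block <- rep(seq_len(nb), each = b / nb)
  ent_block <- rep(seq_len(nb), each = t_ / nb)

  pmat <- function(rows_block, cols_block) {
    same <- outer(rows_block, cols_block, "==")
    ifelse(same, spec$p_in, spec$p_out)
  }
  R <- matrix(stats::rbinom(b * t_, 1L, as.vector(pmat(drug_block, ent_block))),
              b, t_)
  S <- matrix(stats::rbinom(b * b, 1L, as.vector(pmat(drug_block, drug_block))),
              b, b)
  S[lower.tri(S, diag = TRUE)] <- 0L
  S <- S + t(S)
  mode(S) <- "integer"

  # ensure every drug has at least one task edge (resample within block)
  for (d in which(rowSums(R) == 0L)) {
    R[d, sample(which(ent_block == drug_block[d]), 1L)] <- 1L
  }
  mode(R) <- "integer"

  nf <- nb * spec$frags_per_block
  Y <- matrix(0L, b, nf)
  pool_of <- rep(seq_len(nb), each = spec$frags_per_block)
  for (d in seq_len(b)) {
    Y[d, pool_of == drug_block[d]] <- 1L
    if (spec$frag_noise > 0L) {
      extra <- setdiff(seq_len(nf), which(Y[d, ] == 1L))
      if (length(extra)) {
        Y[d, sample(extra, min(spec$frag_noise, length(extra)))] <- 1L
      }
    }
  }
  Z <- matrix(0L, nf, nf)
  for (g in seq_len(nb)) {
    members <- which(pool_of == g)
    if (length(members) > 1L) Z[members[1L], members[-1L]] <- 1L
  }

  drugs <- sprintf("D%03d", seq_len(b))
  ents <- sprintf("T%03d", seq_len(t_))
  frs <- sprintf("F%03d", seq_len(nf))
  dimnames(R) <- list(drugs, ents)
  dimnames(S) <- list(drugs, drugs)
  dimnames(Y) <- list(drugs, frs)
  dimnames(Z) <- list(frs, frs)

  net <- structure(list(task_kind = "DTI", R = R, S = S, Y = Y, Z = Z,
                        W = R, G = NULL, V = NULL,
                        registries = list(drug = drugs, entity = ents,
                                          fragment = frs)),
                   class = "dsmn")
  attr(net, "drug_block") <- drug_block
  attr(net, "entity_block") <- ent_block
  net
}

#' Generate a toy drug table of valid SMILES
#'
#' Drugs are assembled from a fixed library of aromatic/aliphatic scaffolds,
#' BRICS-cleavable linkers (amide/ester/amine bonds) and small substituents,
#' so drugs built on the same scaffold share fragments after decomposition.
#'
#' @param n_scaffolds number of scaffold groups (at most 6).
#' @param per_scaffold drugs per scaffold group.
#' @param seed integer seed.
#' @return data frame `drug_id`, `smiles`, with attribute `scaffold` giving
#'   each drug's scaffold group.
#' @export
make_toy_smiles <- function(n_scaffolds = 2L, per_scaffold = 5L, seed = 1L) {
  scaffolds <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1",
                 "c1ccc2ccccc2c1", "c1ccsc1", "c1ccoc1")
  linkers <- c("C(=O)N", "C(=O)O", "C(=O)NC", "OC(=O)")
  subs <- c("CCO", "CCN", "CC(C)C", "CCc1ccccc1", "CCOC", "CCCC", "CCCN", "CC")
  stopifnot(n_scaffolds >= 1L, n_scaffolds <= length(scaffolds),
            per_scaffold >= 1L,
            per_scaffold <= length(linkers) * length(subs))
  rng <- .with_seed(seed)
  on.exit(rng())
  combos <- expand.grid(linker = linkers, sub = subs, stringsAsFactors = FALSE)
  rows <- list()
  for (s in seq_len(n_scaffolds)) {
    pick <- combos[sample.int(nrow(combos), per_scaffold), , drop = FALSE]
    rows[[s]] <- data.frame(
      drug_id = sprintf("DRUG_%d_%d", s, seq_len(per_scaffold)),
      smiles = paste0(scaffolds[s], pick$linker, pick$sub),
      scaffold = s, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  scaf <- out$scaffold
  out$scaffold <- NULL
  attr(out, "scaffold") <- scaf
  out
}

#' Write planted-network edge lists as TSV files
#'
#' Writes `task.tsv` (drug, entity), `ddi.tsv` (drug, drug), `dfi.tsv`
#' (drug, fragment) and `ffi.tsv` (fragment, fragment) edge lists for a
#' planted network.
#'
#' @param net a [make_planted_network()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_planted_network <- function(net, dir) {
  stopifnot(inherits(net, "dsmn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_edges <- function(m, path) {
    idx <- which(m == 1L, arr.ind = TRUE)
    df <- data.frame(src = rownames(m)[idx[, 1L]], dst = colnames(m)[idx[, 2L]])
    df <- df[order(df$src, df$dst), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  paths <- c(dump_edges(net$R, file.path(dir, "task.tsv")),
             dump_edges(net$S, file.path(dir, "ddi.tsv")),
             dump_edges(net$Y, file.path(dir, "dfi.tsv")),
             dump_edges(net$Z, file.path(dir, "ffi.tsv")))
  invisible(paths)
}
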