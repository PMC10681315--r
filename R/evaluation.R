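# Link-prediction evaluation: AUROC/AUPR, k-fold cross-validation,
# novel-interaction ranking, and embedding-based drug similarity.

#' AUROC and AUPR of scored positives vs negatives
#'
#' AUROC is computed by the rank statistic with tie correction (tied pairs
#' count one half); AUPR by step-wise integration of the precision-recall
#' curve over the distinct score thresholds (no linear interpolation).
#'
#' @param pos_scores,neg_scores numeric score vectors (both non-empty).
#' @return named numeric vector `c(auroc = , aupr = )`.
#' @export
auroc_aupr <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative score")
  if (!all(is.finite(c(pos_scores, neg_scores)))) stop("non-finite scores")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  auroc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  scores <- c(pos_scores, neg_scores)
  labels <- c(rep(1L, np), rep(0L, nn))
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(s) sum(labels == 1L & scores == s), numeric(1)))
  fp <- cumsum(vapply(thr, function(s) sum(labels == 0L & scores == s), numeric(1)))
  prec <- tp / (tp + fp)
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)
  c(auroc = auroc, aupr = aupr)
}

#' Cross-validated evaluation of the model
#'
#' Partitions the positive task edges into `k` folds, rebuilds the
#' hypergraphs from each training view, trains a model per fold, scores the
#' held-out positives against the fold's fixed sampled negatives, and
#' reports per-fold and aggregated AUROC/AUPR.
#'
#' @param dsmn a network from [assemble_dsmn()].
#' @param k number of folds.
#' @param control a [hgdrug_control()] list.
#' @param seed integer seed (folds, initialization, sampling).
#' @param folds optional precomputed [make_folds()] result.
#' @return object of class `hgdrug_cv`: data frame `metrics` (fold, auroc,
#'   aupr), `mean` and `sd` vectors, and the fitted per-fold models.
#' @export
cross_validate <- function(dsmn, k = 5L, control = hgdrug_control(), seed = 1L,
                           folds = NULL) {
  if (is.null(folds)) folds <- make_folds(dsmn, k = k, seed = seed)
  fits <- vector("list", length(folds))
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    fit <- hgdrug(dsmn, fold = fold, control = control, seed = seed + f)
    m <- auroc_aupr(predict(fit, fold$test), predict(fit, fold$test_neg))
    fits[[f]] <- fit
    rows[[f]] <- data.frame(fold = fold$fold, auroc = m[["auroc"]], aupr = m[["aupr"]])
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics,
                 mean = c(auroc = mean(metrics$auroc), aupr = mean(metrics$aupr)),
                 sd = c(auroc = stats::sd(metrics$auroc), aupr = stats::sd(metrics$aupr)),
                 fits = fits, control = control, seed = seed),
            class = "hgdrug_cv")
}

#' @export
print.hgdrug_cv <- function(x, ...) {
  cat("Cross-validated link prediction (", nrow(x$metrics), " folds)\n", sep = "")
  print(x$metrics, row.names = FALSE)
  cat(sprintf("mean AUROC %.4f (sd %.4f), mean AUPR %.4f (sd %.4f)\n",
              x$mean[["auroc"]], x$sd[["auroc"]], x$mean[["aupr"]], x$sd[["aupr"]]))
  invisible(x)
}

#' Rank novel (unobserved) candidate interactions
#'
#' Scores every drug-entity pair, removes the known edges, and returns the
#' top candidates with deterministic tie-breaking (score descending, then
#' drug id, then entity id).
#'
#' @param D,M embeddings.
#' @param known_edges two-column integer matrix of known (drug, entity)
#'   pairs, excluded from the ranking.
#' @param top_n number of candidates to return.
#' @param symmetric treat pairs as unordered drug pairs (drug-drug task):
#'   only `drug < entity` pairs are ranked and self-pairs skipped.
#' @param drug_ids,entity_ids optional id vectors used in the output.
#' @return data frame `drug`, `entity`, `score`, `rank`.
#' @export
rank_novel <- function(D, M, known_edges, top_n = 20L, symmetric = FALSE,
                       drug_ids = NULL, entity_ids = NULL) {
  b <- nrow(D); t_ <- nrow(M)
  s <- tcrossprod(D, M)
  known <- matrix(FALSE, b, t_)
  if (length(known_edges)) {
    ke <- matrix(as.integer(known_edges), ncol = 2L)
    known[ke] <- TRUE
    if (symmetric) known[ke[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  if (symmetric) {
    known[lower.tri(known, diag = TRUE)] <- TRUE  # keep d < e once, no self
  }
  cand <- which(!known, arr.ind = TRUE)
  if (!nrow(cand)) {
    return(data.frame(drug = character(0), entity = character(0),
                      score = numeric(0), rank = integer(0)))
  }
  sc <- s[cand]
  ord <- order(-sc, cand[, 1L], cand[, 2L])
  if (top_n > length(ord)) {
    warning("top_n exceeds the number of candidate pairs; returning all")
    top_n <- length(ord)
  }
  take <- ord[seq_len(top_n)]
  d_ix <- cand[take, 1L]; e_ix <- cand[take, 2L]
  data.frame(
    drug = if (is.null(drug_ids)) d_ix else drug_ids[d_ix],
    entity = if (is.null(entity_ids)) e_ix else entity_ids[e_ix],
    score = sc[take],
    rank = seq_len(top_n))
}

#' Cosine drug-drug similarity from embeddings
#'
#' @param D drug embeddings (b x c).
#' @param drug_ids optional ids for dimnames and the neighbor table.
#' @return list with `similarity` (b x b cosine matrix; rows of an all-zero
#'   embedding give `NA`) and `nearest` (data frame `drug`, `neighbor`,
#'   `similarity`; `NA` neighbor for zero rows).
#' @export
drug_similarity <- function(D, drug_ids = NULL) {
  nrm <- sqrt(rowSums(D^2))
  ok <- nrm > 0
  Dn <- D * ifelse(ok, 1 / nrm, 0)
  sim <- tcrossprod(Dn)
  sim[!ok, ] <- NA_real_
  sim[, !ok] <- NA_real_
  if (!is.null(drug_ids)) dimnames(sim) <- list(drug_ids, drug_ids)
  nearest <- lapply(seq_len(nrow(D)), function(i) {
    if (!ok[i]) return(data.frame(drug = i, neighbor = NA_integer_,
                                  similarity = NA_real_))
    v <- sim[i, ]
    v[i] <- -Inf
    v[is.na(v)] <- -Inf
    jj <- which.max(v)
    data.frame(drug = i, neighbor = jj, similarity = v[jj])
  })
  nearest <- do.call(rbind, nearest)
  if (!is.null(drug_ids)) {
    nearest$drug <- drug_ids[nearest$drug]
    nearest$neighbor <- ifelse(is.na(nearest$neighbor), NA_character_,
                               drug_ids[nearest$neighbor])
  }
  list(similarity = sim, nearest = nearest)
}
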