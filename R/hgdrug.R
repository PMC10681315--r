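# The user-facing model: fit a multi-branch hypergraph-attention link
# predictor on a drug-centric heterogeneous network.

#' Control parameters for model fitting
#'
#' Defaults follow the published configuration of the method: embedding
#' dimension 100, two propagation layers, L2 regularization 0.01, auxiliary
#' task weight 0.001, batch size 2000, adaptive-moment optimizer with initial
#' learning rate 0.001, up to 200 epochs.
#'
#' @param dim embedding dimension `c`.
#' @param layers number of propagation layers `L`.
#' @param reg L2 regularization strength.
#' @param lambda weight of the self-supervised auxiliary loss.
#' @param batch minibatch size (triples per optimizer step).
#' @param epochs training epochs.
#' @param lr initial learning rate of the adaptive-moment optimizer.
#' @param ablation model variant: `"full"`, `"no_hyper"` (no hypergraph
#'   branches), `"frag_only"` (substructure branches j, p only), `"mol_only"`
#'   (molecular-interaction branches i, u only), `"conv"` (attention replaced
#'   by degree-normalized hypergraph convolution), `"no_ssl"` (lambda = 0).
#' @param masked_softmax restrict the attention row-softmax to the nonzero
#'   entries of the incidence matrix (default off: dense softmax as printed).
#' @param propagation_params train the per-branch/convolution propagation
#'   maps (`FALSE` freezes them at identity/zero).
#' @return list of class `hgdrug_control`.
#' @export
hgdrug_control <- function(dim = 100L, layers = 2L, reg = 0.01, lambda = 0.001,
                           batch = 2000L, epochs = 200L, lr = 0.001,
                           ablation = c("full", "no_hyper", "frag_only",
                                        "mol_only", "conv", "no_ssl"),
                           masked_softmax = FALSE, propagation_params = TRUE) {
  ablation <- match.arg(ablation)
  stopifnot(dim >= 1, layers >= 1, reg >= 0, lambda >= 0, batch >= 1,
            epochs >= 0, lr > 0)
  structure(list(dim = as.integer(dim), layers = as.integer(layers), reg = reg,
                 lambda = lambda, batch = as.integer(batch),
                 epochs = as.integer(epochs), lr = lr, ablation = ablation,
                 masked_softmax = masked_softmax,
                 propagation_params = propagation_params),
            class = "hgdrug_control")
}

.ablation_branches <- function(ablation) {
  switch(ablation,
         no_hyper = character(0),
         frag_only = c("j", "p"),
         mol_only = c("i", "u"),
         .branch_names)
}

#' Fit the hypergraph-attention link prediction model
#'
#' Builds the four motif-driven hypergraph incidences from the (training view
#' of the) heterogeneous network, then trains the multi-branch
#' hypergraph-attention encoder with the BPR + self-supervised objective by
#' an adaptive-moment optimizer.
#'
#' @param dsmn a network from [assemble_dsmn()].
#' @param fold optional fold from [make_folds()]; when supplied, the model
#'   sees only the fold's training edges (hypergraphs are rebuilt from the
#'   training view).
#' @param control a [hgdrug_control()] list.
#' @param seed integer seed covering initialization, triple sampling and
#'   corruption.
#' @return object of class `hgdrug` with the trained parameters, final drug
#'   (`D`) and entity (`M`) embeddings, branch attention weights `omega`,
#'   the per-epoch loss trace, and the node registries.
#' @examples
#' \dontrun{
#' net <- make_planted_network(planted_spec(b = 20, t = 12, seed = 1))
#' fit <- hgdrug(net, control = hgdrug_control(dim = 8, epochs = 20))
#' predict(fit)[1:3, 1:3]
#' }
#' @export
hgdrug <- function(dsmn, fold = NULL, control = hgdrug_control(), seed = 1L) {
  stopifnot(inherits(dsmn, "dsmn"))
  view <- train_view(dsmn, fold)
  incid <- build_branch_incidences(view)
  branches <- intersect(.ablation_branches(control$ablation),
                        names(which(incid$enabled)))
  b <- nrow(view$R); t_ <- ncol(view$R)
  if (sum(view$R) == 0) stop("the task network has no training edges")

  data <- encoder_data(incid, view$R, branches)
  cfg <- list(L = control$layers, branches = branches,
              conv = identical(control$ablation, "conv"),
              masked = isTRUE(control$masked_softmax))
  params0 <- init_params(b, t_, control$dim, seed = seed,
                         propagation_params = control$propagation_params)
  fit <- train_loop(params0, data, cfg, control, seed = seed + 1L)

  enc <- encoder_forward(fit$params, data, cfg, ops_plain())
  structure(list(params = fit$params, D = enc$D, M = enc$M,
                 omega = enc$omega, branches = branches,
                 incidences = incid, loss_trace = fit$trace,
                 control = control, seed = seed,
                 task_kind = view$task_kind,
                 registries = view$registries,
                 R_train = view$R, fold = fold),
            class = "hgdrug")
}

#' @export
print.hgdrug <- function(x, ...) {
  cat("Hypergraph-attention link prediction model (", x$task_kind, " task)\n", sep = "")
  cat("  drugs:", nrow(x$D), " entities:", nrow(x$M),
      " dim:", ncol(x$D), " layers:", x$control$layers, "\n")
  cat("  variant:", x$control$ablation,
      " branches:", if (length(x$branches)) paste(x$branches, collapse = ","), "\n")
  if (nrow(x$loss_trace)) {
    n <- nrow(x$loss_trace)
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n", n,
                x$loss_trace$loss_total[1L], x$loss_trace$loss_total[n]))
  } else cat("  untrained (0 epochs)\n")
  invisible(x)
}

#' @export
summary.hgdrug <- function(object, ...) {
  out <- list(task_kind = object$task_kind, dims = dim(object$D),
              branches = object$branches,
              omega_mean = if (!is.null(object$omega)) colMeans(object$omega),
              trace = object$loss_trace, control = object$control)
  class(out) <- "summary.hgdrug"
  out
}

#' @export
print.summary.hgdrug <- function(x, ...) {
  cat("Task:", x$task_kind, "- embeddings", x$dims[1L], "x", x$dims[2L], "\n")
  if (!is.null(x$omega_mean)) {
    cat("Mean branch attention:\n")
    print(round(x$omega_mean, 4))
  }
  if (nrow(x$trace)) {
    cat("Loss trace (first/last):\n")
    print(x$trace[unique(c(1L, nrow(x$trace))), ], row.names = FALSE)
  }
  invisible(x)
}

#' Predict interaction scores
#'
#' @param object a fitted [hgdrug()] model.
#' @param pairs optional two-column matrix of (drug index, entity index);
#'   when omitted, the full score matrix `D M'` is returned with id dimnames.
#' @param ... unused.
#' @return numeric vector of scores, or the full drugs-by-entities score
#'   matrix.
#' @export
predict.hgdrug <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    s <- tcrossprod(object$D, object$M)
    dimnames(s) <- list(object$registries$drug, object$registries$entity)
    return(s)
  }
  score_pairs(object$D, object$M, pairs)
}

#' @export
coef.hgdrug <- function(object, ...) list(D = object$D, M = object$M)

#' @export
plot.hgdrug <- function(x, ...) {
  tr <- x$loss_trace
  if (!nrow(tr)) {
    warning("untrained model: no loss trace to plot")
    return(invisible(x))
  }
  graphics::plot(tr$epoch, tr$loss_total, type = "l", xlab = "epoch",
                 ylab = "loss", main = "Training loss", ...)
  graphics::lines(tr$epoch, tr$loss_bpr, lty = 2L)
  graphics::legend("topright", legend = c("total", "ranking"), lty = 1:2, bty = "n")
  invisible(x)
}
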