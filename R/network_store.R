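# The drug-centric heterogeneous network (DSMN) and its per-fold views.
#
# The container holds binary adjacency matrices over typed node registries:
#   S drug x drug        (drug-drug interactions, symmetric, zero diagonal)
#   Y drug x fragment    (directed drug -> first-level fragment)
#   Z fragment x fragment(directed parent -> child)
#   W drug x target, G drug x side-effect, V drug x disease (optional)
# plus the task network R (drug x entity; R == S for the drug-drug task).
# External files always use string ids; dense 1-based indices are internal.

.task_kinds <- c("DDI", "DTI", "DDiI", "DSI")
.task_slot <- c(DDI = "S", DTI = "W", DDiI = "V", DSI = "G")

#' Read a typed edge list
#'
#' Reads a two-column tab-separated edge list (UTF-8, `#` comments and blank
#' lines ignored) and returns the deduplicated edges as character id pairs.
#'
#' @param path file path.
#' @param src_type,dst_type node-type labels attached to the result (e.g.
#'   `"drug"`, `"target"`).
#' @return data frame with columns `src`, `dst`, deduplicated, in file order;
#'   attributes `src_type` and `dst_type`.
#' @export
read_edge_list <- function(path, src_type = "drug", dst_type = "entity") {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("malformed edge list line(s) in ", path, ": line ",
         paste(idx[nf < 2L], collapse = ", "))
  }
  out <- data.frame(src = vapply(parts, `[[`, character(1), 1L),
                    dst = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$src, out$dst, sep = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "src_type") <- src_type
  attr(out, "dst_type") <- dst_type
  out
}

.binary_matrix <- function(edges, rows, cols) {
  m <- matrix(0L, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(edges)) m[cbind(match(edges$src, rows), match(edges$dst, cols))] <- 1L
  m
}

.first_seen <- function(...) {
  v <- c(...)
  v[!duplicated(v)]
}

#' Assemble the drug-centric heterogeneous network
#'
#' Builds the typed adjacency matrices of the heterogeneous network from a
#' fragmentation result, the task-specific interaction edges, and optional
#' side networks, registering nodes in first-seen order.
#'
#' @param task_edges data frame `src` (drug id), `dst` (entity id) of positive
#'   task interactions (for `task_kind = "DDI"` both columns are drug ids).
#' @param task_kind one of `"DDI"`, `"DTI"`, `"DDiI"`, `"DSI"`.
#' @param fragmentation optional [recursive_decompose()] result supplying the
#'   drug-fragment (Y) and fragment-fragment (Z) matrices.  Drugs present in
#'   the task network but absent from the fragmentation get all-zero Y rows
#'   (with a warning).
#' @param side_edges optional named list of additional edge lists (names among
#'   `"ddi"`, `"dti"`, `"ddii"`, `"dsi"`), each a data frame `src`, `dst`.
#'   The `"ddi"` edges populate S when the task itself is not drug-drug.
#' @param drugs optional frozen drug registry (character); task or side edges
#'   naming a drug outside it raise an error.
#' @return object of class `dsmn` with the matrices `S`, `Y`, `Z`, `W`, `G`,
#'   `V` (absent slots `NULL`), the task matrix `R`, and the node registries.
#' @export
assemble_dsmn <- function(task_edges, task_kind,
                          fragmentation = NULL, side_edges = list(),
                          drugs = NULL) {
  task_kind <- match.arg(task_kind, .task_kinds)
  stopifnot(is.data.frame(task_edges), all(c("src", "dst") %in% names(task_edges)))
  side_edges <- side_edges[!vapply(side_edges, is.null, logical(1))]
  stopifnot(all(names(side_edges) %in% c("ddi", "dti", "ddii", "dsi")))

  side_drugs <- unlist(lapply(side_edges, function(e) e$src), use.names = FALSE)
  ddi_dst <- if (!is.null(side_edges$ddi)) side_edges$ddi$dst else character(0)
  frag_drugs <- if (!is.null(fragmentation)) fragmentation$drug_ids else character(0)
  seen <- .first_seen(task_edges$src,
                      if (task_kind == "DDI") task_edges$dst else character(0),
                      side_drugs, ddi_dst, frag_drugs)
  if (is.null(drugs)) {
    drugs <- seen
  } else if (!all(seen %in% drugs)) {
    stop("edge references unknown drug(s): ",
         paste(utils::head(setdiff(seen, drugs), 5L), collapse = ", "))
  }
  b <- length(drugs)

  entities <- if (task_kind == "DDI") drugs else .first_seen(task_edges$dst)

  R <- .binary_matrix(task_edges, drugs, entities)
  if (task_kind == "DDI") {
    R <- R | t(R)
    mode(R) <- "integer"
    diag(R) <- 0L
  }

  slots <- list(S = NULL, Y = NULL, Z = NULL, W = NULL, G = NULL, V = NULL)
  slots[[.task_slot[[task_kind]]]] <- R
  registries <- list(drug = drugs, entity = entities)

  side_slot <- c(ddi = "S", dti = "W", ddii = "V", dsi = "G")
  for (nm in names(side_edges)) {
    slot <- side_slot[[nm]]
    if (!is.null(slots[[slot]])) next  # the task already owns this slot
    e <- side_edges[[nm]]
    if (nm == "ddi") {
      m <- .binary_matrix(e, drugs, drugs)
      m <- m | t(m); mode(m) <- "integer"; diag(m) <- 0L
      slots$S <- m
    } else {
      ents <- .first_seen(e$dst)
      slots[[slot]] <- .binary_matrix(e, drugs, ents)
      registries[[slot]] <- ents
    }
  }

  if (!is.null(fragmentation)) {
    frag_ids <- as.character(fragmentation$fragments$fragment_id)
    dfi <- data.frame(src = fragmentation$dfi$drug_id,
                      dst = as.character(fragmentation$dfi$fragment_id))
    missing_frag <- setdiff(drugs, fragmentation$drug_ids)
    if (length(missing_frag)) {
      warning(length(missing_frag),
              " drug(s) have no fragmentation; their Y rows are all zero")
    }
    dfi <- dfi[dfi$src %in% drugs, , drop = FALSE]
    slots$Y <- .binary_matrix(dfi, drugs, frag_ids)
    ffi <- data.frame(src = as.character(fragmentation$ffi$parent_id),
                      dst = as.character(fragmentation$ffi$child_id))
    slots$Z <- .binary_matrix(ffi, frag_ids, frag_ids)
    registries$fragment <- frag_ids
  }

  structure(list(task_kind = task_kind, R = R,
                 S = slots$S, Y = slots$Y, Z = slots$Z,
                 W = slots$W, G = slots$G, V = slots$V,
                 registries = registries),
            class = "dsmn")
}

#' @export
print.dsmn <- function(x, ...) {
  cat("Drug-centric heterogeneous network (task:", x$task_kind, ")\n")
  cat("  drugs:", length(x$registries$drug),
      " entities:", length(x$registries$entity), "\n")
  for (nm in c("S", "Y", "Z", "W", "G", "V")) {
    m <- x[[nm]]
    if (!is.null(m)) cat(sprintf("  %s: %d x %d, %d edges\n", nm,
                                 nrow(m), ncol(m), sum(m)))
  }
  invisible(x)
}

# positive task edges as an index matrix (drug, entity); for the drug-drug
# task each undirected pair appears once with drug < entity
.positive_pairs <- function(dsmn) {
  R <- dsmn$R
  idx <- which(R == 1L, arr.ind = TRUE)
  if (dsmn$task_kind == "DDI") idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  unname(idx)
}

#' Build cross-validation folds over the positive task edges
#'
#' Randomly partitions the positive edges of the task network into `k`
#' disjoint test sets and samples, for each fold, an equal number of test
#' negatives uniformly from the never-observed pairs.
#'
#' @param dsmn a [assemble_dsmn()] network.
#' @param k number of folds (default 5).
#' @param seed integer seed; folds are reproducible given the seed.
#' @return list of `k` folds, each with integer pair matrices `train`,
#'   `test`, `test_neg` (columns: drug index, entity index) and the fold id.
#' @export
make_folds <- function(dsmn, k = 5L, seed = 1L) {
  stopifnot(inherits(dsmn, "dsmn"), k >= 2L)
  pos <- .positive_pairs(dsmn)
  n <- nrow(pos)
  if (k > n) stop("k = ", k, " exceeds the number of positive edges (", n, ")")
  rng <- .with_seed(seed)
  perm <- sample.int(n)
  fold_of <- rep(seq_len(k), length.out = n)[order(perm)]

  b <- nrow(dsmn$R); t_ <- ncol(dsmn$R)
  is_pos <- matrix(FALSE, b, t_)
  is_pos[dsmn$R == 1L] <- TRUE
  if (dsmn$task_kind == "DDI") diag(is_pos) <- TRUE  # never sample self-pairs

  sample_negatives <- function(m) {
    out <- matrix(0L, 0L, 2L)
    guard <- 0L
    while (nrow(out) < m) {
      need <- (m - nrow(out)) * 2L
      d <- sample.int(b, need, replace = TRUE)
      e <- sample.int(t_, need, replace = TRUE)
      ok <- !is_pos[cbind(d, e)]
      cand <- cbind(d, e)[ok, , drop = FALSE]
      if (dsmn$task_kind == "DDI" && nrow(cand)) {
        cand <- cbind(pmin(cand[, 1L], cand[, 2L]), pmax(cand[, 1L], cand[, 2L]))
      }
      out <- unique(rbind(out, cand))
      guard <- guard + 1L
      if (guard > 1000L) stop("cannot sample enough negative pairs")
    }
    unname(out[seq_len(m), , drop = FALSE])
  }

  folds <- lapply(seq_len(k), function(f) {
    test <- pos[fold_of == f, , drop = FALSE]
    list(fold = f,
         train = pos[fold_of != f, , drop = FALSE],
         test = test,
         test_neg = sample_negatives(nrow(test)),
         seed = seed)
  })
  rng()
  folds
}

#' Training view of the network for one fold
#'
#' Removes the fold's held-out positive edges from the task matrix (and, for
#' the drug-drug task, from S), so hypergraphs and the model only ever see
#' training edges.
#'
#' @param dsmn a [assemble_dsmn()] network.
#' @param fold one element of [make_folds()] (or `NULL` for the full network).
#' @return a `dsmn` object whose `R` (and task-owned slot) contain training
#'   edges only.
#' @export
train_view <- function(dsmn, fold = NULL) {
  if (is.null(fold)) return(dsmn)
  R <- dsmn$R
  R[fold$test] <- 0L
  if (dsmn$task_kind == "DDI") R[fold$test[, c(2L, 1L), drop = FALSE]] <- 0L
  out <- dsmn
  out$R <- R
  out[[.task_slot[[dsmn$task_kind]]]] <- R
  out
}

# run code under a local RNG seed; returns a restore function
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
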