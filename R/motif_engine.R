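# Motif-induced drug adjacency matrices and the four hypergraph incidences.
#
# Twelve triangle/quadrilateral motifs anchored on two drug nodes are counted
# by closed-form matrix algebra; A_k(i, j) is the number of motif instances
# of M_k in which drugs i and j co-occur (i != j):
#
#   M1  (SS) . S        M4  SS           (drug pair + common drug neighbour)
#   M2  (YY') . S       M5  YY'          (drug pair sharing a fragment)
#   M3  Am + Am',       M6  Am + Am'     (fragment -> child fragment bridge)
#       Am = (YZY') . S      Am = YZY'
#   M7  (WW') . S       M10 WW'          (shared target)
#   M8  (GG') . S       M11 GG'          (shared side-effect)
#   M9  (VV') . S       M12 VV'          (shared disease)
#
# "." is the elementwise product; the S mask restricts to directly-related
# drug pairs.  M1-M3 form the DRSS group (drug related, same substructure),
# M4-M6 DISS, M7-M9 DRSM, M10-M12 DISM.  Each drug-independent motif count
# contains its drug-related counterpart, so the counterpart is subtracted
# before the group sums I_j = A1+A2+A3, I_p = A4+A5+A6, I_i = A7+A8+A9,
# I_u = A10+A11+A12.  Row d of an incidence matrix is the drug-d-centred
# hyperedge (all hyperedge weights are 1; degrees are row sums).
#
# Everything here is integer arithmetic; floats first appear in the encoder.

.motif_requires <- list(
  `1` = "S", `2` = c("Y", "S"), `3` = c("Y", "Z", "S"),
  `4` = "S", `5` = "Y", `6` = c("Y", "Z"),
  `7` = c("W", "S"), `8` = c("G", "S"), `9` = c("V", "S"),
  `10` = "W", `11` = "G", `12` = "V"
)

.motif_group <- c(rep("DRSS", 3), rep("DISS", 3), rep("DRSM", 3), rep("DISM", 3))

#' Motif-induced adjacency matrix
#'
#' Computes the drug-by-drug co-occurrence count matrix of one of the twelve
#' anchored motifs by its closed-form matrix expression, with the diagonal
#' zeroed (the two anchor drugs must differ).  Returns `NULL` when a matrix
#' the motif requires is absent from the network view, so group sums can
#' skip the motif.
#'
#' @param dsmn a `dsmn` network (typically a [train_view()]).
#' @param k motif index, 1 to 12.
#' @return symmetric non-negative integer matrix with zero diagonal, or
#'   `NULL` if the motif is unavailable.
#' @export
motif_adjacency <- function(dsmn, k) {
  stopifnot(k %in% 1:12)
  need <- .motif_requires[[as.character(k)]]
  have <- !vapply(dsmn[need], is.null, logical(1))
  if (!all(have)) return(NULL)
  S <- dsmn$S; Y <- dsmn$Y; Z <- dsmn$Z
  A <- switch(as.character(k),
    `1` = (S %*% S) * S,
    `2` = tcrossprod(Y) * S,
    `3` = { Am <- (Y %*% Z %*% t(Y)) * S; Am + t(Am) },
    `4` = S %*% S,
    `5` = tcrossprod(Y),
    `6` = { Am <- Y %*% Z %*% t(Y); Am + t(Am) },
    `7` = tcrossprod(dsmn$W) * S,
    `8` = tcrossprod(dsmn$G) * S,
    `9` = tcrossprod(dsmn$V) * S,
    `10` = tcrossprod(dsmn$W),
    `11` = tcrossprod(dsmn$G),
    `12` = tcrossprod(dsmn$V)
  )
  diag(A) <- 0L
  mode(A) <- "integer"
  A
}

#' Remove drug-related motif counts from a drug-independent motif matrix
#'
#' Each drug-independent motif instance whose anchor drugs are also directly
#' linked is counted again by the corresponding drug-related motif; the
#' related counts are subtracted so the two matrices partition the instances.
#' The difference is non-negative by construction (the related matrix is the
#' independent one masked by the binary S); a negative entry indicates an
#' internal inconsistency and raises an error.
#'
#' @param independent,related count matrices of the paired motifs (e.g. A4
#'   and A1).
#' @return integer matrix `independent - related`.
#' @export
subtract_redundancy <- function(independent, related) {
  stopifnot(identical(dim(independent), dim(related)))
  out <- independent - related
  if (any(out < 0L)) {
    stop("internal consistency error: negative motif count after redundancy subtraction")
  }
  out
}

#' Build the four branch incidence matrices
#'
#' Sums the motif adjacency matrices of each motif group (after redundancy
#' subtraction for the drug-independent groups) into the hypergraph incidence
#' matrices I_j (DRSS), I_p (DISS), I_i (DRSM), I_u (DISM), together with
#' their degree vectors (row sums).  Motifs whose required matrices are
#' absent are skipped; a group with no available motif yields a disabled
#' branch.
#'
#' @param dsmn a `dsmn` network view.
#' @return object of class `branch_incidence`: list with `I` (named list of
#'   the four matrices, `NULL` when disabled), `deg` (row-sum vectors),
#'   `contributing` (motif indices per branch) and `enabled` (named logical).
#' @export
build_branch_incidences <- function(dsmn) {
  A <- lapply(1:12, function(k) motif_adjacency(dsmn, k))
  # redundancy: independent motif minus its related counterpart (4,1) ... (12,9)
  for (pair in list(c(4L, 1L), c(5L, 2L), c(6L, 3L),
                    c(10L, 7L), c(11L, 8L), c(12L, 9L))) {
    if (!is.null(A[[pair[1L]]]) && !is.null(A[[pair[2L]]])) {
      A[[pair[1L]]] <- subtract_redundancy(A[[pair[1L]]], A[[pair[2L]]])
    }
  }
  groups <- list(j = 1:3, p = 4:6, i = 7:9, u = 10:12)
  I <- lapply(groups, function(ks) {
    avail <- ks[!vapply(A[ks], is.null, logical(1))]
    if (!length(avail)) return(NULL)
    Reduce(`+`, A[avail])
  })
  contributing <- lapply(groups, function(ks) ks[!vapply(A[ks], is.null, logical(1))])
  deg <- lapply(I, function(m) if (is.null(m)) NULL else rowSums(m))
  structure(list(I = I, deg = deg, contributing = contributing,
                 enabled = !vapply(I, is.null, logical(1))),
            class = "branch_incidence")
}

#' @export
print.branch_incidence <- function(x, ...) {
  cat("Motif-driven hypergraph incidences:\n")
  for (nm in names(x$I)) {
    if (is.null(x$I[[nm]])) {
      cat(sprintf("  I_%s: disabled (no available motif)\n", nm))
    } else {
      cat(sprintf("  I_%s: motifs {%s}, %d nonzero entries\n", nm,
                  paste(x$contributing[[nm]], collapse = ","),
                  sum(x$I[[nm]] > 0)))
    }
  }
  invisible(x)
}

#' Brute-force motif instance counting (test oracle)
#'
#' Counts anchored motif instances by exhaustive enumeration over the typed
#' node tuples of the motif pattern, independently of the matrix algebra of
#' [motif_adjacency()].  Intended for small networks only.
#'
#' @param dsmn a `dsmn` network view with at most ~15 nodes per type.
#' @param k motif index, 1 to 12.
#' @return the anchored co-occurrence count matrix, or `NULL` if matrices the
#'   motif requires are absent.
#' @export
brute_force_motif_count <- function(dsmn, k) {
  stopifnot(k %in% 1:12)
  need <- .motif_requires[[as.character(k)]]
  if (any(vapply(dsmn[need], is.null, logical(1)))) return(NULL)
  S <- dsmn$S; Y <- dsmn$Y; Z <- dsmn$Z
  B <- switch(as.character(k), `7` = , `10` = dsmn$W,
              `8` = , `11` = dsmn$G, `9` = , `12` = dsmn$V)
  b <- if (!is.null(S)) nrow(S) else nrow(Y)
  if (b > 15L) stop("brute-force counting is limited to small networks")
  A <- matrix(0L, b, b)
  masked <- k %in% c(1:3, 7:9)
  for (i in seq_len(b)) for (j in seq_len(b)) {
    if (i == j) next
    if (masked && S[i, j] == 0L) next
    cnt <- 0L
    if (k %in% c(1L, 4L)) {
      # triangle through a third drug: i - m - j (S walk of length 2)
      for (m in seq_len(b)) if (S[i, m] == 1L && S[m, j] == 1L) cnt <- cnt + 1L
    } else if (k %in% c(2L, 5L)) {
      # shared first-level fragment
      for (f in seq_len(ncol(Y))) if (Y[i, f] == 1L && Y[j, f] == 1L) cnt <- cnt + 1L
    } else if (k %in% c(3L, 6L)) {
      # quadrilateral through a fragment -> child-fragment cleavage, both
      # orientations (i over the parent, or j over the parent)
      for (f1 in seq_len(ncol(Y))) for (f2 in seq_len(ncol(Y))) {
        if (Z[f1, f2] == 1L) {
          if (Y[i, f1] == 1L && Y[j, f2] == 1L) cnt <- cnt + 1L
          if (Y[j, f1] == 1L && Y[i, f2] == 1L) cnt <- cnt + 1L
        }
      }
    } else {
      # shared interaction partner in a bipartite molecular network
      for (e in seq_len(ncol(B))) if (B[i, e] == 1L && B[j, e] == 1L) cnt <- cnt + 1L
    }
    A[i, j] <- cnt
  }
  A
}
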