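# Recursive BRICS fragmentation of drug SMILES.
#
# Drugs are cleaved at BRICS (retrosynthetically interesting) bonds into
# functional-group fragments, and each fragment is cleaved again until no
# BRICS bond remains.  The recursion yields two directed networks: drug ->
# first-level fragment (DFI) and parent fragment -> child fragment (FFI).
# The chemistry primitives (bond perception, cleavage, canonicalization) are
# delegated to RDKit through a small batch helper; the recursion, fragment
# deduplication and edge assembly live here.
#
# Fragment identity is the canonical SMILES after rewriting every attachment
# dummy atom to a single generic [*] label, so that chemically identical
# functional groups arising from different cleavage contexts merge into one
# node.

.hg_cache <- new.env(parent = emptyenv())

.python_bin <- function() {
  p <- getOption("hgdrug.python", Sys.which("python"))
  if (!nzchar(p)) stop("no 'python' interpreter found on the PATH")
  p
}

.brics_helper <- function() {
  f <- system.file("python", "brics_helper.py", package = "hgdrug")
  if (!nzchar(f)) stop("brics_helper.py not found in the installed package")
  f
}

# One batched call to the RDKit helper.  mode: "canon" or "step".
# Returns a list with elements canon (chr), children (list of chr), error (chr
# or NA) aligned with `smiles`.
.brics_call <- function(mode, smiles) {
  stopifnot(mode %in% c("canon", "step"))
  n <- length(smiles)
  out <- list(canon = rep(NA_character_, n),
              children = rep(list(character(0)), n),
              error = rep(NA_character_, n))
  if (n == 0L) return(out)
  bad <- !nzchar(trimws(smiles))
  out$error[bad] <- "empty SMILES string"
  todo <- which(!bad)
  if (!length(todo)) return(out)
  fin <- tempfile(fileext = ".tsv"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(todo, smiles[todo], sep = "\t"), fin)
  status <- system2(.python_bin(), c(.brics_helper(), mode, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) {
    stop("RDKit helper failed (exit status ", status, ")")
  }
  for (ln in readLines(fout)) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    i <- as.integer(parts[[1L]])
    if (length(parts) >= 2L && identical(parts[[2L]], "ERROR")) {
      out$error[i] <- if (length(parts) >= 3L) parts[[3L]] else "parse error"
    } else if (mode == "canon") {
      out$canon[i] <- parts[[2L]]
    } else {
      out$canon[i] <- parts[[2L]]
      kids <- if (length(parts) >= 3L && nzchar(parts[[3L]]))
        strsplit(parts[[3L]], " ", fixed = TRUE)[[1L]] else character(0)
      out$children[[i]] <- kids
    }
  }
  out
}

# Cached one-step decomposition keyed by the (labelled) SMILES string.
.brics_step_cached <- function(smiles) {
  key <- paste0("s\r", smiles)
  hit <- vapply(key, exists, logical(1), envir = .hg_cache)
  if (any(!hit)) {
    res <- .brics_call("step", smiles[!hit])
    miss <- which(!hit)
    for (j in seq_along(miss)) {
      assign(key[miss[j]],
             list(canon = res$canon[j], children = res$children[[j]],
                  error = res$error[j]),
             envir = .hg_cache)
    }
  }
  lapply(key, get, envir = .hg_cache)
}

#' One-level BRICS decomposition of a molecule
#'
#' Breaks every BRICS-cleavable bond of the input molecule one at a time and
#' returns the resulting fragment SMILES (with numbered attachment points, as
#' produced by the BRICS rule set).  A molecule without any BRICS-cleavable
#' bond is returned unchanged as a single canonicalized fragment.
#'
#' @param smiles a single SMILES string.
#' @return character vector of fragment SMILES.
#' @examples
#' \dontrun{
#' brics_decompose("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
#' brics_decompose("CCO")                    # no cleavable bond -> itself
#' }
#' @export
brics_decompose <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  res <- .brics_step_cached(smiles)[[1L]]
  if (!is.na(res$error)) {
    stop("cannot parse SMILES '", smiles, "': ", res$error)
  }
  if (length(res$children) == 0L) res$canon else res$children
}

#' Canonicalize a fragment SMILES
#'
#' Produces a deterministic canonical SMILES in which every attachment dummy
#' atom is rewritten to the generic `[*]` label, so chemically identical
#' fragments arising from different cleavage contexts compare equal.
#' Canonicalization is idempotent.
#'
#' @param fragment_smiles character vector of fragment SMILES (may contain
#'   `[n*]` attachment dummies).
#' @return character vector of canonical SMILES.
#' @export
canonicalize_fragment <- function(fragment_smiles) {
  stopifnot(is.character(fragment_smiles))
  if (!length(fragment_smiles)) return(character(0))
  res <- .brics_call("canon", fragment_smiles)
  bad <- !is.na(res$error)
  if (any(bad)) {
    stop("cannot parse fragment SMILES: ",
         paste(sprintf("'%s' (%s)", fragment_smiles[bad], res$error[bad]),
               collapse = "; "))
  }
  res$canon
}

#' Recursive BRICS decomposition of a drug table
#'
#' Performs a breadth-first recursive BRICS decomposition of every drug until
#' all leaf fragments are indivisible.  Intermediate (still divisible)
#' fragments are kept as network nodes so the cleavage provenance between
#' fragments is retained.  Emits the drug-fragment (DFI) edges, which link a
#' drug to its first-level fragments, and the fragment-fragment (FFI) edges,
#' which link a parent fragment to each fragment produced by cleaving it.
#' A drug without any BRICS-cleavable bond contributes itself as its single
#' fragment.
#'
#' @param drugs data frame with columns `drug_id` (unique character ids) and
#'   `smiles`.
#' @return object of class `fragmentation` with components
#'   \item{fragments}{data frame `fragment_id`, `canonical_smiles`,
#'     `divisible`, ordered by canonical SMILES}
#'   \item{dfi}{data frame `drug_id`, `fragment_id` (directed drug->fragment)}
#'   \item{ffi}{data frame `parent_id`, `child_id` (directed parent->child)}
#' @export
recursive_decompose <- function(drugs) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  drugs$drug_id <- as.character(drugs$drug_id)
  drugs$smiles <- as.character(drugs$smiles)
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicated drug_id: ",
         paste(unique(drugs$drug_id[duplicated(drugs$drug_id)]), collapse = ", "))
  }

  # fail fast: validate every drug before producing any output
  root <- .brics_step_cached(drugs$smiles)
  bad <- vapply(root, function(r) !is.na(r$error), logical(1))
  if (any(bad)) {
    stop("unparseable SMILES for drug(s): ",
         paste(drugs$drug_id[bad], collapse = ", "))
  }

  canon_of <- new.env(parent = emptyenv())   # labelled smiles -> canon
  children_of <- new.env(parent = emptyenv()) # labelled smiles -> labelled kids
  record <- function(labelled, res) {
    for (j in seq_along(labelled)) {
      assign(labelled[[j]], res[[j]]$canon, envir = canon_of)
      assign(paste0("k\r", labelled[[j]]), res[[j]]$children, envir = children_of)
    }
  }
  record(drugs$smiles, root)

  # first-level fragments per drug: cleavage children, or the drug itself
  first_level <- lapply(seq_len(nrow(drugs)), function(i) {
    kids <- root[[i]]$children
    if (length(kids)) kids else drugs$smiles[[i]]
  })

  frontier <- setdiff(unique(unlist(first_level)), drugs$smiles)
  while (length(frontier)) {
    res <- .brics_step_cached(frontier)
    err <- vapply(res, function(r) !is.na(r$error), logical(1))
    if (any(err)) {
      stop("internal error: BRICS produced unparseable fragment(s): ",
           paste(frontier[err], collapse = ", "))
    }
    record(frontier, res)
    kids <- unique(unlist(lapply(res, `[[`, "children")))
    frontier <- kids[!vapply(kids, exists, logical(1), envir = canon_of)]
  }

  labelled <- setdiff(ls(canon_of), character(0))
  # nodes are fragments only: drugs that were cleaved are not fragment nodes,
  # but an uncleavable drug is its own single fragment
  frag_labelled <- unique(c(unlist(first_level),
                            unlist(mget(paste0("k\r", labelled),
                                        envir = children_of,
                                        ifnotfound = list(character(0))))))
  frag_canon <- vapply(frag_labelled, get, character(1), envir = canon_of)
  divis <- vapply(frag_labelled, function(s)
    length(get(paste0("k\r", s), envir = children_of)) > 0L, logical(1))
  # a canonical fragment is divisible if any labelled variant of it is
  divisible_by_canon <- tapply(divis, frag_canon, any)

  canon_sorted <- sort(unique(frag_canon), method = "radix")
  frag_id <- stats::setNames(seq_along(canon_sorted), canon_sorted)

  fragments <- data.frame(
    fragment_id = unname(frag_id),
    canonical_smiles = canon_sorted,
    divisible = unname(divisible_by_canon[canon_sorted]),
    stringsAsFactors = FALSE
  )

  dfi <- do.call(rbind, lapply(seq_len(nrow(drugs)), function(i) {
    ids <- sort(unique(unname(frag_id[vapply(first_level[[i]], get, character(1),
                                             envir = canon_of)])))
    data.frame(drug_id = drugs$drug_id[[i]], fragment_id = ids,
               stringsAsFactors = FALSE)
  }))

  ffi_pairs <- unique(do.call(rbind, lapply(frag_labelled, function(s) {
    kids <- get(paste0("k\r", s), envir = children_of)
    if (!length(kids)) return(NULL)
    cbind(parent = unname(frag_id[[get(s, envir = canon_of)]]),
          child = unname(frag_id[vapply(kids, get, character(1), envir = canon_of)]))
  })))
  if (is.null(ffi_pairs)) {
    ffi <- data.frame(parent_id = integer(0), child_id = integer(0))
  } else {
    keep <- ffi_pairs[, 1L] != ffi_pairs[, 2L]  # no self-loops
    ffi_pairs <- ffi_pairs[keep, , drop = FALSE]
    ord <- order(ffi_pairs[, 1L], ffi_pairs[, 2L])
    ffi <- data.frame(parent_id = ffi_pairs[ord, 1L],
                      child_id = ffi_pairs[ord, 2L])
  }
  rownames(dfi) <- NULL
  rownames(ffi) <- NULL

  structure(list(fragments = fragments, dfi = dfi, ffi = ffi,
                 drug_ids = drugs$drug_id),
            class = "fragmentation")
}

#' @export
print.fragmentation <- function(x, ...) {
  cat("BRICS fragmentation:", length(x$drug_ids), "drugs,",
      nrow(x$fragments), "fragments,", nrow(x$dfi), "DFI edges,",
      nrow(x$ffi), "FFI edges\n")
  invisible(x)
}

#' Read a drug table
#'
#' Reads a tab-separated table `drug_id<TAB>smiles` (UTF-8, `#` comments and
#' blank lines ignored).
#'
#' @param path file path.
#' @return data frame with columns `drug_id`, `smiles`.
#' @export
read_drug_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    stop("malformed drug table line(s): ", paste(which(nf < 2L), collapse = ", "))
  }
  out <- data.frame(drug_id = vapply(parts, `[[`, character(1), 1L),
                    smiles = vapply(parts, `[[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$drug_id)) {
    stop("duplicated drug_id in ", path)
  }
  out
}

#' Write fragmentation results as TSV files
#'
#' Writes `fragments.tsv` (`fragment_id<TAB>canonical_smiles`), `dfi.tsv`
#' (`drug_id<TAB>fragment_id`) and `ffi.tsv`
#' (`parent_fragment_id<TAB>child_fragment_id`) into `dir`.
#'
#' @param x a `fragmentation` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_fragmentation <- function(x, dir) {
  stopifnot(inherits(x, "fragmentation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("fragments.tsv", "dfi.tsv", "ffi.tsv"))
  utils::write.table(x$fragments[c("fragment_id", "canonical_smiles")], paths[1],
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(x$dfi, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(x$ffi, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
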