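# Recursive BRICS fragmentation: one-step cleavage, canonicalization and the
# recursive driver, checked against an independently coded recursive Python
# driver over the same BRICS rule set.

run_oracle <- function(drugs) {
  fin <- tempfile(fileext = ".tsv")
  writeLines(paste(drugs$drug_id, drugs$smiles, sep = "\t"), fin)
  out <- system2(Sys.which("python"),
                 c(test_path("oracle_brics.py"), fin), stdout = TRUE)
  parts <- strsplit(out, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1L)
  list(
    frags = sort(vapply(parts[kind == "FRAG"], `[[`, character(1), 2L)),
    dfi = sort(vapply(parts[kind == "DFI"], function(p) paste(p[2L], p[3L]), character(1))),
    ffi = sort(vapply(parts[kind == "FFI"], function(p) paste(p[2L], p[3L]), character(1)))
  )
}

frag_as_strings <- function(res) {
  id2smi <- res$fragments$canonical_smiles
  list(frags = sort(res$fragments$canonical_smiles),
       dfi = sort(paste(res$dfi$drug_id, id2smi[res$dfi$fragment_id])),
       ffi = sort(paste(id2smi[res$ffi$parent_id], id2smi[res$ffi$child_id])))
}

test_that("one-step decomposition handles uncleavable, cleavable and bad input", {
  expect_equal(brics_decompose("CCO"), "CCO")
  expect_error(brics_decompose(""), "parse")
  expect_error(brics_decompose("not_a_smiles"), "not_a_smiles")
  # aspirin: fragment multiset must equal the reference one-pass decomposition
  ref <- system2(Sys.which("python"), c("-c", shQuote(paste0(
    "from rdkit import Chem\nfrom rdkit.Chem import BRICS\n",
    "m=Chem.MolFromSmiles('CC(=O)Oc1ccccc1C(=O)O')\n",
    "s=set(BRICS.BRICSDecompose(m,singlePass=True)); s.discard(Chem.MolToSmiles(m))\n",
    "print('\\n'.join(sorted(Chem.MolToSmiles(Chem.MolFromSmiles(x)) for x in s)))"))),
    stdout = TRUE)
  expect_setequal(brics_decompose("CC(=O)Oc1ccccc1C(=O)O"), ref)
})

test_that("fragment canonicalization is idempotent and label-independent", {
  frs <- c("[1*]C(C)=O", "[16*]c1ccccc1", "[3*]OC(C)=O", "CCO")
  canon1 <- canonicalize_fragment(frs)
  expect_equal(canonicalize_fragment(canon1), canon1)
  # two attachment-label variants of the same fragment merge
  expect_equal(canonicalize_fragment("[3*]OC(C)=O"),
               canonicalize_fragment("[14*]OC(C)=O"))
  expect_error(canonicalize_fragment("(((("), "parse")
})

test_that("recursive decomposition: degenerate and duplicate drugs", {
  one <- recursive_decompose(data.frame(drug_id = "d1", smiles = "CCO"))
  expect_equal(nrow(one$fragments), 1L)
  expect_equal(nrow(one$dfi), 1L)
  expect_equal(nrow(one$ffi), 0L)
  expect_false(one$fragments$divisible)

  two <- recursive_decompose(data.frame(drug_id = c("a", "b"),
                                        smiles = rep("CC(=O)Oc1ccccc1C(=O)O", 2)))
  a <- two$dfi$fragment_id[two$dfi$drug_id == "a"]
  b <- two$dfi$fragment_id[two$dfi$drug_id == "b"]
  expect_identical(sort(a), sort(b))

  expect_error(recursive_decompose(data.frame(drug_id = c("x", "y"),
                                              smiles = c("CCO", "??"))), "y")
  expect_error(recursive_decompose(data.frame(drug_id = c("x", "x"),
                                              smiles = c("CCO", "CCN"))),
               "duplicated")
})

test_that("recursive decomposition matches the independent recursive driver", {
  drugs <- data.frame(
    drug_id = c("asp", "benz", "eth"),
    smiles = c("CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1C(=O)NCCO", "CCO"))
  got <- frag_as_strings(recursive_decompose(drugs))
  want <- run_oracle(drugs)
  expect_identical(got$frags, want$frags)
  expect_identical(got$dfi, want$dfi)
  expect_identical(got$ffi, want$ffi)
})

test_that("decomposition is deterministic and monotone under added drugs", {
  drugs <- make_toy_smiles(2L, 3L, seed = 4L)
  r1 <- recursive_decompose(drugs)
  r2 <- recursive_decompose(drugs)
  expect_identical(r1, r2)
  # adding a drug never removes fragments or edges contributed by others
  more <- rbind(drugs, data.frame(drug_id = "extra", smiles = "c1ccsc1C(=O)NCCN"))
  r3 <- frag_as_strings(recursive_decompose(more))
  r1s <- frag_as_strings(r1)
  expect_true(all(r1s$frags %in% r3$frags))
  expect_true(all(r1s$dfi %in% r3$dfi))
  expect_true(all(r1s$ffi %in% r3$ffi))
  # decomposing any leaf again yields only itself
  leaves <- r1$fragments$canonical_smiles[!r1$fragments$divisible]
  for (s in utils::head(leaves, 3L)) {
    expect_equal(brics_decompose(s), canonicalize_fragment(s))
  }
})

test_that("drug table round trip and fragmentation output files", {
  drugs <- make_toy_smiles(2L, 2L, seed = 9L)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# comment", paste(drugs$drug_id, drugs$smiles, sep = "\t")), path)
  back <- read_drug_table(path)
  expect_equal(back$drug_id, drugs$drug_id)
  res <- recursive_decompose(back)
  dir <- tempfile()
  write_fragmentation(res, dir)
  expect_true(all(file.exists(file.path(dir, c("fragments.tsv", "dfi.tsv", "ffi.tsv")))))
  dfi <- utils::read.table(file.path(dir, "dfi.tsv"), sep = "\t")
  expect_setequal(dfi$V1, drugs$drug_id)
})
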