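"""Independent recursive BRICS decomposition driver (test oracle).

Recursively decomposes each input molecule depth-first in Python, entirely
independently of the package's R breadth-first driver, and prints the
resulting node and edge sets:

  FRAG<TAB>canonical
  DFI<TAB>drug_id<TAB>canonical
  FFI<TAB>parent_canonical<TAB>child_canonical

Input: TSV `drug_id<TAB>smiles`.  Canonical ids normalise attachment dummies
to a generic [*].
"""
import sys

from rdkit import Chem
from rdkit.Chem import BRICS
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def canon(mol):
    m = Chem.Mol(mol)
    for a in m.GetAtoms():
        if a.GetAtomicNum() == 0:
            a.SetIsotope(0)
            a.SetAtomMapNum(0)
    return Chem.MolToSmiles(m)


def children(smiles):
    mol = Chem.MolFromSmiles(smiles)
    own = Chem.MolToSmiles(mol)
    kids = set(BRICS.BRICSDecompose(mol, singlePass=True))
    kids.discard(own)
    kids.discard(smiles)
    out = set()
    for k in kids:
        km = Chem.MolFromSmiles(k)
        if km is not None:
            out.add(Chem.MolToSmiles(km))
    return sorted(out)


def main():
    fin = sys.argv[1]
    frags = set()
    dfi = set()
    ffi = set()
    seen = {}

    def decompose(smiles):
        """DFS; returns canonical id, populating ffi below this node."""
        if smiles in seen:
            return seen[smiles]
        cid = canon(Chem.MolFromSmiles(smiles))
        seen[smiles] = cid
        for kid in children(smiles):
            frags.add(canon(Chem.MolFromSmiles(kid)))
            kc = decompose(kid)
            if kc != cid:
                ffi.add((cid, kc))
        return cid

    with open(fin) as fh:
        for ln in fh:
            if not ln.strip() or ln.startswith("#"):
                continue
            drug_id, smiles = ln.rstrip("\n").split("\t")[:2]
            mol = Chem.MolFromSmiles(smiles)
            kids = children(smiles)
            if kids:
                for k in kids:
                    kc = canon(Chem.MolFromSmiles(k))
                    frags.add(kc)
                    dfi.add((drug_id, kc))
                    decompose(k)
            else:
                cid = canon(mol)
                frags.add(cid)
                dfi.add((drug_id, cid))

    for f in sorted(frags):
        print("FRAG\t" + f)
    for d, f in sorted(dfi):
        print("DFI\t%s\t%s" % (d, f))
    for p, c in sorted(ffi):
        print("FFI\t%s\t%s" % (p, c))


if __name__ == "__main__":
    main()
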