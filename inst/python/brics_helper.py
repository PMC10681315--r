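"""Batch helper exposing RDKit BRICS primitives over a simple TSV protocol.

Usage: python brics_helper.py <mode> <in.tsv> <out.tsv>

Modes
  canon : in lines `idx<TAB>smiles`; out `idx<TAB>canonical`
          (attachment dummy labels normalised to a single generic [*]).
  step  : in lines `idx<TAB>smiles`; out `idx<TAB>canonical<TAB>child1 child2 ...`
          children are the one-level BRICS cleavage products (labelled canonical
          SMILES, space separated; empty field when no BRICS bond is cleavable).

Parse failures are reported as `idx<TAB>ERROR<TAB>message`; the caller decides
whether that is fatal.
"""
import sys

from rdkit import Chem
from rdkit.Chem import BRICS
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")


def normalised_canonical(mol):
    """Canonical SMILES with every attachment dummy reduced to a generic [*]."""
    m = Chem.Mol(mol)
    for atom in m.GetAtoms():
        if atom.GetAtomicNum() == 0:
            atom.SetIsotope(0)
            atom.SetAtomMapNum(0)
    return Chem.MolToSmiles(m)


def one_step(mol, smiles):
    """One-level BRICS cleavage: every product of breaking a single BRICS bond.

    RDKit's singlePass decomposition returns the input molecule together with
    both pieces of each single-bond cleavage; dropping the input leaves exactly
    the first-level children.
    """
    own = Chem.MolToSmiles(mol)
    pieces = set(BRICS.BRICSDecompose(mol, singlePass=True))
    pieces.discard(own)
    pieces.discard(smiles)
    # keep labelled canonical form: labels are needed for further cleavage
    out = set()
    for p in pieces:
        pm = Chem.MolFromSmiles(p)
        if pm is not None:
            out.add(Chem.MolToSmiles(pm))
    return sorted(out)


def main():
    mode, fin, fout = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(fin) as fh:
        lines = [ln.rstrip("\n") for ln in fh if ln.strip()]
    out = []
    for ln in lines:
        idx, smi = ln.split("\t", 1)
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append("%s\tERROR\tunparseable SMILES: %s" % (idx, smi))
            continue
        if mode == "canon":
            out.append("%s\t%s" % (idx, normalised_canonical(mol)))
        elif mode == "step":
            kids = one_step(mol, smi)
            out.append("%s\t%s\t%s" % (idx, normalised_canonical(mol), " ".join(kids)))
        else:
            sys.exit("unknown mode: " + mode)
    with open(fout, "w") as fh:
        fh.write("\n".join(out) + ("\n" if out else ""))


if __name__ == "__main__":
    main()
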