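"""Seeded distance-geometry embedding: SMILES + seed -> single-conformer SDF
on stdout. ETKDGv3 with a fixed random seed, then MMFF94 relaxation, so the
output is deterministic per (SMILES, seed)."""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem


def main():
    smiles, seed = sys.argv[1], int(sys.argv[2])
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        sys.stderr.write("parse_error\n")
        return 2
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    cid = AllChem.EmbedMolecule(mol, params)
    if cid < 0:
        sys.stderr.write("embed_error\n")
        return 3
    try:
        AllChem.MMFFOptimizeMolecule(mol, maxIters=500)
    except Exception:
        pass
    sys.stdout.write(Chem.MolToMolBlock(mol, kekulize=True))
    sys.stdout.write("$$$$\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
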