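"""Feature-class circular fingerprints (FCFP-style) as on-bit lists.

Reads "id<TAB>smiles" lines on stdin; writes "id<TAB>b1,b2,..." (0-based
on-bit indices) or "id<TAB>ERROR" for unparseable structures.
Usage: python fcfp_bits.py <radius> <n_bits>
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

radius = int(sys.argv[1])
n_bits = int(sys.argv[2])

for line in sys.stdin:
    line = line.rstrip("\n")
    if not line:
        continue
    cid, _, smi = line.partition("\t")
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        print(f"{cid}\tERROR")
        continue
    fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(
        mol, radius, nBits=n_bits, useFeatures=True)
    print(cid + "\t" + ",".join(str(b) for b in fp.GetOnBits()))
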