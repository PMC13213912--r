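#!/usr/bin/env python
"""Batch molecular descriptor backend.

Reads SMILES (one molecule per line, optional second tab-separated column
kept as an external id), parses with RDKit, and writes a TSV with the
requested descriptor blocks:

  mqn   -- the 42 MQN (molecular quantum numbers) integer counts
  ecfp  -- ECFP4 (Morgan radius 2) folded fingerprint, emitted as the
           space-separated sorted list of on-bit indices
  panel -- MW, HAC, rings, RBC, HBD, HBA, TPSA, FCsp3, aromatic_atoms

Unparseable lines are kept in the output with valid=0 and empty
descriptor fields; they are never fatal.
"""
import argparse
import gzip
import sys


def open_maybe_gz(path):
    if path.endswith(".gz"):
        return gzip.open(path, "rt")
    return open(path, "r")


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("input")
    ap.add_argument("output")
    ap.add_argument("--what", default="mqn",
                    help="comma-separated subset of mqn,ecfp,panel")
    ap.add_argument("--n-bits", type=int, default=2048)
    args = ap.parse_args()

    from rdkit import Chem, RDLogger
    from rdkit.Chem import Descriptors, rdMolDescriptors
    RDLogger.DisableLog("rdApp.*")

    what = set(args.what.split(","))
    n_bits = args.n_bits

    header = ["index", "ext_id", "valid", "canonical_smiles"]
    if "mqn" in what:
        header += ["mqn%02d" % i for i in range(1, 43)]
    if "panel" in what:
        header += ["MW", "HAC", "rings", "RBC", "HBD", "HBA",
                   "TPSA", "FCsp3", "aromatic_atoms"]
    if "ecfp" in what:
        header += ["ecfp_bits"]

    n_in = 0
    n_bad = 0
    with open_maybe_gz(args.input) as fin, open(args.output, "w") as fout:
        fout.write("\t".join(header) + "\n")
        for i, line in enumerate(fin):
            line = line.rstrip("\n").rstrip("\r")
            if line.strip() == "":
                continue
            n_in += 1
            parts = line.split("\t")
            smi = parts[0].strip()
            ext_id = parts[1].strip() if len(parts) > 1 else ""
            mol = Chem.MolFromSmiles(smi) if smi else None
            row = [str(i + 1), ext_id]
            if mol is None:
                n_bad += 1
                row += ["0", ""]
                pad = 0
                if "mqn" in what:
                    pad += 42
                if "panel" in what:
                    pad += 9
                row += [""] * pad
                if "ecfp" in what:
                    row += [""]
                fout.write("\t".join(row) + "\n")
                continue
            row += ["1", Chem.MolToSmiles(mol)]
            if "mqn" in what:
                row += [str(v) for v in rdMolDescriptors.MQNs_(mol)]
            if "panel" in what:
                row += ["%.6g" % Descriptors.MolWt(mol),
                        str(mol.GetNumHeavyAtoms()),
                        str(rdMolDescriptors.CalcNumRings(mol)),
                        str(rdMolDescriptors.CalcNumRotatableBonds(mol)),
                        str(rdMolDescriptors.CalcNumHBD(mol)),
                        str(rdMolDescriptors.CalcNumHBA(mol)),
                        "%.6g" % rdMolDescriptors.CalcTPSA(mol),
                        "%.6g" % rdMolDescriptors.CalcFractionCSP3(mol),
                        str(sum(1 for a in mol.GetAtoms()
                                if a.GetIsAromatic()))]
            if "ecfp" in what:
                fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(
                    mol, 2, nBits=n_bits)
                row += [" ".join(str(b) for b in fp.GetOnBits())]
            fout.write("\t".join(row) + "\n")

    sys.stderr.write("descriptors: %d molecules, %d unparseable\n"
                     % (n_in, n_bad))


if __name__ == "__main__":
    main()
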