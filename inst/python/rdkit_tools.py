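"""Batched RDKit back end for iriscreen.

Reads one JSON request object on stdin, writes one JSON response on stdout.
Requests: {"op": <name>, ...op-specific fields...}. Every per-molecule result
carries ok/error so the R side can report row-level failures.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

# Frozen 45-property list for the 'standard' representation. Order matters:
# the R side treats this as the feature-name contract.
STANDARD_DESCRIPTORS = [
    "MolWt", "ExactMolWt", "HeavyAtomMolWt", "HeavyAtomCount", "NumHeteroatoms",
    "NumValenceElectrons", "NumRadicalElectrons", "NumHDonors", "NumHAcceptors",
    "NHOHCount", "NOCount", "NumRotatableBonds", "RingCount", "NumAromaticRings",
    "NumAliphaticRings", "NumSaturatedRings", "NumAromaticCarbocycles",
    "NumAromaticHeterocycles", "NumAliphaticCarbocycles",
    "NumAliphaticHeterocycles", "NumSaturatedCarbocycles",
    "NumSaturatedHeterocycles", "FractionCSP3", "TPSA", "LabuteASA", "MolLogP",
    "MolMR", "BalabanJ", "BertzCT", "HallKierAlpha", "Kappa1", "Kappa2",
    "Kappa3", "Chi0", "Chi1", "Chi0n", "Chi1n", "Chi2n", "Chi0v", "Chi1v",
    "Chi2v", "qed", "FpDensityMorgan1", "FpDensityMorgan2", "FpDensityMorgan3",
]


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def op_canonical(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
        else:
            out.append({"ok": True, "canonical": Chem.MolToSmiles(m)})
    return {"results": out}


def op_descriptors(req):
    funcs = [getattr(Descriptors, n) for n in STANDARD_DESCRIPTORS]
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        vals = [float(f(m)) for f in funcs]
        out.append({"ok": True, "values": vals})
    return {"names": STANDARD_DESCRIPTORS, "results": out}


def _merged_rings(mol):
    """SSSR rings, merging rings that share more than two atoms."""
    rings = [set(r) for r in Chem.GetSymmSSSR(mol)]
    changed = True
    while changed:
        changed = False
        for i in range(len(rings)):
            for j in range(i + 1, len(rings)):
                if len(rings[i] & rings[j]) > 2:
                    rings[i] |= rings[j]
                    del rings[j]
                    changed = True
                    break
            if changed:
                break
    return rings


def _fragments(mol):
    """Clique decomposition: merged simple rings + every non-ring bond."""
    frags = []
    for ring in _merged_rings(mol):
        atoms = sorted(ring)
        bonds = [b.GetIdx() for b in mol.GetBonds()
                 if b.GetBeginAtomIdx() in ring and b.GetEndAtomIdx() in ring]
        frags.append(Chem.MolFragmentToSmiles(
            mol, atomsToUse=atoms, bondsToUse=bonds, canonical=True))
    for b in mol.GetBonds():
        if not b.IsInRing():
            atoms = [b.GetBeginAtomIdx(), b.GetEndAtomIdx()]
            frags.append(Chem.MolFragmentToSmiles(
                mol, atomsToUse=atoms, bondsToUse=[b.GetIdx()], canonical=True))
    return frags


def op_cliques(req):
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
        else:
            out.append({"ok": True, "fragments": _fragments(m)})
    return {"results": out}


def op_morgan(req):
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(req.get("radius", 2)), fpSize=int(req.get("n_bits", 2048)))
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
        else:
            out.append({"ok": True, "bits": sorted(gen.GetFingerprint(m).GetOnBits())})
    return {"results": out}


def op_embed(req):
    """Deterministic 3D embedding (ETKDGv3) used by the fixture generators."""
    seed = int(req.get("seed", 1))
    out = []
    for k, smi in enumerate(req["smiles"]):
        m = _mol(smi)
        if m is None:
            out.append({"ok": False, "error": "unparseable SMILES"})
            continue
        mh = Chem.AddHs(m)
        ps = AllChem.ETKDGv3()
        ps.randomSeed = (seed + 7919 * k) % (2 ** 31 - 1)
        cid = AllChem.EmbedMolecule(mh, ps)
        if cid < 0:
            ps.useRandomCoords = True
            cid = AllChem.EmbedMolecule(mh, ps)
        if cid < 0:
            out.append({"ok": False, "error": "embedding failed"})
            continue
        conf = mh.GetConformer(cid)
        elements = [a.GetSymbol() for a in mh.GetAtoms()]
        xyz = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
                conf.GetAtomPosition(i).z] for i in range(mh.GetNumAtoms())]
        out.append({"ok": True, "elements": elements, "xyz_angstrom": xyz})
    return {"results": out}


OPS = {
    "canonical": op_canonical,
    "descriptors": op_descriptors,
    "cliques": op_cliques,
    "morgan": op_morgan,
    "embed": op_embed,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"error": f"unknown op: {op}"}, sys.stdout)
        return 1
    json.dump(OPS[op](req), sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
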