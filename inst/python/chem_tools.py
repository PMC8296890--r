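"""Batch cheminformatics helper for the AlertAD R package.

Reads one JSON request on stdin, writes one JSON response on stdout.
Requests: {"op": <name>, ...}; every op is batch-oriented so R pays the
interpreter start-up cost once per screening run, not once per molecule.
"""
import json
import sys

from rdkit import Chem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

BENZENE = Chem.MolFromSmarts("c1ccccc1")


def _parse(smi):
    if not isinstance(smi, str) or smi == "":
        return None
    return Chem.MolFromSmiles(smi)


def op_canonicalize(req):
    """Canonical SMILES of the largest covalent fragment, stereo stripped."""
    out = []
    for smi in req["smiles"]:
        mol = _parse(smi)
        if mol is None:
            out.append({"ok": False, "smiles": None})
            continue
        frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
        # largest fragment by heavy-atom count; ties broken by canonical
        # SMILES so the choice is deterministic across runs
        best = max(frags, key=lambda f: (f.GetNumHeavyAtoms(),
                                         Chem.MolToSmiles(f)))
        Chem.RemoveStereochemistry(best)
        out.append({"ok": True, "smiles": Chem.MolToSmiles(best)})
    return {"results": out}


def op_validate_smarts(req):
    out = []
    for sma in req["smarts"]:
        patt = Chem.MolFromSmarts(sma) if isinstance(sma, str) else None
        out.append(bool(patt))
    return {"ok": out}


def op_match(req):
    """Boolean match matrix, molecules x patterns."""
    patts = []
    bad = []
    for i, sma in enumerate(req["smarts"]):
        patt = Chem.MolFromSmarts(sma)
        if patt is None:
            bad.append(i)
        patts.append(patt)
    if bad:
        return {"error": "unparsable SMARTS", "bad_smarts_index": bad}
    mol_ok = []
    matrix = []
    for smi in req["smiles"]:
        mol = _parse(smi)
        if mol is None:
            mol_ok.append(False)
            matrix.append([False] * len(patts))
        else:
            mol_ok.append(True)
            matrix.append([mol.HasSubstructMatch(p) for p in patts])
    return {"smiles_ok": mol_ok, "matches": matrix}


def _benzene_carbons(mol):
    idx = set()
    for match in mol.GetSubstructMatches(BENZENE):
        idx.update(match)
    return idx


def op_amine_classes(req):
    """Classify every nitrogen bonded to a benzene-ring carbon by H count."""
    out = []
    for smi in req["smiles"]:
        mol = _parse(smi)
        if mol is None:
            out.append({"ok": False, "n_h_counts": [],
                        "two_nh": False, "one_nh": False, "no_nh": False})
            continue
        ring_c = _benzene_carbons(mol)
        counts = []
        for atom in mol.GetAtoms():
            if atom.GetAtomicNum() != 7:
                continue
            if any(nb.GetIdx() in ring_c for nb in atom.GetNeighbors()):
                counts.append(atom.GetTotalNumHs())
        out.append({
            "ok": True,
            "n_h_counts": counts,
            "two_nh": any(c >= 2 for c in counts),
            "one_nh": any(c == 1 for c in counts),
            "no_nh": any(c == 0 for c in counts),
        })
    return {"results": out}


OPS = {
    "canonicalize": op_canonicalize,
    "validate_smarts": op_validate_smarts,
    "match": op_match,
    "amine_classes": op_amine_classes,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"error": "unknown op: %r" % op}, sys.stdout)
        return 1
    json.dump(OPS[op](req), sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
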