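"""Batched cheminformatics bridge.

Reads one JSON request from stdin and writes one JSON response to stdout.
Each request is {"op": <name>, ...}; molecules are passed as SMILES lists
and processed in a single interpreter launch so callers can batch.

Ops:
  canonical : {"smiles": [...]}                -> {"canonical": [...], "valid": [...]}
  fingerprint: {"smiles": [...], "type": "maccs"|"morgan",
                "radius": int, "nbits": int}   -> {"bits": [[...0-based...]|null]}
  fraggle   : {"queries": [...], "refs": [...]} -> {"sim": [...]}   (zipped pairs)
  sa_score  : {"smiles": [...]}                -> {"scores": [...]} (null = unparseable)
  murcko    : {"smiles": [...], "generic": bool} -> {"scaffold": [...]}
"""
import json
import os
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, MACCSkeys, RDConfig
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")


def _mol(smi):
    if smi is None:
        return None
    return Chem.MolFromSmiles(smi)


def op_canonical(req):
    canon, valid = [], []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            canon.append(None)
            valid.append(False)
        else:
            canon.append(Chem.MolToSmiles(m))
            valid.append(True)
    return {"canonical": canon, "valid": valid}


def op_fingerprint(req):
    kind = req.get("type", "maccs")
    bits = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            bits.append(None)
            continue
        if kind == "maccs":
            fp = MACCSkeys.GenMACCSKeys(m)
        elif kind == "morgan":
            fp = AllChem.GetMorganFingerprintAsBitVect(
                m, int(req.get("radius", 3)), nBits=int(req.get("nbits", 1024)))
        else:
            raise ValueError("unknown fingerprint type: %s" % kind)
        bits.append(list(fp.GetOnBits()))
    return {"bits": bits}


def op_fraggle(req):
    from rdkit.Chem.Fraggle import FraggleSim
    sims = []
    for q, r in zip(req["queries"], req["refs"]):
        mq, mr = _mol(q), _mol(r)
        if mq is None or mr is None:
            sims.append(None)
            continue
        try:
            sim, _ = FraggleSim.GetFraggleSimilarity(mq, mr)
        except Exception:
            sim = 0.0
        sims.append(sim)
    return {"sim": sims}


def op_sa_score(req):
    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer
    scores = []
    for smi in req["smiles"]:
        m = _mol(smi)
        scores.append(None if m is None else sascorer.calculateScore(m))
    return {"scores": scores}


def op_murcko(req):
    generic = bool(req.get("generic", False))
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        scaf = MurckoScaffold.GetScaffoldForMol(m)
        if generic:
            scaf = MurckoScaffold.MakeScaffoldGeneric(scaf)
        out.append(Chem.MolToSmiles(scaf))
    return {"scaffold": out}


OPS = {
    "canonical": op_canonical,
    "fingerprint": op_fingerprint,
    "fraggle": op_fraggle,
    "sa_score": op_sa_score,
    "murcko": op_murcko,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        raise SystemExit("unknown op: %r" % op)
    json.dump(OPS[op](req), sys.stdout)


if __name__ == "__main__":
    main()
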