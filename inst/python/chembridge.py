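#!/usr/bin/env python
"""Batch RDKit bridge for the sigenum R package.

Reads a JSON request file {"ops": [{"op": ..., ...}, ...]} and writes a JSON
response file {"results": [...]} with one result per op, in order.  All ops
are vectorized over lists of molecules so a single interpreter start can
serve an entire pipeline stage.

Ops
---
parse:          {"op":"parse", "smiles":[...]}
                -> per item: {ok, error?, smiles (canonical isomeric), mw,
                   n_frags, has_wildcard, n_unassigned_stereo,
                   atoms:[{element,charge,aromatic,nH}], bonds:[{a1,a2,order}]}
                Isotope labels are cleared before canonicalization.
fingerprint:    {"op":"fingerprint", "smiles":[...], "radius":2,
                 "nbits":2048, "chirality":true, "bitinfo":false}
                -> per item: {ok, counts:{"bit":count}, bitinfo?:
                   {"bit":[[atom,radius],...]}}
mol_from_graph: {"op":"mol_from_graph", "graphs":[{atoms,bonds},...]}
                -> per item: {ok, error?, smiles}
stereo_enum:    {"op":"stereo_enum", "smiles":[...], "max_isomers":N,
                 "only_unassigned":true}
                -> per item: {ok, isomers:[canonical smiles, ...] (sorted)}

Atom/bond conventions match the R side: bond order is one of "1","2","3",
"ar"; nH is the total hydrogen count of the heavy atom.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, rdFingerprintGenerator
from rdkit.Chem.EnumerateStereoisomers import (
    EnumerateStereoisomers,
    StereoEnumerationOptions,
)

RDLogger.DisableLog("rdApp.*")

BOND_OUT = {
    Chem.BondType.SINGLE: "1",
    Chem.BondType.DOUBLE: "2",
    Chem.BondType.TRIPLE: "3",
    Chem.BondType.AROMATIC: "ar",
}
BOND_IN = {v: k for k, v in BOND_OUT.items()}


def graph_of(mol):
    atoms = [
        {
            "element": a.GetSymbol(),
            "charge": a.GetFormalCharge(),
            "aromatic": bool(a.GetIsAromatic()),
            "nH": a.GetTotalNumHs(),
        }
        for a in mol.GetAtoms()
    ]
    bonds = [
        {
            "a1": b.GetBeginAtomIdx(),
            "a2": b.GetEndAtomIdx(),
            "order": BOND_OUT.get(b.GetBondType(), "1"),
        }
        for b in mol.GetBonds()
    ]
    return atoms, bonds


def op_parse(req):
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "parse_error"})
            continue
        has_wildcard = any(a.GetAtomicNum() == 0 for a in mol.GetAtoms())
        n_frags = len(Chem.GetMolFrags(mol))
        for a in mol.GetAtoms():
            a.SetIsotope(0)
        # re-canonicalize after isotope strip so equal graphs give equal text
        mol = Chem.MolFromSmiles(Chem.MolToSmiles(mol))
        if mol is None:
            out.append({"ok": False, "error": "parse_error"})
            continue
        unassigned = 0
        if not has_wildcard:
            si = Chem.FindPotentialStereo(mol)
            unassigned = sum(
                1 for e in si if str(e.specified) == "Unspecified"
            )
        atoms, bonds = graph_of(mol)
        out.append(
            {
                "ok": True,
                "smiles": Chem.MolToSmiles(mol),
                "mw": Descriptors.MolWt(mol),
                "n_frags": n_frags,
                "has_wildcard": has_wildcard,
                "n_unassigned_stereo": unassigned,
                "atoms": atoms,
                "bonds": bonds,
            }
        )
    return out


def op_fingerprint(req):
    radius = int(req.get("radius", 2))
    nbits = int(req.get("nbits", 2048))
    chirality = bool(req.get("chirality", True))
    want_bitinfo = bool(req.get("bitinfo", False))
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=radius, fpSize=nbits, includeChirality=chirality
    )
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "parse_error"})
            continue
        res = {"ok": True}
        if want_bitinfo:
            ao = rdFingerprintGenerator.AdditionalOutput()
            ao.AllocateBitInfoMap()
            fp = gen.GetCountFingerprint(mol, additionalOutput=ao)
            res["bitinfo"] = {
                str(b): [[a, r] for (a, r) in v]
                for b, v in ao.GetBitInfoMap().items()
            }
        else:
            fp = gen.GetCountFingerprint(mol)
        res["counts"] = {
            str(b): c for b, c in sorted(fp.GetNonzeroElements().items())
        }
        out.append(res)
    return out


def op_mol_from_graph(req):
    out = []
    for g in req["graphs"]:
        try:
            rw = Chem.RWMol()
            for at in g["atoms"]:
                a = Chem.Atom(at["element"])
                a.SetFormalCharge(int(at["charge"]))
                a.SetIsAromatic(bool(at["aromatic"]))
                a.SetNumExplicitHs(int(at["nH"]))
                a.SetNoImplicit(True)
                rw.AddAtom(a)
            for bd in g["bonds"]:
                rw.AddBond(int(bd["a1"]), int(bd["a2"]), BOND_IN[bd["order"]])
                if bd["order"] == "ar":
                    rw.GetBondBetweenAtoms(
                        int(bd["a1"]), int(bd["a2"])
                    ).SetIsAromatic(True)
            mol = rw.GetMol()
            Chem.SanitizeMol(mol)
            out.append({"ok": True, "smiles": Chem.MolToSmiles(mol)})
        except Exception as exc:  # invalid valence/kekulization -> reject
            out.append({"ok": False, "error": type(exc).__name__})
    return out


def op_stereo_enum(req):
    max_isomers = int(req.get("max_isomers", 0))
    only_unassigned = bool(req.get("only_unassigned", True))
    out = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append({"ok": False, "error": "parse_error"})
            continue
        opts = StereoEnumerationOptions(
            onlyUnassigned=only_unassigned,
            unique=True,
            maxIsomers=max_isomers,
        )
        isomers = sorted(
            {Chem.MolToSmiles(m) for m in EnumerateStereoisomers(mol, opts)}
        )
        out.append({"ok": True, "isomers": isomers})
    return out


OPS = {
    "parse": op_parse,
    "fingerprint": op_fingerprint,
    "mol_from_graph": op_mol_from_graph,
    "stereo_enum": op_stereo_enum,
}


def main(argv):
    if len(argv) != 3:
        sys.stderr.write("usage: chembridge.py request.json response.json\n")
        return 2
    with open(argv[1]) as fh:
        request = json.load(fh)
    results = [OPS[op["op"]](op) for op in request["ops"]]
    with open(argv[2], "w") as fh:
        json.dump({"results": results}, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
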