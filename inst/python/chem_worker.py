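"""Line-oriented JSON worker exposing RDKit perception to the R package.

One request per line on stdin, one JSON response per line on stdout.
All perception (sanitization, aromaticity, conjugation, ring info,
bridgehead/spiro, Morgan fingerprints, substructure matching) is delegated
to RDKit's default models; the RDKit version is reported via "ping" so runs
can log the perception model in use.
"""
import sys
import json
import itertools

from rdkit import Chem, rdBase
from rdkit.Chem import rdMolDescriptors, Lipinski, AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

# Fused 5-7 bicycle with C/N ring atoms, topology of azulene.  Conjugation of
# the matched ring bonds is checked separately (SMARTS cannot express it).
AZULENE_TOPOLOGY = Chem.MolFromSmarts(
    "[#6,#7]1~[#6,#7]~[#6,#7]2~[#6,#7]~[#6,#7]~[#6,#7]~[#6,#7]~[#6,#7]~[#6,#7]2~[#6,#7]1"
)

# Azulene numbering: positions 1-8 are the CH positions (1-3 five-ring,
# 4-8 seven-ring), 9 = C3a and 10 = C8a are the ring-fusion carbons.
# Kekule bond list (position_a, position_b, order).
AZULENE_BONDS = [
    (1, 2, 2), (2, 3, 1), (3, 9, 2), (9, 4, 1), (4, 5, 2), (5, 6, 1),
    (6, 7, 2), (7, 8, 1), (8, 10, 2), (10, 1, 1), (9, 10, 1),
]
BOND_TYPES = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE,
              3: Chem.BondType.TRIPLE}


def is_azulene_like(mol):
    for match in mol.GetSubstructMatches(AZULENE_TOPOLOGY, uniquify=True):
        atoms = set(match)
        ok = True
        for b in mol.GetBonds():
            if (b.GetBeginAtomIdx() in atoms and b.GetEndAtomIdx() in atoms
                    and b.IsInRing() and not b.GetIsConjugated()):
                ok = False
                break
        if ok:
            return True
    return False


def build_core(npos):
    """Azaazulene with N at the given IUPAC positions, CH elsewhere."""
    rw = Chem.RWMol()
    idx = {}
    for p in range(1, 11):
        idx[p] = rw.AddAtom(Chem.Atom("N" if p in npos else "C"))
    for a, b, o in AZULENE_BONDS:
        rw.AddBond(idx[a], idx[b], BOND_TYPES[o])
    mol = rw.GetMol()
    flagged = False
    try:
        Chem.SanitizeMol(mol)
    except Exception:
        # fall back to the localized Kekule form without aromaticity
        mol = rw.GetMol()
        Chem.SanitizeMol(mol, Chem.SanitizeFlags.SANITIZE_ALL
                         ^ Chem.SanitizeFlags.SANITIZE_SETAROMATICITY)
        flagged = True
    return mol, flagged


def attach_substituent(npos, sub_smiles, positions):
    """Same substituent bonded at both positions, replacing one H at each.

    The substituent's attachment point is its first atom; it must carry at
    least one implicit hydrogen (RDKit sanitization rejects the product
    otherwise, which is reported as an error)."""
    for p in positions:
        if p in npos:
            return None, "position %d carries a ring nitrogen" % p
    sub = Chem.MolFromSmiles(sub_smiles)
    if sub is None:
        return None, "unparsable substituent"
    try:
        Chem.Kekulize(sub, clearAromaticFlags=True)
    except Exception:
        return None, "substituent cannot be kekulized"
    rw = Chem.RWMol()
    idx = {}
    for p in range(1, 11):
        idx[p] = rw.AddAtom(Chem.Atom("N" if p in npos else "C"))
    for a, b, o in AZULENE_BONDS:
        rw.AddBond(idx[a], idx[b], BOND_TYPES[o])
    for p in positions:
        offset = rw.GetNumAtoms()
        rw.InsertMol(sub)
        rw.AddBond(idx[p], offset, Chem.BondType.SINGLE)
    mol = rw.GetMol()
    try:
        Chem.SanitizeMol(mol)
    except Exception as exc:
        return None, "sanitization failed: %s" % exc
    return Chem.MolToSmiles(mol), None


def describe_one(smi, forbidden):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return {"ok": False, "input": smi}
    heavy = mol.GetNumHeavyAtoms()
    if heavy == 0:
        return {"ok": False, "input": smi}
    arom = sum(1 for a in mol.GetAtoms() if a.GetIsAromatic())
    hh_bonds = mol.GetNumBonds()  # hydrogens are implicit: all bonds are heavy-heavy
    conj = (sum(1 for b in mol.GetBonds() if b.GetIsConjugated()) / hh_bonds
            if hh_bonds > 0 else 0.0)
    ri = mol.GetRingInfo()
    sizes = [len(r) for r in ri.AtomRings()]
    rec = {
        "ok": True,
        "input": smi,
        "canonical": Chem.MolToSmiles(mol),
        "heavy": heavy,
        "total_atoms": mol.GetNumAtoms() + sum(a.GetTotalNumHs() for a in mol.GetAtoms()),
        "charge": Chem.GetFormalCharge(mol),
        "radicals": sum(a.GetNumRadicalElectrons() for a in mol.GetAtoms()),
        "bridgehead": rdMolDescriptors.CalcNumBridgeheadAtoms(mol),
        "spiro": rdMolDescriptors.CalcNumSpiroAtoms(mol),
        "arom_deg": arom / heavy,
        "conj_deg": conj,
        "ring_min": min(sizes) if sizes else None,
        "ring_max": max(sizes) if sizes else None,
        "azulene_like": is_azulene_like(mol),
        "n_arom_n": sum(1 for a in mol.GetAtoms()
                        if a.GetSymbol() == "N" and a.GetIsAromatic() and a.IsInRing()),
        "h_donors": Lipinski.NumHDonors(mol),
        "forbidden_hit": False,
    }
    for patt in forbidden:
        if patt is not None and mol.HasSubstructMatch(patt):
            rec["forbidden_hit"] = True
            break
    return rec


def fingerprint_bits(smi, radius, nbits):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None
    fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=nbits)
    return list(fp.GetOnBits())


def graph_of(smi):
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return None
    if Chem.GetFormalCharge(mol) != 0:
        return None
    Chem.Kekulize(mol, clearAromaticFlags=True)
    order_num = {Chem.BondType.SINGLE: 1, Chem.BondType.DOUBLE: 2,
                 Chem.BondType.TRIPLE: 3}
    bonds = []
    for b in mol.GetBonds():
        o = order_num.get(b.GetBondType())
        if o is None:
            return None
        bonds.append([b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1, o])
    return {"atoms": [a.GetSymbol() for a in mol.GetAtoms()], "bonds": bonds}


def handle(req):
    op = req["op"]
    if op == "ping":
        return {"pong": True, "rdkit": rdBase.rdkitVersion}
    if op == "describe":
        forbidden = [Chem.MolFromSmarts(s) for s in req.get("forbidden", [])]
        return {"records": [describe_one(s, forbidden) for s in req["smiles"]]}
    if op == "fingerprint":
        radius = req.get("radius", 2)
        nbits = req.get("nbits", 1024)
        return {"bits": [fingerprint_bits(s, radius, nbits) for s in req["smiles"]]}
    if op == "graph":
        return {"graphs": [graph_of(s) for s in req["smiles"]]}
    if op == "core":
        mol, flagged = build_core(set(req["npos"]))
        return {"smiles": Chem.MolToSmiles(mol), "kekule_fallback": flagged}
    if op == "attach":
        out = []
        for sub in req["subs"]:
            smi, err = attach_substituent(set(req["npos"]), sub,
                                          [int(p) for p in req["positions"]])
            out.append({"smiles": smi, "error": err})
        return {"attached": out}
    if op == "match":
        patt = Chem.MolFromSmarts(req["smarts"])
        res = []
        for s in req["smiles"]:
            mol = Chem.MolFromSmiles(s)
            res.append(None if mol is None or patt is None
                       else mol.HasSubstructMatch(patt))
        return {"matches": res}
    if op == "shutdown":
        return {"bye": True}
    return {"error": "unknown op %r" % op}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            resp = handle(req)
            resp["id"] = req.get("id")
        except Exception as exc:  # never die mid-session; report instead
            resp = {"id": None, "error": str(exc)}
        sys.stdout.write(json.dumps(resp) + "\n")
        sys.stdout.flush()
        if resp.get("bye"):
            break


if __name__ == "__main__":
    main()
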