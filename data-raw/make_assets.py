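#!/usr/bin/env python
"""One-time generator for the plain-text parameter/geometry assets shipped in
inst/extdata/.  Uses the PDB Chemical Component Dictionary ideal geometries
(via biotite), rdkit for Gasteiger charges, and scipy for the torsional
closure of the idealized duplex backbone and the rigid docking of the
canonical side-chain motif poses.

Run from the repository root:  python data-raw/make_assets.py
"""
import numpy as np
import biotite.structure.info as info
from rdkit import Chem
from rdkit.Chem import AllChem
from scipy.optimize import least_squares
from scipy.spatial.transform import Rotation
import os, math, csv

OUT = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata")
os.makedirs(OUT, exist_ok=True)

AA = ["ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
      "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL"]
NUC = ["DA","DC","DG","DT"]
PUR = {"DA","DG"}

# ---------------------------------------------------------------- helpers

def res_as_dict(name):
    r = info.residue(name)
    names = [str(a) for a in r.atom_name]
    elems = [str(e) for e in r.element]
    coords = np.asarray(r.coord, dtype=float)
    bonds = []
    for i, j, t in r.bonds.as_array():
        order = {1: 1, 5: 1, 2: 2, 6: 2, 3: 3, 7: 3}.get(int(t), 1)
        bonds.append((names[i], names[j], order))
    return dict(names=names, elems=dict(zip(names, elems)),
                xyz=dict(zip(names, coords)), bonds=bonds)


def drop_atoms(d, drop):
    drop = set(drop)
    d["names"] = [n for n in d["names"] if n not in drop]
    d["bonds"] = [(a, b, o) for a, b, o in d["bonds"]
                  if a not in drop and b not in drop]
    for n in drop:
        d["elems"].pop(n, None)
        d["xyz"].pop(n, None)


def neighbours(d, atom):
    out = []
    for a, b, o in d["bonds"]:
        if a == atom:
            out.append(b)
        elif b == atom:
            out.append(a)
    return out


def unit(v):
    return v / np.linalg.norm(v)


def place_h(d, parent, n_add, names, length, added):
    """Append n_add hydrogens on `parent`, completing its substituent shell."""
    p = d["xyz"][parent]
    subs = [unit(d["xyz"][n] - p) for n in neighbours(d, parent)]
    new_dirs = []
    if len(subs) == 0:
        new_dirs = [np.array([0, 0, 1.0]), np.array([0.943, 0, -0.333]),
                    np.array([-0.471, 0.816, -0.333]),
                    np.array([-0.471, -0.816, -0.333])][:n_add]
    elif len(subs) == 1:
        u = subs[0]
        ref = np.array([1.0, 0, 0]) if abs(u[0]) < 0.9 else np.array([0, 1.0, 0])
        perp = unit(np.cross(u, ref))
        ang = math.radians(109.5)
        for k in range(n_add):
            az = 2 * math.pi * k / max(n_add, 1)
            dirv = (math.cos(ang) * u +
                    math.sin(ang) * (math.cos(az) * perp +
                                     math.sin(az) * unit(np.cross(u, perp))))
            new_dirs.append(unit(dirv))
    elif len(subs) == 2:
        u1, u2 = subs
        w1 = unit(u1 + u2)
        nrm = np.cross(u1, u2)
        if np.linalg.norm(nrm) < 1e-6:
            nrm = np.cross(u1, np.array([1.0, 0, 0]))
        nrm = unit(nrm)
        if n_add == 1:
            new_dirs = [-w1]
        else:
            half = math.radians(109.5 / 2)
            new_dirs = [unit(-w1 * math.cos(half) + nrm * math.sin(half)),
                        unit(-w1 * math.cos(half) - nrm * math.sin(half))]
    else:
        new_dirs = [-unit(sum(subs))]
    for k in range(n_add):
        nm = names[k]
        d["names"].append(nm)
        d["elems"][nm] = "H"
        d["xyz"][nm] = p + length * new_dirs[k]
        d["bonds"].append((parent, nm, 1))
        added.append(nm)


def formal_charges(d):
    fc = {}
    order = {n: 0 for n in d["names"]}
    for a, b, o in d["bonds"]:
        order[a] += o
        order[b] += o
    for n in d["names"]:
        e = d["elems"][n]
        v = order[n]
        q = 0
        if e == "N" and v == 4:
            q = 1
        elif e == "O" and v == 1:
            q = -1
        elif e == "S" and v == 1:
            q = -1
        fc[n] = q
    return fc


def gasteiger(d):
    mol = Chem.RWMol()
    idx = {}
    for n in d["names"]:
        at = Chem.Atom(d["elems"][n])
        at.SetNoImplicit(True)
        idx[n] = mol.AddAtom(at)
    for n, q in formal_charges(d).items():
        mol.GetAtomWithIdx(idx[n]).SetFormalCharge(q)
    bt = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE,
          3: Chem.BondType.TRIPLE}
    for a, b, o in d["bonds"]:
        mol.AddBond(idx[a], idx[b], bt[o])
    m = mol.GetMol()
    Chem.SanitizeMol(m)
    AllChem.ComputeGasteigerCharges(m, nIter=50)
    q = {n: float(m.GetAtomWithIdx(idx[n]).GetProp("_GasteigerCharge"))
         for n in d["names"]}
    return q, m, idx


def symmetrise(q, groups):
    for g in groups:
        g = [a for a in g if a in q]
        if len(g) > 1:
            mval = sum(q[a] for a in g) / len(g)
            for a in g:
                q[a] = mval
    return q


def lj_class(d, m, idx, atom):
    e = d["elems"][atom]
    if e == "P":
        return "P"
    if e == "S":
        return "S"
    if e == "N":
        return "N"
    nb = neighbours(d, atom)
    if e == "O":
        if any(d["elems"][x] == "H" for x in nb):
            return "OH"
        heavy = [x for x in nb if d["elems"][x] != "H"]
        return "O" if len(heavy) == 1 else "OS"
    if e == "C":
        a = m.GetAtomWithIdx(idx[atom])
        sp2 = a.GetIsAromatic() or any(
            b.GetBondTypeAsDouble() > 1.0 for b in a.GetBonds())
        return "C" if sp2 else "CT"
    par = nb[0]
    pe = d["elems"][par]
    if pe == "O":
        return "HO"
    if pe == "S":
        return "HS"
    if pe == "N":
        return "H"
    pa = m.GetAtomWithIdx(idx[par])
    if pa.GetIsAromatic() or any(b.GetBondTypeAsDouble() > 1.0
                                 for b in pa.GetBonds()):
        return "HA"
    en = sum(1 for x in neighbours(d, par) if d["elems"][x] in ("N", "O", "S"))
    return ["HC", "H1", "H2", "H3"][min(en, 3)]


SYM_GROUPS = {
    "ARG": [["NH1", "NH2"], ["HH11", "HH12", "HH21", "HH22"]],
    "ASP": [["OD1", "OD2"]],
    "GLU": [["OE1", "OE2"]],
    "LYS": [["HZ1", "HZ2", "HZ3"]],
    "ASN": [["HD21", "HD22"]],
    "GLN": [["HE21", "HE22"]],
}
NUC_SYM = [["OP1", "OP2"]]


def o3prime_cap(P, OP1, OP2, O5):
    n = unit(np.cross(OP2 - OP1, O5 - OP1))
    if np.dot(P - OP1, n) < 0:
        n = -n
    return P + 1.610 * n


def build_fragment(res):
    d = res_as_dict(res)
    added = []
    if res == "PRO":
        drop_atoms(d, ["C", "O", "OXT", "HXT", "H"])
        place_h(d, "N", 1, ["H1"], 1.01, added)
    elif res == "GLY":
        drop_atoms(d, ["N", "C", "O", "OXT", "H", "H2", "HXT"])
        place_h(d, "CA", 2, ["HA1", "HA4"], 1.09, added)
    else:
        drop_atoms(d, ["N", "C", "O", "OXT", "H", "H2", "HXT"])
        if res == "HIS":
            drop_atoms(d, ["HD1"])
        if res == "ASP":
            drop_atoms(d, ["HD2"])
        if res == "GLU":
            drop_atoms(d, ["HE2"])
        place_h(d, "CA", 2, ["HA2", "HA3"], 1.09, added)
    return d, added


def build_dnmp(res):
    d = res_as_dict(res)
    drop_atoms(d, ["OP3", "HOP3", "HOP2"])
    added = []
    o3t = o3prime_cap(d["xyz"]["P"], d["xyz"]["OP1"], d["xyz"]["OP2"],
                      d["xyz"]["O5'"])
    d["names"].append("O3T")
    d["elems"]["O3T"] = "O"
    d["xyz"]["O3T"] = o3t
    d["bonds"].append(("P", "O3T", 1))
    place_h(d, "O3T", 1, ["HO3T"], 0.96, added)
    return d, added


BASE_ATOMS = {
    "DA": ["N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4",
           "H8", "H61", "H62", "H2"],
    "DG": ["N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4",
           "H8", "H1", "H21", "H22"],
    "DC": ["N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6",
           "H41", "H42", "H5", "H6"],
    "DT": ["N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6",
           "H3", "H71", "H72", "H73", "H6"],
}


def build_base(res):
    d = res_as_dict(res)
    keep = set(BASE_ATOMS[res])
    drop_atoms(d, [n for n in d["names"] if n not in keep])
    added = []
    gly_n = "N9" if res in PUR else "N1"
    place_h(d, gly_n, 1, ["H9" if res in PUR else "H1"], 1.01, added)
    return d, added


species_rows = []
bond_rows = []
dihedral_rows = []


def rotor_torsions(d, classes, m, idx):
    """Torsion terms that restrain added-hydrogen rotors: strong 2-fold
    planar terms on sp2 N-H (amide, guanidinium, ring, amino), weak 3-fold
    terms on sp3 O-H/S-H/N-H/C-H rotors."""
    rows = []
    for h in d["names"]:
        if d["elems"][h] != "H":
            continue
        p = [x for x in neighbours(d, h) if d["elems"][x] != "H"][0]
        heavy_nb = [x for x in neighbours(d, p)
                    if d["elems"][x] != "H" and x != h]
        if not heavy_nb:
            continue
        pa = m.GetAtomWithIdx(idx[p])
        sp2 = str(pa.GetHybridization()) == "SP2" or pa.GetIsAromatic()
        if sp2 and d["elems"][p] == "N":
            c = heavy_nb[0]
            xnb = [x for x in neighbours(d, c)
                   if d["elems"][x] != "H" and x != p]
            if not xnb:
                continue
            xnb.sort(key=lambda x: {"O": 0, "N": 1}.get(d["elems"][x], 2))
            rows.append([h, p, c, xnb[0], 25.0, 2, 180.0])
        else:
            y = heavy_nb[0]
            znb = [x for x in neighbours(d, y)
                   if d["elems"][x] != "H" and x != p]
            if not znb:
                continue
            rows.append([h, p, y, znb[0], 1.5, 3, 0.0])
    return rows



# ---------------------------------------------------------------- charges
# Bond-increment charge scheme in Amber-like magnitudes: every bond moves a
# fixed increment of charge from the less to the more electronegative atom,
# formal charges are added on top, and chemically equivalent atoms are
# averaged.  Totals are integral by construction.

ELECTRONEG = {"H": 2.20, "P": 2.19, "C": 2.55, "S": 2.58, "N": 3.04,
              "O": 3.44}


def bond_increment(d, a, b, classes, ring_subst_n):
    """Charge moved between a bonded pair.  Pyridine-type ring nitrogens
    (two ring neighbours, no substituent) draw a full ring increment;
    substituted or protonated ring nitrogens are already saturated and draw
    almost none (mirrors the near-zero glycosidic-nitrogen charges of
    published nucleic-acid sets)."""
    e1, e2 = d["elems"][a], d["elems"][b]
    cls1, cls2 = classes[a], classes[b]
    pair = frozenset([e1, e2])
    if "H" in (e1, e2):
        other, other_e, other_c = (b, e2, cls2) if e1 == "H" else (a, e1, cls1)
        if other_e == "O":
            return 0.46
        if other_e == "N":
            return 0.42
        if other_e == "S":
            return 0.16
        if other_c == "C":   # sp2/aromatic carbon
            return 0.15
        return 0.05
    if pair == frozenset(["C", "N"]):
        n_atom = a if e1 == "N" else b
        if n_atom in ring_subst_n:
            return 0.05
        return 0.35
    if pair == frozenset(["C", "O"]):
        oc = cls1 if e1 == "O" else cls2
        return 0.60 if oc == "O" else 0.28
    if pair == frozenset(["C", "S"]):
        return 0.11
    if pair == frozenset(["P", "O"]):
        oc = cls1 if e1 == "O" else cls2
        return 0.60 if oc == "O" else 0.33
    return 0.0


def increment_charges(d, classes, m, idx):
    fc = formal_charges(d)
    q = {n: float(fc[n]) for n in d["names"]}
    ring_subst_n = set()
    for n in d["names"]:
        if d["elems"][n] != "N":
            continue
        at = m.GetAtomWithIdx(idx[n])
        if at.IsInRing() and len(neighbours(d, n)) >= 3:
            ring_subst_n.add(n)
    for a, b, o in d["bonds"]:
        ea, eb = d["elems"][a], d["elems"][b]
        delta = bond_increment(d, a, b, classes, ring_subst_n)
        if delta == 0.0:
            continue
        if ELECTRONEG[ea] < ELECTRONEG[eb]:
            q[a] += delta
            q[b] -= delta
        else:
            q[a] -= delta
            q[b] += delta
    return q

def emit_species(sid, d, added, sym):
    _, m, idx = gasteiger(d)   # rdkit mol only for hybridisation/LJ classes
    classes = {n: lj_class(d, m, idx, n) for n in d["names"]}
    q = increment_charges(d, classes, m, idx)
    q = symmetrise(q, sym)
    tot = sum(q.values())
    assert abs(tot - round(tot)) < 1e-3, (sid, tot)
    for n in d["names"]:
        cls = classes[n]
        x, y, z = d["xyz"][n]
        species_rows.append([sid, n, d["elems"][n], cls,
                             round(q[n], 4), round(x, 3), round(y, 3),
                             round(z, 3), int(n in added)])
    for a, b, o in d["bonds"]:
        bond_rows.append([sid, a, b])
    for row in rotor_torsions(d, classes, m, idx):
        dihedral_rows.append([sid] + row)

for a in AA:
    d, added = build_fragment(a)
    emit_species("frag_" + a, d, added, SYM_GROUPS.get(a, []))
for n in NUC:
    d, added = build_dnmp(n)
    emit_species("nuc_" + n, d, added, NUC_SYM)
    d, added = build_base(n)
    emit_species("base_" + n, d, added, [])

with open(os.path.join(OUT, "species_atoms.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["species", "atom", "element", "lj", "charge",
                "x", "y", "z", "added"])
    w.writerows(species_rows)
with open(os.path.join(OUT, "species_bonds.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["species", "atom1", "atom2"])
    w.writerows(bond_rows)
with open(os.path.join(OUT, "species_dihedrals.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["species", "atom1", "atom2", "atom3", "atom4",
                "k_kj", "n", "gamma_deg"])
    w.writerows(dihedral_rows)
print("species written:", len(set(r[0] for r in species_rows)),
      "with", len(dihedral_rows), "rotor torsions")

# ---------------------------------------------------------------- small tables

AMBER_LJ = {  # class: (Rmin/2 in A, eps in kcal/mol)
    "CT": (1.9080, 0.1094), "C": (1.9080, 0.0860), "N": (1.8240, 0.1700),
    "O": (1.6612, 0.2100), "OH": (1.7210, 0.2104), "OS": (1.6837, 0.1700),
    "P": (2.1000, 0.2000), "S": (2.0000, 0.2500), "H": (0.6000, 0.0157),
    "HO": (0.0000, 0.0000), "HS": (0.6000, 0.0157), "HC": (1.4870, 0.0157),
    "H1": (1.3870, 0.0157), "H2": (1.2870, 0.0157), "H3": (1.1870, 0.0157),
    "HA": (1.4590, 0.0150),
}
with open(os.path.join(OUT, "lj_classes.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["lj", "sigma_nm", "eps_kj"])
    for k, (rm2, eps) in AMBER_LJ.items():
        sigma = 2.0 * rm2 / (2 ** (1 / 6)) / 10.0
        w.writerow([k, round(sigma, 6), round(eps * 4.184, 6)])

GB = {"H": (1.20, 0.85), "C": (1.70, 0.72), "N": (1.55, 0.79),
      "O": (1.50, 0.85), "P": (1.85, 0.86), "S": (1.80, 0.96)}
with open(os.path.join(OUT, "gb_params.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["element", "radius_nm", "screen"])
    for k, (r, s) in GB.items():
        w.writerow([k, round(r / 10.0, 4), s])

VDW = {"C": 1.70, "N": 1.55, "O": 1.52, "P": 1.80, "S": 1.80, "H": 1.10}
with open(os.path.join(OUT, "vdw_radii.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["element", "radius_A"])
    for k, v in VDW.items():
        w.writerow([k, v])

REF_ATOMS = {
    "ALA": ["CB", "CA", "N"], "ARG": ["CZ", "NH1", "NH2"],
    "ASN": ["CG", "OD1", "ND2"], "ASP": ["CG", "OD1", "OD2"],
    "CYS": ["SG", "CB", "CA"], "GLN": ["CD", "OE1", "NE2"],
    "GLU": ["CD", "OE1", "OE2"], "GLY": ["CA", "N", "C"],
    "HIS": ["CG", "ND1", "NE2"], "ILE": ["CG1", "CG2", "CD1"],
    "LEU": ["CG", "CD1", "CD2"], "LYS": ["NZ", "CE", "CD"],
    "MET": ["SD", "CG", "CE"], "PHE": ["CG", "CE1", "CE2"],
    "PRO": ["CG", "CB", "CD"], "SER": ["OG", "CB", "CA"],
    "THR": ["OG1", "CG2", "CB"], "TRP": ["CG", "NE1", "CZ3"],
    "TYR": ["OH", "CE1", "CE2"], "VAL": ["CB", "CG1", "CG2"],
}
for res, atoms in REF_ATOMS.items():
    full = res_as_dict(res)
    for a in atoms:
        assert a in full["names"], (res, a)
with open(os.path.join(OUT, "reference_atoms.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["residue", "ref1", "ref2", "ref3"])
    for res, atoms in REF_ATOMS.items():
        w.writerow([res] + atoms)

# ----------------------------------------------------------------
# Idealized duplex strand template.
# Bases are pinned analytically using the standard base-pair reference frame
# (glycosidic N of purines at (-1.291, 4.498, 0), of pyrimidines at
# (-1.285, 4.508, 0), C1' at (-2.479, 5.346, 0); the complementary base is
# the image under a 2-fold rotation about x).  The duplex is generated
# helically: twist 36 deg about z, rise 3.38 A per step.

GLYC = {"DA": "N9", "DG": "N9", "DC": "N1", "DT": "N1"}
GLYC_NB = {"DA": ["C8", "C4"], "DG": ["C8", "C4"],
           "DC": ["C2", "C6"], "DT": ["C2", "C6"]}
N_STD = {"DA": np.array([-1.291, 4.498]), "DG": np.array([-1.291, 4.498]),
         "DC": np.array([-1.285, 4.508]), "DT": np.array([-1.285, 4.508])}
C1_STD = np.array([-2.479, 5.346])
RING = {
    "DA": ["N9", "C8", "N7", "C5", "C4"],
    "DG": ["N9", "C8", "N7", "C5", "C4"],
    "DC": ["N1", "C2", "N3", "C4", "C5", "C6"],
    "DT": ["N1", "C2", "N3", "C4", "C5", "C6"],
}
TWIST = math.radians(-36.0)  # helix advance in this frame's convention
RISE = 3.38


def flatten_base(res, flip=False):
    """Base heavy atoms in a planar frame with chosen handedness."""
    d = res_as_dict(res)
    atoms = [a for a in BASE_ATOMS[res] if not a.startswith("H")]
    X = np.array([d["xyz"][a] for a in atoms])
    c = X.mean(0)
    X = X - c
    _, _, Vt = np.linalg.svd(X)
    Y = X @ Vt.T
    ring = [atoms.index(a) for a in RING[res]]
    P2 = Y[ring][:, :2]
    area = 0.0
    for i in range(len(P2)):
        x1, y1 = P2[i]
        x2, y2 = P2[(i + 1) % len(P2)]
        area += x1 * y2 - x2 * y1
    if (area < 0) != flip:
        Y[:, 1] *= -1.0
    Y[:, 2] = 0.0
    return {a: Y[i, :2] for i, a in enumerate(atoms)}


def rot2(t):
    c, s = math.cos(t), math.sin(t)
    return np.array([[c, -s], [s, c]])


def place_base_std(res, flip=False):
    """Pin the flattened base: glyc N at the standard position with the
    ring-bond bisector pointing away from the standard C1' position."""
    xy = flatten_base(res, flip)
    n0 = xy[GLYC[res]]
    u = unit(xy[GLYC_NB[res][0]] - n0) + unit(xy[GLYC_NB[res][1]] - n0)
    g0 = unit(u)  # bisector INTO the base
    g_target = unit(N_STD[res] - C1_STD) * -1.0  # from C1' into the base
    g_target = -g_target
    g_target = unit(N_STD[res] - C1_STD)
    th = math.atan2(g_target[1], g_target[0]) - math.atan2(g0[1], g0[0])
    R = rot2(th)
    return {a: R @ (v - n0) + N_STD[res] for a, v in xy.items()}


def mirror_pair(xy):
    return {a: np.array([v[0], -v[1]]) for a, v in xy.items()}


HB = {("DA", "DT"): [("N1", "N3"), ("N6", "O4")],
      ("DG", "DC"): [("O6", "N4"), ("N1", "N3"), ("N2", "O2")]}


def hb_cost(placed):
    c = 0.0
    for (pu, py), hbs in HB.items():
        A = placed[pu]
        B = mirror_pair(placed[py])
        for a, b in hbs:
            c += (float(np.linalg.norm(A[a] - B[b])) - 2.9) ** 2
    return c


best_fl = None
for fpu in (False, True):
    for fpy in (False, True):
        placed = {b: place_base_std(b, fpu if b in PUR else fpy) for b in NUC}
        c = hb_cost(placed)
        if best_fl is None or c < best_fl[0]:
            best_fl = (c, fpu, fpy, placed)
print("base handedness flips (pur, pyr):", best_fl[1], best_fl[2],
      "cost:", round(best_fl[0], 3))
placed2d = best_fl[3]
for (pu, py), hbs in HB.items():
    A = placed2d[pu]
    B = mirror_pair(placed2d[py])
    print(pu, py, "H-bonds:",
          [round(float(np.linalg.norm(A[a] - B[b])), 3) for a, b in hbs])

# sugar-phosphate closure: ring rigid, chi/gamma/beta/alpha free
dt = res_as_dict("DT")
N3d = np.array([N_STD["DT"][0], N_STD["DT"][1], 0.0])
C13d = np.array([C1_STD[0], C1_STD[1], 0.0])
g3d = unit(N3d - C13d)

RING_UNIT = ["C1'", "C2'", "C3'", "C4'", "O4'", "O3'"]
SUGAR = RING_UNIT + ["C5'", "O5'", "P", "OP1", "OP2"]


def rodrigues(v, p1, p2, theta):
    k = unit(p2 - p1)
    p = v - p1
    return (p * math.cos(theta) + np.cross(k, p) * math.sin(theta) +
            k * np.dot(k, p) * (1 - math.cos(theta))) + p1


def build_sugar(par):
    chi, gamma, beta, alpha, delta = par
    X = {a: dt["xyz"][a].copy() for a in SUGAR}
    c1 = dt["xyz"]["C1'"]
    gl = unit(dt["xyz"]["N1"] - c1)
    v = np.cross(gl, g3d)
    s = np.linalg.norm(v)
    cth = float(np.dot(gl, g3d))
    if s < 1e-9:
        R = np.eye(3) if cth > 0 else -np.eye(3)
    else:
        vx = np.array([[0, -v[2], v[1]], [v[2], 0, -v[0]], [-v[1], v[0], 0]])
        R = np.eye(3) + vx + vx @ vx * ((1 - cth) / s ** 2)
    for a in SUGAR:
        X[a] = R @ (X[a] - c1) + C13d
    for a in SUGAR:
        X[a] = rodrigues(X[a], C13d, N3d, chi)
    X["O3'"] = rodrigues(X["O3'"], X["C4'"], X["C3'"], delta)
    for a in ["O5'", "P", "OP1", "OP2"]:
        X[a] = rodrigues(X[a], X["C4'"], X["C5'"], gamma)
    for a in ["P", "OP1", "OP2"]:
        X[a] = rodrigues(X[a], X["C5'"], X["O5'"], beta)
    for a in ["OP1", "OP2"]:
        X[a] = rodrigues(X[a], X["O5'"], X["P"], alpha)
    return X


def helical(X, k):
    c, s = math.cos(k * TWIST), math.sin(k * TWIST)
    R = np.array([[c, -s, 0], [s, c, 0], [0, 0, 1]])
    return X @ R.T + np.array([0, 0, k * RISE])


base3d = {}
for b in NUC:
    atoms = [a for a in BASE_ATOMS[b] if not a.startswith("H")]
    base3d[b] = np.array([[placed2d[b][a][0], placed2d[b][a][1], 0.0]
                          for a in atoms])
allbase = np.vstack([base3d[b] for b in NUC])


I_EX1 = [SUGAR.index(a) for a in ("O3'", "C3'", "C4'")]
I_EX2 = [SUGAR.index(a) for a in ("P", "O5'", "OP1", "OP2")]


def sugar_resid(par):
    X = build_sugar(par)
    res = []
    o3_next = helical(X["O3'"][None, :], 1)[0]
    res.append(10.0 * (np.linalg.norm(o3_next - X["P"]) - 1.595))
    res.append(0.5 * (np.hypot(X["P"][0], X["P"][1]) - 9.3))
    c3_next = helical(X["C3'"][None, :], 1)[0]
    v1 = unit(c3_next - o3_next)
    v2 = unit(X["P"] - o3_next)
    res.append(2.0 * (np.dot(v1, v2) - math.cos(math.radians(119.0))))
    w1 = unit(o3_next - X["P"])
    w2 = unit(X["O5'"] - X["P"])
    res.append(2.0 * (np.dot(w1, w2) - math.cos(math.radians(101.0))))
    for op in ("OP1", "OP2"):
        wo = unit(X[op] - X["P"])
        res.append(2.0 * (np.dot(w1, wo) - math.cos(math.radians(108.0))))
    coords = np.array([X[a] for a in SUGAR])
    # neighbour-step sugar, exempting the covalent O3'-P linkage region
    nb = helical(coords, 1)
    Dn = np.linalg.norm(coords[:, None, :] - nb[None, :, :], axis=2)
    for i in I_EX1:
        for j in I_EX2:
            Dn[i, j] = 9.0
            Dn[j, i] = 9.0
    mirr = coords.copy()
    mirr[:, 1] *= -1
    mirr[:, 2] *= -1
    mb = allbase.copy()
    mb[:, 1] *= -1
    mb[:, 2] *= -1
    G = np.vstack([helical(allbase, 1), helical(allbase, -1), mb] +
                  [helical(mirr, k) for k in (-1, 0, 1)])
    D = np.linalg.norm(coords[:, None, :] - G[None, :, :], axis=2)
    allD = np.hstack([D, Dn])
    viol = np.clip(2.7 - allD, 0.0, None)
    viol[allD <= 1e-6] = 0.0
    res.extend((2.0 * viol).ravel())
    return np.array(res)


best = None
_rng = np.random.default_rng(5)
for _t in range(80):
    p0 = _rng.uniform(-math.pi, math.pi, size=5)
    p0[4] = _rng.normal(0, 0.6)
    try:
        s = least_squares(sugar_resid, p0, xtol=1e-14, ftol=1e-14)
    except Exception:
        continue
    if best is None or s.cost < best.cost:
        best = s
print("sugar closure cost:", round(float(best.cost), 5), "par:",
      [round(float(x), 2) for x in best.x])
spos = build_sugar(best.x)
o3n = helical(spos["O3'"][None, :], 1)[0]
print("P radius:", round(float(np.hypot(spos['P'][0], spos['P'][1])), 3),
      "O3'->P(next):", round(float(np.linalg.norm(o3n - spos['P'])), 3))
pp = helical(spos["P"][None, :], 1)[0]
print("P-P step:", round(float(np.linalg.norm(pp - spos["P"])), 3))

rows = []
for b in NUC:
    atoms = [a for a in BASE_ATOMS[b] if not a.startswith("H")]
    for a in atoms:
        v = placed2d[b][a]
        rows.append([b, a, "N" if a.startswith("N") else
                     ("O" if a.startswith("O") else "C"),
                     round(float(v[0]), 3), round(float(v[1]), 3), 0.0])
    for a in SUGAR:
        e = "P" if a == "P" else ("O" if a.startswith("O") else "C")
        rows.append([b, a, e, round(float(spos[a][0]), 3),
                     round(float(spos[a][1]), 3), round(float(spos[a][2]), 3)])
with open(os.path.join(OUT, "bdna_frame.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["base", "atom", "element", "x", "y", "z"])
    w.writerows(rows)

# duplex self-check on ACGTACGT
comp = {"DA": "DT", "DT": "DA", "DG": "DC", "DC": "DG"}
seq = ["DA", "DC", "DG", "DT", "DA", "DC", "DG", "DT"]
coordsI, coordsII = [], []
for k, b in enumerate(seq):
    atoms = [a for a in BASE_ATOMS[b] if not a.startswith("H")] + SUGAR
    X = np.array([[placed2d[b][a][0], placed2d[b][a][1], 0.0]
                  if a not in SUGAR else spos[a] for a in atoms])
    coordsI.append((b, atoms, helical(X, k)))
    bc = comp[b]
    atoms2 = [a for a in BASE_ATOMS[bc] if not a.startswith("H")] + SUGAR
    X2 = np.array([[placed2d[bc][a][0], placed2d[bc][a][1], 0.0]
                   if a not in SUGAR else spos[a] for a in atoms2])
    X2m = X2.copy()
    X2m[:, 1] *= -1
    X2m[:, 2] *= -1
    coordsII.append((bc, atoms2, helical(X2m, k)))
pps = []
for k in range(1, len(seq)):
    p1 = coordsI[k - 1][2][coordsI[k - 1][1].index("P")]
    p2 = coordsI[k][2][coordsI[k][1].index("P")]
    pps.append(float(np.linalg.norm(p1 - p2)))
print("P-P steps strand I:", [round(x, 2) for x in pps])
allc = np.vstack([c for _, _, c in coordsI + coordsII])
D = np.linalg.norm(allc[:, None] - allc[None, :], axis=2)
np.fill_diagonal(D, 9e9)
print("global min heavy-heavy distance:", round(float(D.min()), 2))

# ---------------------------------------------------------------- motif poses
# Canonical side-chain poses docked against the stripped-base species
# coordinates (the common base frame used by the geometry module).

def species_coords(sid):
    out = {}
    for r in species_rows:
        if r[0] == sid:
            out[r[1]] = np.array([r[5], r[6], r[7]], dtype=float)
    return out


def base_plane(xyz, names):
    X = np.array([xyz[a] for a in names])
    c = X.mean(0)
    _, _, Vt = np.linalg.svd(X - c)
    return c, Vt[2]


MOTIFS = {
    "asn_ade_hoogsteen": ("ASN", "base_DA",
                          [("ND2", "N7", 2.90), ("OD1", "N6", 2.93)],
                          ["CG", "OD1", "ND2"]),
    "gln_ade_hoogsteen": ("GLN", "base_DA",
                          [("NE2", "N7", 2.90), ("OE1", "N6", 2.93)],
                          ["CD", "OE1", "NE2"]),
    "arg_gua_hoogsteen": ("ARG", "base_DG",
                          [("NH1", "O6", 2.90), ("NH2", "N7", 2.90)],
                          ["CZ", "NH1", "NH2"]),
    "ser_ade_hoogsteen": ("SER", "base_DA",
                          [("OG", "N7", 2.80)],
                          ["OG"]),
}

motif_rows = []
rng = np.random.default_rng(11)
for mid, (res, bsid, hbs, planar) in MOTIFS.items():
    bxyz = species_coords(bsid)
    bnames = [a for a in bxyz if not a.startswith("H")]
    bc, bn = base_plane(bxyz, RING[bsid.replace("base_", "")])
    d = res_as_dict(res)
    drop_atoms(d, ["OXT", "HXT"] + [a for a in d["names"]
                                    if d["elems"][a] == "H"])
    anames = list(d["names"])
    A0 = np.array([d["xyz"][a] for a in anames])
    A0 = A0 - A0.mean(0)
    B = np.array([bxyz[a] for a in bnames])

    hb_pairs = [(anames.index(a), bxyz[b], t) for a, b, t in hbs]
    pl_idx = [anames.index(a) for a in planar]
    ca_idx = anames.index("CA")
    hb_aidx = {ia for ia, _, _ in hb_pairs}

    def resid(par):
        R = Rotation.from_rotvec(par[:3]).as_matrix()
        t = par[3:6]
        X = A0 @ R.T + t
        rr = []
        for ia, bpos, tgt in hb_pairs:
            rr.append(3.0 * (np.linalg.norm(X[ia] - bpos) - tgt))
        for ip in pl_idx:
            rr.append(1.0 * float(np.dot(X[ip] - bc, bn)))
        rr.append(0.3 * max(0.0, 7.5 - float(np.linalg.norm(X[ca_idx] - bc))))
        Dm = np.linalg.norm(X[:, None, :] - B[None, :, :], axis=2)
        lims = np.where(np.isin(np.arange(Dm.shape[0]), list(hb_aidx)),
                        2.7, 3.0)[:, None]
        rr.extend((2.0 * np.clip(lims - Dm, 0.0, None)).ravel())
        return np.array(rr)

    bestm = None
    for trial in range(40):
        rv = rng.normal(scale=1.5, size=3)
        hbdir = unit(hb_pairs[0][1] - bc)
        t0 = hb_pairs[0][1] + hbdir * 4.0 + rng.normal(scale=1.5, size=3)
        try:
            s = least_squares(resid, np.concatenate([rv, t0]),
                              xtol=1e-10, ftol=1e-10)
        except Exception:
            continue
        if bestm is None or s.cost < bestm.cost:
            bestm = s
    R = Rotation.from_rotvec(bestm.x[:3]).as_matrix()
    X = A0 @ R.T + bestm.x[3:6]
    print(mid, "cost:", round(float(bestm.cost), 4), "H-bonds:",
          [round(float(np.linalg.norm(X[ia] - bp)), 3)
           for ia, bp, _ in hb_pairs])
    for i, a in enumerate(anames):
        motif_rows.append([mid, res, bsid, a, d["elems"][a],
                           round(float(X[i, 0]), 3), round(float(X[i, 1]), 3),
                           round(float(X[i, 2]), 3)])

with open(os.path.join(OUT, "motifs.csv"), "w", newline="") as f:
    w = csv.writer(f)
    w.writerow(["motif", "residue", "base_species", "atom", "element",
                "x", "y", "z"])
    w.writerows(motif_rows)
print("assets complete")
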