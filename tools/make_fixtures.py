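#!/usr/bin/env python
"""Generate FCIDUMP fixtures (STO-3G, RHF canonical MOs) for the test molecules.

Standalone integral generator: McMurchie-Davidson Gaussian integrals over
contracted s/p shells, restricted Hartree-Fock with DIIS, AO->MO
transformation, Molpro-style FCIDUMP output (chemists' notation, 1-based
indices, 8-fold symmetry, core energy on the trailing all-zero index line).

STO-3G data from the standard tabulation (Hehre, Stewart, Pople): universal
contraction coefficients with per-element Slater zeta scaling
(H 1s 1.24; Li 1s 2.69, 2sp 0.80; Be 1s 3.68, 2sp 1.15).

Run from the repository root:  python tools/make_fixtures.py
Requires numpy + scipy only.  A small determinant-basis FCI validates each
file before it is written (and against literature values for H2 / LiH).
"""

import itertools
import math
import os

import numpy as np
from scipy.special import gammainc, gamma
from scipy.sparse import identity as spidentity, csr_matrix, kron

ANG2BOHR = 1.0 / 0.529177210903

# ---------------------------------------------------------------- basis data
D1S = np.array([0.1543289673, 0.5353281423, 0.4446345422])
D2S = np.array([-0.09996722919, 0.3995128261, 0.7001154689])
D2P = np.array([0.1559162750, 0.6076837186, 0.3919573931])
A1S = np.array([2.227660584, 0.4057711562, 0.1098175104])   # zeta = 1
A2SP = np.array([0.9942034600, 0.2310313100, 0.0751386200])  # zeta = 1

STO3G = {
    "H":  [("s", A1S * 1.24**2, D1S)],
    "Li": [("s", A1S * 2.69**2, D1S),
           ("s", A2SP * 0.80**2, D2S),
           ("p", A2SP * 0.80**2, D2P)],
    "Be": [("s", A1S * 3.68**2, D1S),
           ("s", A2SP * 1.15**2, D2S),
           ("p", A2SP * 1.15**2, D2P)],
}
CHARGE = {"H": 1, "Li": 3, "Be": 4}


def boys(n, x):
    x = np.asarray(x, dtype=float)
    small = x < 1e-12
    xs = np.where(small, 1.0, x)
    val = gamma(n + 0.5) * gammainc(n + 0.5, xs) / (2.0 * xs ** (n + 0.5))
    return np.where(small, 1.0 / (2 * n + 1), val)


def hermite_E(i, j, t, Qx, a, b):
    """Hermite expansion coefficient E_t^{ij} (McMurchie-Davidson recursion)."""
    p = a + b
    q = a * b / p
    if t < 0 or t > i + j:
        return 0.0
    if i == j == t == 0:
        return math.exp(-q * Qx * Qx)
    if j == 0:
        return (1.0 / (2 * p) * hermite_E(i - 1, j, t - 1, Qx, a, b)
                - q * Qx / a * hermite_E(i - 1, j, t, Qx, a, b)
                + (t + 1) * hermite_E(i - 1, j, t + 1, Qx, a, b))
    return (1.0 / (2 * p) * hermite_E(i, j - 1, t - 1, Qx, a, b)
            + q * Qx / b * hermite_E(i, j - 1, t, Qx, a, b)
            + (t + 1) * hermite_E(i, j - 1, t + 1, Qx, a, b))


def hermite_R(t, u, v, n, p, PC):
    """Auxiliary Hermite Coulomb integral R^n_{tuv}."""
    x, y, z = PC
    if t < 0 or u < 0 or v < 0:
        return 0.0
    if t == u == v == 0:
        return (-2.0 * p) ** n * boys(n, p * (x * x + y * y + z * z))
    if t > 0:
        return ((t - 1) * hermite_R(t - 2, u, v, n + 1, p, PC)
                + x * hermite_R(t - 1, u, v, n + 1, p, PC))
    if u > 0:
        return ((u - 1) * hermite_R(t, u - 2, v, n + 1, p, PC)
                + y * hermite_R(t, u - 1, v, n + 1, p, PC))
    return ((v - 1) * hermite_R(t, u, v - 2, n + 1, p, PC)
            + z * hermite_R(t, u, v - 1, n + 1, p, PC))


def prim_overlap3(a, la, A, b, lb, B):
    p = a + b
    val = 1.0
    for k in range(3):
        val *= hermite_E(la[k], lb[k], 0, A[k] - B[k], a, b)
    return val * (math.pi / p) ** 1.5


def prim_kinetic(a, la, A, b, lb, B):
    lx, ly, lz = lb
    term0 = b * (2 * (lx + ly + lz) + 3) * prim_overlap3(a, la, A, b, lb, B)
    term1 = -2.0 * b * b * (
        prim_overlap3(a, la, A, b, (lx + 2, ly, lz), B)
        + prim_overlap3(a, la, A, b, (lx, ly + 2, lz), B)
        + prim_overlap3(a, la, A, b, (lx, ly, lz + 2), B))
    term2 = -0.5 * (
        lx * (lx - 1) * prim_overlap3(a, la, A, b, (lx - 2, ly, lz), B)
        + ly * (ly - 1) * prim_overlap3(a, la, A, b, (lx, ly - 2, lz), B)
        + lz * (lz - 1) * prim_overlap3(a, la, A, b, (lx, ly, lz - 2), B))
    return term0 + term1 + term2


def prim_nuclear(a, la, A, b, lb, B, C):
    p = a + b
    P = (a * np.asarray(A) + b * np.asarray(B)) / p
    val = 0.0
    for t in range(la[0] + lb[0] + 1):
        Et = hermite_E(la[0], lb[0], t, A[0] - B[0], a, b)
        for u in range(la[1] + lb[1] + 1):
            Eu = hermite_E(la[1], lb[1], u, A[1] - B[1], a, b)
            for v in range(la[2] + lb[2] + 1):
                Ev = hermite_E(la[2], lb[2], v, A[2] - B[2], a, b)
                val += Et * Eu * Ev * hermite_R(t, u, v, 0, p, P - np.asarray(C))
    return 2.0 * math.pi / p * val


def prim_eri(a, la, A, b, lb, B, c, lc, C, d, ld, D):
    p = a + b
    q = c + d
    alpha = p * q / (p + q)
    P = (a * np.asarray(A) + b * np.asarray(B)) / p
    Q = (c * np.asarray(C) + d * np.asarray(D)) / q
    val = 0.0
    for t in range(la[0] + lb[0] + 1):
        Et = hermite_E(la[0], lb[0], t, A[0] - B[0], a, b)
        for u in range(la[1] + lb[1] + 1):
            Eu = hermite_E(la[1], lb[1], u, A[1] - B[1], a, b)
            for v in range(la[2] + lb[2] + 1):
                Ev = hermite_E(la[2], lb[2], v, A[2] - B[2], a, b)
                if Et * Eu * Ev == 0.0:
                    continue
                for tt in range(lc[0] + ld[0] + 1):
                    Ft = hermite_E(lc[0], ld[0], tt, C[0] - D[0], c, d)
                    for uu in range(lc[1] + ld[1] + 1):
                        Fu = hermite_E(lc[1], ld[1], uu, C[1] - D[1], c, d)
                        for vv in range(lc[2] + ld[2] + 1):
                            Fv = hermite_E(lc[2], ld[2], vv, C[2] - D[2], c, d)
                            if Ft * Fu * Fv == 0.0:
                                continue
                            val += (Et * Eu * Ev * Ft * Fu * Fv
                                    * (-1) ** (tt + uu + vv)
                                    * hermite_R(t + tt, u + uu, v + vv, 0,
                                                alpha, P - Q))
    return val * 2.0 * math.pi ** 2.5 / (p * q * math.sqrt(p + q))


def norm_prim(a, l):
    """Normalization of a Cartesian Gaussian primitive."""
    lx, ly, lz = l
    df = lambda n: 1.0 if n < 2 else np.prod(np.arange(n, 0, -2, dtype=float))
    L = lx + ly + lz
    return ((2 * a / math.pi) ** 0.75 * (4 * a) ** (L / 2.0)
            / math.sqrt(df(2 * lx - 1) * df(2 * ly - 1) * df(2 * lz - 1)))


class BasisFunction:
    def __init__(self, center, l, exps, coefs):
        self.A = np.asarray(center, dtype=float)
        self.l = l
        self.exps = exps
        self.coefs = coefs * np.array([norm_prim(a, l) for a in exps])
        # normalize the contracted function
        s = 0.0
        for a, ca in zip(exps, self.coefs):
            for b, cb in zip(exps, self.coefs):
                s += ca * cb * prim_overlap3(a, l, self.A, b, l, self.A)
        self.coefs = self.coefs / math.sqrt(s)


def build_basis(atoms):
    bfs = []
    for (el, xyz) in atoms:
        for (shell, exps, coefs) in STO3G[el]:
            if shell == "s":
                bfs.append(BasisFunction(xyz, (0, 0, 0), exps, coefs))
            else:
                for l in [(1, 0, 0), (0, 1, 0), (0, 0, 1)]:
                    bfs.append(BasisFunction(xyz, l, exps, coefs))
    return bfs


def one_electron(bfs, atoms):
    n = len(bfs)
    S = np.zeros((n, n)); T = np.zeros((n, n)); V = np.zeros((n, n))
    for i in range(n):
        for j in range(i + 1):
            bi, bj = bfs[i], bfs[j]
            s = t = v = 0.0
            for a, ca in zip(bi.exps, bi.coefs):
                for b, cb in zip(bj.exps, bj.coefs):
                    s += ca * cb * prim_overlap3(a, bi.l, bi.A, b, bj.l, bj.A)
                    t += ca * cb * prim_kinetic(a, bi.l, bi.A, b, bj.l, bj.A)
                    for (el, C) in atoms:
                        v -= CHARGE[el] * ca * cb * prim_nuclear(
                            a, bi.l, bi.A, b, bj.l, bj.A, C)
            S[i, j] = S[j, i] = s
            T[i, j] = T[j, i] = t
            V[i, j] = V[j, i] = v
    return S, T, V


def two_electron(bfs):
    n = len(bfs)
    g = np.zeros((n, n, n, n))
    done = {}
    for i in range(n):
        for j in range(i + 1):
            for k in range(n):
                for l in range(k + 1):
                    if (i * (i + 1) // 2 + j) < (k * (k + 1) // 2 + l):
                        continue
                    bi, bj, bk, bl = bfs[i], bfs[j], bfs[k], bfs[l]
                    val = 0.0
                    for a, ca in zip(bi.exps, bi.coefs):
                        for b, cb in zip(bj.exps, bj.coefs):
                            for c, cc in zip(bk.exps, bk.coefs):
                                for d, cd in zip(bl.exps, bl.coefs):
                                    val += ca * cb * cc * cd * prim_eri(
                                        a, bi.l, bi.A, b, bj.l, bj.A,
                                        c, bk.l, bk.A, d, bl.l, bl.A)
                    for (p, q) in [(i, j), (j, i)]:
                        for (r, s) in [(k, l), (l, k)]:
                            g[p, q, r, s] = g[r, s, p, q] = val
    return g


def nuclear_repulsion(atoms):
    e = 0.0
    for (el1, A), (el2, B) in itertools.combinations(atoms, 2):
        e += CHARGE[el1] * CHARGE[el2] / np.linalg.norm(np.asarray(A) - np.asarray(B))
    return e


def rhf(S, T, V, g, n_elec, e_nuc, maxiter=200, tol=1e-12):
    n = S.shape[0]
    nocc = n_elec // 2
    Hcore = T + V
    w, U = np.linalg.eigh(S)
    X = U @ np.diag(w ** -0.5) @ U.T
    F = Hcore.copy()
    E_old = 0.0
    fock_list, err_list = [], []
    D = np.zeros_like(S)
    for it in range(maxiter):
        Fp = X.T @ F @ X
        eps, Cp = np.linalg.eigh(Fp)
        C = X @ Cp
        Cocc = C[:, :nocc]
        D = Cocc @ Cocc.T
        J = np.einsum("pqrs,rs->pq", g, D)
        K = np.einsum("prqs,rs->pq", g, D)
        F = Hcore + 2.0 * J - K
        E = np.sum(D * (Hcore + F)) + e_nuc
        err = F @ D @ S - S @ D @ F
        fock_list.append(F.copy()); err_list.append(err.copy())
        if len(fock_list) > 8:
            fock_list.pop(0); err_list.pop(0)
        if abs(E - E_old) < tol and np.max(np.abs(err)) < 1e-9:
            return E, eps, C
        E_old = E
        # DIIS extrapolation
        m = len(fock_list)
        if m > 1:
            B = -np.ones((m + 1, m + 1)); B[m, m] = 0.0
            for a in range(m):
                for b in range(m):
                    B[a, b] = np.sum(err_list[a] * err_list[b])
            rhs = np.zeros(m + 1); rhs[m] = -1.0
            try:
                c = np.linalg.solve(B, rhs)[:m]
                F = sum(ci * Fi for ci, Fi in zip(c, fock_list))
            except np.linalg.LinAlgError:
                pass
    raise RuntimeError("SCF did not converge")


def mo_integrals(Hcore, g, C):
    h_mo = C.T @ Hcore @ C
    g_mo = np.einsum("pqrs,pi,qj,rk,sl->ijkl", g, C, C, C, C, optimize=True)
    return h_mo, g_mo


def write_fcidump(path, h, g, e_core, n_elec, ms2=0, thresh=1e-12):
    n = h.shape[0]
    with open(path, "w") as f:
        f.write(" &FCI NORB=%d,NELEC=%d,MS2=%d,\n" % (n, n_elec, ms2))
        f.write("  ORBSYM=" + "1," * n + "\n")
        f.write("  ISYM=1,\n &END\n")
        for p in range(n):
            for q in range(p + 1):
                pq = p * (p + 1) // 2 + q
                for r in range(p + 1):
                    for s in range(r + 1):
                        rs = r * (r + 1) // 2 + s
                        if rs > pq:
                            continue
                        v = g[p, q, r, s]
                        if abs(v) > thresh:
                            f.write("%23.16e %3d %3d %3d %3d\n"
                                    % (v, p + 1, q + 1, r + 1, s + 1))
        for p in range(n):
            for q in range(p + 1):
                if abs(h[p, q]) > thresh:
                    f.write("%23.16e %3d %3d   0   0\n" % (h[p, q], p + 1, q + 1))
        f.write("%23.16e   0   0   0   0\n" % e_core)


# ------------------------------------------------------- determinant-basis FCI
def ladder_ops(n_so):
    ops = []
    Z = csr_matrix(np.array([[1.0, 0.0], [0.0, -1.0]]))
    Ad = csr_matrix(np.array([[0.0, 0.0], [1.0, 0.0]]))  # |1><0|, qubit0 = LSB
    I2 = spidentity(2, format="csr")
    for p in range(n_so):
        op = csr_matrix(np.array([[1.0]]))
        for q in range(n_so):  # q = 0 is least significant -> rightmost kron
            if q < p:
                m = Z
            elif q == p:
                m = Ad
            else:
                m = I2
            op = kron(m, op, format="csr")
        ops.append(op)
    return ops


def fci_energy(h, g, e_core, n_alpha, n_beta):
    n = h.shape[0]
    n_so = 2 * n
    ad = ladder_ops(n_so)
    a = [x.T for x in ad]
    dim = 2 ** n_so
    H = csr_matrix((dim, dim))
    so = lambda p, s: 2 * p + s
    for p in range(n):
        for q in range(n):
            if abs(h[p, q]) > 1e-14:
                for s in range(2):
                    H = H + h[p, q] * (ad[so(p, s)] @ a[so(q, s)])
    for p in range(n):
        for q in range(n):
            for r in range(n):
                for s in range(n):
                    v = g[p, q, r, s]
                    if abs(v) > 1e-14:
                        for s1 in range(2):
                            for s2 in range(2):
                                H = H + 0.5 * v * (ad[so(p, s1)] @ ad[so(r, s2)]
                                                   @ a[so(s, s2)] @ a[so(q, s1)])
    # restrict to the particle-number / Sz sector
    amask = sum(1 << (2 * k) for k in range(n))
    bmask = sum(1 << (2 * k + 1) for k in range(n))
    idx = [i for i in range(dim)
           if bin(i & amask).count("1") == n_alpha
           and bin(i & bmask).count("1") == n_beta]
    Hs = H[np.ix_(idx, idx)].toarray()
    w = np.linalg.eigvalsh(Hs)
    return w[0] + e_core


def make(molname, atoms, path, n_elec, check_fci=True):
    bfs = build_basis(atoms)
    S, T, V = one_electron(bfs, atoms)
    g = two_electron(bfs)
    e_nuc = nuclear_repulsion(atoms)
    E_hf, eps, C = rhf(S, T, V, g, n_elec, e_nuc)
    h_mo, g_mo = mo_integrals(T + V, g, C)
    write_fcidump(path, h_mo, g_mo, e_nuc, n_elec)
    e_fci = None
    if check_fci and h_mo.shape[0] <= 7:
        e_fci = fci_energy(h_mo, g_mo, e_nuc, n_elec // 2, n_elec // 2)
        assert e_fci < E_hf + 1e-10
    print("%-22s E(RHF) = %.10f   E(FCI) = %s" % (
        os.path.basename(path), E_hf,
        "%.10f" % e_fci if e_fci is not None else "skipped"))
    return E_hf, e_fci


def geom(mol, R):
    RB = R * ANG2BOHR
    if mol == "lih":
        return [("Li", (0, 0, 0)), ("H", (0, 0, RB))]
    if mol == "beh2":
        return [("H", (0, 0, -RB)), ("Be", (0, 0, 0)), ("H", (0, 0, RB))]
    if mol == "h6":
        return [("H", (0, 0, k * RB)) for k in range(6)]
    if mol == "h2":
        return [("H", (0, 0, 0)), ("H", (0, 0, RB))]
    raise ValueError(mol)


def main():
    out = os.path.join(os.path.dirname(__file__), "..", "inst", "extdata", "fcidump")
    os.makedirs(out, exist_ok=True)
    nel = {"h2": 2, "lih": 4, "beh2": 6, "h6": 6}

    jobs = [("h2", [0.7414])]
    jobs.append(("lih", [round(x, 2) for x in np.arange(0.8, 4.01, 0.2)] + [2.39]))
    jobs.append(("beh2", [1.2, 1.8, 2.39, 3.0]))
    jobs.append(("h6", [0.8, 1.2, 1.6, 2.0]))

    for mol, Rs in jobs:
        for R in Rs:
            tag = ("%.4f" % R).rstrip("0").rstrip(".")
            path = os.path.join(out, "%s_%s.fcidump" % (mol, tag))
            make(mol, geom(mol, R), path, nel[mol], check_fci=(mol != "beh2"))


if __name__ == "__main__":
    main()
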