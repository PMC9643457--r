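#!/usr/bin/env python
"""Arbitrary-precision kernel for the layered photon-diffusion solver.

Reads one JSON request on stdin, writes one JSON response on stdout.
All arithmetic runs in mpmath at the requested decimal precision (dps);
34 digits corresponds to quadruple precision, 71 to octuple. The layered
Green's function uses the same bounded reflection-coefficient sweep as the
double-precision path; in mp arithmetic there is no overflow or underflow
to guard against.

Ops:
  roots        {n_max, dps}                      -> roots (str), residual j0
  j0_at        {x: [str], dps}                   -> j0 values (str)
  fluence_ss   {medium, rho[], n_terms, dps}     -> values[]
  fluence_td   {medium, rho[], times[], n_laplace, t1, t2, phi, n_terms, dps}
                                                 -> values[rho][time]
  ss_semiinf   {mu_a, mu_sp, A, rho[], dps}      -> values[]
  td_semiinf   {mu_a, mu_sp, n_rel, A, rho[], times[], dps} -> values[rho][time]
"""
import sys, json, math
from mpmath import mp, mpf, mpc, sqrt, exp, cos, sin, besselj, besseljzero, pi

C0 = mpf("29.9792458")


# ---- Bessel evaluation -----------------------------------------------------
# Hankel asymptotic expansion for J0/J1 at large argument; far faster than
# mpmath.besselj for the tens of thousands of evaluations the Hankel sum
# needs. Valid once exp(-2x) is below the working epsilon.

def asym_cutoff():
    return 1.2 * mp.dps + 10


def j01_asym(x):
    """Return (J0(x), J1(x)) via the P/Q asymptotic series."""
    inv2 = 1 / (x * x)
    eps = mpf(10) ** (-mp.dps - 4)
    # order 0
    res = []
    for nu in (0, 1):
        fournu2 = 4 * nu * nu
        a = mpf(1)
        p = mpf(1)
        q = mpf(0)
        powx = 1 / x
        m = 1
        while True:
            a = a * (fournu2 - (2 * m - 1) ** 2) / (8 * m)
            term = a * powx
            if m % 2 == 1:
                q += term if (m % 4 == 1) else -term
            else:
                p += term if (m % 4 == 0) else -term
            if abs(term) < eps or m > 4 * mp.dps:
                break
            powx = powx / x
            m += 1
        chi = x - (2 * nu + 1) * pi / 4
        res.append(sqrt(2 / (pi * x)) * (p * cos(chi) - q * sin(chi)))
    return res[0], res[1]


def j0(x):
    if x >= asym_cutoff():
        return j01_asym(x)[0]
    return besselj(0, x)


def j1(x):
    if x >= asym_cutoff():
        return j01_asym(x)[1]
    return besselj(1, x)


def j0_roots(n_max):
    """First n_max positive zeros of J0: float McMahon guess + mp Newton."""
    roots = []
    for n in range(1, n_max + 1):
        b = (n - 0.25) * math.pi
        x0 = b + 1 / (8 * b) - 124 / (3 * (8 * b) ** 3) + 120928 / (15 * (8 * b) ** 5)
        if x0 < asym_cutoff():
            roots.append(besseljzero(0, n))
            continue
        x = mpf(x0)
        for _ in range(3):
            f0, f1 = j01_asym(x)
            x = x + f0 / f1          # J0' = -J1
        roots.append(x)
    return roots


# ---- medium ----------------------------------------------------------------

class Medium:
    def __init__(self, spec):
        self.mu_a = [mpf(str(v)) for v in spec["mu_a"]]
        self.mu_sp = [mpf(str(v)) for v in spec["mu_sp"]]
        self.l = [mpf(str(v)) for v in spec["thickness"]]
        self.n_r = mpf(str(spec["n_r"]))
        self.radius = mpf(str(spec["radius"]))
        self.A = mpf(str(spec["A"]))
        self.nl = len(self.mu_a)
        self.D = [1 / (3 * m) for m in self.mu_sp]
        self.z0 = 1 / self.mu_sp[0]
        self.zb_top = 2 * self.A * self.D[0]
        self.zb_bot = 2 * self.A * self.D[-1]
        self.a_prime = self.radius + self.zb_top
        self.c = C0 / self.n_r


def greens_surface(med, s, sbar, z_mode, z=None):
    """G at z = 0 ('top'), z = L ('bottom'), or depth z in layer 1 ('z1')."""
    nl = med.nl
    alpha = []
    for k in range(nl):
        a = sqrt((med.mu_a[k] + sbar / med.c) / med.D[k] + s * s)
        if a.real < 0:
            a = -a
        alpha.append(a)
    E = [exp(-2 * alpha[k] * med.l[k]) for k in range(nl)]
    R = [None] * nl
    R[nl - 1] = exp(-2 * alpha[nl - 1] * med.zb_bot)
    for k in range(nl - 2, -1, -1):
        xv = R[k + 1] * E[k + 1]
        bk = med.D[k] * alpha[k]
        bk1 = med.D[k + 1] * alpha[k + 1]
        R[k] = ((bk1 - bk) + (bk1 + bk) * xv) / ((bk1 + bk) + (bk1 - bk) * xv)
    a1 = alpha[0]
    e_zb = exp(-2 * a1 * med.zb_top)
    S0, C0_ = 1 - e_zb, 1 + e_zb
    R1E1 = R[0] * E[0]
    inv = 1 / (med.D[0] * a1 * (S0 * (1 + R1E1) + C0_ * (1 - R1E1)))
    if z_mode in ("top", "z1"):
        zq = mpf(0) if z_mode == "top" else mpf(str(z))
        if zq <= med.z0:
            num = (exp(-a1 * (med.z0 - zq))
                   - R[0] * exp(-a1 * (2 * med.l[0] - med.z0 - zq))
                   - exp(-a1 * (med.z0 + zq + 2 * med.zb_top))
                   + R[0] * exp(-a1 * (2 * med.l[0] - med.z0 + zq + 2 * med.zb_top)))
        else:
            S_z0 = 1 - exp(-2 * a1 * (med.z0 + med.zb_top))
            num = S_z0 * (exp(-a1 * (zq - med.z0))
                          - R[0] * exp(-a1 * (2 * med.l[0] - zq - med.z0)))
        return num * inv
    # bottom, z = L
    S_z0 = 1 - exp(-2 * a1 * (med.z0 + med.zb_top))
    X = a1 * med.z0
    P = mpc(1)
    for j in range(nl - 1):
        X = X - alpha[j] * med.l[j]
        P = P * (1 - R[j]) / (1 - R[j + 1] * E[j + 1])
    lk = med.l[nl - 1]
    num = (1 - R[nl - 1]) * exp(X - alpha[nl - 1] * lk)
    return S_z0 * P * num * inv


def hankel_weights(med, n_terms, rho_list):
    roots = j0_roots(n_terms)
    w = [1 / j1(r) ** 2 for r in roots]
    s = [r / med.a_prime for r in roots]
    j0r = [[j0(sv * r) for sv in s] for r in rho_list]
    return roots, w, s, j0r


def fluence_ss_hp(med, rho_list, n_terms, z=0):
    _, w, s, j0r = hankel_weights(med, n_terms, rho_list)
    norm = 1 / (pi * med.a_prime ** 2)
    out = []
    zq = mpf(str(z))
    mode = "top" if zq == 0 else "z1"
    g = [greens_surface(med, sv, mpf(0), mode, zq) for sv in s]
    for ri in range(len(rho_list)):
        acc = mpf(0)
        for i in range(n_terms):
            acc += g[i] * j0r[ri][i] * w[i]
        out.append(acc * norm)
    return out


def fluence_ss_batch(configs, n_terms):
    """Several steady-state evaluations sharing one root table; J0 rows are
    cached per (a_prime, rho)."""
    roots = j0_roots(n_terms)
    w = [1 / j1(r) ** 2 for r in roots]
    j0_cache = {}
    out = []
    for cf in configs:
        med = Medium(cf["medium"])
        zq = mpf(str(cf.get("z", 0)))
        s = [r / med.a_prime for r in roots]
        mode = "top" if zq == 0 else "z1"
        g = [greens_surface(med, sv, mpf(0), mode, zq) for sv in s]
        norm = 1 / (pi * med.a_prime ** 2)
        vals = []
        for r in aslist(cf["rho"]):
            key = (mp.nstr(med.a_prime, 25), str(r))
            if key not in j0_cache:
                rr = mpf(str(r))
                j0_cache[key] = [j0(sv * rr) for sv in s]
            row = j0_cache[key]
            acc = mpf(0)
            for i in range(n_terms):
                acc += g[i] * row[i] * w[i]
            vals.append(acc * norm)
        out.append([float(v) for v in vals])
    return out


def contour(n_evals, t1, t2, phi):
    lam = t2 / t1
    A = mp.acosh(((pi - 2 * phi) * lam + 4 * phi - pi) / ((4 * phi - pi) * sin(phi)))
    mu_c = (4 * pi * phi - pi * pi) * n_evals / (A * t2)
    h = A / n_evals
    nodes, dnodes = [], []
    for k in range(1, n_evals + 1):
        x = (k - mpf(1) / 2) * h
        nodes.append(mu_c * (1 + sin(mpc(0, 1) * x - phi)))
        dnodes.append(mpc(0, 1) * mu_c * cos(mpc(0, 1) * x - phi))
    return nodes, dnodes, h


def fluence_td_hp(med, rho_list, times, n_evals, t1, t2, phi, n_terms):
    nodes, dnodes, h = contour(n_evals, mpf(str(t1)), mpf(str(t2)), mpf(str(phi)))
    _, w, s, j0r = hankel_weights(med, n_terms, rho_list)
    norm = 1 / (pi * med.a_prime ** 2)
    # H[k][ri]: Hankel sum at node k
    H = []
    for k in range(n_evals):
        g = [greens_surface(med, sv, nodes[k], "top") for sv in s]
        row = []
        for ri in range(len(rho_list)):
            acc = mpc(0)
            for i in range(n_terms):
                acc += g[i] * j0r[ri][i] * w[i]
            row.append(acc * norm * dnodes[k] / mpc(0, 1))
        H.append(row)
    out = []
    for ri in range(len(rho_list)):
        vals = []
        for t in times:
            tt = mpf(str(t))
            acc = mpf(0)
            for k in range(n_evals):
                acc += (exp(nodes[k] * tt) * H[k][ri]).real
            vals.append(acc * h / pi)
        out.append(vals)
    return out


def td_semiinf_hp(mu_a, mu_sp, n_rel, A, rho_list, times):
    D = 1 / (3 * mu_sp)
    z0 = 1 / mu_sp
    zb = 2 * A * D
    c = C0 / n_rel
    out = []
    for r in rho_list:
        r1s = r * r + z0 * z0
        r2s = r * r + (z0 + 2 * zb) ** 2
        vals = []
        for t in times:
            tt = mpf(str(t))
            v = (c * (4 * pi * D * c * tt) ** mpf("-1.5") * exp(-mu_a * c * tt)
                 * (exp(-r1s / (4 * D * c * tt)) - exp(-r2s / (4 * D * c * tt))))
            vals.append(v)
        out.append(vals)
    return out


def aslist(v):
    return v if isinstance(v, list) else [v]


def main():
    req = json.load(sys.stdin)
    mp.dps = int(req.get("dps", 34))
    op = req["op"]
    if op == "roots":
        n_max = int(req["n_max"])
        roots = j0_roots(n_max)
        resp = {
            "root_str": [mp.nstr(r, mp.dps, strip_zeros=False) for r in roots],
            "root": [float(r) for r in roots],
            "resid": [float(abs(j0(r))) for r in roots[:: max(1, n_max // 50)]],
        }
    elif op == "j0_at":
        xs = [mpf(x) for x in aslist(req["x"])]
        resp = {"j0": [mp.nstr(j0(x), mp.dps) for x in xs],
                "abs_j0": [float(abs(j0(x))) for x in xs]}
    elif op == "fluence_ss":
        med = Medium(req["medium"])
        rho = [mpf(str(r)) for r in aslist(req["rho"])]
        vals = fluence_ss_hp(med, rho, int(req["n_terms"]), req.get("z", 0))
        resp = {"fluence": [float(v) for v in vals],
                "fluence_str": [mp.nstr(v, mp.dps) for v in vals]}
    elif op == "fluence_ss_batch":
        cfgs = req["configs"]
        if isinstance(cfgs, dict):
            cfgs = [cfgs]
        resp = {"fluence": fluence_ss_batch(cfgs, int(req["n_terms"]))}
    elif op == "fluence_td":
        med = Medium(req["medium"])
        rho = [mpf(str(r)) for r in aslist(req["rho"])]
        vals = fluence_td_hp(med, rho, aslist(req["times"]), int(req["n_laplace"]),
                             req["t1"], req["t2"], req.get("phi", 1.09),
                             int(req["n_terms"]))
        resp = {"fluence": [[float(v) for v in row] for row in vals]}
    elif op == "ss_semiinf":
        mu_a, mu_sp = mpf(str(req["mu_a"])), mpf(str(req["mu_sp"]))
        A = mpf(str(req["A"]))
        D = 1 / (3 * mu_sp)
        z0 = 1 / mu_sp
        zb = 2 * A * D
        mu_eff = sqrt(mu_a / D)
        vals = []
        for r in [mpf(str(r)) for r in aslist(req["rho"])]:
            r1 = sqrt(r * r + z0 * z0)
            r2 = sqrt(r * r + (z0 + 2 * zb) ** 2)
            vals.append((exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D))
        resp = {"fluence": [float(v) for v in vals],
                "fluence_str": [mp.nstr(v, mp.dps) for v in vals]}
    elif op == "td_semiinf":
        vals = td_semiinf_hp(mpf(str(req["mu_a"])), mpf(str(req["mu_sp"])),
                             mpf(str(req["n_rel"])), mpf(str(req["A"])),
                             [mpf(str(r)) for r in aslist(req["rho"])], aslist(req["times"]))
        resp = {"fluence": [[float(v) for v in row] for row in vals]}
    else:
        raise SystemExit("unknown op: %s" % op)
    json.dump(resp, sys.stdout)


if __name__ == "__main__":
    main()
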