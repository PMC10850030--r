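#!/usr/bin/env python
"""Independent reference implementation of the two-node MEMI PET model.

Implements the same published formulation as the R package (three-node
steady-state balance with Gagge-type vasomotor/sudomotor control; PET as
the reference-environment air temperature reproducing the actual core/skin
state and regulatory sweat flux), but coded independently: the node state
is solved simultaneously with scipy.optimize.fsolve and the reference
search uses scipy.optimize.brentq. Used once to freeze the cross-check
grid in tests/testthat/pet_reference_grid.csv.

Usage: python tools/pet_reference.py > tests/testthat/pet_reference_grid.csv
"""
import sys
import numpy as np
from scipy.optimize import fsolve, brentq

SIGMA = 5.67e-8
C_AIR = 1010.0
L_VAP = 2.42e6
EM_SKIN = 0.99
EM_CLOTH = 0.95
F_EFF = 0.725
LEWIS_HPA = 1.65
P_REF = 1013.25

# standardized person
AGE, HT, WT, CLO, WORK = 35.0, 1.75, 75.0, 0.9, 80.0


def es(t):
    return 6.112 * np.exp(17.62 * t / (243.12 + t))


def body_const():
    a_du = 0.203 * WT ** 0.425 * HT ** 0.725
    basal = 3.45 * WT ** 0.75 * (1 + 0.004 * (30 - AGE)
                                 + 0.010 * (HT * 100 / WT ** (1 / 3) - 43.4))
    m_total = WORK + basal
    facl = (-2.36 + 173.51 * CLO - 100.76 * CLO ** 2 + 19.28 * CLO ** 3) / 100
    facl = min(1.0, max(0.0, facl))
    return dict(a_du=a_du, m=m_total / a_du, m_total=m_total,
                rtv=1.44e-6 * m_total, facl=facl,
                f_cl=1 + 0.31 * CLO, r_cl=0.155 * CLO)


B = body_const()


def hc_of(v, p):
    return (2.67 + 6.5 * max(v, 0.1) ** 0.67) * (p / P_REF) ** 0.55


def respiration(t_a, vpa, p):
    t_ex = 0.47 * t_a + 21
    c_res = C_AIR * (t_ex - t_a) * B["rtv"] / B["a_du"]
    e_res = 0.623 * L_VAP / p * (es(t_ex) - vpa) * B["rtv"] / B["a_du"]
    return c_res + e_res


def blood_flow(t_cr, t_sk):
    dilat = max(0.0, t_cr - 36.6)
    constr = max(0.0, 34.0 - t_sk)
    return min(90.0, max(0.5, (6.3 + 75 * dilat) / (1 + 0.5 * constr)))


def sweat_flux(t_cr, t_sk, e_max):
    m_bl = blood_flow(t_cr, t_sk)
    alpha = 0.0417737 + 0.7451833 / (m_bl + 0.585417)
    t_body = alpha * t_sk + (1 - alpha) * t_cr
    m_rsw = min(500.0, 304.94 * max(0.0, t_body - 36.6))
    e_req = m_rsw * 1e-3 * L_VAP / 3600
    e_diff = max(0.0, 0.06 * e_max)
    return e_diff, max(0.0, min(e_req, e_max - e_diff))


def rad(t_s, t_mrt, em):
    return em * SIGMA * F_EFF * ((t_s + 273.15) ** 4 - (t_mrt + 273.15) ** 4)


def solve_state(t_a, t_mrt, vpa, v, p=P_REF):
    hc = hc_of(v, p)
    q_res = respiration(t_a, vpa, p)

    def system(x):
        t_cr, t_sk, t_cl = x
        m_bl = blood_flow(t_cr, t_sk)
        q_cr_sk = (5.28 + 1.163 * m_bl) * (t_cr - t_sk)
        e_max = LEWIS_HPA * hc * (es(t_sk) - vpa)
        e_diff, e_sw = sweat_flux(t_cr, t_sk, e_max)
        q_bare = (1 - B["facl"]) * (hc * (t_sk - t_a)
                                    + rad(t_sk, t_mrt, EM_SKIN))
        q_cond = B["facl"] * (t_sk - t_cl) / B["r_cl"]
        q_cl_out = B["facl"] * B["f_cl"] * (hc * (t_cl - t_a)
                                            + rad(t_cl, t_mrt, EM_CLOTH))
        return [B["m"] - q_res - q_cr_sk,
                q_cr_sk - (e_diff + e_sw) - q_bare - q_cond,
                q_cond - q_cl_out]

    x0 = np.array([36.9, 33.5, (t_a + t_mrt + 33.5) / 3])
    x, info, ier, msg = fsolve(system, x0, full_output=True)
    if ier != 1 or max(abs(np.array(system(x)))) > 1e-6:
        raise RuntimeError(f"no convergence for {t_a} {t_mrt} {vpa} {v}: {msg}")
    t_cr, t_sk, t_cl = x
    e_max = LEWIS_HPA * hc_of(v, p) * (es(t_sk) - vpa)
    _, e_sw = sweat_flux(t_cr, t_sk, e_max)
    return t_cr, t_sk, e_sw


def pet(t_a, t_mrt, vpa, v, p=P_REF):
    t_cr, t_sk, e_sw = solve_state(t_a, t_mrt, vpa, v, p)
    hc = hc_of(0.1, p)

    def resid(t_x):
        q_res = respiration(t_x, 12.0, p)
        t_cl = brentq(
            lambda tc: B["facl"] * (t_sk - tc) / B["r_cl"]
            - B["facl"] * B["f_cl"] * (hc * (tc - t_x)
                                       + rad(tc, t_x, EM_CLOTH)),
            min(t_sk, t_x) - 10, max(t_sk, t_x) + 10, xtol=1e-8)
        e_max = LEWIS_HPA * hc * (es(t_sk) - 12.0)
        e_diff = max(0.0, 0.06 * e_max)
        e_sk = e_diff + min(e_sw, max(0.0, e_max - e_diff))
        q_bare = (1 - B["facl"]) * (hc * (t_sk - t_x)
                                    + rad(t_sk, t_x, EM_SKIN))
        q_cond = B["facl"] * (t_sk - t_cl) / B["r_cl"]
        return B["m"] - q_res - e_sk - q_bare - q_cond

    return brentq(resid, -50.0, 80.0, xtol=1e-6)


def main():
    rng = np.random.RandomState(20260909)
    rows = []
    while len(rows) < 100:
        t_a = rng.uniform(5, 38)
        t_mrt = t_a + rng.uniform(-5, 30)
        vp_max = min(30.0, 0.95 * es(t_a))
        vp = rng.uniform(3, max(3.5, vp_max))
        v = rng.uniform(0.1, 3.0)
        try:
            val = pet(t_a, t_mrt, vp, v)
        except RuntimeError:
            continue
        rows.append((t_a, t_mrt, vp, v, val))
    sys.stdout.write("T_a,T_mrt,VP,v,PET_ref\n")
    for r in rows:
        sys.stdout.write(",".join(f"{x:.6f}" for x in r) + "\n")


if __name__ == "__main__":
    main()
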