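"""Independent dense LP oracle for the assignment flow network.

Codes the FULL network system directly -- explicit variables for the
source->compound flows, the absorbed volume, the hub->peak flows, and the
peak->target flows, with source conservation, hub conservation, peak
proportionality, peak flow conservation, and target capacities -- and
solves it with scipy's HiGHS interface. Reads a JSON list of instances,
writes a JSON list of {status, objective}.
"""

import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve_instance(inst):
    scales = np.asarray(inst["axis_scales"], float)
    r = float(inst["r"])
    c_abs = float(inst["c_absorption"])
    ndim = len(scales)
    tpos = np.asarray(inst["target_positions"], float).reshape(-1, ndim)
    tw = np.asarray(inst["target_weights"], float).ravel()
    vy = tw.sum()

    peaks = []  # (compound, fraction, position)
    for k, comp in enumerate(inst["compounds"]):
        pos = np.asarray(comp["positions"], float).reshape(-1, ndim)
        w = np.asarray(comp["weights"], float).ravel()
        p = w / w.sum()
        for i in range(len(w)):
            peaks.append((k, p[i], pos[i]))
    K = len(inst["compounds"])
    P = len(peaks)

    arcs = []  # (peak, target, cost)
    for q, (_, _, x) in enumerate(peaks):
        d = np.sqrt((((tpos - x) * scales) ** 2).sum(axis=1))
        for j in np.nonzero(d <= r)[0]:
            arcs.append((q, int(j), float(d[j])))
    nA = len(arcs)
    if nA == 0:
        return {"status": 0, "objective": c_abs * vy}

    # variables: f_sk (K) | f_abs | f_ki (P) | f_ij (nA)
    n = K + 1 + P + nA
    iabs = K
    iki = K + 1
    iij = K + 1 + P

    c = np.zeros(n)
    c[iabs] = c_abs
    for a, (_, _, cost) in enumerate(arcs):
        c[iij + a] = cost

    Aeq, beq = [], []
    row = np.zeros(n)
    row[:K] = 1.0
    row[iabs] = 1.0
    Aeq.append(row)
    beq.append(vy)
    for k in range(K):  # hub conservation
        row = np.zeros(n)
        row[k] = -1.0
        for q, (kk, _, _) in enumerate(peaks):
            if kk == k:
                row[iki + q] = 1.0
        Aeq.append(row)
        beq.append(0.0)
    for q, (k, p, _) in enumerate(peaks):  # proportional hub->peak split
        row = np.zeros(n)
        row[iki + q] = 1.0
        row[k] = -p
        Aeq.append(row)
        beq.append(0.0)
    for q in range(P):  # peak node flow conservation
        row = np.zeros(n)
        row[iki + q] = -1.0
        for a, (qq, _, _) in enumerate(arcs):
            if qq == q:
                row[iij + a] = 1.0
        Aeq.append(row)
        beq.append(0.0)

    Aub, bub = [], []
    for j in range(len(tw)):  # target sink capacities
        row = np.zeros(n)
        hit = False
        for a, (_, jj, _) in enumerate(arcs):
            if jj == j:
                row[iij + a] = 1.0
                hit = True
        if hit:
            Aub.append(row)
            bub.append(tw[j])

    res = linprog(c, A_ub=np.asarray(Aub) if Aub else None,
                  b_ub=np.asarray(bub) if bub else None,
                  A_eq=np.asarray(Aeq), b_eq=np.asarray(beq),
                  method="highs")
    return {"status": int(res.status), "objective": float(res.fun)}


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    out = [solve_instance(inst) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
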