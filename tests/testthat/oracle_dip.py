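"""Exact small-n oracle for the Hartigan dip statistic via LP enumeration.

dip(Fn) = min over unimodal CDFs G of sup_x |Fn(x) - G(x)|.

Reduce to unique sorted values u_1..u_m with cumulative counts c_j (c_0 = 0),
F_hi = c_j/n, F_lo = c_{j-1}/n. A unimodal CDF is convex left of its mode,
concave right of it, nondecreasing, continuous except for a possible atom at
the mode. Enumerate mode placements:
  split(k), k = 1..m : mode at u_k, no atom; convex slope triples on 1..k,
      concave triples on k..m (covers modes in inter-point gaps too).
  atom(p), p = 1..m  : atom at u_p; left-limit v carries the F_lo band at u_p.
Each case is a small LP in (G_1..G_m [, v], d); dip = min over cases.

Reads JSON {"x": [...]} on stdin, writes {"dip": value} on stdout.
"""
import sys, json
import numpy as np
from scipy.optimize import linprog


def solve_case(u, c, n, kind, k):
    m = len(u)
    nv = m + 1 + (1 if kind == "atom" and k > 1 else 0)
    iv = m if (kind == "atom" and k > 1) else None  # 0-based index of v
    idd = nv - 1
    rows, rhs = [], []

    def row(cols, b):
        r = np.zeros(nv)
        for j, co in cols:
            r[j] += co
        rows.append(r)
        rhs.append(b)

    for j in range(m):  # 0-based point j  (point number j+1)
        hi, lo = c[j] / n, (c[j - 1] / n if j > 0 else 0.0)
        relaxed = kind == "atom" and j == k - 1
        #  |G_j - hi| <= d  always
        row([(j, 1), (idd, -1)], hi)
        row([(j, -1), (idd, -1)], -hi)
        if not relaxed:  # |G_j - lo| <= d
            row([(j, 1), (idd, -1)], lo)
            row([(j, -1), (idd, -1)], -lo)
        row([(j, 1)], 1.0)  # G_j <= 1
    for j in range(m - 1):  # monotone
        row([(j, 1), (j + 1, -1)], 0.0)

    dx = np.diff(u)

    def convex(i):  # triple at 0-based i,i+1,i+2
        row([(i, -dx[i + 1]), (i + 1, dx[i + 1] + dx[i]), (i + 2, -dx[i])], 0.0)

    def concave(i):
        row([(i, dx[i + 1]), (i + 1, -dx[i + 1] - dx[i]), (i + 2, dx[i])], 0.0)

    if kind == "split":
        for i in range(m - 2):
            if i + 3 <= k:       # i+2 <= k in 1-based
                convex(i)
            if i + 1 >= k:       # i >= k in 1-based
                concave(i)
    else:
        p = k  # 1-based atom point
        if p > 1:
            lo_p = c[p - 2] / n
            row([(iv, 1), (idd, -1)], lo_p)   # |v - lo_p| <= d
            row([(iv, -1), (idd, -1)], -lo_p)
            row([(p - 2, 1), (iv, -1)], 0.0)  # G_{p-1} <= v
            row([(iv, 1), (p - 1, -1)], 0.0)  # v <= G_p
            for i in range(m - 2):
                if i + 3 <= p - 1:
                    convex(i)
            if p >= 3:  # junction: slope(p-2,p-1) <= slope(p-1, v at u_p)
                row([(p - 3, -dx[p - 2]), (p - 2, dx[p - 2] + dx[p - 3]),
                     (iv, -dx[p - 3])], 0.0)
        for i in range(m - 2):
            if i + 1 >= p:
                concave(i)

    cobj = np.zeros(nv)
    cobj[idd] = 1.0
    res = linprog(cobj, A_ub=np.array(rows), b_ub=np.array(rhs),
                  bounds=[(0, None)] * nv, method="highs")
    return res.fun if res.status == 0 else None


def dip_oracle(x):
    x = np.sort(np.asarray(x, float))
    n = len(x)
    u, counts = np.unique(x, return_counts=True)
    c = np.cumsum(counts)
    vals = []
    for k in range(1, len(u) + 1):
        for kind in ("split", "atom"):
            v = solve_case(u, c, n, kind, k)
            if v is not None:
                vals.append(v)
    return min(vals)


if __name__ == "__main__":
    data = json.load(sys.stdin)
    out = [dip_oracle(x) for x in data["xs"]]
    json.dump({"dip": out}, sys.stdout)
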