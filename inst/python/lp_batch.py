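#!/usr/bin/env python
"""Batch LP solver backend.

Reads a JSON problem bundle (sparse constraint matrix in triplet form, ranged
row/column bounds, a list of tasks each with its own objective/sense and
optional bound overrides), solves every task with scipy's HiGHS interface and
writes a JSON result bundle.  Used by the R package as its linear-programming
backend.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import csr_matrix


def main(inp, outp):
    with open(inp) as fh:
        prob = json.load(fh)

    ncol = prob["ncol"]
    nrow = prob["nrow"]
    A = csr_matrix(
        (prob["A"]["x"], (np.array(prob["A"]["i"]) - 1, np.array(prob["A"]["j"]) - 1)),
        shape=(nrow, ncol),
    )
    def definf(a):
        a = np.array(a, dtype=float)
        a[a >= 1e29] = np.inf
        a[a <= -1e29] = -np.inf
        return a

    rowlb = definf(prob["rowlb"])
    rowub = definf(prob["rowub"])

    results = []
    for task in prob["tasks"]:
        collb = definf(task.get("collb", prob["collb"]))
        colub = definf(task.get("colub", prob["colub"]))
        obj = np.array(task["obj"], dtype=float)
        sense = task.get("sense", "min")
        c = -obj if sense == "max" else obj

        eq = np.abs(rowub - rowlb) < 1e-12
        A_eq = A[eq] if eq.any() else None
        b_eq = rowlb[eq] if eq.any() else None
        ub_rows = ~eq & np.isfinite(rowub)
        lb_rows = ~eq & np.isfinite(rowlb)
        A_ub = None
        b_ub = None
        if ub_rows.any() or lb_rows.any():
            from scipy.sparse import vstack

            parts, bs = [], []
            if ub_rows.any():
                parts.append(A[ub_rows])
                bs.append(rowub[ub_rows])
            if lb_rows.any():
                parts.append(-A[lb_rows])
                bs.append(-rowlb[lb_rows])
            A_ub = vstack(parts)
            b_ub = np.concatenate(bs)

        bounds = list(zip(collb, colub))
        res = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                      bounds=bounds, method="highs")
        status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                  3: "unbounded", 4: "numerical"}.get(res.status, "failed")
        out = {"name": task.get("name", ""), "status": status}
        if res.status == 0:
            out["objective"] = float(-res.fun if sense == "max" else res.fun)
            out["x"] = [float(v) for v in res.x]
        results.append(out)

    with open(outp, "w") as fh:
        json.dump({"results": results}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
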