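"""Mixed-integer linear programming backend.

Reads a problem description from a JSON file (argv[1]), solves one or more
objectives over a shared constraint set with scipy.optimize.milp (HiGHS),
and writes a JSON list of results to argv[2].

Input schema:
  n_var: int
  lb, ub: arrays (values with |v| >= 1e29 are treated as infinite)
  integrality: array of 0/1
  constraints: {nrow, i, j, x, cl, cu}  (1-based triplet indices)
  objectives: [{idx, val, sense}]       (1-based sparse objective)
  options: {mip_rel_gap, time_limit}
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp

INF = 1e29


def _clean(v):
    a = np.asarray(v, dtype=float)
    a[a >= INF] = np.inf
    a[a <= -INF] = -np.inf
    return a


def main():
    with open(sys.argv[1]) as fh:
        inp = json.load(fh)
    n = int(inp["n_var"])
    lb = _clean(inp["lb"])
    ub = _clean(inp["ub"])
    integrality = np.asarray(inp.get("integrality", [0] * n), dtype=int)
    cons = inp["constraints"]
    nrow = int(cons["nrow"])
    constraints = []
    if nrow > 0:
        A = sparse.csc_matrix(
            (
                np.asarray(cons["x"], dtype=float),
                (
                    np.asarray(cons["i"], dtype=int) - 1,
                    np.asarray(cons["j"], dtype=int) - 1,
                ),
            ),
            shape=(nrow, n),
        )
        constraints = LinearConstraint(A, _clean(cons["cl"]), _clean(cons["cu"]))
    opts = inp.get("options", {})
    if not isinstance(opts, dict):  # empty R list serializes as []
        opts = {}
    milp_options = {
        "mip_rel_gap": float(opts.get("mip_rel_gap", 0.0)),
        "time_limit": float(opts.get("time_limit", 600.0)),
        "presolve": bool(opts.get("presolve", True)),
    }
    out = []
    for ob in inp["objectives"]:
        c = np.zeros(n)
        idx = np.asarray(ob["idx"], dtype=int) - 1
        if idx.size:
            c[idx] = np.asarray(ob["val"], dtype=float)
        sense = ob.get("sense", "max")
        sgn = -1.0 if sense == "max" else 1.0
        res = milp(
            c=sgn * c,
            constraints=constraints,
            bounds=Bounds(lb, ub),
            integrality=integrality,
            options=milp_options,
        )
        if res.status == 0:
            out.append(
                {
                    "status": "optimal",
                    "objective": float(sgn * res.fun),
                    "x": [float(v) for v in res.x],
                }
            )
        elif res.status == 2:
            out.append({"status": "infeasible"})
        elif res.status == 3:
            out.append({"status": "unbounded"})
        else:
            out.append({"status": "error", "message": str(res.message)})
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
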