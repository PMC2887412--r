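"""Solve a batch of LP/MILP problems with HiGHS via scipy.optimize.milp.

Usage: python milp.py IN.json OUT.json

IN.json is a list of problems, each an object with:
  ncol      : number of variables
  obj       : objective coefficients (length ncol)
  maximize  : bool
  lb, ub    : variable bounds (+-1e30 encodes infinity)
  vtype     : list of "C" or "B"
  A         : {"i": [...], "j": [...], "x": [...]} 1-based constraint triplets
  sense     : list of "<=", ">=", "=" per constraint row
  rhs       : right-hand sides
  time_limit: optional seconds

OUT.json is a list of {status, objective, x, mip_gap} objects; status is one
of optimal / infeasible / unbounded / limit / error.
"""
import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import milp, LinearConstraint, Bounds

INF = 1e30


def _lst(v):
    return [v] if isinstance(v, str) else list(v)


def _inf(v):
    v = np.atleast_1d(np.asarray(v, dtype=float))
    v = np.where(v >= INF, np.inf, v)
    v = np.where(v <= -INF, -np.inf, v)
    return v


def solve_one(p):
    n = int(p["ncol"])
    obj = np.atleast_1d(np.asarray(p["obj"], dtype=float)).reshape(n)
    maximize = bool(p.get("maximize", True))
    c = -obj if maximize else obj
    lb = _inf(p["lb"]).reshape(n)
    ub = _inf(p["ub"]).reshape(n)
    vtype = _lst(p.get("vtype", ["C"] * n))
    integrality = np.array([1 if t in ("B", "I") else 0 for t in vtype])

    senses = _lst(p.get("sense", []))
    m = len(senses)
    constraints = []
    if m:
        i = np.atleast_1d(np.asarray(p["A"]["i"], dtype=int)).reshape(-1) - 1
        j = np.atleast_1d(np.asarray(p["A"]["j"], dtype=int)).reshape(-1) - 1
        x = np.atleast_1d(np.asarray(p["A"]["x"], dtype=float)).reshape(-1)
        A = sparse.csr_matrix((x, (i, j)), shape=(m, n))
        rhs = np.atleast_1d(np.asarray(p["rhs"], dtype=float)).reshape(m)
        lo = np.where([s == "<=" for s in senses], -np.inf, rhs)
        hi = np.where([s == ">=" for s in senses], np.inf, rhs)
        constraints = [LinearConstraint(A, lo, hi)]

    options = {}
    if p.get("time_limit") is not None:
        options["time_limit"] = float(p["time_limit"])
    options["mip_rel_gap"] = float(p.get("mip_rel_gap", 0.0))

    res = milp(c, constraints=constraints, bounds=Bounds(lb, ub),
               integrality=integrality, options=options)
    status = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded",
              4: "error"}.get(res.status, "error")
    out = {"status": status}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["objective"] = float(obj @ res.x)
    else:
        out["x"] = None
        out["objective"] = None
    gap = getattr(res, "mip_gap", None)
    out["mip_gap"] = float(gap) if gap is not None else None
    return out


def main():
    with open(sys.argv[1]) as fh:
        problems = json.load(fh)
    results = []
    for p in problems:
        try:
            results.append(solve_one(p))
        except Exception as exc:  # report, keep batch going
            results.append({"status": "error", "message": str(exc),
                            "x": None, "objective": None, "mip_gap": None})
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
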