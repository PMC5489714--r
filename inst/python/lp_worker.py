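"""Persistent LP/MILP worker.

Reads one JSON request per line on stdin, writes one JSON response per line
on stdout. All indices are 0-based. Infinite bounds are encoded as the
strings "inf"/"-inf" (JSON has no infinity literal).

Request ops:
  lp       -- single linear program
  lp_batch -- one base LP, many scenarios (bound overrides + objective)
  fva      -- min and max of each listed variable over a fixed region
  milp     -- mixed-integer linear program (HiGHS via scipy.optimize.milp)
  quit     -- terminate
"""
import sys
import json

import numpy as np
from scipy.optimize import linprog, milp, LinearConstraint, Bounds
from scipy.sparse import csr_matrix


def _num(v):
    if v == "inf":
        return np.inf
    if v == "-inf":
        return -np.inf
    return float(v)


def _vec(v):
    return np.array([_num(x) for x in v], dtype=float)


def _sparse(block, n):
    if not block or block["nrow"] == 0:
        return None, None
    A = csr_matrix(
        (np.atleast_1d(np.asarray(block["x"], dtype=float)),
         (np.atleast_1d(np.asarray(block["i"], dtype=int)),
          np.atleast_1d(np.asarray(block["j"], dtype=int)))),
        shape=(int(block["nrow"]), n))
    return A, _vec(block["rhs"])


_LP_STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def _run_lp(c, A_ub, b_ub, A_eq, b_eq, lb, ub, want_x):
    res = linprog(c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq, b_eq=b_eq,
                  bounds=np.column_stack([lb, ub]), method="highs")
    status = _LP_STATUS.get(res.status, "error")
    out = {"status": status}
    if status == "optimal":
        out["obj"] = float(res.fun)
        if want_x:
            out["x"] = [float(v) for v in res.x]
    return out


def op_lp(req):
    n = int(req["n"])
    c = _vec(req["obj"]) if req.get("obj") else np.zeros(n)
    lb, ub = _vec(req["lb"]), _vec(req["ub"])
    A_eq, b_eq = _sparse(req.get("eq"), n)
    A_ub, b_ub = _sparse(req.get("le"), n)
    return _run_lp(c, A_ub, b_ub, A_eq, b_eq, lb, ub, bool(req.get("want_x", False)))


def op_lp_batch(req):
    n = int(req["n"])
    lb0, ub0 = _vec(req["lb"]), _vec(req["ub"])
    A_eq, b_eq = _sparse(req.get("eq"), n)
    A_ub, b_ub = _sparse(req.get("le"), n)
    want_x = bool(req.get("want_x", False))
    results = []
    for sc in req["scenarios"]:
        if not isinstance(sc, dict):  # empty scenario serializes as []
            sc = {}
        lb, ub = lb0.copy(), ub0.copy()
        if sc.get("lb_idx") is not None:
            lb[np.atleast_1d(sc["lb_idx"]).astype(int)] = np.atleast_1d(_vec(np.atleast_1d(sc["lb_val"])))
        if sc.get("ub_idx") is not None:
            ub[np.atleast_1d(sc["ub_idx"]).astype(int)] = np.atleast_1d(_vec(np.atleast_1d(sc["ub_val"])))
        c = _vec(sc["obj"]) if sc.get("obj") else np.zeros(n)
        results.append(_run_lp(c, A_ub, b_ub, A_eq, b_eq, lb, ub, want_x))
    return {"results": results}


def op_fva(req):
    n = int(req["n"])
    lb, ub = _vec(req["lb"]), _vec(req["ub"])
    A_eq, b_eq = _sparse(req.get("eq"), n)
    A_ub, b_ub = _sparse(req.get("le"), n)
    cols = [int(j) for j in req["cols"]]
    mins, maxs = [], []
    for j in cols:
        c = np.zeros(n)
        c[j] = 1.0
        lo = _run_lp(c, A_ub, b_ub, A_eq, b_eq, lb, ub, False)
        if lo["status"] == "infeasible":
            return {"status": "infeasible"}
        hi = _run_lp(-c, A_ub, b_ub, A_eq, b_eq, lb, ub, False)
        mins.append(lo.get("obj") if lo["status"] == "optimal" else "-inf")
        maxs.append(-hi["obj"] if hi["status"] == "optimal" else "inf")
    return {"status": "ok", "min": mins, "max": maxs}


def op_milp(req):
    n = int(req["n"])
    c = _vec(req["obj"])
    lb, ub = _vec(req["lb"]), _vec(req["ub"])
    cons = []
    A_eq, b_eq = _sparse(req.get("eq"), n)
    if A_eq is not None:
        cons.append(LinearConstraint(A_eq, b_eq, b_eq))
    A_ub, b_ub = _sparse(req.get("le"), n)
    if A_ub is not None:
        cons.append(LinearConstraint(A_ub, -np.inf, b_ub))
    integrality = np.asarray(req["integrality"], dtype=int)
    options = {}
    if req.get("time_limit") is not None:
        options["time_limit"] = float(req["time_limit"])
    if req.get("mip_gap") is not None:
        options["mip_rel_gap"] = float(req["mip_gap"])
    res = milp(c, constraints=cons, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    # scipy milp status: 0 optimal, 1 limit reached, 2 infeasible, 3 unbounded
    if res.status == 2:
        return {"status": "infeasible"}
    if res.x is not None:
        status = "optimal" if res.status == 0 else "feasible"
        return {"status": status, "obj": float(res.fun),
                "x": [float(v) for v in res.x],
                "gap": float(res.mip_gap) if res.mip_gap is not None else None}
    if res.status == 3:
        return {"status": "unbounded"}
    return {"status": "timeout"}


OPS = {"lp": op_lp, "lp_batch": op_lp_batch, "fva": op_fva, "milp": op_milp}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            if req.get("op") == "quit":
                break
            out = OPS[req["op"]](req)
        except Exception as exc:  # report, never die mid-session
            out = {"status": "error", "message": f"{type(exc).__name__}: {exc}"}
        sys.stdout.write(json.dumps(out) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
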