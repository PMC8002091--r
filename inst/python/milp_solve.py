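"""Batch MILP runner: reads a JSON list of instances, solves each with
scipy.optimize.milp (HiGHS) and writes a JSON list of results."""
import json
import sys
import warnings

import numpy as np
from scipy.optimize import milp, LinearConstraint, Bounds
from scipy.sparse import coo_matrix

STATUS = {0: "optimal", 1: "limit", 2: "infeasible", 3: "unbounded", 4: "error"}


def solve_one(p, time_limit, objective_target=None, heuristic_effort=None):
    n = int(p["n"])
    c = np.asarray(p["obj"], dtype=float)
    lb = np.asarray(p["lb"], dtype=float)
    ub = np.asarray(p["ub"], dtype=float)
    integrality = np.asarray(p["integrality"], dtype=int)
    ncon = len(p["con_lb"])
    constraints = None
    if ncon:
        a = coo_matrix(
            (np.asarray(p["a_val"], dtype=float),
             (np.asarray(p["a_row"], dtype=int), np.asarray(p["a_col"], dtype=int))),
            shape=(ncon, n),
        ).tocsr()
        constraints = LinearConstraint(
            a, np.asarray(p["con_lb"], dtype=float), np.asarray(p["con_ub"], dtype=float)
        )
    options = {"time_limit": float(time_limit), "presolve": True}
    if objective_target is not None:
        # early stop once an incumbent at or below the target is found
        options["objective_target"] = float(objective_target)
    if heuristic_effort is not None:
        # hard feasibility-style instances need aggressive primal heuristics
        options["mip_heuristic_effort"] = float(heuristic_effort)
    with warnings.catch_warnings():
        warnings.simplefilter("ignore")
        res = milp(
            c=c,
            constraints=constraints,
            bounds=Bounds(lb, ub),
            integrality=integrality,
            options=options,
        )
    out = {"status": STATUS.get(res.status, "error")}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["fun"] = float(res.fun)
    return out


def main():
    with open(sys.argv[1]) as fh:
        payload = json.load(fh)
    time_limit = payload.get("time_limit", 120)
    target = payload.get("objective_target")
    effort = payload.get("heuristic_effort")
    results = [solve_one(p, time_limit, target, effort) for p in payload["problems"]]
    with open(sys.argv[2], "w") as fh:
        json.dump(results, fh)


if __name__ == "__main__":
    main()
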