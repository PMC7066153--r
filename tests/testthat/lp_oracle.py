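"""Independent dense-LP oracle for the transportation problem.

Reads a JSON file holding a list of instances, each with fields
  cost: m x n matrix (list of rows)
  w1:   length-m source weights
  w2:   length-n target weights
solves each as an explicit linear program with scipy.optimize.linprog
(HiGHS), and writes a JSON list of optimal objective values.

Usage: python lp_oracle.py instances.json values.json
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(cost, w1, w2):
    C = np.asarray(cost, dtype=float)
    m, n = C.shape
    A_eq = []
    b_eq = []
    for i in range(m):
        row = np.zeros(m * n)
        row[i * n:(i + 1) * n] = 1.0
        A_eq.append(row)
        b_eq.append(w1[i])
    for j in range(n):
        row = np.zeros(m * n)
        row[j::n] = 1.0
        A_eq.append(row)
        b_eq.append(w2[j])
    res = linprog(C.ravel(), A_eq=np.array(A_eq), b_eq=np.array(b_eq),
                  bounds=(0, None), method="highs")
    if not res.success:
        raise RuntimeError(f"LP failed: {res.message}")
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    values = [solve(inst["cost"], inst["w1"], inst["w2"]) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(values, fh)


if __name__ == "__main__":
    main()
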