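#!/usr/bin/env python
"""Independent dense-LP oracle for the vector-valued W1 distance.

Reads a JSON file with a list of instances and writes a JSON list of optimal
objectives.  Each instance:
  nG:      number of spatial nodes
  edges:   list of [tail, head] 0-based spatial edges
  lengths: per-edge costs
  m:       number of layers
  ledges:  list of [a, b] 0-based layer edges
  gamma:   cross-layer cost
  rho0, rho1: flattened (layer-major: index = layer*nG + gene) marginals

The LP is built from scratch here (fluxes split into nonnegative parts,
equality constraints from the two divergence operators) and solved with
scipy's HiGHS backend; it shares no code with the package's flow solver.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def solve(inst):
    nG = inst["nG"]
    m = inst["m"]
    edges = inst["edges"]
    lengths = inst["lengths"]
    ledges = inst["ledges"]
    gamma = inst["gamma"]
    b = np.asarray(inst["rho0"], float) - np.asarray(inst["rho1"], float)

    n_rows = nG * m
    nu = len(edges) * m       # spatial fluxes, per (edge, layer)
    nw = nG * len(ledges)     # cross-layer fluxes, per (gene, layer edge)

    A = np.zeros((n_rows, nu + nw))
    c = np.zeros(nu + nw)
    col = 0
    for j in range(m):
        for e, (t, h) in enumerate(edges):
            A[j * nG + t, col] = 1.0
            A[j * nG + h, col] = -1.0
            c[col] = lengths[e]
            col += 1
    for f, (a, bb) in enumerate(ledges):
        for i in range(nG):
            A[a * nG + i, col] = 1.0
            A[bb * nG + i, col] = -1.0
            c[col] = gamma
            col += 1

    # split x = x+ - x- to express |x| linearly
    A_full = np.hstack([A, -A])
    c_full = np.concatenate([c, c])
    res = linprog(c_full, A_eq=A_full, b_eq=b, bounds=(0, None),
                  method="highs")
    if not res.success:
        return None
    return float(res.fun)


def main():
    with open(sys.argv[1]) as fh:
        instances = json.load(fh)
    out = [solve(inst) for inst in instances]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
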