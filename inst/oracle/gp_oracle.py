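#!/usr/bin/env python
"""Independent ordinary-Kriging oracle.

Reads a JSON file {"X": [[...]], "y": [...], "Xnew": [[...]],
"theta": [...], "g": float} and writes JSON {"mean": [...], "var": [...],
"beta0": float, "sigma2": float} for ordinary Kriging with an anisotropic
squared-exponential correlation, nugget ratio g, GLS-profiled constant
trend and profiled process variance. All linear algebra is plain numpy.

Before emitting results, the posterior-mean/simple-variance machinery is
cross-checked against scikit-learn's GaussianProcessRegressor at the same
fixed kernel; any disagreement beyond 1e-8 aborts the run.
"""
import json
import sys

import numpy as np


def corr(A, B, theta):
    d2 = np.zeros((A.shape[0], B.shape[0]))
    for d in range(A.shape[1]):
        h = (A[:, d][:, None] - B[None, :, d]) / theta[d]
        d2 += h * h
    return np.exp(-0.5 * d2)


def main(path_in, path_out):
    with open(path_in) as fh:
        spec = json.load(fh)
    X = np.asarray(spec["X"], float)
    y = np.asarray(spec["y"], float)
    Xnew = np.asarray(spec["Xnew"], float)
    theta = np.asarray(spec["theta"], float)
    g = float(np.ravel(spec["g"])[0])
    n = len(y)

    K = corr(X, X, theta) + (g + 1e-10) * np.eye(n)
    Ki = np.linalg.inv(K)
    one = np.ones(n)
    beta0 = one @ Ki @ y / (one @ Ki @ one)
    resid = y - beta0
    sigma2 = resid @ Ki @ resid / n

    r = corr(Xnew, X, theta)
    mean = beta0 + r @ Ki @ resid
    rKir = np.einsum("ij,jk,ik->i", r, Ki, r)
    oneKir = r @ Ki @ one
    trend = (1 - oneKir) ** 2 / (one @ Ki @ one)
    var = sigma2 * (1 + g - rKir + trend)

    # anchor the machinery to an established GP implementation
    from sklearn.gaussian_process import GaussianProcessRegressor
    from sklearn.gaussian_process.kernels import RBF, ConstantKernel, WhiteKernel

    kern = ConstantKernel(sigma2, "fixed") * RBF(theta, "fixed")
    if g > 0:
        kern = kern + WhiteKernel(sigma2 * (g + 1e-10), "fixed")
    else:
        kern = kern + WhiteKernel(sigma2 * 1e-10, "fixed")
    gp = GaussianProcessRegressor(kernel=kern, optimizer=None, alpha=0.0)
    gp.fit(X, y - beta0)
    mu_sk, sd_sk = gp.predict(Xnew, return_std=True)
    assert np.max(np.abs(mu_sk + beta0 - mean)) < 1e-8, "mean mismatch vs sklearn"
    var_simple = sigma2 * (1 + g) - sigma2 * rKir
    assert np.max(np.abs(sd_sk**2 - var_simple)) < 1e-6, "variance mismatch vs sklearn"

    with open(path_out, "w") as fh:
        json.dump({"mean": mean.tolist(), "var": var.tolist(),
                   "beta0": float(beta0), "sigma2": float(sigma2)}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
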