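"""Independent reference implementation of the texture features.

Brute-force numpy implementation of the gray-level co-occurrence,
dependence, size-zone and run-length features plus the first-order 90th
percentile, used as an external cross-check oracle by the test suite.
Reads a JSON job from argv[1] (image, mask, dims in Fortran/column-major
order, settings) and writes a JSON object of feature values to stdout.

Deliberately naive: explicit loops over voxels, pairs and zones, no shared
code with the R package.
"""
import json
import sys

import numpy as np


def discretize(img, mask, n_bins):
    v = img[mask]
    lo, hi = v.min(), v.max()
    lev = np.zeros(img.shape, dtype=int)
    if hi - lo < 1e-300:
        lev[mask] = 1
        return lev
    lev[mask] = np.minimum(n_bins, 1 + np.floor(n_bins * (img[mask] - lo) / (hi - lo)).astype(int))
    return lev


def direction_offsets(mode):
    if mode == "2D":
        return [(1, 0, 0), (0, 1, 0), (1, 1, 0), (1, -1, 0)]
    offs = []
    for dx in (-1, 0, 1):
        for dy in (-1, 0, 1):
            for dz in (-1, 0, 1):
                if (dx, dy, dz) == (0, 0, 0):
                    continue
                if dz > 0 or (dz == 0 and dy > 0) or (dz == 0 and dy == 0 and dx > 0):
                    offs.append((dx, dy, dz))
    return offs


def in_grid(c, shape):
    return all(0 <= c[i] < shape[i] for i in range(3))


def glcm_per_angle(lev, mask, n_bins, mode):
    mats = []
    for off in direction_offsets(mode):
        P = np.zeros((n_bins, n_bins))
        for x in range(lev.shape[0]):
            for y in range(lev.shape[1]):
                for z in range(lev.shape[2]):
                    if not mask[x, y, z]:
                        continue
                    nb = (x + off[0], y + off[1], z + off[2])
                    if in_grid(nb, lev.shape) and mask[nb]:
                        i, j = lev[x, y, z] - 1, lev[nb] - 1
                        P[i, j] += 1
                        P[j, i] += 1
        if P.sum() > 0:
            mats.append(P / P.sum())
    return mats


def glcm_inverse_variance(lev, mask, n_bins, mode):
    vals = []
    for P in glcm_per_angle(lev, mask, n_bins, mode):
        s = 0.0
        for i in range(n_bins):
            for j in range(n_bins):
                if i != j:
                    s += P[i, j] / (i - j) ** 2
        vals.append(s)
    return float(np.mean(vals))


def glcm_mcc(lev, mask, n_bins, mode):
    vals = []
    for P in glcm_per_angle(lev, mask, n_bins, mode):
        px = P.sum(axis=1)
        keep = px > 0
        if keep.sum() < 2:
            continue
        P = P[np.ix_(keep, keep)]
        px = P.sum(axis=1)
        py = P.sum(axis=0)
        n = P.shape[0]
        Q = np.zeros((n, n))
        for i in range(n):
            for j in range(n):
                Q[i, j] = sum(P[i, k] * P[j, k] / (px[i] * py[k]) for k in range(n))
        ev = sorted(np.real(np.linalg.eigvals(Q)), reverse=True)
        vals.append(np.sqrt(max(0.0, min(1.0, ev[1]))))
    return float(np.mean(vals))


def neighbors26(mode):
    offs = direction_offsets(mode)
    return offs + [(-a, -b, -c) for (a, b, c) in offs]


def gldm_dnn(lev, mask, n_bins, mode, alpha=0):
    counts = {}
    for x in range(lev.shape[0]):
        for y in range(lev.shape[1]):
            for z in range(lev.shape[2]):
                if not mask[x, y, z]:
                    continue
                dep = 1
                for off in neighbors26(mode):
                    nb = (x + off[0], y + off[1], z + off[2])
                    if in_grid(nb, lev.shape) and mask[nb] and abs(int(lev[nb]) - int(lev[x, y, z])) <= alpha:
                        dep += 1
                key = (lev[x, y, z], dep)
                counts[key] = counts.get(key, 0) + 1
    nz = sum(counts.values())
    byj = {}
    for (_, j), c in counts.items():
        byj[j] = byj.get(j, 0) + c
    return float(sum(c * c for c in byj.values()) / nz ** 2)


def glszm_sae(lev, mask, n_bins, mode):
    seen = np.zeros(lev.shape, dtype=bool)
    zones = []
    for x in range(lev.shape[0]):
        for y in range(lev.shape[1]):
            for z in range(lev.shape[2]):
                if not mask[x, y, z] or seen[x, y, z]:
                    continue
                g = lev[x, y, z]
                stack = [(x, y, z)]
                seen[x, y, z] = True
                size = 0
                while stack:
                    c = stack.pop()
                    size += 1
                    for off in neighbors26(mode):
                        nb = (c[0] + off[0], c[1] + off[1], c[2] + off[2])
                        if in_grid(nb, lev.shape) and mask[nb] and not seen[nb] and lev[nb] == g:
                            seen[nb] = True
                            stack.append(nb)
                zones.append(size)
    return float(sum(1.0 / s ** 2 for s in zones) / len(zones))


def glrlm_sre(lev, mask, n_bins, mode):
    vals = []
    for off in direction_offsets(mode):
        runs = []
        for x in range(lev.shape[0]):
            for y in range(lev.shape[1]):
                for z in range(lev.shape[2]):
                    if not mask[x, y, z]:
                        continue
                    prev = (x - off[0], y - off[1], z - off[2])
                    if in_grid(prev, lev.shape) and mask[prev] and lev[prev] == lev[x, y, z]:
                        continue  # not a run start
                    length = 1
                    cur = (x, y, z)
                    while True:
                        nxt = (cur[0] + off[0], cur[1] + off[1], cur[2] + off[2])
                        if in_grid(nxt, lev.shape) and mask[nxt] and lev[nxt] == lev[cur]:
                            length += 1
                            cur = nxt
                        else:
                            break
                    runs.append(length)
        vals.append(sum(1.0 / r ** 2 for r in runs) / len(runs))
    return float(np.mean(vals))


def ngtdm_coarseness(lev, mask, n_bins, mode):
    s = np.zeros(n_bins + 1)
    n = np.zeros(n_bins + 1)
    for x in range(lev.shape[0]):
        for y in range(lev.shape[1]):
            for z in range(lev.shape[2]):
                if not mask[x, y, z]:
                    continue
                nbv = []
                for off in neighbors26(mode):
                    nb = (x + off[0], y + off[1], z + off[2])
                    if in_grid(nb, lev.shape) and mask[nb]:
                        nbv.append(lev[nb])
                if not nbv:
                    continue
                i = lev[x, y, z]
                s[i] += abs(i - np.mean(nbv))
                n[i] += 1
    p = n / n.sum()
    denom = float((p * s).sum())
    return 1e6 if denom < 1e-12 else 1.0 / denom


def main():
    with open(sys.argv[1]) as fh:
        job = json.load(fh)

    def scalar(x, default=None):
        if x is None:
            return default
        return x[0] if isinstance(x, list) else x

    dims = [int(d) for d in job["dims"]]
    img = np.array(job["image"], dtype=float).reshape(dims, order="F")
    mask = np.array(job["mask"], dtype=int).reshape(dims, order="F") > 0
    n_bins = int(scalar(job.get("n_bins"), 32))
    mode = str(scalar(job.get("mode"), "3D"))
    lev = discretize(img, mask, n_bins)
    out = {
        "glcm_InverseVariance": glcm_inverse_variance(lev, mask, n_bins, mode),
        "glcm_MCC": glcm_mcc(lev, mask, n_bins, mode),
        "gldm_DependenceNonUniformityNormalized": gldm_dnn(lev, mask, n_bins, mode),
        "glszm_SmallAreaEmphasis": glszm_sae(lev, mask, n_bins, mode),
        "glrlm_ShortRunEmphasis": glrlm_sre(lev, mask, n_bins, mode),
        "ngtdm_Coarseness": ngtdm_coarseness(lev, mask, n_bins, mode),
        "firstorder_90Percentile": float(np.percentile(img[mask], 90)),
    }
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
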