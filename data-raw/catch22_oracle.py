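"""Independent reference implementation of the 22 canonical time-series
statistics, written against numpy/scipy only. Used to freeze the expected
values in tests/testthat/catch22-reference.csv (see freeze_catch22.R).

Conventions shared with the R implementation (documented in the package's
methods vignette): z-score with sample SD; autocorrelation with denominator-N;
histogram bins closed on the right edge; Welch with rectangular window,
floor(n/4.5)-sample segments, 50% overlap, nfft = max(256, next pow2),
angular frequency units.
"""
import sys

import numpy as np
from scipy import signal as sps


def acf(y, lag_max):
    y = y - y.mean()
    n = len(y)
    denom = np.dot(y, y)
    return np.array([np.dot(y[: n - k], y[k:]) / denom
                     for k in range(1, lag_max + 1)])


def first_zero_ac(y):
    a = acf(y, len(y) - 1)
    idx = np.flatnonzero(a <= 0)
    return int(idx[0]) + 1 if idx.size else len(y)


def hist_counts(x, edges):
    idx = np.clip(np.digitize(x, edges) - 1, 0, len(edges) - 2)
    return np.bincount(idx, minlength=len(edges) - 1)


def histogram_mode(y, nbins):
    edges = np.linspace(y.min(), y.max(), nbins + 1)
    counts = hist_counts(y, edges)
    centers = (edges[:-1] + edges[1:]) / 2
    return centers[counts == counts.max()].mean()


def f1ecac(y):
    n = len(y)
    a = np.concatenate([[1.0], acf(y, n - 1)])
    thr = np.exp(-1)
    for k in range(1, n):
        if a[k] < thr:
            return (k - 1) + (a[k - 1] - thr) / (a[k - 1] - a[k])
    return float(n)


def first_min_ac(y):
    a = acf(y, len(y) - 1)
    for k in range(2, len(a)):          # lag k, a[k-1] is lag k
        if a[k - 1] < a[k - 2] and a[k - 1] < a[k]:
            return k
    return len(y)


def histogram_ami(y, tau=2, nbins=5):
    n = len(y)
    edges = np.linspace(y.min() - 0.1, y.max() + 0.1, nbins + 1)
    i1 = np.clip(np.digitize(y[: n - tau], edges) - 1, 0, nbins - 1)
    i2 = np.clip(np.digitize(y[tau:], edges) - 1, 0, nbins - 1)
    joint = np.zeros((nbins, nbins))
    for a_, b_ in zip(i1, i2):
        joint[a_, b_] += 1
    p = joint / joint.sum()
    px = p.sum(axis=1, keepdims=True)
    py = p.sum(axis=0, keepdims=True)
    nz = p > 0
    return float((p[nz] * np.log(p[nz] / (px @ py)[nz])).sum())


def longest_run(b):
    best = cur = 0
    for v in b:
        cur = cur + 1 if v else 0
        best = max(best, cur)
    return best


def symbolize3(z):
    m = len(z)
    order = np.argsort(z, kind="stable")
    r = np.empty(m, dtype=int)
    r[order] = np.arange(1, m + 1)
    return 1 + (r > np.ceil(m / 3)) + (r > np.ceil(2 * m / 3))


def transition_matrix_3ac(y):
    tau = first_zero_ac(y)
    z = y[::tau]
    m = len(z)
    if m < 4:
        return np.nan
    sym = symbolize3(z)
    tm = np.zeros((3, 3))
    for a_, b_ in zip(sym[:-1], sym[1:]):
        tm[a_ - 1, b_ - 1] += 1
    tm /= m - 1
    return float(np.trace(np.cov(tm, rowvar=False, ddof=1)))


def spline_detrend(y):
    n = len(y)
    x = np.arange(1, n + 1, dtype=float)
    mid = (n + 1) / 2
    B = np.column_stack([np.ones(n), x, x**2, x**3,
                         np.maximum(x - mid, 0) ** 3])
    coef, *_ = np.linalg.lstsq(B, y, rcond=None)
    return y - B @ coef


def periodicity_wang(y, th=0.01):
    n = len(y)
    r = spline_detrend(y)
    if np.var(r) == 0:
        return 0
    K = max(3, n // 3)
    a = acf(r, K)                       # a[k-1] is lag k
    for k in range(2, K):
        if a[k - 1] > a[k - 2] and a[k - 1] > a[k] and a[k - 1] > 0:
            seg = a[:k]
            s = np.sign(np.diff(seg))
            troughs = np.flatnonzero(np.diff(s) > 0) + 2   # lag of local min
            if troughs.size:
                tr = troughs.max()
                if a[k - 1] - a[tr - 1] >= th:
                    return k
    return 0


def embed2_expfit_meandiff(y):
    n = len(y)
    tau = max(min(first_zero_ac(y), n // 10), 1)
    a = y[: n - tau]
    b = y[tau:]
    d = np.sqrt(np.diff(a) ** 2 + np.diff(b) ** 2)
    m = len(d)
    mean_d = d.mean()
    w = 3.5 * d.std(ddof=1) / m ** (1 / 3)
    if w <= 0 or d.max() == d.min():
        return np.nan
    nb = int(np.ceil((d.max() - d.min()) / w))
    edges = np.linspace(d.min(), d.max(), nb + 1)
    counts = hist_counts(d, edges)
    bw = edges[1] - edges[0]
    obs = counts / (m * bw)
    centers = (edges[:-1] + edges[1:]) / 2
    return float(np.abs(obs - np.exp(-centers / mean_d) / mean_d).mean())


def ami_fmmi(y):
    L = min(40, len(y) // 2)
    a = acf(y, L)
    ami = -0.5 * np.log(np.maximum(1 - a**2, np.finfo(float).tiny))
    for k in range(2, L):
        if ami[k - 1] < ami[k - 2] and ami[k - 1] < ami[k]:
            return k
    return L


def tauresrat(y):
    return first_zero_ac(np.diff(y)) / first_zero_ac(y)


def outlier_include_mdrmd(w):
    n = len(w)
    inc = 0.01
    if w.max() < inc:
        return 0.0
    n_thr = int(np.floor(w.max() / inc + 1e-10)) + 1
    stats4, counts = [], []
    for j in range(n_thr):
        thr = j * inc
        idx = np.flatnonzero(w >= thr) + 1       # 1-based positions
        counts.append(len(idx))
        stats4.append(np.median(idx) / ((n + 1) / 2) - 1)
    keep = np.array(counts) > 2
    if not keep.any():
        return 0.0
    return float(np.median(np.array(stats4)[keep]))


def welch_rect(y):
    n = len(y)
    nseg = min(max(8, int(np.floor(n / 4.5))), n)
    nov = nseg // 2
    nfft = max(256, int(2 ** np.ceil(np.log2(nseg))))
    f, S = sps.welch(y, fs=2 * np.pi, window="boxcar", nperseg=nseg,
                     noverlap=nov, nfft=nfft, detrend=False,
                     scaling="density", average="mean")
    return f, S


def welch_area51(y):
    f, S = welch_rect(y)
    df = f[1] - f[0]
    return float(S[: len(S) // 5].sum() * df)


def welch_centroid(y):
    f, S = welch_rect(y)
    cs = np.cumsum(S)
    return float(f[np.flatnonzero(cs > cs[-1] / 2)[0]])


def motif_three_hh(y):
    sym = symbolize3(y)
    n = len(sym)
    p = np.zeros((3, 3))
    for a_, b_ in zip(sym[:-1], sym[1:]):
        p[a_ - 1, b_ - 1] += 1
    p /= n - 1
    nz = p > 0
    return float(-(p[nz] * np.log(p[nz])).sum())


def fluct_prop_r1(z, how):
    n = len(z)
    taus = np.unique(np.round(np.exp(np.linspace(np.log(5),
                                                 np.log(n // 2), 50))))
    taus = taus[(taus >= 5) & (taus <= n // 2)].astype(int)
    ntt = len(taus)
    min_pts = 6
    if ntt < 2 * min_pts:
        return np.nan
    FF = []
    for tau in taus:
        nwin = n // tau
        x = np.arange(1, tau + 1, dtype=float)
        vals = []
        for wi in range(nwin):
            seg = z[wi * tau:(wi + 1) * tau]
            b, a = np.polyfit(x, seg, 1)
            res = seg - (a + b * x)
            vals.append((res.max() - res.min()) ** 2 if how == "rsrange"
                        else np.mean(res**2))
        FF.append(np.sqrt(np.mean(vals)))
    FF = np.array(FF)
    if (FF <= 0).any():
        return np.nan
    lt, lf = np.log(taus), np.log(FF)

    def sse(xx, yy):
        b, a = np.polyfit(xx, yy, 1)
        return float(((yy - a - b * xx) ** 2).sum())

    idx = np.arange(min_pts, ntt - min_pts + 2)
    scores = [sse(lt[:i], lf[:i]) / i + sse(lt[i - 1:], lf[i - 1:]) / (ntt - i + 1)
              for i in idx]
    return float(idx[int(np.argmin(scores))] / ntt)


def local_simple_mean3_stderr(y):
    n = len(y)
    pred = (y[: n - 3] + y[1: n - 2] + y[2: n - 1]) / 3
    return float(np.std(y[3:] - pred, ddof=1))


def catch22(values):
    values = np.asarray(values, dtype=float)
    y = (values - values.mean()) / values.std(ddof=1)
    d = np.diff(y)
    out = [
        histogram_mode(y, 5),
        histogram_mode(y, 10),
        f1ecac(y),
        first_min_ac(y),
        histogram_ami(y),
        float(np.mean(d**3)),
        float(np.mean(np.abs(d) > 0.04)),
        float(longest_run(y > y.mean())),
        transition_matrix_3ac(y),
        periodicity_wang(y),
        embed2_expfit_meandiff(y),
        ami_fmmi(y),
        tauresrat(y),
        outlier_include_mdrmd(y),
        outlier_include_mdrmd(-y),
        welch_area51(y),
        float(longest_run(~(d > 0))),
        motif_three_hh(y),
        fluct_prop_r1(np.cumsum(y), "rsrange"),
        fluct_prop_r1(np.cumsum(y[::2]), "dfa"),
        welch_centroid(y),
        local_simple_mean3_stderr(y),
    ]
    return [0.0 if not np.isfinite(v) else float(v) for v in out]


if __name__ == "__main__":
    series = np.loadtxt(sys.argv[1], delimiter=",")   # one series per row
    rows = [catch22(row) for row in np.atleast_2d(series)]
    np.savetxt(sys.argv[2], np.array(rows), delimiter=",", fmt="%.15g")
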