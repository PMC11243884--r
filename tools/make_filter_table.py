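#!/usr/bin/env python
"""Regenerate inst/extdata/wavelet_filters.csv and the frozen reference fixtures.

Tap values for the classical families are the standard published filter tables
(as carried by PyWavelets). The discrete Meyer filter is constructed here from
its frequency-domain definition (102 taps, the conventional length). Beylkin
and Vaidyanathan are the published tables (verified against the QMF
orthonormality conditions below). Run from the repository root:

    python tools/make_filter_table.py
"""
import json
import numpy as np
import pywt

FAMILIES = {
    "haar": "Daubechies",
    "db": "Daubechies",
    "sym": "Symlets",
    "coif": "Coiflets",
    "fk": "Fejer-Korovkin",
    "bl": "Best-localized Daubechies",
    "mb": "Morris minimum-bandwidth",
    "beyl": "Beylkin",
    "vaid": "Vaidyanathan",
    "han": "Han linear-phase moments",
    "dmey": "Discrete Meyer",
    "bior": "BiorSplines",
    "rbio": "ReverseBior",
}

BIOR = "1.1 1.3 1.5 2.2 2.4 2.6 2.8 3.1 3.3 3.5 3.7 3.9 4.4 5.5 6.8".split()

BEYLKIN = [
    0.099305765374, 0.424215360813, 0.699825214057, 0.449718251149,
    -0.110927598348, -0.264497231446, 0.026900308804, 0.155538731877,
    -0.017520746267, -0.088543630623, 0.019679866044, 0.042916387274,
    -0.017460408696, -0.014365807969, 0.010040411845, 0.001484234782,
    -0.002736031626, 0.000640485329,
]
VAIDYANATHAN = [
    -0.000062906118, 0.000343631905, -0.000453956620, -0.000944897136,
    0.002843834547, 0.000708137504, -0.008839103409, 0.003153847056,
    0.019687215010, -0.014853448005, -0.035470398607, 0.038742619293,
    0.055892523691, -0.077709750902, -0.083928884366, 0.131971661417,
    0.135084227129, -0.194450471766, -0.263494802488, 0.201612161775,
    0.635601059872, 0.572797793211, 0.250184129505, 0.045799334111,
]


def check_qmf(h, name, tol=1e-8):
    h = np.asarray(h)
    assert abs(h.sum() - np.sqrt(2)) < tol, name
    assert abs(h @ h - 1) < 1e-10, name
    for k in range(1, len(h) // 2):
        assert abs(h[2 * k:] @ h[:len(h) - 2 * k]) < 1e-10, name


def dmey_filter(taps=102, nfft=2 ** 16):
    """Frequency-sampled orthonormal Meyer lowpass, truncated to `taps` taps."""
    def nu(x):
        x = np.clip(x, 0.0, 1.0)
        return x ** 4 * (35 - 84 * x + 70 * x ** 2 - 20 * x ** 3)

    om = 2 * np.pi * np.fft.fftfreq(nfft)
    a = np.abs(om)
    H = np.where(a <= np.pi / 3, np.sqrt(2),
                 np.where(a <= 2 * np.pi / 3,
                          np.sqrt(2) * np.cos(np.pi / 2 * nu(3 * a / np.pi - 1)),
                          0.0))
    h = np.fft.fftshift(np.real(np.fft.ifft(H)))
    c = nfft // 2
    return h[c - taps // 2: c + taps // 2]


def fmt(v):
    return " ".join("%.17g" % x for x in v)


def main():
    rows = []

    def add(name, family, orthogonal, dec_lo, rec_lo, support, implemented=True):
        rows.append(dict(name=name, family=family, orthogonal=int(orthogonal),
                         support=support if support is not None else "NA",
                         implemented=int(implemented),
                         dec_lo=fmt(dec_lo) if implemented else "",
                         rec_lo=fmt(rec_lo) if implemented else ""))

    def add_pywt(name, family):
        w = pywt.Wavelet(name)
        add(name, family, w.orthogonal, w.dec_lo, w.rec_lo, w.dec_len)
        # verify the high-pass derivation rule used by the R registry
        dec_hi = [(-1) ** (m + 1) * w.rec_lo[m] for m in range(w.dec_len)]
        rec_hi = [(-1) ** m * w.dec_lo[m] for m in range(w.dec_len)]
        assert np.allclose(dec_hi, w.dec_hi), name
        assert np.allclose(rec_hi, w.rec_hi), name

    add_pywt("haar", "Daubechies")
    for i in range(1, 11):
        add_pywt(f"db{i}", "Daubechies")
    for i in range(2, 11):
        add_pywt(f"sym{i}", "Symlets")
    for i in range(1, 6):
        add_pywt(f"coif{i}", "Coiflets")
    for n in (4, 6, 8, 14, 18, 22):
        add(f"fk{n}", "Fejer-Korovkin", True, [], [], n, implemented=False)
    for n in (7, 9, 10):
        add(f"bl{n}", "Best-localized Daubechies", True, [], [], None,
            implemented=False)
    for s, n in (("4.2", 4), ("8.2", 8), ("8.3", 8), ("8.4", 8)):
        add(f"mb{s}", "Morris minimum-bandwidth", True, [], [], n,
            implemented=False)
    check_qmf(BEYLKIN, "beyl")
    add("beyl", "Beylkin", True, list(reversed(BEYLKIN)), BEYLKIN, len(BEYLKIN))
    check_qmf(VAIDYANATHAN, "vaid", tol=1e-7)
    add("vaid", "Vaidyanathan", True, list(reversed(VAIDYANATHAN)),
        VAIDYANATHAN, len(VAIDYANATHAN))
    for s in ("2.3", "3.3", "4.5", "5.5"):
        add(f"han{s}", "Han linear-phase moments", True, [], [], None,
            implemented=False)
    dm = dmey_filter()
    add("dmey", "Discrete Meyer", True, list(reversed(dm)), dm, len(dm))
    for s in BIOR:
        add_pywt(f"bior{s}", "BiorSplines")
    for s in BIOR:
        add_pywt(f"rbio{s}", "ReverseBior")

    assert len(rows) == 75, len(rows)
    assert len({r["family"] for r in rows}) == 12

    cols = ["name", "family", "orthogonal", "support", "implemented",
            "dec_lo", "rec_lo"]
    with open("inst/extdata/wavelet_filters.csv", "w") as f:
        f.write(",".join(cols) + "\n")
        for r in rows:
            f.write(",".join(str(r[c]) for c in cols) + "\n")

    # Frozen reference fixture: periodized single-level and multilevel
    # coefficients for a fixed input, used to pin down the transform phase
    # convention in the R tests.
    rng = np.random.default_rng(20240629)
    x16 = np.round(rng.normal(size=16), 6)
    ref = {"x16": x16.tolist(), "cases": []}
    for wn in ("db2", "sym4", "coif1", "bior2.2", "rbio3.1"):
        w = pywt.Wavelet(wn)
        ca, cd = pywt.dwt(x16, w, mode="periodization")
        lev = pywt.wavedec(x16, w, mode="periodization", level=2)
        ref["cases"].append({
            "wavelet": wn,
            "dwt_a": ca.tolist(), "dwt_d": cd.tolist(),
            "wavedec2_a2": lev[0].tolist(),
            "wavedec2_d2": lev[1].tolist(),
            "wavedec2_d1": lev[2].tolist(),
        })
    with open("tests/testthat/fixtures/pywt_reference.json", "w") as f:
        json.dump(ref, f, indent=1)
    print("wrote", len(rows), "registry rows")


if __name__ == "__main__":
    main()
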