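#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Adaptive-partitioning mutual information on rank coordinates.
//
// Points live in the unit square after dividing ranks by n; cells are split
// at their midpoints while a chi-square heterogeneity statistic over the four
// sub-cells exceeds `chi` (df = 3). Leaf cells contribute
// (n_c/N) * log[(n_c/N) / (w_x * w_y)] where w_x, w_y are the cell's marginal
// rank-width fractions (for complete rank vectors these equal the marginal
// point fractions). `max_depth` > 0 forces splitting to exactly that depth
// (no chi-square test), which pins the final partition for oracle checks.

namespace {

struct ApmiState {
    const std::vector<double>* x;
    const std::vector<double>* y;
    double chi;
    int max_depth;
    double n;      // number of points (rank scale)
    double mi;

    void recurse(std::vector<int>& idx, int lo, int hi,
                 double x1, double x2, double y1, double y2, int depth) {
        const int npts = hi - lo;
        if (npts == 0) return;
        const double xm = 0.5 * (x1 + x2);
        const double ym = 0.5 * (y1 + y2);

        bool split;
        if (max_depth > 0) {
            split = depth < max_depth;
        } else {
            split = false;
            if (npts >= 8 && (x2 - x1) > 1.0 && (y2 - y1) > 1.0) {
                int cnt[4] = {0, 0, 0, 0};
                for (int k = lo; k < hi; ++k) {
                    const int i = idx[k];
                    const int qx = ((*x)[i] <= xm) ? 0 : 1;
                    const int qy = ((*y)[i] <= ym) ? 0 : 1;
                    ++cnt[qx + 2 * qy];
                }
                const double e = npts / 4.0;
                double stat = 0.0;
                for (int q = 0; q < 4; ++q) {
                    const double d = cnt[q] - e;
                    stat += d * d / e;
                }
                split = stat > chi;
            }
        }

        if (!split) {
            const double p = npts / n;
            const double wx = (x2 - x1) / n;
            const double wy = (y2 - y1) / n;
            mi += p * std::log(p / (wx * wy));
            return;
        }

        // partition idx[lo, hi) into the four sub-cells (two stable passes)
        std::vector<int> cell[4];
        for (int k = lo; k < hi; ++k) {
            const int i = idx[k];
            const int qx = ((*x)[i] <= xm) ? 0 : 1;
            const int qy = ((*y)[i] <= ym) ? 0 : 1;
            cell[qx + 2 * qy].push_back(i);
        }
        int pos = lo;
        int starts[5];
        for (int q = 0; q < 4; ++q) {
            starts[q] = pos;
            for (size_t k = 0; k < cell[q].size(); ++k) idx[pos++] = cell[q][k];
        }
        starts[4] = pos;
        const double bx[3] = {x1, xm, x2};
        const double by[3] = {y1, ym, y2};
        for (int q = 0; q < 4; ++q) {
            recurse(idx, starts[q], starts[q + 1],
                    bx[q % 2], bx[q % 2 + 1], by[q / 2], by[q / 2 + 1],
                    depth + 1);
        }
    }
};

double apmi_ranks(const std::vector<double>& xr, const std::vector<double>& yr,
                  double chi, int max_depth) {
    const int n = (int)xr.size();
    if (n < 2) return 0.0;
    ApmiState st;
    st.x = &xr; st.y = &yr; st.chi = chi; st.max_depth = max_depth;
    st.n = (double)n; st.mi = 0.0;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    st.recurse(idx, 0, n, 0.0, (double)n, 0.0, (double)n, 0);
    return st.mi > 0.0 ? st.mi : 0.0;
}

// midranks (average ties) of the values in v
std::vector<double> midranks(const std::vector<double>& v) {
    const int n = (int)v.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return v[a] < v[b]; });
    std::vector<double> r(n);
    int i = 0;
    while (i < n) {
        int j = i;
        while (j + 1 < n && v[ord[j + 1]] == v[ord[i]]) ++j;
        const double avg = 0.5 * (i + j) + 1.0;
        for (int k = i; k <= j; ++k) r[ord[k]] = avg;
        i = j + 1;
    }
    return r;
}

// hybrid MI of two raw value vectors with NA = censored/missing:
// chain-rule decomposition into the 2x2 observed/missing table plus the
// within-quadrant-1 adaptive-partitioning term.
double hpmi_values(const std::vector<double>& xv, const std::vector<double>& yv,
                   double chi, int max_depth, int* quad = 0) {
    const int n = (int)xv.size();
    std::vector<double> xo, yo;
    xo.reserve(n); yo.reserve(n);
    int a = 0, b = 0, c = 0, d = 0;  // (xobs,yobs) (xobs,ymiss) (xmiss,yobs) (both miss)
    for (int i = 0; i < n; ++i) {
        const bool ox = !ISNAN(xv[i]);
        const bool oy = !ISNAN(yv[i]);
        if (ox && oy) { ++a; xo.push_back(xv[i]); yo.push_back(yv[i]); }
        else if (ox) ++b;
        else if (oy) ++c;
        else ++d;
    }
    if (quad) { quad[0] = a; quad[1] = d; quad[2] = c; quad[3] = b; }
    const double N = (double)n;
    const double px_o = (a + b) / N, px_m = (c + d) / N;
    const double py_o = (a + c) / N, py_m = (b + d) / N;
    double mi = 0.0;
    const double cells[4] = {(double)a, (double)b, (double)c, (double)d};
    const double rowp[4] = {px_o, px_o, px_m, px_m};
    const double colp[4] = {py_o, py_m, py_o, py_m};
    for (int q = 0; q < 4; ++q) {
        if (cells[q] > 0.0) {
            const double p = cells[q] / N;
            mi += p * std::log(p / (rowp[q] * colp[q]));
        }
    }
    if (a >= 4) {
        const std::vector<double> xr = midranks(xo);
        const std::vector<double> yr = midranks(yo);
        mi += (a / N) * apmi_ranks(xr, yr, chi, max_depth);
    }
    return mi > 0.0 ? mi : 0.0;
}

} // namespace

// [[Rcpp::export(name = ".cpp_apmi")]]
double cpp_apmi(NumericVector x, NumericVector y,
                double chi = 7.814728, int max_depth = 0) {
    std::vector<double> xv(x.begin(), x.end());
    std::vector<double> yv(y.begin(), y.end());
    const std::vector<double> xr = midranks(xv);
    const std::vector<double> yr = midranks(yv);
    return apmi_ranks(xr, yr, chi, max_depth);
}

// [[Rcpp::export(name = ".cpp_hpmi")]]
List cpp_hpmi(NumericVector x, NumericVector y,
              double chi = 7.814728, int max_depth = 0) {
    std::vector<double> xv(x.begin(), x.end());
    std::vector<double> yv(y.begin(), y.end());
    int quad[4];
    const double mi = hpmi_values(xv, yv, chi, max_depth, quad);
    return List::create(_["mi"] = mi,
                        _["quadrant_counts"] = IntegerVector::create(
                            _["n11"] = quad[0], _["n00"] = quad[1],
                            _["n01"] = quad[2], _["n10"] = quad[3]));
}

// Batch MI over candidate pairs of rows of X (features x samples, NA allowed).
// cols: 1-based column indices (bootstrap resample); estimator:
// 0 = hybrid (hpMI), 1 = complete-case (dMI: apMI on jointly observed only).
// [[Rcpp::export(name = ".cpp_mi_pairs")]]
NumericVector cpp_mi_pairs(NumericMatrix X, IntegerVector reg, IntegerVector tgt,
                           IntegerVector cols, int estimator = 0,
                           double chi = 7.814728, int max_depth = 0) {
    const int npair = reg.size();
    const int nc = cols.size();
    NumericVector out(npair);
    std::vector<double> xv(nc), yv(nc);
    for (int p = 0; p < npair; ++p) {
        const int ri = reg[p] - 1, ti = tgt[p] - 1;
        for (int j = 0; j < nc; ++j) {
            xv[j] = X(ri, cols[j] - 1);
            yv[j] = X(ti, cols[j] - 1);
        }
        if (estimator == 0) {
            out[p] = hpmi_values(xv, yv, chi, max_depth);
        } else {
            std::vector<double> xo, yo;
            for (int j = 0; j < nc; ++j) {
                if (!ISNAN(xv[j]) && !ISNAN(yv[j])) {
                    xo.push_back(xv[j]); yo.push_back(yv[j]);
                }
            }
            if ((int)xo.size() >= 8) {
                out[p] = apmi_ranks(midranks(xo), midranks(yo), chi, max_depth);
            } else {
                out[p] = 0.0;
            }
        }
    }
    return out;
}
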