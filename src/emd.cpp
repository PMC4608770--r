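#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (xs, ys) (xs strictly increasing), evaluated
// at the integer grid 0..n-1 into out. Constant extrapolation outside.
static void splineEval(const std::vector<double>& xs,
                       const std::vector<double>& ys,
                       int n, std::vector<double>& out) {
    int k = (int)xs.size();
    if (k == 1) { std::fill(out.begin(), out.end(), ys[0]); return; }
    if (k == 2) {  // linear
        double slope = (ys[1] - ys[0]) / (xs[1] - xs[0]);
        for (int t = 0; t < n; ++t) {
            double x = t;
            if (x <= xs[0]) out[t] = ys[0];
            else if (x >= xs[1]) out[t] = ys[1];
            else out[t] = ys[0] + slope * (x - xs[0]);
        }
        return;
    }
    // second derivatives via Thomas algorithm (natural BCs)
    std::vector<double> h(k - 1), alpha(k, 0.0), l(k), mu(k), z(k), c(k);
    for (int i = 0; i < k - 1; ++i) h[i] = xs[i + 1] - xs[i];
    for (int i = 1; i < k - 1; ++i)
        alpha[i] = 3.0 * ((ys[i + 1] - ys[i]) / h[i] -
                          (ys[i] - ys[i - 1]) / h[i - 1]);
    l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
    for (int i = 1; i < k - 1; ++i) {
        l[i] = 2.0 * (xs[i + 1] - xs[i - 1]) - h[i - 1] * mu[i - 1];
        mu[i] = h[i] / l[i];
        z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
    }
    c[k - 1] = 0.0;
    for (int i = k - 2; i >= 0; --i) c[i] = z[i] - mu[i] * c[i + 1];
    int seg = 0;
    for (int t = 0; t < n; ++t) {
        double x = t;
        if (x <= xs[0]) { out[t] = ys[0]; continue; }
        if (x >= xs[k - 1]) { out[t] = ys[k - 1]; continue; }
        while (seg < k - 2 && xs[seg + 1] < x) ++seg;
        double dx = x - xs[seg];
        double b = (ys[seg + 1] - ys[seg]) / h[seg] -
                   h[seg] * (c[seg + 1] + 2.0 * c[seg]) / 3.0;
        double d = (c[seg + 1] - c[seg]) / (3.0 * h[seg]);
        out[t] = ys[seg] + b * dx + c[seg] * dx * dx + d * dx * dx * dx;
    }
}

// Strict local extrema of h (sign change of the first difference).
static void findExtrema(const std::vector<double>& h,
                        std::vector<int>& mx, std::vector<int>& mn) {
    mx.clear(); mn.clear();
    int n = (int)h.size();
    int lastSign = 0, lastIdx = 0;
    for (int i = 1; i < n; ++i) {
        double d = h[i] - h[i - 1];
        int s = (d > 0) - (d < 0);
        if (s == 0) continue;
        if (lastSign > 0 && s < 0) mx.push_back(lastIdx);
        else if (lastSign < 0 && s > 0) mn.push_back(lastIdx);
        lastSign = s;
        lastIdx = i;
    }
}

// Empirical mode decomposition by sifting with natural-cubic-spline
// envelopes. Stop criterion per sift: sum(mean^2)/sum(h^2) < sdThresh.
// Returns list(imfs = n x K matrix, residue = numeric(n)).
// [[Rcpp::export]]
List emdC(NumericVector x, int maxImf = 10, int maxSift = 10,
          double sdThresh = 0.05) {
    int n = x.size();
    std::vector<double> r(x.begin(), x.end());
    std::vector<std::vector<double> > imfs;
    std::vector<int> mx, mn;
    std::vector<double> up(n), lo(n), h(n);

    for (int im = 0; im < maxImf; ++im) {
        findExtrema(r, mx, mn);
        if ((int)(mx.size() + mn.size()) < 3) break;
        h = r;
        for (int sift = 0; sift < maxSift; ++sift) {
            findExtrema(h, mx, mn);
            if (mx.empty() || mn.empty()) break;
            std::vector<double> xs, ys;
            // upper envelope: clamp endpoints to first/last maximum value
            xs.clear(); ys.clear();
            xs.push_back(0.0); ys.push_back(h[mx.front()]);
            for (size_t i = 0; i < mx.size(); ++i)
                if (mx[i] > 0 && mx[i] < n - 1) {
                    xs.push_back((double)mx[i]); ys.push_back(h[mx[i]]);
                }
            xs.push_back((double)(n - 1)); ys.push_back(h[mx.back()]);
            splineEval(xs, ys, n, up);
            // lower envelope
            xs.clear(); ys.clear();
            xs.push_back(0.0); ys.push_back(h[mn.front()]);
            for (size_t i = 0; i < mn.size(); ++i)
                if (mn[i] > 0 && mn[i] < n - 1) {
                    xs.push_back((double)mn[i]); ys.push_back(h[mn[i]]);
                }
            xs.push_back((double)(n - 1)); ys.push_back(h[mn.back()]);
            splineEval(xs, ys, n, lo);
            double num = 0.0, den = 0.0;
            for (int t = 0; t < n; ++t) {
                double m = 0.5 * (up[t] + lo[t]);
                num += m * m;
                den += h[t] * h[t];
                h[t] -= m;
            }
            if (den <= 0.0 || num / den < sdThresh) break;
        }
        imfs.push_back(h);
        for (int t = 0; t < n; ++t) r[t] -= h[t];
    }
    int K = (int)imfs.size();
    NumericMatrix M(n, K);
    for (int k = 0; k < K; ++k)
        std::copy(imfs[k].begin(), imfs[k].end(), M.column(k).begin());
    return List::create(_["imfs"] = M,
                        _["residue"] = NumericVector(r.begin(), r.end()));
}
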