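#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Approximate entropy (Pincus): Phi^m - Phi^{m+1}, self-matches included,
// Chebyshev distance, tolerance r (absolute). Fused symmetric pair scan.
// [[Rcpp::export]]
double apenC(NumericVector x, int m, double r) {
    int N = x.size();
    if (N <= m + 1) return NA_REAL;
    const double* p = x.begin();
    int n1 = N - m + 1;      // m-length templates
    int n2 = N - m;          // (m+1)-length templates
    std::vector<int> Cm(n1, 1), Cm1(n2, 1);   // self-matches
    for (int i = 0; i < n1 - 1; ++i) {
        for (int j = i + 1; j < n1; ++j) {
            double d = 0.0;
            for (int k = 0; k < m; ++k) {
                double a = std::fabs(p[i + k] - p[j + k]);
                if (a > d) d = a;
            }
            if (d <= r) { ++Cm[i]; ++Cm[j]; }
            if (j < n2) {   // i < j < n2
                double a = std::fabs(p[i + m] - p[j + m]);
                if (a > d) d = a;
                if (d <= r) { ++Cm1[i]; ++Cm1[j]; }
            }
        }
    }
    double phi1 = 0.0, phi2 = 0.0;
    for (int i = 0; i < n1; ++i) phi1 += std::log((double)Cm[i] / n1);
    for (int i = 0; i < n2; ++i) phi2 += std::log((double)Cm1[i] / n2);
    return phi1 / n1 - phi2 / n2;
}

// Sample entropy (Richman-Moorman): -log(A/B), self-matches excluded.
// Templates i = 1..N-m for both lengths so each m-template has an extension.
// [[Rcpp::export]]
double sampenC(NumericVector x, int m, double r) {
    int N = x.size();
    if (N <= m + 1) return NA_REAL;
    const double* p = x.begin();
    int n = N - m;
    long long A = 0, B = 0;
    for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double d = 0.0;
            for (int k = 0; k < m; ++k) {
                double a = std::fabs(p[i + k] - p[j + k]);
                if (a > d) d = a;
            }
            if (d <= r) {
                ++B;
                if (std::fabs(p[i + m] - p[j + m]) <= r) ++A;
            }
        }
    }
    if (A == 0 || B == 0) return NA_REAL;
    return -std::log((double)A / (double)B);
}

// Fuzzy entropy (Chen): templates are baseline-removed (template mean
// subtracted); similarity weight exp(-(d/r)^nf); self-matches excluded.
// Both template lengths share the same N-m offsets; fused pair scan.
// [[Rcpp::export]]
double fuzzyenC(NumericVector x, int m, double r, double nf) {
    int N = x.size();
    if (N <= m + 1) return NA_REAL;
    const double* p = x.begin();
    int n = N - m;
    int m1 = m + 1;
    std::vector<double> tm((size_t)n * m), tm1((size_t)n * m1);
    for (int i = 0; i < n; ++i) {
        double mu = 0.0;
        for (int k = 0; k < m; ++k) mu += p[i + k];
        mu /= m;
        for (int k = 0; k < m; ++k) tm[(size_t)i * m + k] = p[i + k] - mu;
        double mu1 = 0.0;
        for (int k = 0; k < m1; ++k) mu1 += p[i + k];
        mu1 /= m1;
        for (int k = 0; k < m1; ++k) tm1[(size_t)i * m1 + k] = p[i + k] - mu1;
    }
    const bool sq = (nf == 2.0);
    double inv2 = (r > 0.0) ? 1.0 / (r * r) : 0.0;
    double accm = 0.0, accm1 = 0.0;
    long long cnt = 0;
    for (int i = 0; i < n - 1; ++i) {
        const double* ai = &tm[(size_t)i * m];
        const double* bi = &tm1[(size_t)i * m1];
        for (int j = i + 1; j < n; ++j) {
            const double* aj = &tm[(size_t)j * m];
            double d = 0.0;
            for (int k = 0; k < m; ++k) {
                double v = std::fabs(ai[k] - aj[k]);
                if (v > d) d = v;
            }
            const double* bj = &tm1[(size_t)j * m1];
            double d1 = 0.0;
            for (int k = 0; k < m1; ++k) {
                double v = std::fabs(bi[k] - bj[k]);
                if (v > d1) d1 = v;
            }
            if (r > 0.0) {
                if (sq) {
                    accm  += std::exp(-d * d * inv2);
                    accm1 += std::exp(-d1 * d1 * inv2);
                } else {
                    accm  += std::exp(-std::pow(d / r, nf));
                    accm1 += std::exp(-std::pow(d1 / r, nf));
                }
            } else {
                accm  += (d == 0.0) ? 1.0 : 0.0;
                accm1 += (d1 == 0.0) ? 1.0 : 0.0;
            }
            ++cnt;
        }
    }
    double phim = accm / (double)cnt, phim1 = accm1 / (double)cnt;
    if (phim <= 0.0 || phim1 <= 0.0) return NA_REAL;
    return std::log(phim) - std::log(phim1);
}
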