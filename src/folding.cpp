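#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Additive pair-energy secondary-structure engine.
// Bases are encoded A=0, C=1, G=2, U=3. `E16` is a flattened 4x4 matrix of
// pair energies (kcal/mol, negative for permitted pairs); entries >= BIG/2
// mark forbidden pairs. A pair (i,j) (1-based, i<j) is allowed iff
// j - i > minloop, the pair type is permitted, and neither position is
// masked unpaired by `canPair`.

static const double BIG = 1e9;
static const double EPS = 1e-9;

static inline bool pair_ok(int a, int b, const std::vector<double> &E) {
    return E[a * 4 + b] < BIG / 2;
}

// [[Rcpp::export(name = ".c_fold_mfe")]]
List c_fold_mfe(IntegerVector seq, NumericVector E16, int minloop,
                LogicalVector canPair) {
    const int n = seq.size();
    std::vector<double> E(E16.begin(), E16.end());
    std::vector<int> s(n);
    std::vector<bool> cp(n);
    for (int i = 0; i < n; ++i) { s[i] = seq[i]; cp[i] = canPair[i]; }

    // bestE/bestN over closed intervals [i,j], 0-based; empty => 0 energy.
    std::vector<double> bestE((size_t)n * n, 0.0);
    std::vector<int> bestN((size_t)n * n, 0);
    auto idx = [n](int i, int j) { return (size_t)i * n + j; };
    auto getE = [&](int i, int j) { return (i > j) ? 0.0 : bestE[idx(i, j)]; };
    auto getN = [&](int i, int j) { return (i > j) ? 0 : bestN[idx(i, j)]; };

    for (int span = 1; span <= n; ++span) {
        for (int i = 0; i + span - 1 < n; ++i) {
            int j = i + span - 1;
            double be = getE(i + 1, j);
            int bn = getN(i + 1, j);
            if (cp[i]) {
                for (int k = i + minloop + 1; k <= j; ++k) {
                    if (!cp[k] || !pair_ok(s[i], s[k], E)) continue;
                    double e = E[s[i] * 4 + s[k]] + getE(i + 1, k - 1) +
                               getE(k + 1, j);
                    int nn = 1 + getN(i + 1, k - 1) + getN(k + 1, j);
                    if (e < be - EPS || (std::fabs(e - be) <= EPS && nn < bn)) {
                        be = e; bn = nn;
                    }
                }
            }
            bestE[idx(i, j)] = be;
            bestN[idx(i, j)] = bn;
        }
    }

    // Traceback; among co-optimal (energy, pair count) decompositions prefer
    // pairing the leftmost base with its smallest partner (deterministic,
    // lexicographically smallest pair list).
    std::vector<int> pi, pj;
    std::vector<std::pair<int, int> > stack;
    if (n > 0) stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        double be = bestE[idx(i, j)];
        int bn = bestN[idx(i, j)];
        bool done = false;
        if (cp[i]) {
            for (int k = i + minloop + 1; k <= j && !done; ++k) {
                if (!cp[k] || !pair_ok(s[i], s[k], E)) continue;
                double e = E[s[i] * 4 + s[k]] + getE(i + 1, k - 1) +
                           getE(k + 1, j);
                int nn = 1 + getN(i + 1, k - 1) + getN(k + 1, j);
                if (std::fabs(e - be) <= EPS && nn == bn) {
                    pi.push_back(i + 1);
                    pj.push_back(k + 1);
                    if (k - 1 > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
                    if (j > k + 1) stack.push_back(std::make_pair(k + 1, j));
                    done = true;
                }
            }
        }
        if (!done) stack.push_back(std::make_pair(i + 1, j));
    }

    IntegerMatrix pairs(pi.size(), 2);
    for (size_t r = 0; r < pi.size(); ++r) {
        pairs(r, 0) = pi[r];
        pairs(r, 1) = pj[r];
    }
    return List::create(_["energy"] = (n > 0) ? bestE[idx(0, n - 1)] : 0.0,
                        _["pairs"] = pairs);
}

// McCaskill-style inside-outside recursions for the additive model, with
// per-nucleotide rescaling so 400-nt folds stay within double range.
//
// Inside (scaled):  Zs(i,j) = Zs(i+1,j)/s + sum_k w'(i,k) Zs(i+1,k-1) Zs(k+1,j)
// Outside (scaled): O(i,j)  = O(i-1,j)/s
//                           + w'(i-1,j+1) sum_{m>j} O(i-1,m) Zs(j+2,m)
//                           + sum_{h<i-1} O(h,j) w'(h,i-1) Zs(h+1,i-2)
// p(i,j) = w'(i,j) Zs(i+1,j-1) sum_{m>=j} O(i,m) Zs(j+1,m) / Zs(1,n)
// with w'(a,b) = exp(-E(a,b)/RT)/s^2 and scale s chosen from the MFE.

// [[Rcpp::export(name = ".c_partition")]]
List c_partition(IntegerVector seq, NumericVector E16, double RT, int minloop,
                 LogicalVector canPair, double mfe, bool wantBpp) {
    const int n = seq.size();
    std::vector<double> E(E16.begin(), E16.end());
    std::vector<int> s(n);
    std::vector<bool> cp(n);
    for (int i = 0; i < n; ++i) { s[i] = seq[i]; cp[i] = canPair[i]; }

    const double scale = std::exp(-mfe / (RT * std::max(n, 1))) * 1.4;
    std::vector<double> wp(16, 0.0);
    for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
            if (E[a * 4 + b] < BIG / 2)
                wp[a * 4 + b] = std::exp(-E[a * 4 + b] / RT) / (scale * scale);

    auto allowed = [&](int i, int k) {  // 0-based, i < k
        return (k - i > minloop) && cp[i] && cp[k] && wp[s[i] * 4 + s[k]] > 0;
    };

    // Zs over closed intervals, Zs = 1 for empty intervals.
    std::vector<double> Zs((size_t)n * n, 0.0);
    auto idx = [n](int i, int j) { return (size_t)i * n + j; };
    auto getZ = [&](int i, int j) { return (i > j) ? 1.0 : Zs[idx(i, j)]; };

    for (int span = 1; span <= n; ++span) {
        for (int i = 0; i + span - 1 < n; ++i) {
            int j = i + span - 1;
            double v = getZ(i + 1, j) / scale;
            for (int k = i + minloop + 1; k <= j; ++k)
                if (allowed(i, k))
                    v += wp[s[i] * 4 + s[k]] * getZ(i + 1, k - 1) * getZ(k + 1, j);
            Zs[idx(i, j)] = v;
        }
    }
    const double Ztot = (n > 0) ? Zs[idx(0, n - 1)] : 1.0;
    const double logZ = std::log(Ztot) + n * std::log(scale);

    NumericMatrix bpp(wantBpp ? n : 0, wantBpp ? n : 0);
    if (wantBpp && n > 0) {
        std::vector<double> O((size_t)n * n, 0.0);
        O[idx(0, n - 1)] = 1.0;
        for (int i = 0; i < n; ++i) {
            for (int j = i; j < n; ++j) {
                if (i == 0 && j == n - 1) continue;
                double v = 0.0;
                if (i > 0) {
                    v += O[idx(i - 1, j)] / scale;
                    if (j < n - 1 && allowed(i - 1, j + 1)) {
                        double acc = 0.0;
                        for (int m = j + 1; m < n; ++m)
                            acc += O[idx(i - 1, m)] * getZ(j + 2, m);
                        v += wp[s[i - 1] * 4 + s[j + 1]] * acc;
                    }
                    for (int h = 0; h <= i - 2; ++h)
                        if (allowed(h, i - 1))
                            v += O[idx(h, j)] * wp[s[h] * 4 + s[i - 1]] *
                                 getZ(h + 1, i - 2);
                }
                O[idx(i, j)] = v;
            }
        }
        for (int i = 0; i < n; ++i) {
            for (int j = i + 1; j < n; ++j) {
                if (!allowed(i, j)) continue;
                double T = 0.0;
                for (int m = j; m < n; ++m)
                    T += O[idx(i, m)] * getZ(j + 1, m);
                double p = wp[s[i] * 4 + s[j]] * getZ(i + 1, j - 1) * T / Ztot;
                if (p < 0) p = 0;
                if (p > 1) p = 1;
                bpp(i, j) = p;
                bpp(j, i) = p;
            }
        }
    }
    return List::create(_["logZ"] = logZ, _["bpp"] = bpp);
}
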