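#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <cmath>
#include <map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Distinct-substring-growth complexity.
// For each position i (1-based) the number of new distinct substrings ending
// there is i - l_i, where l_i is the length of the longest suffix of w[1..i]
// that also occurs ending strictly before i (overlapping occurrences count).
// Score = sum_i log2(i - l_i); exported per-nucleotide (divided by length).
// l_i <= l_{i-1} + 1, so candidates are checked downward from there.
// ---------------------------------------------------------------------------

static bool occurs_before(const std::string &w, int i, int len) {
    // does w[i-len+1..i] (0-based end i) occur ending at some i' < i?
    if (len == 0) return true;
    const char *suf = w.data() + (i - len + 1);
    for (int end = i - 1; end >= len - 1; --end) {
        const char *cand = w.data() + (end - len + 1);
        if (std::memcmp(cand, suf, len) == 0) return true;
    }
    return false;
}

// [[Rcpp::export]]
NumericVector icomplexity_cpp(CharacterVector seqs) {
    int m = seqs.size();
    NumericVector out(m);
    for (int r = 0; r < m; ++r) {
        std::string w = as<std::string>(seqs[r]);
        int n = (int)w.size();
        if (n == 0) stop("empty read sequence");
        double I = 0.0;
        int lprev = 0;
        for (int i = 0; i < n; ++i) {
            int l = std::min(lprev + 1, i);
            while (l > 0 && !occurs_before(w, i, l)) --l;
            I += std::log2((double)(i + 1 - l));
            lprev = l;
        }
        out[r] = I / n;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Antisense target-site scan with position-weighted mismatch penalties.
// sRNA positions are 1-based 5'->3'; penalties (mismatch 1, G:U 0.5,
// bulged nt 1) are doubled at sRNA positions 2-13. Bases are coded
// A=0, C=1, G=2, T/U=3, anything else -1. The sRNA pairs antiparallel with
// the target; in an ungapped window starting at t (0-based), sRNA position i
// pairs target position t + n - i. One single-nucleotide bulge on either
// strand is allowed.
// ---------------------------------------------------------------------------

static const double BIG = 1e9;

static inline double pairpen(int s, int t) {
    if (s < 0 || t < 0) return 1.0;          // N never pairs
    int sum = s + t;
    if (sum == 3) return 0.0;                // Watson-Crick
    if (sum == 5) return 0.5;                // G:U wobble
    return 1.0;
}

static inline double posmult(int i) { return (i >= 2 && i <= 13) ? 2.0 : 1.0; }

// E_t(i) = posmult(i) * pairpen(s_i, T[t + n - i]); BIG when out of bounds
static void fill_E(const std::vector<int> &T, const std::vector<int> &s,
                   int t, std::vector<double> &E) {
    int n = (int)s.size();
    int L = (int)T.size();
    for (int i = 1; i <= n; ++i) {
        int idx = t + n - i;
        E[i] = (idx >= 0 && idx < L) ? posmult(i) * pairpen(s[i - 1], T[idx])
                                     : BIG;
    }
}

struct Site { int t, var, j, c; double score; };

// core windowed scan; emits the best-scoring duplex variant per window start
static void scan_core(const std::vector<int> &T, const std::vector<int> &s,
                      double max_score, std::vector<Site> &sites) {
    int L = (int)T.size(), n = (int)s.size();
    sites.clear();
    if (L < n) return;
    std::vector<double> Em(n + 1), E0(n + 1), Ep(n + 1);
    std::vector<double> pref(n + 1), suf(n + 2), prefP(n + 1), prefM(n + 1);
    for (int t = 0; t <= L - n + 1; ++t) {
        fill_E(T, s, t - 1, Em);
        fill_E(T, s, t, E0);
        fill_E(T, s, t + 1, Ep);
        pref[0] = prefP[0] = prefM[0] = 0.0;
        for (int i = 1; i <= n; ++i) {
            pref[i] = pref[i - 1] + E0[i];
            prefP[i] = prefP[i - 1] + Ep[i];
            prefM[i] = prefM[i - 1] + Em[i];
        }
        suf[n + 1] = 0.0;
        for (int i = n; i >= 1; --i) suf[i] = suf[i + 1] + E0[i];

        double best = BIG;
        int best_var = 0, best_j = 0, best_c = -1;

        // ungapped: window [t, t+n-1]
        if (t <= L - n && pref[n] < BIG) {
            best = pref[n];
            best_var = 0; best_j = 0; best_c = t + n - 10;
        }
        // target bulge between sRNA positions j and j+1: window [t, t+n]
        if (t <= L - n - 1) {
            for (int j = 1; j <= n - 1; ++j) {
                double sc = prefP[j] + suf[j + 1] + posmult(j + 1) * 1.0;
                if (sc < best) {
                    best = sc; best_var = 1; best_j = j;
                    best_c = (j >= 10) ? t + n - 9 : t + n - 10;
                }
            }
        }
        // sRNA bulge at position j (unpaired sRNA nt): window [t, t+n-2]
        if (t >= 1 || true) {
            for (int j = 2; j <= n - 1; ++j) {
                double sc = prefM[j - 1] + suf[j + 1] + posmult(j) * 1.0;
                if (sc < best) {
                    best = sc; best_var = 2; best_j = j;
                    best_c = (j > 10) ? t + n - 11
                           : (j == 10) ? t + n - 10 : t + n - 10;
                }
            }
        }
        if (best <= max_score && best_c >= 0 && best_c < L) {
            Site st = {t, best_var, best_j, best_c, best};
            sites.push_back(st);
        }
    }
}

// keep the best-scoring site per cleavage coordinate (sites arrive in
// ascending t; cleavage coordinates are non-decreasing up to small offsets)
static void dedupe_by_cleavage(std::vector<Site> &sites) {
    std::map<int, Site> best;
    for (size_t i = 0; i < sites.size(); ++i) {
        std::map<int, Site>::iterator it = best.find(sites[i].c);
        if (it == best.end() || sites[i].score < it->second.score)
            best[sites[i].c] = sites[i];
    }
    sites.clear();
    for (std::map<int, Site>::iterator it = best.begin(); it != best.end(); ++it)
        sites.push_back(it->second);
}

// [[Rcpp::export]]
DataFrame scan_targets_cpp(IntegerVector target, IntegerVector srna,
                           double max_score) {
    std::vector<int> T(target.begin(), target.end());
    std::vector<int> s(srna.begin(), srna.end());
    std::vector<Site> sites;
    scan_core(T, s, max_score, sites);
    int m = (int)sites.size();
    IntegerVector out_t(m), out_var(m), out_j(m), out_c(m);
    NumericVector out_score(m);
    for (int i = 0; i < m; ++i) {
        out_t[i] = sites[i].t; out_var[i] = sites[i].var;
        out_j[i] = sites[i].j; out_c[i] = sites[i].c;
        out_score[i] = sites[i].score;
    }
    return DataFrame::create(_["start"] = out_t, _["variant"] = out_var,
                             _["bulge"] = out_j, _["score"] = out_score,
                             _["cleavage"] = out_c);
}

static double flank_max_at(const double *dense, int L, int c, int w) {
    double mx = 0.0;
    int lo = std::max(0, c - w), hi = std::min(L - 1, c + w);
    for (int p = lo; p <= hi; ++p) {
        if (p >= c - 1 && p <= c + 1) continue;
        if (dense[p] > mx) mx = dense[p];
    }
    return mx;
}

// Process a whole shuffled cohort: for every shuffle x transcript, scan for
// sites (deduped per cleavage coordinate exactly like the R-level observed
// path), then compute the local fold change on the transcript's dense
// 5'-end value vector. Returns the pooled null fold changes and scores.
// [[Rcpp::export]]
List null_site_stats_cpp(List targets, List dense, List cohort,
                         double max_score, int window) {
    int n_tx = targets.size();
    std::vector<std::vector<int> > T(n_tx);
    std::vector<NumericVector> D(n_tx);
    for (int k = 0; k < n_tx; ++k) {
        IntegerVector tv = targets[k];
        T[k].assign(tv.begin(), tv.end());
        D[k] = as<NumericVector>(dense[k]);
    }
    std::vector<double> out_fc, out_as;
    std::vector<Site> sites;
    for (int si = 0; si < cohort.size(); ++si) {
        IntegerVector sv = cohort[si];
        std::vector<int> s(sv.begin(), sv.end());
        for (int k = 0; k < n_tx; ++k) {
            scan_core(T[k], s, max_score, sites);
            if (sites.empty()) continue;
            dedupe_by_cleavage(sites);
            int L = (int)T[k].size();
            for (size_t i = 0; i < sites.size(); ++i) {
                int c = sites[i].c;
                double site = D[k][c];
                double fm = flank_max_at(REAL(D[k]), L, c, window);
                out_fc.push_back((site + 1.0) / (fm + 1.0));
                out_as.push_back(sites[i].score);
            }
        }
    }
    return List::create(_["fc"] = wrap(out_fc), _["score"] = wrap(out_as));
}

// rolling flank maximum: for each site offset, max of values in
// [site - w, site + w] excluding offsets within 1 nt of the site,
// clipped to [0, L)
// [[Rcpp::export]]
NumericVector flank_max_cpp(NumericVector dense, IntegerVector sites, int w) {
    int L = dense.size(), m = sites.size();
    NumericVector out(m);
    for (int k = 0; k < m; ++k) {
        int c = sites[k];
        double mx = 0.0;
        int lo = std::max(0, c - w), hi = std::min(L - 1, c + w);
        for (int p = lo; p <= hi; ++p) {
            if (p >= c - 1 && p <= c + 1) continue;
            if (dense[p] > mx) mx = dense[p];
        }
        out[k] = mx;
    }
    return out;
}
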