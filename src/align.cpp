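#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-cost global Levenshtein distance, two-row DP.
static int lev(const std::string& a, const std::string& b) {
    const size_t m = a.size(), n = b.size();
    std::vector<int> prev(n + 1), cur(n + 1);
    for (size_t j = 0; j <= n; ++j) prev[j] = (int) j;
    for (size_t i = 1; i <= m; ++i) {
        cur[0] = (int) i;
        const char ai = a[i - 1];
        for (size_t j = 1; j <= n; ++j) {
            int best = prev[j - 1] + (ai != b[j - 1]);
            if (prev[j] + 1 < best) best = prev[j] + 1;
            if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    return prev[n];
}

// Semi-global ("infix") end-point distances: out[j] = min over i of
// lev(pattern, text[i..j)), for j = 0..n. Myers (1999) bit-parallel scan for
// patterns up to 64 nt, column DP otherwise.
static void infix_end_dists(const std::string& pat, const std::string& text,
                            std::vector<int>& out) {
    const size_t m = pat.size(), n = text.size();
    out.assign(n + 1, (int) m);
    if (m == 0) { std::fill(out.begin(), out.end(), 0); return; }
    if (m <= 64) {
        uint64_t Peq[256];
        std::fill(Peq, Peq + 256, 0ULL);
        for (size_t i = 0; i < m; ++i)
            Peq[(unsigned char) pat[i]] |= (1ULL << i);
        uint64_t Pv = (m == 64) ? ~0ULL : ((1ULL << m) - 1);
        uint64_t Mv = 0;
        int score = (int) m;
        const uint64_t mbit = 1ULL << (m - 1);
        for (size_t j = 0; j < n; ++j) {
            const uint64_t Eq = Peq[(unsigned char) text[j]];
            const uint64_t Xv = Eq | Mv;
            const uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
            uint64_t Ph = Mv | ~(Xh | Pv);
            uint64_t Mh = Pv & Xh;
            if (Ph & mbit) ++score;
            else if (Mh & mbit) --score;
            Ph <<= 1;
            Mh <<= 1;
            Pv = Mh | ~(Xv | Ph);
            Mv = Ph & Xv;
            out[j + 1] = score;
        }
    } else {
        std::vector<int> prev(m + 1), cur(m + 1);
        for (size_t i = 0; i <= m; ++i) prev[i] = (int) i;
        for (size_t j = 1; j <= n; ++j) {
            cur[0] = 0; // free start anywhere in text
            const char tj = text[j - 1];
            for (size_t i = 1; i <= m; ++i) {
                int best = prev[i - 1] + (pat[i - 1] != tj);
                if (prev[i] + 1 < best) best = prev[i] + 1;
                if (cur[i - 1] + 1 < best) best = cur[i - 1] + 1;
                cur[i] = best;
            }
            out[j] = cur[m];
            std::swap(prev, cur);
        }
    }
}

// Recover the start of a hit that ends at 0-based position `end` (exclusive)
// with known distance: align reversed pattern against reversed suffix and
// take the prefix length achieving the minimum.
static int match_start(const std::string& pat, const std::string& text,
                       int end, int dist) {
    const int m = (int) pat.size();
    const int lo = std::max(0, end - m - dist - 1);
    std::string tr(text.begin() + lo, text.begin() + end);
    std::reverse(tr.begin(), tr.end());
    std::string pr(pat.rbegin(), pat.rend());
    const int L = (int) tr.size();
    std::vector<int> prev(L + 1), cur(L + 1);
    for (int j = 0; j <= L; ++j) prev[j] = j; // row 0: deleting text prefix... (global in text)
    // We need lev(pr, tr[0..l)) for every l: standard DP rows over pr.
    for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        const char pi = pr[i - 1];
        for (int j = 1; j <= L; ++j) {
            int best = prev[j - 1] + (pi != tr[j - 1]);
            if (prev[j] + 1 < best) best = prev[j] + 1;
            if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    int bestL = 0, bestD = prev[0];
    for (int j = 1; j <= L; ++j)
        if (prev[j] < bestD) { bestD = prev[j]; bestL = j; }
    return end - bestL; // 0-based start
}

struct Hit { int start, end, dist; };

static std::vector<Hit> locate_hits(const std::string& pattern,
                                    const std::string& text, int max_dist) {
    std::vector<Hit> accepted;
    const int n = (int) text.size();
    if ((int) pattern.size() == 0 || n == 0) return accepted;
    std::vector<int> d;
    infix_end_dists(pattern, text, d);
    // one candidate per contiguous run of end positions within max_dist:
    // the best end of each basin (distinct occurrences are separated by
    // positions above the threshold)
    std::vector<std::pair<int, int> > cand; // (dist, end)
    int runBestD = INT_MAX, runBestJ = -1;
    for (int j = 1; j <= n + 1; ++j) {
        if (j <= n && d[j] <= max_dist) {
            if (d[j] < runBestD) { runBestD = d[j]; runBestJ = j; }
        } else if (runBestJ >= 0) {
            cand.push_back(std::make_pair(runBestD, runBestJ));
            runBestD = INT_MAX;
            runBestJ = -1;
        }
    }
    std::sort(cand.begin(), cand.end());
    for (size_t c = 0; c < cand.size(); ++c) {
        const int end = cand[c].second, dist = cand[c].first;
        const int start = match_start(pattern, text, end, dist);
        bool clash = false;
        for (size_t a = 0; a < accepted.size(); ++a) {
            if (start < accepted[a].end && end > accepted[a].start) {
                clash = true;
                break;
            }
        }
        if (!clash) accepted.push_back(Hit{start, end, dist});
    }
    std::sort(accepted.begin(), accepted.end(),
              [](const Hit& x, const Hit& y) { return x.start < y.start; });
    return accepted;
}

//' @noRd
// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) { return lev(a, b); }

// All non-overlapping approximate occurrences of `pattern` in `text` with
// edit distance <= max_dist. Returns 1-based closed intervals.
// [[Rcpp::export]]
DataFrame cpp_locate(std::string pattern, std::string text, int max_dist) {
    std::vector<Hit> hits = locate_hits(pattern, text, max_dist);
    const int k = (int) hits.size();
    IntegerVector start(k), end(k), dist(k);
    for (int i = 0; i < k; ++i) {
        start[i] = hits[i].start + 1;
        end[i] = hits[i].end;
        dist[i] = hits[i].dist;
    }
    return DataFrame::create(_["start"] = start, _["end"] = end,
                             _["dist"] = dist);
}

// Locate several patterns in one text; `max_dists` is parallel to `patterns`.
// [[Rcpp::export]]
DataFrame cpp_locate_multi(CharacterVector patterns, std::string text,
                           IntegerVector max_dists) {
    std::vector<int> pidx, start, end, dist;
    for (int p = 0; p < patterns.size(); ++p) {
        const std::string pat = as<std::string>(patterns[p]);
        std::vector<Hit> hits = locate_hits(pat, text, max_dists[p]);
        for (size_t i = 0; i < hits.size(); ++i) {
            pidx.push_back(p + 1);
            start.push_back(hits[i].start + 1);
            end.push_back(hits[i].end);
            dist.push_back(hits[i].dist);
        }
    }
    return DataFrame::create(_["pattern"] = wrap(pidx),
                             _["start"] = wrap(start), _["end"] = wrap(end),
                             _["dist"] = wrap(dist));
}

// Best semi-global match of each candidate in `window`; returns the index of
// the unique best candidate (0 on tie / none passing max_dist).
// [[Rcpp::export]]
List cpp_best_candidate(CharacterVector candidates, std::string window,
                        int max_dist) {
    int bestIdx = 0, bestD = INT_MAX, secondD = INT_MAX;
    std::vector<int> d;
    for (int c = 0; c < candidates.size(); ++c) {
        const std::string pat = as<std::string>(candidates[c]);
        infix_end_dists(pat, window, d);
        int dd = INT_MAX;
        for (size_t j = 1; j < d.size(); ++j) dd = std::min(dd, d[j]);
        if (d.size() <= 1) dd = (int) pat.size();
        if (dd < bestD) {
            secondD = bestD;
            bestD = dd;
            bestIdx = c + 1;
        } else if (dd < secondD) {
            secondD = dd;
        }
    }
    const bool tie = (secondD == bestD);
    const bool pass = (bestD <= max_dist) && !tie;
    return List::create(_["index"] = pass ? bestIdx : 0,
                        _["dist"] = (bestD == INT_MAX) ? NA_INTEGER : bestD,
                        _["second"] = (secondD == INT_MAX) ? NA_INTEGER : secondD,
                        _["tie"] = tie);
}

// Minimum semi-global distance of pattern anywhere in text (no location).
// [[Rcpp::export]]
int cpp_min_infix_dist(std::string pattern, std::string text) {
    std::vector<int> d;
    infix_end_dists(pattern, text, d);
    int dd = (int) pattern.size();
    for (size_t j = 1; j < d.size(); ++j) dd = std::min(dd, d[j]);
    return dd;
}

// Reverse complement (ACGTN, case-preserving not needed: inputs upper-case).
// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t k = 0; k < seqs.size(); ++k) {
        std::string s = as<std::string>(seqs[k]);
        std::string r(s.rbegin(), s.rend());
        for (size_t i = 0; i < r.size(); ++i) {
            switch (r[i]) {
            case 'A': r[i] = 'T'; break;
            case 'C': r[i] = 'G'; break;
            case 'G': r[i] = 'C'; break;
            case 'T': r[i] = 'A'; break;
            default: break;
            }
        }
        out[k] = r;
    }
    return out;
}
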