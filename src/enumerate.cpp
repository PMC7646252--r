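#include <Rcpp.h>
#include <string>
#include <vector>
#include <deque>
#include <unordered_set>

using namespace Rcpp;

// Cassette states are encoded as compact strings with loxP sites at even
// offsets ('+'/'-') and spacer segments at odd offsets: segment id k forward
// is 'A'+k-1, inverted is 'a'+k-1. The alternating site/segment structure is
// preserved by both event types, so offsets stay valid throughout.

static inline char flip_tok(char c) {
    if (c == '+') return '-';
    if (c == '-') return '+';
    if (c >= 'A' && c <= 'Z') return (char) (c - 'A' + 'a');
    return (char) (c - 'a' + 'A');
}

static inline std::string seg_signature(const std::string& s) {
    std::string r;
    for (size_t i = 1; i < s.size(); i += 2) r += s[i];
    return r;
}

static std::string render_code(const std::string& sig) {
    if (sig.empty()) return "EX";
    std::string out;
    for (size_t i = 0; i < sig.size(); ++i) {
        if (i) out += '-';
        const char c = sig[i];
        if (c >= 'A' && c <= 'Z') {
            out += std::to_string(c - 'A' + 1);
        } else {
            out += std::to_string(c - 'a' + 1);
            out += 'R';
        }
    }
    return out;
}

// Breadth-first closure of the recombination system: every state reachable
// from the intact cassette by legal excisions (same-orientation site pairs)
// and inversions (opposite-orientation pairs). Returns the distinct
// oriented-segment barcodes, canonically rendered ("1-4R-9", "EX").
// [[Rcpp::export]]
CharacterVector cpp_enumerate(CharacterVector siteOrient) {
    const int ns = siteOrient.size(); // n + 1 sites
    const int n = ns - 1;
    std::string intact;
    for (int i = 0; i < ns; ++i) {
        intact += as<std::string>(siteOrient[i])[0];
        if (i < n) intact += (char) ('A' + i);
    }
    std::unordered_set<std::string> seen, codes;
    std::deque<std::string> q;
    seen.insert(intact);
    codes.insert(seg_signature(intact));
    q.push_back(intact);
    long long processed = 0;
    while (!q.empty()) {
        const std::string s = q.front();
        q.pop_front();
        if ((++processed & 0x3FFFLL) == 0) Rcpp::checkUserInterrupt();
        const int len = (int) s.size();
        const int k = (len + 1) / 2; // number of sites
        for (int a = 0; a < k; ++a) {
            for (int b = a + 1; b < k; ++b) {
                const int pa = 2 * a, pb = 2 * b;
                std::string t;
                if (s[pa] != s[pb]) {
                    // inversion: reverse + flip tokens strictly between
                    t = s;
                    int l = pa + 1, r = pb - 1;
                    while (l < r) {
                        const char cl = flip_tok(s[l]);
                        const char cr = flip_tok(s[r]);
                        t[l] = cr;
                        t[r] = cl;
                        ++l;
                        --r;
                    }
                    if (l == r) t[l] = flip_tok(s[l]);
                } else {
                    // excision: drop interval plus one boundary site
                    t = s.substr(0, pa + 1) + s.substr(pb + 1);
                }
                if (seen.insert(t).second) {
                    codes.insert(seg_signature(t));
                    q.push_back(t);
                }
            }
        }
    }
    CharacterVector out(codes.size());
    R_xlen_t i = 0;
    for (std::unordered_set<std::string>::const_iterator it = codes.begin();
         it != codes.end(); ++it) {
        out[i++] = render_code(*it);
    }
    return out;
}
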