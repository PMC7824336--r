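#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Instrumented classical exact string matchers.
//
// All seven algorithms follow their published handbook formulations.
// The instrumentation counts the CC metric: every equality test between a
// pattern character and a text character executed during the scan phase.
// Pattern-vs-pattern work in preprocessing (failure functions, shift
// tables) is never counted. A successful and a failed equality test each
// count as 1; no sentinel/guard tricks that would elide explicit tests are
// used, so the counts reflect the textbook algorithms.
//
// Offsets are 0-based. Characters are compared bytewise.

namespace {

struct Outcome {
    std::vector<int> occ;
    double comp = 0.0;
};

const int ASIZE = 256;

inline unsigned char uc(char c) { return static_cast<unsigned char>(c); }

// ---- preprocessing (uncounted: pattern-vs-pattern comparisons) ----------

// Morris-Pratt failure table, size m + 1
void pre_mp(const std::string &x, std::vector<int> &mpNext) {
    int m = static_cast<int>(x.size());
    mpNext.assign(m + 1, 0);
    int i = 0, j = -1;
    mpNext[0] = -1;
    while (i < m) {
        while (j > -1 && x[i] != x[j]) j = mpNext[j];
        mpNext[++i] = ++j;
    }
}

// Knuth-Morris-Pratt optimised failure table, size m + 1
void pre_kmp(const std::string &x, std::vector<int> &kmpNext) {
    int m = static_cast<int>(x.size());
    kmpNext.assign(m + 1, 0);
    int i = 0, j = -1;
    kmpNext[0] = -1;
    while (i < m) {
        while (j > -1 && x[i] != x[j]) j = kmpNext[j];
        i++; j++;
        if (i < m && x[i] == x[j]) kmpNext[i] = kmpNext[j];
        else kmpNext[i] = j;
    }
}

// bad-character table shared by BM and HOR
void pre_bad_char(const std::string &x, std::vector<int> &bc) {
    int m = static_cast<int>(x.size());
    bc.assign(ASIZE, m);
    for (int i = 0; i < m - 1; ++i) bc[uc(x[i])] = m - 1 - i;
}

void suffixes(const std::string &x, std::vector<int> &suff) {
    int m = static_cast<int>(x.size());
    suff.assign(m, 0);
    suff[m - 1] = m;
    int f = 0, g = m - 1;
    for (int i = m - 2; i >= 0; --i) {
        if (i > g && suff[i + m - 1 - f] < i - g) {
            suff[i] = suff[i + m - 1 - f];
        } else {
            if (i < g) g = i;
            f = i;
            while (g >= 0 && x[g] == x[g + m - 1 - f]) --g;
            suff[i] = f - g;
        }
    }
}

// Boyer-Moore good-suffix table
void pre_good_suffix(const std::string &x, std::vector<int> &bmGs) {
    int m = static_cast<int>(x.size());
    std::vector<int> suff;
    suffixes(x, suff);
    bmGs.assign(m, m);
    int j = 0;
    for (int i = m - 1; i >= 0; --i) {
        if (suff[i] == i + 1) {
            for (; j < m - 1 - i; ++j) {
                if (bmGs[j] == m) bmGs[j] = m - 1 - i;
            }
        }
    }
    for (int i = 0; i <= m - 2; ++i) bmGs[m - 1 - suff[i]] = m - 1 - i;
}

// Quick-Search bad-character table (character just right of the window)
void pre_qs_bad_char(const std::string &x, std::vector<int> &qbc) {
    int m = static_cast<int>(x.size());
    qbc.assign(ASIZE, m + 1);
    for (int i = 0; i < m; ++i) qbc[uc(x[i])] = m - i;
}

// ---- scan phases (counted) ----------------------------------------------

Outcome bf_search(const std::string &y, const std::string &x) {
    Outcome out;
    int n = static_cast<int>(y.size()), m = static_cast<int>(x.size());
    for (int j = 0; j <= n - m; ++j) {
        int i = 0;
        while (i < m) {
            out.comp += 1;
            if (x[i] != y[j + i]) break;
            ++i;
        }
        if (i == m) out.occ.push_back(j);
    }
    return out;
}

// shared scan for MP and KMP: only the failure table differs
Outcome mp_family_search(const std::string &y, const std::string &x,
                         const std::vector<int> &next) {
    Outcome out;
    int n = static_cast<int>(y.size()), m = static_cast<int>(x.size());
    int i = 0;
    for (int j = 0; j < n; ++j) {
        while (i > -1) {
            out.comp += 1;
            if (x[i] == y[j]) break;
            i = next[i];
        }
        ++i;
        if (i >= m) {
            out.occ.push_back(j + 1 - i);
            i = next[i];
        }
    }
    return out;
}

Outcome bm_search(const std::string &y, const std::string &x) {
    Outcome out;
    int n = static_cast<int>(y.size()), m = static_cast<int>(x.size());
    std::vector<int> bc, gs;
    pre_bad_char(x, bc);
    pre_good_suffix(x, gs);
    int j = 0;
    while (j <= n - m) {
        int i = m - 1;
        while (i >= 0) {
            out.comp += 1;
            if (x[i] != y[i + j]) break;
            --i;
        }
        if (i < 0) {
            out.occ.push_back(j);
            j += gs[0];
        } else {
            j += std::max(gs[i], bc[uc(y[i + j])] - m + 1 + i);
        }
    }
    return out;
}

Outcome hor_search(const std::string &y, const std::string &x) {
    Outcome out;
    int n = static_cast<int>(y.size()), m = static_cast<int>(x.size());
    std::vector<int> bc;
    pre_bad_char(x, bc);
    int j = 0;
    while (j <= n - m) {
        unsigned char c = uc(y[j + m - 1]);
        int i = m - 1;
        while (i >= 0) {
            out.comp += 1;
            if (x[i] != y[j + i]) break;
            --i;
        }
        if (i < 0) out.occ.push_back(j);
        j += bc[c];
    }
    return out;
}

Outcome qs_search(const std::string &y, const std::string &x) {
    Outcome out;
    int n = static_cast<int>(y.size()), m = static_cast<int>(x.size());
    std::vector<int> qbc;
    pre_qs_bad_char(x, qbc);
    int j = 0;
    while (j <= n - m) {
        int i = 0;
        while (i < m) {
            out.comp += 1;
            if (x[i] != y[j + i]) break;
            ++i;
        }
        if (i == m) out.occ.push_back(j);
        if (j + m >= n) break;  // shift character would fall past the text
        j += qbc[uc(y[j + m])];
    }
    return out;
}

Outcome ac_search(const std::string &y, const std::string &x) {
    Outcome out;
    int n = static_cast<int>(y.size()), m = static_cast<int>(x.size());
    std::vector<int> kmpNext;
    pre_kmp(x, kmpNext);
    int ell = 1;
    while (ell < m && x[ell - 1] == x[ell]) ++ell;
    if (ell == m) ell = 0;

    int i = ell, j = 0, k = 0;
    while (j <= n - m) {
        while (i < m) {
            out.comp += 1;
            if (x[i] != y[i + j]) break;
            ++i;
        }
        if (i >= m) {
            while (k < ell) {
                out.comp += 1;
                if (x[k] != y[j + k]) break;
                ++k;
            }
            if (k >= ell) out.occ.push_back(j);
        }
        j += (i - kmpNext[i]);
        if (i == ell) {
            k = std::max(0, k - 1);
        } else if (kmpNext[i] <= ell) {
            k = std::max(0, kmpNext[i]);
            i = ell;
        } else {
            k = ell;
            i = kmpNext[i];
        }
    }
    return out;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cc_match")]]
List cc_match(const std::string &algorithm, const std::string &text,
              const std::string &pattern) {
    int n = static_cast<int>(text.size());
    int m = static_cast<int>(pattern.size());
    if (m < 1) stop("pattern must have length >= 1");

    Outcome out;
    if (m <= n) {
        if (algorithm == "BF")       out = bf_search(text, pattern);
        else if (algorithm == "MP") {
            std::vector<int> next;
            pre_mp(pattern, next);
            out = mp_family_search(text, pattern, next);
        } else if (algorithm == "KMP") {
            std::vector<int> next;
            pre_kmp(pattern, next);
            out = mp_family_search(text, pattern, next);
        } else if (algorithm == "AC")  out = ac_search(text, pattern);
        else if (algorithm == "QS")    out = qs_search(text, pattern);
        else if (algorithm == "BM")    out = bm_search(text, pattern);
        else if (algorithm == "HOR")   out = hor_search(text, pattern);
        else stop("unknown algorithm id: " + algorithm);
    } else {
        // window longer than text: no scan performed at all
        if (algorithm != "BF" && algorithm != "MP" && algorithm != "KMP" &&
            algorithm != "AC" && algorithm != "QS" && algorithm != "BM" &&
            algorithm != "HOR")
            stop("unknown algorithm id: " + algorithm);
    }
    return List::create(_["occurrences"] = wrap(out.occ),
                        _["comparisons"] = out.comp);
}
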