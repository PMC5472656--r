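#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Ends-free ("overlap") global alignment with unit costs:
// match +1, mismatch -1, gap -1; leading and trailing gaps free.
// Returns matches and alignment length (columns from the first to the last
// aligned pair, internal gaps included, free end gaps excluded).
static void nw_overlap(const std::string &a, const std::string &b,
                       int &matches, int &aln_len) {
    const int n = a.size(), m = b.size();
    // S: (n+1) x (m+1); traceback: 0 diag, 1 up (gap in b), 2 left (gap in a)
    std::vector<int> S((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tb((n + 1) * (m + 1), 0);
    auto idx = [m](int i, int j) { return i * (m + 1) + j; };
    for (int i = 0; i <= n; ++i) { S[idx(i, 0)] = 0; tb[idx(i, 0)] = 1; }
    for (int j = 0; j <= m; ++j) { S[idx(0, j)] = 0; tb[idx(0, j)] = 2; }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int diag = S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1);
            int up   = S[idx(i - 1, j)] - 1;
            int left = S[idx(i, j - 1)] - 1;
            int best = diag; unsigned char t = 0;
            if (up > best)   { best = up;   t = 1; }
            if (left > best) { best = left; t = 2; }
            S[idx(i, j)] = best; tb[idx(i, j)] = t;
        }
    }
    // best cell on last row / last column (free trailing gaps)
    int bi = n, bj = m, bscore = S[idx(n, m)];
    for (int j = 0; j <= m; ++j)
        if (S[idx(n, j)] > bscore) { bscore = S[idx(n, j)]; bi = n; bj = j; }
    for (int i = 0; i <= n; ++i)
        if (S[idx(i, m)] > bscore) { bscore = S[idx(i, m)]; bi = i; bj = m; }
    matches = 0; aln_len = 0;
    int i = bi, j = bj;
    while (i > 0 && j > 0) {
        unsigned char t = tb[idx(i, j)];
        if (t == 0) {
            if (a[i - 1] == b[j - 1]) ++matches;
            --i; --j;
        } else if (t == 1) {
            --i;
        } else {
            --j;
        }
        ++aln_len;
    }
}

// [[Rcpp::export]]
List cpp_nw_identity(std::string a, std::string b) {
    int matches = 0, aln_len = 0;
    nw_overlap(a, b, matches, aln_len);
    return List::create(_["matches"] = matches, _["aln_length"] = aln_len);
}

// Best ends-free hit of one query against many references.
// [[Rcpp::export]]
DataFrame cpp_nw_identity_many(std::string query, CharacterVector refs) {
    int n = refs.size();
    IntegerVector matches(n), aln_len(n);
    for (int k = 0; k < n; ++k) {
        std::string r = as<std::string>(refs[k]);
        int mm = 0, al = 0;
        nw_overlap(query, r, mm, al);
        matches[k] = mm; aln_len[k] = al;
    }
    return DataFrame::create(_["matches"] = matches, _["aln_length"] = aln_len);
}

// Ungapped merge of mate1 with the reverse-complemented mate2.
// a/qa: mate1 sequence and Phred+33 qualities; b/qb: revcomp(mate2) and its
// (reversed) qualities. Considers every ungapped relative placement with
// overlap >= min_overlap; admissible iff matches/overlap >= min_match.
// Best by identity, ties by longer overlap, then smaller |shift|, then
// smaller shift. Consensus takes the higher-quality base at mismatches
// (tie -> mate1). Returns R_NilValue when no admissible overlap exists.
// [[Rcpp::export]]
SEXP cpp_merge_pair(std::string a, std::string qa,
                    std::string b, std::string qb,
                    int min_overlap, double min_match) {
    const int n = a.size(), m = b.size();
    if (n == 0 || m == 0) return R_NilValue;
    int best_shift = 0, best_ov = -1, best_mm = 0;
    double best_id = -1.0;
    bool found = false;
    // shift s: offset of b's start relative to a's start (0-based), may be <0
    for (int s = -(m - 1); s <= n - 1; ++s) {
        int lo = std::max(0, s);            // overlap start in a coords
        int hi = std::min(n, s + m);        // overlap end (excl) in a coords
        int ov = hi - lo;
        if (ov < min_overlap) continue;
        int mism = 0;
        for (int i = lo; i < hi; ++i)
            if (a[i] != b[i - s]) ++mism;
        double id = (double)(ov - mism) / ov;
        if (id + 1e-12 < min_match) continue;
        bool better = false;
        if (!found) better = true;
        else if (id > best_id + 1e-12) better = true;
        else if (std::abs(id - best_id) <= 1e-12) {
            if (ov > best_ov) better = true;
            else if (ov == best_ov) {
                if (std::abs(s) < std::abs(best_shift)) better = true;
                else if (std::abs(s) == std::abs(best_shift) && s < best_shift)
                    better = true;
            }
        }
        if (better) {
            found = true; best_shift = s; best_ov = ov; best_mm = mism;
            best_id = id;
        }
    }
    if (!found) return R_NilValue;
    const int s = best_shift;
    const int lo = std::max(0, s), hi = std::min(n, s + m);
    const int total = n + m - best_ov;
    std::string merged(total, 'N');
    int p = 0;
    if (s > 0) for (int i = 0; i < s; ++i) merged[p++] = a[i];
    else       for (int j = 0; j < -s; ++j) merged[p++] = b[j];
    for (int i = lo; i < hi; ++i) {
        char ca = a[i], cb = b[i - s];
        if (ca == cb) merged[p++] = ca;
        else merged[p++] = (qa[i] >= qb[i - s]) ? ca : cb;
    }
    if (s + m > n) for (int j = n - s; j < m; ++j) merged[p++] = b[j];
    else           for (int i = s + m; i < n; ++i) merged[p++] = a[i];
    return List::create(_["sequence"] = merged,
                        _["overlap_len"] = best_ov,
                        _["mismatches_in_overlap"] = best_mm,
                        _["shift"] = s);
}

// Vectorised merge over read pairs; returns a list with one element per
// pair (NULL where unjoined).
// [[Rcpp::export]]
List cpp_merge_many(CharacterVector a, CharacterVector qa,
                    CharacterVector b, CharacterVector qb,
                    int min_overlap, double min_match) {
    int n = a.size();
    List out(n);
    for (int k = 0; k < n; ++k) {
        out[k] = cpp_merge_pair(as<std::string>(a[k]), as<std::string>(qa[k]),
                                as<std::string>(b[k]), as<std::string>(qb[k]),
                                min_overlap, min_match);
    }
    return out;
}
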