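#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Only unambiguous bases participate in exact matches; N (or any other
// letter) breaks a match even against another N.
static inline bool base_ok(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// All maximal exact matches of length >= min_len between two sequence sets,
// plus strand only (the caller handles reverse complements). Seeds are
// rolling-hash k-mers with k = min_len; a seed is expanded only when the
// match cannot be extended one base to the left, so every maximal match is
// reported from its unique leftmost seed and duplicates cannot arise.
// Coordinates returned are 1-based starts.
// [[Rcpp::export]]
DataFrame mem_scan_cpp(CharacterVector queries, CharacterVector subjects,
                       int min_len) {
    if (min_len < 1) stop("min_len must be >= 1");
    const uint64_t B = 1315423911ULL;
    const int k = min_len;
    uint64_t Bk1 = 1;
    for (int i = 0; i < k - 1; ++i) Bk1 *= B;

    std::vector<std::string> subj(subjects.size());
    for (int j = 0; j < subjects.size(); ++j)
        subj[j] = as<std::string>(subjects[j]);

    // k-mer index over the subject set: hash -> (subject idx, 0-based pos)
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
    for (int j = 0; j < (int)subj.size(); ++j) {
        const std::string& s = subj[j];
        const int n = (int)s.size();
        if (n < k) continue;
        uint64_t h = 0;
        int valid = 0;
        for (int i = 0; i < n; ++i) {
            const char c = s[i];
            if (!base_ok(c)) { valid = 0; h = 0; continue; }
            if (valid < k) {
                h = h * B + (uint64_t)c;
                ++valid;
            } else {
                h = (h - (uint64_t)s[i - k] * Bk1) * B + (uint64_t)c;
            }
            if (valid >= k)
                index[h].push_back(std::make_pair(j, i - k + 1));
        }
    }

    std::vector<int> out_q, out_s, out_qstart, out_sstart, out_len;
    for (int qi = 0; qi < queries.size(); ++qi) {
        const std::string q = as<std::string>(queries[qi]);
        const int m = (int)q.size();
        if (m < k) continue;
        uint64_t h = 0;
        int valid = 0;
        for (int i = 0; i < m; ++i) {
            const char c = q[i];
            if (!base_ok(c)) { valid = 0; h = 0; continue; }
            if (valid < k) {
                h = h * B + (uint64_t)c;
                ++valid;
            } else {
                h = (h - (uint64_t)q[i - k] * Bk1) * B + (uint64_t)c;
            }
            if (valid < k) continue;
            const int qpos = i - k + 1;
            std::unordered_map<uint64_t,
                std::vector<std::pair<int, int> > >::const_iterator it =
                index.find(h);
            if (it == index.end()) continue;
            const std::vector<std::pair<int, int> >& cand = it->second;
            for (size_t ci = 0; ci < cand.size(); ++ci) {
                const int sj = cand[ci].first;
                const int spos = cand[ci].second;
                const std::string& s = subj[sj];
                // guard against hash collisions
                if (q.compare(qpos, k, s, spos, k) != 0) continue;
                // left-maximality: only expand from the leftmost seed
                if (qpos > 0 && spos > 0) {
                    const char ql = q[qpos - 1];
                    if (base_ok(ql) && ql == s[spos - 1]) continue;
                }
                // extend right maximally
                int e = k;
                const int smax = (int)s.size();
                while (qpos + e < m && spos + e < smax) {
                    const char a = q[qpos + e];
                    if (!base_ok(a) || a != s[spos + e]) break;
                    ++e;
                }
                out_q.push_back(qi + 1);
                out_s.push_back(sj + 1);
                out_qstart.push_back(qpos + 1);
                out_sstart.push_back(spos + 1);
                out_len.push_back(e);
            }
        }
    }

    return DataFrame::create(
        Named("qidx") = out_q,
        Named("sidx") = out_s,
        Named("qstart") = out_qstart,
        Named("sstart") = out_sstart,
        Named("length") = out_len);
}
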