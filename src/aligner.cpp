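// k-mer anchor alignment kernel.
//
// Exact k-mer anchors between a query contig and a set of target sequences
// are grouped per (target, strand, diagonal), chained along each diagonal,
// extended with an x-drop rule, and reported as gap-free segments with an
// identity computed by direct base comparison along the diagonal.  N bases
// never count as matches.  Coordinates are 0-based half-open throughout.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <unordered_map>
#include <map>

using namespace Rcpp;

static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;   // N and anything else: never a match
    }
}

static std::string revComp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default:  c = 'N'; break;
        }
    }
    return r;
}

struct KEntry {
    uint64_t kmer;
    int32_t  seq;
    int32_t  pos;
};

struct Hit {
    int32_t t;
    int32_t diag;   // tpos - qpos
    int32_t qpos;
};

// Emit all valid k-mers of s (no N inside) as (kmer, pos) via callback.
template <typename F>
static void eachKmer(const std::string &s, int k, F f) {
    const int n = (int) s.size();
    if (n < k) return;
    uint64_t kmer = 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int run = 0;                       // length of current valid-base run
    for (int i = 0; i < n; ++i) {
        int c = baseCode(s[i]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t) c) & mask;
        if (++run >= k) f(kmer, i - k + 1);
    }
}

struct Segment {
    int32_t t, diag, qs, qe;
    int32_t matches;
    char strand;
};

// Count exact matches of query[qs,qe) against target along diagonal.
static int countMatches(const std::string &q, const std::string &t,
                        int diag, int qs, int qe) {
    int m = 0;
    for (int i = qs; i < qe; ++i) {
        int a = baseCode(q[i]);
        int b = baseCode(t[i + diag]);
        if (a >= 0 && a == b) ++m;
    }
    return m;
}

// X-drop extension of [qs,qe) along a fixed diagonal; match +1, mismatch -2.
static void xdropExtend(const std::string &q, const std::string &t,
                        int diag, int &qs, int &qe, int xdrop) {
    const int qlen = (int) q.size(), tlen = (int) t.size();
    // right
    {
        int sc = 0, best = 0, bestPos = qe;
        for (int i = qe; i < qlen && i + diag < tlen; ++i) {
            int a = baseCode(q[i]), b = baseCode(t[i + diag]);
            sc += (a >= 0 && a == b) ? 1 : -2;
            if (sc > best) { best = sc; bestPos = i + 1; }
            if (sc < best - xdrop) break;
        }
        qe = bestPos;
    }
    // left
    {
        int sc = 0, best = 0, bestPos = qs;
        for (int i = qs - 1; i >= 0 && i + diag >= 0; --i) {
            int a = baseCode(q[i]), b = baseCode(t[i + diag]);
            sc += (a >= 0 && a == b) ? 1 : -2;
            if (sc > best) { best = sc; bestPos = i; }
            if (sc < best - xdrop) break;
        }
        qs = bestPos;
    }
}

// Align one oriented query against indexed targets; returns raw segments in
// the oriented query's coordinates.
static void alignOriented(const std::string &q,
                          const std::vector<std::string> &targets,
                          const std::vector<KEntry> &index,
                          int k, int maxGap, int maxOcc, int xdrop,
                          char strand, std::vector<Segment> &out) {
    std::vector<Hit> hits;
    eachKmer(q, k, [&](uint64_t kmer, int pos) {
        KEntry key; key.kmer = kmer; key.seq = 0; key.pos = 0;
        auto rng = std::equal_range(
            index.begin(), index.end(), key,
            [](const KEntry &a, const KEntry &b) { return a.kmer < b.kmer; });
        std::ptrdiff_t cnt = rng.second - rng.first;
        if (cnt == 0 || cnt > maxOcc) return;
        for (auto it = rng.first; it != rng.second; ++it)
            hits.push_back(Hit{it->seq, it->pos - pos, pos});
    });
    if (hits.empty()) return;
    std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
        if (a.t != b.t) return a.t < b.t;
        if (a.diag != b.diag) return a.diag < b.diag;
        return a.qpos < b.qpos;
    });

    std::vector<Segment> segs;
    size_t i = 0;
    while (i < hits.size()) {
        size_t j = i + 1;
        int qs = hits[i].qpos, qe = hits[i].qpos + k;
        while (j < hits.size() && hits[j].t == hits[i].t &&
               hits[j].diag == hits[i].diag &&
               hits[j].qpos - (qe - k) <= maxGap) {
            qe = std::max(qe, hits[j].qpos + k);
            ++j;
        }
        segs.push_back(Segment{hits[i].t, hits[i].diag, qs, qe, 0, strand});
        i = j;
    }

    // extend, then merge same-diagonal segments that touch after extension
    for (auto &s : segs)
        xdropExtend(q, targets[s.t], s.diag, s.qs, s.qe, xdrop);
    std::sort(segs.begin(), segs.end(), [](const Segment &a, const Segment &b) {
        if (a.t != b.t) return a.t < b.t;
        if (a.diag != b.diag) return a.diag < b.diag;
        return a.qs < b.qs;
    });
    std::vector<Segment> merged;
    for (auto &s : segs) {
        if (!merged.empty() && merged.back().t == s.t &&
            merged.back().diag == s.diag && s.qs <= merged.back().qe) {
            merged.back().qe = std::max(merged.back().qe, s.qe);
        } else {
            merged.push_back(s);
        }
    }
    for (auto &s : merged) {
        s.matches = countMatches(q, targets[s.t], s.diag, s.qs, s.qe);
        out.push_back(s);
    }
}

static std::vector<KEntry> buildIndex(const std::vector<std::string> &targets,
                                      int k) {
    std::vector<KEntry> index;
    size_t total = 0;
    for (auto &t : targets) total += t.size();
    index.reserve(total);
    for (size_t s = 0; s < targets.size(); ++s)
        eachKmer(targets[s], k, [&](uint64_t kmer, int pos) {
            index.push_back(KEntry{kmer, (int32_t) s, (int32_t) pos});
        });
    std::sort(index.begin(), index.end(),
              [](const KEntry &a, const KEntry &b) { return a.kmer < b.kmer; });
    return index;
}

// [[Rcpp::export(name = ".cppAlignContigs")]]
List cppAlignContigs(CharacterVector contigs, CharacterVector targets,
                     int k = 21, int maxGap = 500, int maxOcc = 50,
                     int xdrop = 20) {
    std::vector<std::string> tg(targets.size());
    for (int i = 0; i < targets.size(); ++i) tg[i] = as<std::string>(targets[i]);
    std::vector<KEntry> index = buildIndex(tg, k);

    List res(contigs.size());
    for (int ci = 0; ci < contigs.size(); ++ci) {
        std::string q = as<std::string>(contigs[ci]);
        std::vector<Segment> fw, rv;
        alignOriented(q, tg, index, k, maxGap, maxOcc, xdrop, '+', fw);
        std::string qr = revComp(q);
        alignOriented(qr, tg, index, k, maxGap, maxOcc, xdrop, '-', rv);

        const int L = (int) q.size();
        int n = (int) (fw.size() + rv.size());
        IntegerVector cs(n), ce(n), ti(n), ts(n), te(n), mt(n);
        CharacterVector st(n);
        int r = 0;
        for (auto &s : fw) {
            cs[r] = s.qs; ce[r] = s.qe; ti[r] = s.t + 1;
            ts[r] = s.qs + s.diag; te[r] = s.qe + s.diag;
            mt[r] = s.matches; st[r] = "+"; ++r;
        }
        for (auto &s : rv) {
            cs[r] = L - s.qe; ce[r] = L - s.qs; ti[r] = s.t + 1;
            ts[r] = s.qs + s.diag; te[r] = s.qe + s.diag;
            mt[r] = s.matches; st[r] = "-"; ++r;
        }
        res[ci] = DataFrame::create(
            _["contig_start"] = cs, _["contig_end"] = ce,
            _["target"] = ti, _["target_start"] = ts, _["target_end"] = te,
            _["matches"] = mt, _["strand"] = st);
    }
    return res;
}

// Best gap-free single-diagonal identity between two sequences, both strands.
// Identity denominator is the longer sequence, so equal-length substitution
// pairs give exactly the global (gap-free) identity.
// [[Rcpp::export(name = ".cppPairIdentity")]]
List cppPairIdentity(std::string a, std::string b, int k = 11,
                     int maxDiags = 25) {
    const int la = (int) a.size(), lb = (int) b.size();
    const int denom = std::max(la, lb);
    std::unordered_map<uint64_t, std::vector<int>> amap;
    eachKmer(a, k, [&](uint64_t kmer, int pos) { amap[kmer].push_back(pos); });

    double best = 0.0;
    std::string bestStrand = "+";
    for (int pass = 0; pass < 2; ++pass) {
        std::string q = (pass == 0) ? b : revComp(b);
        std::map<int, int> votes;  // diag (a_pos - q_pos) -> count
        eachKmer(q, k, [&](uint64_t kmer, int pos) {
            auto it = amap.find(kmer);
            if (it == amap.end() || (int) it->second.size() > 10) return;
            for (int ap : it->second) votes[ap - pos] += 1;
        });
        std::vector<std::pair<int, int>> diags(votes.begin(), votes.end());
        std::sort(diags.begin(), diags.end(),
                  [](const std::pair<int,int> &x, const std::pair<int,int> &y) {
                      return x.second > y.second;
                  });
        if ((int) diags.size() > maxDiags) diags.resize(maxDiags);
        for (auto &dv : diags) {
            int d = dv.first;  // a_pos = q_pos + d
            int qs = std::max(0, -d);
            int qe = std::min((int) q.size(), la - d);
            if (qe <= qs) continue;
            int m = 0;
            for (int i = qs; i < qe; ++i) {
                int x = baseCode(q[i]), y = baseCode(a[i + d]);
                if (x >= 0 && x == y) ++m;
            }
            double id = (double) m / denom;
            if (id > best) { best = id; bestStrand = (pass == 0) ? "+" : "-"; }
        }
    }
    return List::create(_["identity"] = best, _["strand"] = bestStrand);
}
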