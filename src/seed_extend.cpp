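// Seed-and-extend local similarity search over integer-encoded sequences.
// Exact k-mer seeds are looked up in a hash index of the targets, chained
// into clusters of near-collinear seeds, and each cluster is refined by a
// banded affine-gap Smith-Waterman restricted to its neighbourhood.
// Codes >= seed_alphabet (e.g. N) never seed and score via the matrix only.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

struct SeqIndex {
    int k;
    int seed_asz;
    std::vector<std::vector<int16_t>> seqs;
    std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> seeds;
};

static inline bool kmer_code(const std::vector<int16_t>& s, int pos, int k,
                             int asz, uint64_t& code) {
    code = 0;
    for (int i = 0; i < k; ++i) {
        int c = s[pos + i];
        if (c < 0 || c >= asz) return false;
        code = code * (uint64_t)asz + (uint64_t)c;
    }
    return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(List targets, int k, int seed_asz) {
    XPtr<SeqIndex> idx(new SeqIndex(), true);
    idx->k = k;
    idx->seed_asz = seed_asz;
    int nt = targets.size();
    idx->seqs.resize(nt);
    for (int t = 0; t < nt; ++t) {
        IntegerVector v = targets[t];
        std::vector<int16_t> s(v.size());
        for (R_xlen_t i = 0; i < v.size(); ++i) s[i] = (int16_t)v[i];
        idx->seqs[t] = std::move(s);
        int L = (int)idx->seqs[t].size();
        for (int p = 0; p + k <= L; ++p) {
            uint64_t code;
            if (kmer_code(idx->seqs[t], p, k, seed_asz, code))
                idx->seeds[code].push_back({(int32_t)t, (int32_t)p});
        }
    }
    return idx;
}

// [[Rcpp::export]]
int cpp_index_n_positions(SEXP idxp) {
    XPtr<SeqIndex> idx(idxp);
    size_t n = 0;
    for (auto& kv : idx->seeds) n += kv.second.size();
    return (int)n;
}

struct Hit {
    int tid, tstart, tend, qstart, qend, score, matches, alnlen;
};

// Banded local affine-gap DP over windows [q0,q1) x [t0,t1).
// Window-relative target slot j is constrained to |j - (i + dmid)| <= band.
static bool banded_sw(const std::vector<int16_t>& Q, const std::vector<int16_t>& T,
                      int q0, int q1, int t0, int t1, int dmid, int band,
                      const IntegerMatrix& smat, int gap_open, int gap_extend,
                      Hit& out) {
    const int NEG = -100000000;
    int qw = q1 - q0, tw = t1 - t0;
    int W = 2 * band + 1;
    if (qw <= 0 || tw <= 0) return false;
    std::vector<int> M((size_t)qw * W, NEG), X((size_t)qw * W, NEG),
        Y((size_t)qw * W, NEG);
    int best = 0, bi = -1, bj = -1;
    for (int i = 0; i < qw; ++i) {
        int centre = i + dmid;
        int jlo = std::max(0, centre - band), jhi = std::min(tw - 1, centre + band);
        for (int j = jlo; j <= jhi; ++j) {
            size_t at = (size_t)i * W + (j - centre + band);
            int sc = smat(Q[q0 + i], T[t0 + j]);
            int diag = sc; // fresh local start
            if (i > 0 && j > 0) {
                int pc = (i - 1) + dmid;
                if (j - 1 >= pc - band && j - 1 <= pc + band) {
                    size_t pd = (size_t)(i - 1) * W + ((j - 1) - pc + band);
                    int prev = std::max(M[pd], std::max(X[pd], Y[pd]));
                    if (prev > 0) diag = prev + sc;
                }
            }
            int xv = NEG; // gap in target (consumes query)
            if (i > 0) {
                int pc = (i - 1) + dmid;
                if (j >= pc - band && j <= pc + band) {
                    size_t pu = (size_t)(i - 1) * W + (j - pc + band);
                    xv = std::max(M[pu] - gap_open - gap_extend, X[pu] - gap_extend);
                }
            }
            int yv = NEG; // gap in query (consumes target)
            if (j > jlo) {
                size_t pl = at - 1;
                yv = std::max(M[pl] - gap_open - gap_extend, Y[pl] - gap_extend);
            }
            M[at] = diag;
            X[at] = xv;
            Y[at] = yv;
            int cell = std::max(diag, std::max(xv, yv));
            if (cell > best) { best = cell; bi = i; bj = j; }
        }
    }
    if (best <= 0) return false;
    // traceback for start coordinates, match count and alignment length
    int i = bi, j = bj, matches = 0, alnlen = 0;
    int endi = bi, endj = bj;
    size_t at = (size_t)i * W + (j - (i + dmid) + band);
    int state = (M[at] >= X[at] && M[at] >= Y[at]) ? 1 : (X[at] >= Y[at] ? 2 : 3);
    bool done = false;
    while (!done && i >= 0 && j >= 0) {
        int centre = i + dmid;
        if (j < centre - band || j > centre + band) break;
        at = (size_t)i * W + (j - centre + band);
        if (state == 1) {
            ++alnlen;
            if (Q[q0 + i] == T[t0 + j] && smat(Q[q0 + i], T[t0 + j]) > 0)
                ++matches;
            int sc = smat(Q[q0 + i], T[t0 + j]);
            bool fromPrev = false;
            int pstate = 1;
            if (i > 0 && j > 0) {
                int pc = (i - 1) + dmid;
                if (j - 1 >= pc - band && j - 1 <= pc + band) {
                    size_t pd = (size_t)(i - 1) * W + ((j - 1) - pc + band);
                    int prev = std::max(M[pd], std::max(X[pd], Y[pd]));
                    if (prev > 0 && M[at] == prev + sc) {
                        fromPrev = true;
                        pstate = (M[pd] >= X[pd] && M[pd] >= Y[pd]) ? 1
                                 : (X[pd] >= Y[pd] ? 2 : 3);
                    }
                }
            }
            --i; --j;
            if (!fromPrev) done = true; // local start reached
            else state = pstate;
        } else if (state == 2) { // gap in target, consumed query row
            ++alnlen;
            int pc = (i - 1) + dmid;
            size_t pu = (size_t)(i - 1) * W + (j - pc + band);
            state = (M[pu] - gap_open - gap_extend >= X[pu] - gap_extend) ? 1 : 2;
            --i;
        } else { // gap in query
            size_t pl = at - 1;
            ++alnlen;
            state = (M[pl] - gap_open - gap_extend >= Y[pl] - gap_extend) ? 1 : 3;
            --j;
        }
    }
    out.qstart = q0 + i + 1;
    out.qend = q0 + endi + 1; // half-open
    out.tstart = t0 + j + 1;
    out.tend = t0 + endj + 1;
    out.score = best;
    out.matches = matches;
    out.alnlen = alnlen;
    return true;
}

struct Chain {
    int qmin, qmax, tmin, tmax, dmin, dmax, dlast, n;
};

// [[Rcpp::export]]
DataFrame cpp_search(SEXP idxp, IntegerVector query, IntegerMatrix smat,
                     int gap_open, int gap_extend, int band, int margin,
                     int chain_gap, int min_score, int max_band) {
    XPtr<SeqIndex> idx(idxp);
    int k = idx->k, seed_asz = idx->seed_asz;
    int qlen = (int)query.size();
    std::vector<int16_t> Q(qlen);
    for (int i = 0; i < qlen; ++i) Q[i] = (int16_t)query[i];
    std::unordered_map<int, std::vector<std::pair<int, int>>> by_target;
    for (int p = 0; p + k <= qlen; ++p) {
        uint64_t code;
        if (!kmer_code(Q, p, k, seed_asz, code)) continue;
        auto it = idx->seeds.find(code);
        if (it == idx->seeds.end()) continue;
        for (auto& pr : it->second)
            by_target[pr.first].push_back({p, (int)pr.second});
    }
    std::vector<Hit> hits;
    for (auto& kv : by_target) {
        int tid = kv.first;
        const std::vector<int16_t>& T = idx->seqs[tid];
        auto& seeds = kv.second;
        // sort by target position so chains can be closed once the scan
        // has moved past them (keeps chaining near-linear)
        std::sort(seeds.begin(), seeds.end(),
                  [](const std::pair<int,int>& a, const std::pair<int,int>& b) {
                      if (a.second != b.second) return a.second < b.second;
                      return a.first < b.first;
                  });
        std::vector<Chain> chains;   // closed
        std::vector<Chain> open;
        for (auto& sd : seeds) {
            int qp = sd.first, tp = sd.second, d = tp - qp;
            // close chains the scan has passed
            size_t w = 0;
            for (size_t ci = 0; ci < open.size(); ++ci) {
                if (open[ci].tmax + k + chain_gap < tp) {
                    chains.push_back(open[ci]);
                } else {
                    open[w++] = open[ci];
                }
            }
            open.resize(w);
            bool joined = false;
            for (auto& c : open) {
                if (d >= c.dmin - band && d <= c.dmax + band &&
                    qp >= c.qmin - chain_gap && qp <= c.qmax + k + chain_gap) {
                    c.qmin = std::min(c.qmin, qp); c.qmax = std::max(c.qmax, qp);
                    c.tmin = std::min(c.tmin, tp); c.tmax = std::max(c.tmax, tp);
                    c.dmin = std::min(c.dmin, d); c.dmax = std::max(c.dmax, d);
                    c.n++;
                    joined = true;
                    break;
                }
            }
            if (!joined) open.push_back({qp, qp, tp, tp, d, d, d, 1});
        }
        for (auto& c : open) chains.push_back(c);
        std::vector<Hit> thits;
        for (auto& c : chains) {
            int wq0 = std::max(0, c.qmin - margin);
            int wq1 = std::min(qlen, c.qmax + k + margin);
            int wt0 = std::max(0, c.tmin - margin);
            int wt1 = std::min((int)T.size(), c.tmax + k + margin);
            // window-relative centre diagonal of the chain
            int dmid = (c.dmin + c.dmax) / 2 + wq0 - wt0;
            int beff = band + (c.dmax - c.dmin) / 2 + 1;
            if (beff > max_band) beff = max_band;
            Hit h;
            if (!banded_sw(Q, T, wq0, wq1, wt0, wt1, dmid, beff, smat,
                           gap_open, gap_extend, h))
                continue;
            if (h.score < min_score) continue;
            h.tid = tid;
            // drop if essentially duplicating an already kept hit
            bool dup = false;
            for (auto& o : thits) {
                int ov = std::min(o.tend, h.tend) - std::max(o.tstart, h.tstart);
                int shorter = std::min(o.tend - o.tstart, h.tend - h.tstart);
                if (ov > 0 && ov >= (int)(0.5 * shorter)) {
                    if (h.score > o.score) o = h;
                    dup = true;
                    break;
                }
            }
            if (!dup) thits.push_back(h);
        }
        for (auto& h : thits) hits.push_back(h);
    }
    int n = (int)hits.size();
    IntegerVector tid(n), ts(n), te(n), qs(n), qe(n), sc(n), mt(n), al(n);
    for (int i = 0; i < n; ++i) {
        tid[i] = hits[i].tid + 1;
        ts[i] = hits[i].tstart; te[i] = hits[i].tend;
        qs[i] = hits[i].qstart; qe[i] = hits[i].qend;
        sc[i] = hits[i].score; mt[i] = hits[i].matches; al[i] = hits[i].alnlen;
    }
    return DataFrame::create(_["tid"] = tid, _["tstart"] = ts, _["tend"] = te,
                             _["qstart"] = qs, _["qend"] = qe, _["score"] = sc,
                             _["matches"] = mt, _["alnlen"] = al);
}
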