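#include "common.h"
using namespace Rcpp;

// ---------------------------------------------------------------- index ----

// [[Rcpp::export]]
SEXP tl_index_build(std::string concat, IntegerVector block_start,
                    IntegerVector block_end, int seed_len) {
    if (seed_len < 1 || seed_len > 32)
        stop("seed_len must be in 1..32");
    XPtr<TLIndex> p(new TLIndex(), true);
    p->seed_len = seed_len;
    p->concat = std::move(concat);
    p->block_start = as<std::vector<int> >(block_start);
    p->block_end = as<std::vector<int> >(block_end);

    const std::string &s = p->concat;
    const uint64_t mask =
        (seed_len == 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    uint64_t key = 0;
    int run = 0;
    std::vector<std::pair<uint64_t, int32_t> > &v = p->seeds;
    v.reserve(s.size() > (size_t)seed_len ? s.size() - seed_len + 1 : 0);
    for (size_t i = 0; i < s.size(); ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)b) & mask;
        if (++run >= seed_len)
            v.push_back(std::make_pair(key, (int32_t)(i - seed_len + 1)));
    }
    std::sort(v.begin(), v.end());
    return p;
}

static bool pack_seed(const char *s, int k, uint64_t &key) {
    key = 0;
    for (int i = 0; i < k; ++i) {
        int b = base2bits(s[i]);
        if (b < 0) return false;
        key = (key << 2) | (uint64_t)b;
    }
    return true;
}

// [[Rcpp::export]]
IntegerVector tl_lookup(SEXP ptr, std::string seed) {
    XPtr<TLIndex> p(ptr);
    if ((int)seed.size() != p->seed_len)
        stop("seed length %d does not match index seed_len %d",
             (int)seed.size(), p->seed_len);
    uint64_t key;
    if (!pack_seed(seed.c_str(), p->seed_len, key)) return IntegerVector(0);
    std::pair<uint64_t, int32_t> lo(key, INT32_MIN), hi(key, INT32_MAX);
    auto a = std::lower_bound(p->seeds.begin(), p->seeds.end(), lo);
    auto b = std::upper_bound(p->seeds.begin(), p->seeds.end(), hi);
    IntegerVector out(b - a);
    for (R_xlen_t i = 0; a != b; ++a, ++i) out[i] = a->second;
    return out;
}

// [[Rcpp::export]]
double tl_n_seed_positions(SEXP ptr) {
    XPtr<TLIndex> p(ptr);
    return (double)p->seeds.size();
}

// ---------------------------------------------- banded edit distance ------

static const int EDIT_INF = 1 << 28;

// Global banded Levenshtein (Ukkonen band |i-j| <= max_d) with traceback.
// Returns distance (or EDIT_INF) and expanded op string over {M,X,I,D}:
// I = extra base in query, D = query missing a target base.
static int banded_global(const std::string &q, const std::string &t, int max_d,
                         std::string *ops) {
    int m = (int)q.size(), n = (int)t.size();
    if (std::abs(n - m) > max_d) return EDIT_INF;
    std::vector<int> dp((size_t)(m + 1) * (n + 1), EDIT_INF);
    auto at = [&](int i, int j) -> int & { return dp[(size_t)i * (n + 1) + j]; };
    for (int j = 0; j <= std::min(n, max_d); ++j) at(0, j) = j;
    for (int i = 1; i <= m; ++i) {
        int jlo = std::max(0, i - max_d), jhi = std::min(n, i + max_d);
        if (jlo == 0) at(i, 0) = i;
        for (int j = std::max(1, jlo); j <= jhi; ++j) {
            int best = EDIT_INF;
            int diag = at(i - 1, j - 1);
            if (diag < EDIT_INF)
                best = diag + (q[i - 1] == t[j - 1] ? 0 : 1);
            int up = at(i - 1, j);   // I
            if (up < EDIT_INF && up + 1 < best) best = up + 1;
            int left = at(i, j - 1); // D
            if (left < EDIT_INF && left + 1 < best) best = left + 1;
            at(i, j) = best;
        }
    }
    int d = at(m, n);
    if (d > max_d) return EDIT_INF;
    if (ops) {
        std::string rev;
        int i = m, j = n;
        while (i > 0 || j > 0) {
            int cur = at(i, j);
            if (i > 0 && j > 0 && at(i - 1, j - 1) < EDIT_INF &&
                at(i - 1, j - 1) + (q[i - 1] == t[j - 1] ? 0 : 1) == cur) {
                rev.push_back(q[i - 1] == t[j - 1] ? 'M' : 'X');
                --i; --j;
            } else if (j > 0 && at(i, j - 1) < EDIT_INF && at(i, j - 1) + 1 == cur) {
                rev.push_back('D'); --j;
            } else {
                rev.push_back('I'); --i;
            }
        }
        ops->assign(rev.rbegin(), rev.rend());
    }
    return d;
}

// [[Rcpp::export]]
List banded_levenshtein_cpp(std::string query, std::string target, int max_d) {
    if (max_d < 0) stop("max_d must be >= 0");
    std::string ops;
    int d = banded_global(query, target, max_d, &ops);
    if (d >= EDIT_INF)
        return List::create(_["distance"] = R_PosInf, _["ops"] = NA_STRING);
    return List::create(_["distance"] = (double)d, _["ops"] = ops);
}

// Semi-global: query end-to-end, free leading/trailing target offset.
// Alignment start restricted to target column offset0 +/- max_d, band
// half-width 2*max_d around the implied diagonal. On success fills
// distance, target start ts, target end te, op string; returns true.
struct SemiResult {
    int dist, ts, te;
    std::string ops;
};

static bool semi_global(const std::string &q, const std::string &t,
                        int offset0, int max_d, SemiResult &res) {
    int m = (int)q.size(), n = (int)t.size();
    int hw = 2 * max_d;
    std::vector<int> dp((size_t)(m + 1) * (n + 1), EDIT_INF);
    auto at = [&](int i, int j) -> int & { return dp[(size_t)i * (n + 1) + j]; };
    int s_lo = std::max(0, offset0 - max_d), s_hi = std::min(n, offset0 + max_d);
    if (s_lo > n) return false;
    for (int j = s_lo; j <= s_hi; ++j) at(0, j) = 0;
    for (int i = 1; i <= m; ++i) {
        int jlo = std::max(0, offset0 + i - hw);
        int jhi = std::min(n, offset0 + i + hw);
        if (jlo > jhi) return false;
        for (int j = jlo; j <= jhi; ++j) {
            int best = EDIT_INF;
            if (j > 0) {
                int diag = at(i - 1, j - 1);
                if (diag < EDIT_INF)
                    best = diag + (q[i - 1] == t[j - 1] ? 0 : 1);
                int left = at(i, j - 1);
                if (left < EDIT_INF && left + 1 < best) best = left + 1;
            }
            int up = at(i - 1, j);
            if (up < EDIT_INF && up + 1 < best) best = up + 1;
            if (best < EDIT_INF) at(i, j) = best;
        }
    }
    int bj = -1, bd = EDIT_INF;
    int jlo = std::max(0, offset0 + m - hw), jhi = std::min(n, offset0 + m + hw);
    for (int j = jlo; j <= jhi; ++j)
        if (at(m, j) < bd) { bd = at(m, j); bj = j; }
    if (bd > max_d) return false;
    // traceback: prefer diagonal, then D (target consume), then I
    std::string rev;
    int i = m, j = bj;
    while (i > 0) {
        int cur = at(i, j);
        if (i > 0 && j > 0 && at(i - 1, j - 1) < EDIT_INF &&
            at(i - 1, j - 1) + (q[i - 1] == t[j - 1] ? 0 : 1) == cur) {
            rev.push_back(q[i - 1] == t[j - 1] ? 'M' : 'X');
            --i; --j;
        } else if (j > 0 && at(i, j - 1) < EDIT_INF && at(i, j - 1) + 1 == cur) {
            rev.push_back('D'); --j;
        } else if (at(i - 1, j) < EDIT_INF && at(i - 1, j) + 1 == cur) {
            rev.push_back('I'); --i;
        } else {
            return false; // unreachable
        }
    }
    res.dist = bd;
    res.ts = j;
    res.te = bj;
    res.ops.assign(rev.rbegin(), rev.rend());
    return true;
}

// ---------------------------------------------------------- align batch ---

// Seed offsets: 0, stride, 2*stride, ... plus a flush-right seed.
static void seed_offsets(int read_len, int seed_len, int stride,
                         std::vector<int> &out) {
    out.clear();
    if (read_len < seed_len) return;
    for (int o = 0; o + seed_len <= read_len; o += stride) out.push_back(o);
    int last = read_len - seed_len;
    if (out.empty() || out.back() != last) out.push_back(last);
}

struct Cand {
    int64_t diag;
    int votes;
};

// Align a batch of C2T-converted reads against the index.
// status: 0 unique, 1 multiple, 2 unmapped.
// [[Rcpp::export]]
List tl_align_batch(SEXP ptr, CharacterVector reads, int stride, int max_d,
                    int uniq_gap, int max_seed_hits, int max_candidates) {
    XPtr<TLIndex> p(ptr);
    const int k = p->seed_len;
    const std::string &cat = p->concat;
    R_xlen_t nr = reads.size();

    IntegerVector status(nr), cstart(nr), span(nr), dist(nr), second(nr);
    CharacterVector script(nr);

    std::vector<int> offs;
    std::vector<int64_t> diags;
    std::vector<Cand> cands;

    for (R_xlen_t r = 0; r < nr; ++r) {
        std::string q = as<std::string>(reads[r]);
        int m = (int)q.size();
        status[r] = 2;
        cstart[r] = NA_INTEGER; span[r] = NA_INTEGER;
        dist[r] = NA_INTEGER; second[r] = NA_INTEGER;
        script[r] = NA_STRING;
        seed_offsets(m, k, stride, offs);
        if (offs.empty()) continue;

        diags.clear();
        for (int o : offs) {
            uint64_t key;
            if (!pack_seed(q.c_str() + o, k, key)) continue;
            std::pair<uint64_t, int32_t> lo(key, INT32_MIN), hi(key, INT32_MAX);
            auto a = std::lower_bound(p->seeds.begin(), p->seeds.end(), lo);
            auto b = std::upper_bound(p->seeds.begin(), p->seeds.end(), hi);
            if (b - a > (ptrdiff_t)max_seed_hits) continue; // repeat seed
            for (; a != b; ++a) diags.push_back((int64_t)a->second - o);
        }
        if (diags.empty()) continue;
        std::sort(diags.begin(), diags.end());

        // cluster diagonals within max_d; votes = max per-diagonal count
        cands.clear();
        size_t i0 = 0;
        while (i0 < diags.size()) {
            size_t i1 = i0 + 1;
            int64_t best_diag = diags[i0];
            int best_cnt = 1, cur_cnt = 1;
            while (i1 < diags.size() && diags[i1] - diags[i1 - 1] <= max_d) {
                if (diags[i1] == diags[i1 - 1]) {
                    if (++cur_cnt > best_cnt) { best_cnt = cur_cnt; best_diag = diags[i1]; }
                } else cur_cnt = 1;
                ++i1;
            }
            cands.push_back(Cand{best_diag, best_cnt});
            i0 = i1;
        }
        std::sort(cands.begin(), cands.end(), [](const Cand &a, const Cand &b) {
            if (a.votes != b.votes) return a.votes > b.votes;
            return a.diag < b.diag;
        });
        if ((int)cands.size() > max_candidates) cands.resize(max_candidates);

        int best_d = EDIT_INF, second_d = EDIT_INF;
        int best_start = -1;
        SemiResult best_res;
        for (const Cand &c : cands) {
            int64_t diag = c.diag;
            int center = (int)std::min<int64_t>(
                std::max<int64_t>(diag + m / 2, 0), (int64_t)cat.size() - 1);
            int blk = p->find_block(center);
            if (blk < 0) continue;
            int bs = p->block_start[blk], be = p->block_end[blk];
            int wlo = (int)std::max<int64_t>(bs, diag - max_d);
            int whi = (int)std::min<int64_t>(be, diag + m + max_d);
            if (whi - wlo < m - max_d) continue;
            SemiResult res;
            if (!semi_global(q, cat.substr(wlo, whi - wlo),
                             (int)(diag - wlo), max_d, res))
                continue;
            int abs_ts = wlo + res.ts;
            if (best_start >= 0 && std::abs(abs_ts - best_start) <= max_d) {
                // same locus rediscovered
                if (res.dist < best_d) {
                    best_d = res.dist; best_start = abs_ts; best_res = res;
                }
            } else if (res.dist < best_d) {
                second_d = best_d;
                best_d = res.dist; best_start = abs_ts; best_res = res;
            } else if (res.dist < second_d) {
                second_d = res.dist;
            }
            if (best_d == 0) break; // early stop on perfect hit
        }
        if (best_d > max_d) continue; // unmapped
        dist[r] = best_d;
        cstart[r] = best_start;
        span[r] = best_res.te - best_res.ts;
        script[r] = best_res.ops;
        second[r] = (second_d >= EDIT_INF) ? NA_INTEGER : second_d;
        bool unique = (second_d >= EDIT_INF) || (second_d - best_d >= uniq_gap);
        status[r] = unique ? 0 : 1;
    }
    return List::create(_["status"] = status, _["concat_start"] = cstart,
                        _["span"] = span, _["distance"] = dist,
                        _["second_best"] = second, _["script"] = script);
}
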