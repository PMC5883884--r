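#include "common.h"
#include <map>
#include <tuple>
using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
        out[i] = revcomp_str(as<std::string>(seqs[i]));
    }
    return out;
}

// Origin-strand-frame reference segment for an alignment:
// '+' -> watson[pos, pos+span); '-' -> revcomp of the same interval.
static std::string ref_segment(const std::string &watson, int pos, int span,
                               bool plus) {
    std::string s = watson.substr(pos, span);
    return plus ? s : revcomp_str(s);
}

// target span (M+X+D) of an expanded op string
static int script_span(const std::string &ops) {
    int n = 0;
    for (char c : ops) if (c == 'M' || c == 'X' || c == 'D') ++n;
    return n;
}

// bisulfite-aware comparison in origin-strand frame:
// 0 match, 1 conversion (genome C, read T), 2 mismatch
static int bis_compare(char ref, char rd) {
    if (ref == rd) return 0;
    if (ref == 'C' && rd == 'T') return 1;
    return 2;
}

// Bisulfite-aware mismatch recount with randomized visit order and early
// termination. Visit order is seeded from a stable hash of the read id so
// that results are independent of chunking.
// [[Rcpp::export]]
DataFrame recount_batch(CharacterVector orig_seqs, CharacterVector read_ids,
                        IntegerVector chrom_idx, IntegerVector pos,
                        CharacterVector strand, CharacterVector scripts,
                        CharacterVector watson_seqs, int max_mismatches) {
    R_xlen_t n = orig_seqs.size();
    IntegerVector mm(n), conv(n), evaluated(n);
    LogicalVector accepted(n);
    std::vector<std::string> genome(watson_seqs.size());
    for (R_xlen_t i = 0; i < watson_seqs.size(); ++i)
        genome[i] = as<std::string>(watson_seqs[i]);

    std::vector<int> order;
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string rd = as<std::string>(orig_seqs[r]);
        std::string ops = as<std::string>(scripts[r]);
        bool plus = as<std::string>(strand[r]) == "+";
        const std::string &wat = genome[chrom_idx[r] - 1];
        int span = script_span(ops);
        std::string ref = ref_segment(wat, pos[r], span, plus);

        // per-column items: >=0 -> (read_idx<<16)|ref_idx compare; -1 indel
        std::vector<std::pair<int, int> > items; // (read_i or -1, ref_i or -1)
        int ri = 0, ti = 0;
        for (char c : ops) {
            switch (c) {
            case 'M': case 'X': items.push_back({ri++, ti++}); break;
            case 'I': items.push_back({-1, -1}); ++ri; break;
            case 'D': items.push_back({-1, -1}); ++ti; break;
            }
        }
        if (ri != (int)rd.size() || ti != (int)ref.size())
            stop("edit script inconsistent with sequences for read '%s'",
                 as<std::string>(read_ids[r]).c_str());

        int K = (int)items.size();
        order.resize(K);
        for (int i = 0; i < K; ++i) order[i] = i;
        SplitMix rng(fnv1a(as<std::string>(read_ids[r])));
        for (int i = K - 1; i > 0; --i)
            std::swap(order[i], order[rng.below(i + 1)]);

        int m = 0, cv = 0, ev = 0;
        bool acc = true;
        for (int i = 0; i < K; ++i) {
            const std::pair<int, int> &it = items[order[i]];
            ++ev;
            if (it.first < 0) ++m;      // indel unit
            else {
                int cmp = bis_compare(ref[it.second], rd[it.first]);
                if (cmp == 1) ++cv;
                else if (cmp == 2) ++m;
            }
            if (m > max_mismatches) { acc = false; break; }
        }
        mm[r] = m; conv[r] = cv; evaluated[r] = ev; accepted[r] = acc;
    }
    return DataFrame::create(_["bis_mismatches"] = mm, _["conversions"] = conv,
                             _["positions_evaluated"] = evaluated,
                             _["accepted"] = accepted,
                             _["stringsAsFactors"] = false);
}

// Per-cytosine pileup over unique alignments: on the origin strand, genome C
// with read C = methylated call, read T = unmethylated call; other read
// bases and indel columns ignored. Returns sorted site counts.
// [[Rcpp::export]]
DataFrame pileup_batch(CharacterVector orig_seqs, IntegerVector chrom_idx,
                       IntegerVector pos, CharacterVector strand,
                       CharacterVector scripts, CharacterVector watson_seqs) {
    std::vector<std::string> genome(watson_seqs.size());
    for (R_xlen_t i = 0; i < watson_seqs.size(); ++i)
        genome[i] = as<std::string>(watson_seqs[i]);
    // key: (chrom, watson pos, strand 0='+' 1='-') -> (meth, total)
    std::map<std::tuple<int, int, int>, std::pair<int, int> > acc;

    for (R_xlen_t r = 0; r < orig_seqs.size(); ++r) {
        std::string rd = as<std::string>(orig_seqs[r]);
        std::string ops = as<std::string>(scripts[r]);
        bool plus = as<std::string>(strand[r]) == "+";
        const std::string &wat = genome[chrom_idx[r] - 1];
        int span = script_span(ops);
        int ri = 0, ti = 0;
        for (char c : ops) {
            if (c == 'I') { ++ri; continue; }
            if (c == 'D') { ++ti; continue; }
            // M or X column
            int wpos = plus ? pos[r] + ti : pos[r] + span - 1 - ti;
            char ref = plus ? wat[wpos] : comp_base(wat[wpos]);
            if (ref == 'C') {
                char b = rd[ri];
                if (b == 'C' || b == 'T') {
                    auto &e = acc[std::make_tuple(chrom_idx[r], wpos, plus ? 0 : 1)];
                    ++e.second;
                    if (b == 'C') ++e.first;
                }
            }
            ++ri; ++ti;
        }
    }
    R_xlen_t n = (R_xlen_t)acc.size();
    IntegerVector ci(n), p(n), meth(n), total(n);
    CharacterVector st(n);
    R_xlen_t i = 0;
    for (auto &kv : acc) {
        ci[i] = std::get<0>(kv.first);
        p[i] = std::get<1>(kv.first);
        st[i] = std::get<2>(kv.first) == 0 ? "+" : "-";
        meth[i] = kv.second.first;
        total[i] = kv.second.second;
        ++i;
    }
    return DataFrame::create(_["chrom_idx"] = ci, _["pos"] = p,
                             _["strand"] = st, _["meth_count"] = meth,
                             _["total_count"] = total,
                             _["stringsAsFactors"] = false);
}

// Per-cycle bisulfite-aware mismatch QC. Cycle = position in the read as
// sequenced (origin-strand frame). Conversions are not mismatches; inserted
// read bases count as mismatches at their cycle; deletions have no cycle.
// [[Rcpp::export]]
List mismatch_profile_cpp(CharacterVector orig_seqs, IntegerVector chrom_idx,
                          IntegerVector pos, CharacterVector strand,
                          CharacterVector scripts, CharacterVector watson_seqs,
                          int max_len) {
    std::vector<std::string> genome(watson_seqs.size());
    for (R_xlen_t i = 0; i < watson_seqs.size(); ++i)
        genome[i] = as<std::string>(watson_seqs[i]);
    IntegerVector mism(max_len), cover(max_len);
    for (R_xlen_t r = 0; r < orig_seqs.size(); ++r) {
        std::string rd = as<std::string>(orig_seqs[r]);
        std::string ops = as<std::string>(scripts[r]);
        bool plus = as<std::string>(strand[r]) == "+";
        const std::string &wat = genome[chrom_idx[r] - 1];
        int span = script_span(ops);
        std::string ref = ref_segment(wat, pos[r], span, plus);
        int ri = 0, ti = 0;
        for (char c : ops) {
            if (c == 'D') { ++ti; continue; }
            if (ri >= max_len) break;
            if (c == 'I') {
                ++mism[ri]; ++cover[ri]; ++ri; continue;
            }
            ++cover[ri];
            if (bis_compare(ref[ti], rd[ri]) == 2) ++mism[ri];
            ++ri; ++ti;
        }
    }
    return List::create(_["mismatches"] = mism, _["coverage"] = cover);
}

// Adapter trimming: remove the longest read suffix matching a prefix of the
// adapter with >= min_overlap bases and <= 10% mismatches (no indels).
// Returns the kept read length.
// [[Rcpp::export]]
IntegerVector trim_adapter_batch(CharacterVector seqs, std::string adapter,
                                 int min_overlap, double max_mismatch_frac) {
    IntegerVector out(seqs.size());
    int alen = (int)adapter.size();
    for (R_xlen_t r = 0; r < seqs.size(); ++r) {
        std::string s = as<std::string>(seqs[r]);
        int len = (int)s.size();
        int keep = len;
        for (int st = 0; st <= len - min_overlap; ++st) {
            int ov = std::min(len - st, alen);
            if (ov < min_overlap) break;
            int allowed = (int)(max_mismatch_frac * ov);
            int mm = 0;
            bool ok = true;
            for (int i = 0; i < ov; ++i) {
                if (s[st + i] != adapter[i] && ++mm > allowed) { ok = false; break; }
            }
            if (ok) { keep = st; break; } // smallest start = longest suffix
        }
        out[r] = keep;
    }
    return out;
}
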