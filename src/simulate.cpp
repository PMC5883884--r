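#include "common.h"
using namespace Rcpp;

static int runif_below(int n) {
    int k;
    do { k = (int)(unif_rand() * n); } while (k >= n);
    return k;
}

static char random_base() { return "ACGT"[runif_below(4)]; }

static char random_other_base(char b) {
    char c;
    do { c = random_base(); } while (c == b);
    return c;
}

// Simulate single-end bisulfite reads with known truth. Uses R's RNG: call
// set.seed() before this for reproducibility. Methylation state vectors are
// per watson coordinate: -1 = no cytosine on that strand, 0 = unmethylated,
// 1 = methylated ('+': watson C positions; '-': watson G positions, i.e.
// crick Cs). Reads are emitted in the origin-strand frame; in
// non-directional mode half the reads are PCR complements (revcomp).
// [[Rcpp::export]]
List simulate_reads_cpp(CharacterVector chrom_seqs, List wstates, List cstates,
                        int n_reads, int read_len, double sub_rate,
                        double indel_rate, double conversion_rate,
                        bool directional) {
    int nc = (int)chrom_seqs.size();
    std::vector<std::string> seqs(nc);
    std::vector<IntegerVector> ws(nc), cs(nc);
    std::vector<double> weight(nc);
    double wtot = 0;
    for (int i = 0; i < nc; ++i) {
        seqs[i] = as<std::string>(chrom_seqs[i]);
        ws[i] = as<IntegerVector>(wstates[i]);
        cs[i] = as<IntegerVector>(cstates[i]);
        int w = (int)seqs[i].size() - read_len + 1;
        weight[i] = w > 0 ? (double)w : 0.0;
        wtot += weight[i];
    }
    if (wtot <= 0) stop("no chromosome is long enough for read_len");

    CharacterVector out_seq(n_reads), out_id(n_reads), out_strand(n_reads);
    IntegerVector out_chrom(n_reads), out_pos(n_reads), out_subs(n_reads),
        out_indels(n_reads);
    LogicalVector out_flip(n_reads);

    for (int r = 0; r < n_reads; ++r) {
        std::string read;
        int ci = 0, L = 0, nsub = 0, nind = 0;
        bool plus = true, ok = false;
        for (int attempt = 0; attempt < 1000 && !ok; ++attempt) {
            // chromosome weighted by number of valid start positions
            double u = unif_rand() * wtot, acc = 0;
            ci = nc - 1;
            for (int i = 0; i < nc; ++i) {
                acc += weight[i];
                if (u < acc) { ci = i; break; }
            }
            const std::string &chr = seqs[ci];
            int nstart = (int)chr.size() - read_len + 1;
            L = runif_below(nstart);
            plus = unif_rand() < 0.5;
            // reject origins with N in the intended window
            bool hasN = false;
            for (int i = L; i < L + read_len; ++i)
                if (chr[i] == 'N') { hasN = true; break; }
            if (hasN) continue;

            read.clear();
            nsub = nind = 0;
            // walk the origin strand; deletions consume extra genome bases
            int g = plus ? L : L + read_len - 1;
            bool ran_off = false;
            while ((int)read.size() < read_len) {
                if (plus ? g >= (int)chr.size() : g < 0) { ran_off = true; break; }
                double e = unif_rand();
                if (e < indel_rate) {
                    if (unif_rand() < 0.5) {            // insertion
                        read.push_back(random_base());
                        ++nind;
                    } else {                            // deletion
                        ++nind;
                        g += plus ? 1 : -1;
                    }
                    continue;
                }
                char base = plus ? chr[g] : comp_base(chr[g]);
                if (base == 'N') { ran_off = true; break; }
                if (base == 'C') {
                    int st = plus ? ws[ci][g] : cs[ci][g];
                    if (st == 0 && unif_rand() < conversion_rate) base = 'T';
                }
                if (unif_rand() < sub_rate) {
                    base = random_other_base(base);
                    ++nsub;
                }
                read.push_back(base);
                g += plus ? 1 : -1;
            }
            if (!ran_off && (int)read.size() == read_len) ok = true;
        }
        if (!ok) stop("failed to draw a valid read origin after 1000 attempts");
        bool flip = false;
        if (!directional && unif_rand() < 0.5) {
            read = revcomp_str(read);
            flip = true;
        }
        char idbuf[32];
        snprintf(idbuf, sizeof(idbuf), "r%07d", r + 1);
        out_id[r] = idbuf;
        out_seq[r] = read;
        out_chrom[r] = ci + 1; // index; names attached in R
        out_pos[r] = L;
        out_strand[r] = plus ? "+" : "-";
        out_subs[r] = nsub;
        out_indels[r] = nind;
        out_flip[r] = flip;
    }
    return List::create(_["read_id"] = out_id, _["seq"] = out_seq,
                        _["chrom_idx"] = out_chrom, _["pos"] = out_pos,
                        _["strand"] = out_strand, _["n_subs"] = out_subs,
                        _["n_indels"] = out_indels, _["pcr_complement"] = out_flip);
}
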