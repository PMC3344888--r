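#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// SOLiD di-base encoding. With A,C,G,T coded 0..3 the color of a transition
// is the XOR of the two base codes, which reproduces the canonical 4x4
// matrix (identical pair -> 0; A/C, G/T -> 1; A/G, C/T -> 2; A/T, C/G -> 3)
// and makes the complement-invariance of colors immediate.

static inline int baseCode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export(name = ".cs_encode")]]
CharacterVector cs_encode(CharacterVector seqs, CharacterVector primer) {
    R_xlen_t n = seqs.size();
    if (primer.size() != 1 && primer.size() != n)
        stop("primer must have length 1 or length(seqs)");
    CharacterVector out(n);
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string s = as<std::string>(seqs[r]);
        std::string p = as<std::string>(primer[primer.size() == 1 ? 0 : r]);
        if (p.size() != 1 || baseCode(p[0]) < 0)
            stop("primer base must be a single A/C/G/T character");
        if (s.empty()) stop("cannot encode an empty sequence");
        std::string cols(s.size(), '0');
        int prev = baseCode(p[0]);
        for (size_t i = 0; i < s.size(); ++i) {
            int b = baseCode(s[i]);
            if (b < 0)
                stop("non-ACGT character '%s' at position %d of sequence %d",
                     std::string(1, s[i]).c_str(), (int)(i + 1), (int)(r + 1));
            cols[i] = (char)('0' + (prev ^ b));
            prev = b;
        }
        out[r] = cols;
    }
    return out;
}

// [[Rcpp::export(name = ".cs_decode")]]
CharacterVector cs_decode(CharacterVector primer, CharacterVector colors) {
    R_xlen_t n = colors.size();
    if (primer.size() != 1 && primer.size() != n)
        stop("primer must have length 1 or length(colors)");
    CharacterVector out(n);
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string cs = as<std::string>(colors[r]);
        std::string p = as<std::string>(primer[primer.size() == 1 ? 0 : r]);
        if (p.size() != 1 || baseCode(p[0]) < 0)
            stop("primer base must be a single A/C/G/T character");
        std::string seq(cs.size(), 'A');
        int b = baseCode(p[0]);
        for (size_t i = 0; i < cs.size(); ++i) {
            int c = cs[i] - '0';
            if (c < 0 || c > 3)
                stop("invalid color character '%s' at position %d of read %d",
                     std::string(1, cs[i]).c_str(), (int)(i + 1), (int)(r + 1));
            b ^= c;
            seq[i] = BASES[b];
        }
        out[r] = seq;
    }
    return out;
}

// [[Rcpp::export(name = ".cs_revcomp")]]
CharacterVector cs_revcomp(CharacterVector seqs) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string s = as<std::string>(seqs[r]);
        std::string o(s.size(), 'N');
        for (size_t i = 0; i < s.size(); ++i) {
            int b = baseCode(s[s.size() - 1 - i]);
            o[i] = b < 0 ? 'N' : BASES[3 - b];
        }
        out[r] = o;
    }
    return out;
}

// Transition colors of a reference sequence: element i (0-based) encodes the
// (base i, base i+1) di-base; -1 marks transitions touching a non-ACGT base
// (the 60-N scaffold spacers), which can never be matched.
// [[Rcpp::export(name = ".cs_ref_colors")]]
IntegerVector cs_ref_colors(std::string seq) {
    if (seq.size() < 2) stop("reference must have length >= 2");
    IntegerVector out(seq.size() - 1);
    int prev = baseCode(seq[0]);
    for (size_t i = 1; i < seq.size(); ++i) {
        int b = baseCode(seq[i]);
        out[i - 1] = (prev < 0 || b < 0) ? -1 : (prev ^ b);
        prev = b;
    }
    return out;
}

// Seed-and-verify color-space mapper.
//
// The informative portion of a tag read is its colors 2..L (the first color
// crosses the synthetic primer base and is excluded from mismatch counting
// when skip_first is true). A tag occupying reference bases [p, p+L) matches
// the + strand when those m = L-1 colors equal refColors[p .. p+m-1], and
// the - strand when their REVERSE equals that window (reverse complementing
// a sequence reverses its color string). Seeds: the m query colors are cut
// into blocks of k; with <= max_mm mismatches and m/k > max_mm blocks at
// least one block is exact (pigeonhole), so an exact k-mer index over the
// reference colors makes the search lossless.
struct ColorIndex {
    int k;
    std::vector<int> bucketStart;  // size 4^k + 1
    std::vector<int> pos;          // window start positions, bucketed
};

static void buildIndex(const IntegerVector& refc, int k, ColorIndex& idx) {
    int Lc = refc.size();
    int nkey = 1 << (2 * k);
    idx.k = k;
    idx.bucketStart.assign(nkey + 1, 0);
    int nwin = Lc - k + 1;
    std::vector<int> keys(nwin > 0 ? nwin : 0, -1);
    int key = 0, run = 0, mask = nkey - 1;
    for (int i = 0; i < Lc; ++i) {
        int c = refc[i];
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | c) & mask;
        ++run;
        if (run >= k) {
            int w = i - k + 1;
            keys[w] = key;
            idx.bucketStart[key + 1]++;
        }
    }
    for (int b = 0; b < nkey; ++b) idx.bucketStart[b + 1] += idx.bucketStart[b];
    idx.pos.assign(idx.bucketStart[nkey], 0);
    std::vector<int> fill(idx.bucketStart.begin(), idx.bucketStart.end() - 1);
    for (int w = 0; w < nwin; ++w)
        if (keys[w] >= 0) idx.pos[fill[keys[w]]++] = w;
}

static inline int verify(const int* q, int m, const IntegerVector& refc, int p,
                         int maxmm) {
    int mm = 0;
    for (int i = 0; i < m; ++i) {
        int rc = refc[p + i];
        if (rc != q[i]) { if (++mm > maxmm) return -1; }
    }
    return mm;
}

static void gatherCandidates(const int* q, int m, const ColorIndex& idx,
                             int Lc, std::vector<int>& cand) {
    cand.clear();
    int k = idx.k;
    int nb = m / k;
    for (int b = 0; b <= nb; ++b) {
        int off = (b == nb) ? (m - k) : (b * k);
        if (b == nb && (m % k == 0)) break;  // last block only if m % k != 0
        int key = 0;
        bool ok = true;
        for (int i = 0; i < k; ++i) {
            int c = q[off + i];
            if (c < 0) { ok = false; break; }
            key = (key << 2) | c;
        }
        if (!ok) continue;
        for (int j = idx.bucketStart[key]; j < idx.bucketStart[key + 1]; ++j) {
            int p = idx.pos[j] - off;
            if (p >= 0 && p + m <= Lc) cand.push_back(p);
        }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
}

// Returns a flat hit table (read index 1-based, pos = 1-based leftmost
// reference base of the tag, strand +1/-1, mismatch count).
// [[Rcpp::export(name = ".cs_map_reads")]]
List cs_map_reads(CharacterVector colors, IntegerVector refColors,
                  int max_mismatches, bool skip_first, int seed_k) {
    int Lc = refColors.size();
    if (seed_k < 4 || seed_k > 12) stop("seed_k must be in [4, 12]");
    ColorIndex idx;
    buildIndex(refColors, seed_k, idx);

    std::vector<int> outRead, outPos, outStrand, outMM;
    std::vector<int> q, rq, cand;
    R_xlen_t n = colors.size();
    int expectLen = -1;
    for (R_xlen_t r = 0; r < n; ++r) {
        std::string cs = as<std::string>(colors[r]);
        if (expectLen < 0) expectLen = (int)cs.size();
        else if ((int)cs.size() != expectLen)
            stop("read %d has %d colors; expected %d (uniform tag length)",
                 (int)(r + 1), (int)cs.size(), expectLen);
        int L = (int)cs.size();
        int off0 = skip_first ? 1 : 0;
        int m = L - off0;
        if (m < seed_k || m > Lc) continue;
        q.resize(m); rq.resize(m);
        bool bad = false;
        for (int i = 0; i < m; ++i) {
            int c = cs[off0 + i] - '0';
            if (c < 0 || c > 3) { bad = true; break; }
            q[i] = c;
        }
        if (bad) continue;  // unmappable read (non-color characters)
        for (int i = 0; i < m; ++i) rq[i] = q[m - 1 - i];

        // + strand: decoded read sequence matches the forward reference
        gatherCandidates(q.data(), m, idx, Lc, cand);
        for (size_t j = 0; j < cand.size(); ++j) {
            int mm = verify(q.data(), m, refColors, cand[j], max_mismatches);
            if (mm >= 0) {
                outRead.push_back((int)(r + 1));
                outPos.push_back(cand[j] + 1);
                outStrand.push_back(1);
                outMM.push_back(mm);
            }
        }
        // - strand: reversed colors match the forward reference
        gatherCandidates(rq.data(), m, idx, Lc, cand);
        for (size_t j = 0; j < cand.size(); ++j) {
            int mm = verify(rq.data(), m, refColors, cand[j], max_mismatches);
            if (mm >= 0) {
                outRead.push_back((int)(r + 1));
                outPos.push_back(cand[j] + 1);
                outStrand.push_back(-1);
                outMM.push_back(mm);
            }
        }
    }
    return List::create(_["read"] = wrap(outRead), _["pos"] = wrap(outPos),
                        _["strand"] = wrap(outStrand), _["mm"] = wrap(outMM));
}

// Fractional accumulation of grouped hits into strand-resolved arrays.
// Hits must be ordered by read (as emitted by the mapper). For each read the
// locations with the fewest mismatches share weight 1/n; in unique-only mode
// multi-hit reads are discarded whole. Cell convention: "tss" records the
// transcript-5'-most base of the tag (right end of a +strand-mapped tag,
// left end of a -strand-mapped tag, because tag reads run antisense to the
// transcript); "start" records the leftmost mapped base on either strand.
// [[Rcpp::export(name = ".cs_accumulate")]]
List cs_accumulate(IntegerVector read, IntegerVector pos, IntegerVector strand,
                   IntegerVector mm, int ref_len, int tag_len,
                   bool unique_only, bool tss_position) {
    R_xlen_t n = read.size();
    NumericVector plus(ref_len), minus(ref_len);
    double total = 0.0;
    int nReads = 0, nUnique = 0, nMulti = 0, nDiscarded = 0;
    R_xlen_t i = 0;
    while (i < n) {
        R_xlen_t j = i;
        int minmm = mm[i];
        while (j < n && read[j] == read[i]) {
            if (mm[j] < minmm) minmm = mm[j];
            ++j;
        }
        int nbest = 0;
        for (R_xlen_t t = i; t < j; ++t) if (mm[t] == minmm) ++nbest;
        ++nReads;
        if (nbest == 1) ++nUnique; else ++nMulti;
        if (unique_only && nbest > 1) {
            ++nDiscarded;
        } else {
            double w = 1.0 / nbest;
            for (R_xlen_t t = i; t < j; ++t) {
                if (mm[t] != minmm) continue;
                int cell;
                if (strand[t] > 0)
                    cell = tss_position ? (pos[t] - 1 + tag_len - 1) : (pos[t] - 1);
                else
                    cell = pos[t] - 1;
                if (cell < 0 || cell >= ref_len)
                    stop("tag cell %d outside reference of length %d", cell, ref_len);
                if (strand[t] > 0) plus[cell] += w; else minus[cell] += w;
                total += w;
            }
        }
        i = j;
    }
    return List::create(_["plus"] = plus, _["minus"] = minus,
                        _["total"] = total, _["n_reads"] = nReads,
                        _["n_unique"] = nUnique, _["n_multi"] = nMulti,
                        _["n_discarded"] = nDiscarded);
}
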