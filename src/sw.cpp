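#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Affine-gap local alignment score (Gotoh, score-only, two-row).
// Scores: match > 0 > mismatch; a gap of length k contributes
// gap_open + (k-1) * gap_extend (both <= 0, open includes the first base).
// 'N' (or any non-ACGT symbol) scores as a mismatch against everything.
static int sw_score_one(const std::string& a, const std::string& b,
                        int match, int mismatch, int gap_open, int gap_extend) {
    const int m = (int) a.size(), n = (int) b.size();
    const int NEG = -1000000000;
    std::vector<int> H(n + 1, 0), E(n + 1, NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
        int Hdiag = 0;     // H[i-1][j-1]
        int F = NEG;       // gap in b (vertical), per row
        H[0] = 0;
        const char ai = a[(size_t)(i - 1)];
        const bool a_ok = (ai == 'A' || ai == 'C' || ai == 'G' || ai == 'T');
        for (int j = 1; j <= n; ++j) {
            E[j] = std::max(H[j] + gap_open, E[j] + gap_extend);
            F    = std::max(H[j - 1] + gap_open, F + gap_extend);
            const char bj = b[(size_t)(j - 1)];
            int s = (a_ok && ai == bj) ? match : mismatch;
            int h = Hdiag + s;
            if (E[j] > h) h = E[j];
            if (F > h) h = F;
            if (h < 0) h = 0;
            Hdiag = H[j];
            H[j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string a, std::string b,
                 int match, int mismatch, int gap_open, int gap_extend) {
    return sw_score_one(a, b, match, mismatch, gap_open, gap_extend);
}

// Scores `a` against n mononucleotide shuffles of `b`. Permutations are
// Fisher-Yates draws from R's RNG stream, so results are reproducible under
// set.seed() on the R side.
// [[Rcpp::export(name = ".sw_shuffle_scores_cpp")]]
IntegerVector sw_shuffle_scores_cpp(std::string a, std::string b, int n,
                                    int match, int mismatch, int gap_open,
                                    int gap_extend) {
    RNGScope scope;
    IntegerVector out(n);
    std::string bs = b;
    const int len = (int) bs.size();
    for (int k = 0; k < n; ++k) {
        for (int i = len - 1; i > 0; --i) {
            int j = (int) (unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(bs[(size_t) i], bs[(size_t) j]);
        }
        out[k] = sw_score_one(a, bs, match, mismatch, gap_open, gap_extend);
    }
    return out;
}

// [[Rcpp::export(name = ".sw_score_many_cpp")]]
IntegerVector sw_score_many_cpp(std::string a, std::vector<std::string> bs,
                                int match, int mismatch, int gap_open, int gap_extend) {
    IntegerVector out((R_xlen_t) bs.size());
    for (size_t k = 0; k < bs.size(); ++k)
        out[(R_xlen_t) k] = sw_score_one(a, bs[k], match, mismatch, gap_open, gap_extend);
    return out;
}
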