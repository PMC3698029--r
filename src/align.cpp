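#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Best local alignment under linear gap costs. Full O(nm) matrix is kept so
// the span can be recovered by traceback; sequences here are short queries,
// not chromosomes. Tie-break: the best-scoring cell with the smallest
// (i, j) in row-major order wins, which makes spans deterministic.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
    const int n = (int) a.size(), m = (int) b.size();
    if (n == 0 || m == 0) {
        return List::create(_["score"] = 0.0,
                            _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0);
    }
    std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double diag = H[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                          (a[i - 1] == b[j - 1] ? match : mismatch);
            double up   = H[(size_t)(i - 1) * (m + 1) + j] + gap;
            double left = H[(size_t)i * (m + 1) + (j - 1)] + gap;
            double h = diag;
            if (up > h) h = up;
            if (left > h) h = left;
            if (h < 0.0) h = 0.0;
            H[(size_t)i * (m + 1) + j] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best <= 0.0) {
        return List::create(_["score"] = 0.0,
                            _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0);
    }
    // Traceback from the best cell to the first zero cell. Preference order
    // diagonal, up, left mirrors the fill so the path is well defined.
    int i = bi, j = bj;
    while (i > 0 && j > 0 && H[(size_t)i * (m + 1) + j] > 0.0) {
        double h = H[(size_t)i * (m + 1) + j];
        double diag = H[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                      (a[i - 1] == b[j - 1] ? match : mismatch);
        if (h == diag) { --i; --j; continue; }
        if (h == H[(size_t)(i - 1) * (m + 1) + j] + gap) { --i; continue; }
        --j;
    }
    return List::create(_["score"] = best,
                        _["q_start"] = i, _["q_end"] = bi,
                        _["s_start"] = j, _["s_end"] = bj);
}

// Best ungapped window of a position weight matrix over a residue string.
// weights is L x A with columns in the order of `alphabet`; lookup[c] maps a
// residue byte to its column or -1.
// [[Rcpp::export]]
List pwm_scan_cpp(std::string query, NumericMatrix weights,
                  std::string alphabet) {
    const int L = weights.nrow();
    const int n = (int) query.size();
    int lookup[256];
    for (int c = 0; c < 256; ++c) lookup[c] = -1;
    for (int k = 0; k < (int) alphabet.size(); ++k)
        lookup[(unsigned char) alphabet[k]] = k;
    if (n < L)
        return List::create(_["found"] = false, _["score"] = R_NegInf,
                            _["offset"] = -1);
    double best = R_NegInf;
    int best_o = -1;
    for (int o = 0; o + L <= n; ++o) {
        double s = 0.0;
        for (int i = 0; i < L; ++i) {
            int col = lookup[(unsigned char) query[o + i]];
            if (col < 0) stop("residue '%c' not in model alphabet", query[o + i]);
            s += weights(i, col);
        }
        if (s > best) { best = s; best_o = o; }  // leftmost offset wins ties
    }
    return List::create(_["found"] = true, _["score"] = best,
                        _["offset"] = best_o);
}

// CRC-32 (IEEE 802.3 polynomial, reflected), table-based.
static uint32_t crc_table[256];
static bool crc_ready = false;

static void crc_init() {
    for (uint32_t i = 0; i < 256; ++i) {
        uint32_t c = i;
        for (int k = 0; k < 8; ++k)
            c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
        crc_table[i] = c;
    }
    crc_ready = true;
}

// [[Rcpp::export]]
double crc32_cpp(RawVector data) {
    if (!crc_ready) crc_init();
    uint32_t c = 0xFFFFFFFFu;
    for (R_xlen_t i = 0; i < data.size(); ++i)
        c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
    return (double) (c ^ 0xFFFFFFFFu);
}
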