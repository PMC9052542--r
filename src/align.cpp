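#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// A gap of length L costs open + (L - 1) * extend.  Scores are maximised.

static const double NEG_INF = -1e300;

// Build a 256-entry residue -> matrix-row lookup from the alphabet attached
// to the substitution matrix.  Unknown residues map to -1.
static std::vector<int> make_lookup(const CharacterVector &alphabet) {
    std::vector<int> lut(256, -1);
    for (int i = 0; i < alphabet.size(); ++i) {
        std::string s = as<std::string>(alphabet[i]);
        if (s.size() != 1)
            stop("alphabet entries must be single characters");
        lut[(unsigned char)s[0]] = i;
    }
    return lut;
}

static std::vector<int> encode(const std::string &s, const std::vector<int> &lut) {
    std::vector<int> out(s.size());
    for (size_t i = 0; i < s.size(); ++i) {
        int code = lut[(unsigned char)s[i]];
        if (code < 0)
            stop("sequence '%s' contains a residue outside the substitution alphabet", s.c_str());
        out[i] = code;
    }
    return out;
}

// Core Gotoh recursion on encoded sequences; returns the optimal score.
// Scratch buffers are reused across calls (hot path: millions of short
// alignments per kernel build).
static double gotoh(const std::vector<int> &a, const std::vector<int> &b,
                    const NumericMatrix &sub, double open, double ext) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n == 0 || m == 0) stop("alignment requires non-empty sequences");
    static thread_local std::vector<double> M, X, Y, Mp, Xp, Yp;
    static thread_local std::vector<int> boff;
    M.resize(m + 1); X.resize(m + 1); Y.resize(m + 1);
    Mp.resize(m + 1); Xp.resize(m + 1); Yp.resize(m + 1);
    boff.resize(m);
    const double *base = &sub[0];
    const int nr = sub.nrow();
    for (int j = 0; j < m; ++j) boff[j] = nr * b[j];
    // Rolling rows: M = match state, X = gap in b (consumes a), Y = gap in a.
    Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mp[j] = NEG_INF; Xp[j] = NEG_INF;
        Yp[j] = -(open + (j - 1) * ext);
    }
    for (int i = 1; i <= n; ++i) {
        M[0] = NEG_INF; Y[0] = NEG_INF;
        X[0] = -(open + (i - 1) * ext);
        const double *sa = base + a[i - 1];
        for (int j = 1; j <= m; ++j) {
            double diag = Mp[j - 1];
            if (Xp[j - 1] > diag) diag = Xp[j - 1];
            if (Yp[j - 1] > diag) diag = Yp[j - 1];
            M[j] = diag + sa[boff[j - 1]];
            double xo = Mp[j] > Yp[j] ? Mp[j] : Yp[j];
            X[j] = std::max(xo - open, Xp[j] - ext);
            double yo = M[j - 1] > X[j - 1] ? M[j - 1] : X[j - 1];
            Y[j] = std::max(yo - open, Y[j - 1] - ext);
        }
        std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    }
    double best = Mp[m];
    if (Xp[m] > best) best = Xp[m];
    if (Yp[m] > best) best = Yp[m];
    return best;
}

// [[Rcpp::export]]
NumericVector cpp_align_score(CharacterVector a, CharacterVector b,
                              NumericMatrix sub, CharacterVector alphabet,
                              double gap_open, double gap_extend) {
    if (a.size() != b.size())
        stop("'a' and 'b' must have the same length");
    std::vector<int> lut = make_lookup(alphabet);
    NumericVector out(a.size());
    for (int i = 0; i < a.size(); ++i) {
        std::vector<int> ea = encode(as<std::string>(a[i]), lut);
        std::vector<int> eb = encode(as<std::string>(b[i]), lut);
        out[i] = gotoh(ea, eb, sub, gap_open, gap_extend);
    }
    return out;
}

// Self-alignment score of an encoded sequence (used for the homology
// normalisation d(a,a)); computed with the same DP, no shortcut.
static double self_score(const std::vector<int> &a, const NumericMatrix &sub,
                         double open, double ext) {
    return gotoh(a, a, sub, open, ext);
}

struct EncodedRepertoire {
    std::vector<std::vector<int> > seqs;
    std::vector<double> w;
    std::vector<double> self;  // d(a,a)
    double wtot;
};

static EncodedRepertoire encode_repertoire(const CharacterVector &seqs,
                                           const NumericVector &w,
                                           const std::vector<int> &lut,
                                           const NumericMatrix &sub,
                                           double open, double ext) {
    if (seqs.size() != w.size())
        stop("sequences and abundances differ in length");
    if (seqs.size() == 0)
        stop("empty repertoire");
    EncodedRepertoire er;
    er.wtot = 0.0;
    for (int k = 0; k < seqs.size(); ++k) {
        er.seqs.push_back(encode(as<std::string>(seqs[k]), lut));
        er.w.push_back(w[k]);
        er.wtot += w[k];
        double d = self_score(er.seqs.back(), sub, open, ext);
        if (d <= 0)
            stop("sequence '%s' has non-positive self-alignment score; cannot normalise",
                 as<std::string>(seqs[k]).c_str());
        er.self.push_back(d);
    }
    return er;
}

// Abundance-weighted best-match homology between two encoded repertoires:
//   [ sum_k w_ik max_l s(a_ik, a_jl) + sum_l w_jl max_k s(a_ik, a_jl) ]
//     / (sum_k w_ik + sum_l w_jl)
static double pair_homology(const EncodedRepertoire &ri, const EncodedRepertoire &rj,
                            const NumericMatrix &sub, double open, double ext) {
    size_t mi = ri.seqs.size(), mj = rj.seqs.size();
    std::vector<double> rowmax(mi, NEG_INF), colmax(mj, NEG_INF);
    for (size_t k = 0; k < mi; ++k) {
        for (size_t l = 0; l < mj; ++l) {
            double d = gotoh(ri.seqs[k], rj.seqs[l], sub, open, ext);
            double s = d / std::sqrt(ri.self[k] * rj.self[l]);
            if (s > rowmax[k]) rowmax[k] = s;
            if (s > colmax[l]) colmax[l] = s;
        }
    }
    double acc = 0.0;
    for (size_t k = 0; k < mi; ++k) acc += ri.w[k] * rowmax[k];
    for (size_t l = 0; l < mj; ++l) acc += rj.w[l] * colmax[l];
    return acc / (ri.wtot + rj.wtot);
}

// [[Rcpp::export]]
double cpp_repertoire_homology(CharacterVector seqs_i, NumericVector w_i,
                               CharacterVector seqs_j, NumericVector w_j,
                               NumericMatrix sub, CharacterVector alphabet,
                               double gap_open, double gap_extend) {
    std::vector<int> lut = make_lookup(alphabet);
    EncodedRepertoire ri = encode_repertoire(seqs_i, w_i, lut, sub, gap_open, gap_extend);
    EncodedRepertoire rj = encode_repertoire(seqs_j, w_j, lut, sub, gap_open, gap_extend);
    return pair_homology(ri, rj, sub, gap_open, gap_extend);
}

// Full n x n repertoire-homology matrix.  The diagonal is set to 1
// analytically (every within-subject best match is the sequence itself,
// with s = 1), avoiding m_i^2 self-alignments per subject.
// [[Rcpp::export]]
NumericMatrix cpp_build_kernel(List seq_list, List w_list,
                               NumericMatrix sub, CharacterVector alphabet,
                               double gap_open, double gap_extend) {
    int n = seq_list.size();
    if (w_list.size() != n) stop("sequence and abundance lists differ in length");
    std::vector<int> lut = make_lookup(alphabet);
    std::vector<EncodedRepertoire> reps;
    reps.reserve(n);
    for (int i = 0; i < n; ++i) {
        reps.push_back(encode_repertoire(as<CharacterVector>(seq_list[i]),
                                         as<NumericVector>(w_list[i]),
                                         lut, sub, gap_open, gap_extend));
    }
    NumericMatrix S(n, n);
    for (int i = 0; i < n; ++i) {
        S(i, i) = 1.0;
        for (int j = i + 1; j < n; ++j) {
            double v = pair_homology(reps[i], reps[j], sub, gap_open, gap_extend);
            S(i, j) = v;
            S(j, i) = v;
        }
        if (i % 16 == 0) Rcpp::checkUserInterrupt();
    }
    return S;
}
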