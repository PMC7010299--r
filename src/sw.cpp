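#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman local alignment.
//
// Scoring: +match / mismatch per aligned pair; a gap of length L costs
// gap_open + L * gap_ext (both supplied as positive costs).  This is the
// convention used by Biostrings::pairwiseAlignment, which the test suite
// uses as an independent exhaustive oracle.
//
// Returns the single best local alignment with a per-column trace so callers
// can compute identity and count matched columns on either side of a
// position (needed for junction-overhang accounting).  Coordinates are
// 1-based inclusive.  Ties are broken deterministically: smallest subject
// end, then smallest query end.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch, int gap_open, int gap_ext) {
    const int m = q.size(), n = s.size();
    if (m == 0 || n == 0)
        return List::create(_["score"] = 0);
    const int NEG = -1000000000;
    // H: best ending at (i,j) with q[i] aligned to s[j]or gap-closed state
    // Ix: gap in subject (consumes query), Iy: gap in query (consumes subject)
    std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
    std::vector<int> Ixprev(n + 1, NEG), Ixcur(n + 1, NEG);
    std::vector<int> Iycur(n + 1, NEG);
    // full traceback matrices (small inputs only; callers window the subject)
    // dir codes: 0 stop, 1 diagonal, 2 up (gap in subject), 3 left (gap in query)
    std::vector<unsigned char> dirH((size_t)(m + 1) * (n + 1), 0);
    std::vector<unsigned char> extIx((size_t)(m + 1) * (n + 1), 0);
    std::vector<unsigned char> extIy((size_t)(m + 1) * (n + 1), 0);

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        std::fill(Iycur.begin(), Iycur.end(), NEG);
        Hcur[0] = 0; Ixcur[0] = NEG;
        for (int j = 1; j <= n; ++j) {
            // gap in subject: extend down (consume query base i)
            int openIx = Hprev[j] - gap_open - gap_ext;
            int extdIx = Ixprev[j] - gap_ext;
            if (openIx >= extdIx) { Ixcur[j] = openIx; extIx[(size_t)i * (n + 1) + j] = 0; }
            else                  { Ixcur[j] = extdIx; extIx[(size_t)i * (n + 1) + j] = 1; }
            // gap in query: extend right (consume subject base j)
            int openIy = Hcur[j - 1] - gap_open - gap_ext;
            int extdIy = Iycur[j - 1] - gap_ext;
            if (openIy >= extdIy) { Iycur[j] = openIy; extIy[(size_t)i * (n + 1) + j] = 0; }
            else                  { Iycur[j] = extdIy; extIy[(size_t)i * (n + 1) + j] = 1; }
            int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
            int diag = Hprev[j - 1] + sub;
            int h = 0; unsigned char d = 0;
            if (diag > h) { h = diag; d = 1; }
            if (Ixcur[j] > h) { h = Ixcur[j]; d = 2; }
            if (Iycur[j] > h) { h = Iycur[j]; d = 3; }
            Hcur[j] = h;
            dirH[(size_t)i * (n + 1) + j] = d;
            if (h > best) { best = h; bi = i; bj = j; }
        }
        std::swap(Hprev, Hcur);
        std::swap(Ixprev, Ixcur);
    }
    if (best <= 0)
        return List::create(_["score"] = 0);

    // traceback from (bi, bj)
    std::vector<int> qpos, spos; std::vector<int> ismatch;
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = Ix, 2 = Iy
    while (i > 0 && j > 0) {
        if (state == 0) {
            unsigned char d = dirH[(size_t)i * (n + 1) + j];
            if (d == 0) break;
            if (d == 1) {
                qpos.push_back(i); spos.push_back(j);
                ismatch.push_back(q[i - 1] == s[j - 1] ? 1 : 0);
                --i; --j;
            } else if (d == 2) state = 1;
            else state = 2;
        } else if (state == 1) {
            qpos.push_back(i); spos.push_back(0); ismatch.push_back(0);
            unsigned char e = extIx[(size_t)i * (n + 1) + j];
            --i;
            if (!e) state = 0;
        } else {
            qpos.push_back(0); spos.push_back(j); ismatch.push_back(0);
            unsigned char e = extIy[(size_t)i * (n + 1) + j];
            --j;
            if (!e) state = 0;
        }
    }
    std::reverse(qpos.begin(), qpos.end());
    std::reverse(spos.begin(), spos.end());
    std::reverse(ismatch.begin(), ismatch.end());
    int q1 = 0, q2 = 0, s1 = 0, s2 = 0, nm = 0;
    for (size_t k = 0; k < qpos.size(); ++k) {
        if (qpos[k] > 0) { if (!q1) q1 = qpos[k]; q2 = qpos[k]; }
        if (spos[k] > 0) { if (!s1) s1 = spos[k]; s2 = spos[k]; }
        nm += ismatch[k];
    }
    return List::create(
        _["score"] = best,
        _["q_start"] = q1, _["q_end"] = q2,
        _["s_start"] = s1, _["s_end"] = s2,
        _["n_match"] = nm, _["n_col"] = (int)qpos.size(),
        _["qpos"] = wrap(qpos), _["spos"] = wrap(spos),
        _["match_col"] = wrap(ismatch));
}
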