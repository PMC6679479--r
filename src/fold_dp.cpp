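#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbor minimum-free-energy fill for pseudoknot-free secondary
// structure with positions optionally forced single-stranded.
//
// Sequence encoding: A=1, C=2, G=3, U=4, N=0 (N never pairs).
// Pair types: AU=1, UA=2, GC=3, CG=4, GU=5, UG=6, none=0.
//
// Energy conventions (all kcal/mol, resolved at temperature by the caller):
//   stackG[p1][p2]   stack of inner pair p2 directly under outer pair p1
//   hairpinG[L]      hairpin loop of L unpaired nt (L >= minHairpin)
//   bulgeG[L]        bulge of L nt
//   internalG[L]     internal loop of L total unpaired nt
//   multiA/B/C       multiloop closing / per-branch / per-unpaired-nt
//
// Recurrences (WM = multiloop component, >= 1 branch, canonical
// rightmost-branch decomposition so enumeration is unambiguous):
//   V(i,j)  = min(hairpin, interior loops up to maxInternal, multi)
//   multi   = A + B + min_{p<=q<j} V(p,q) + B + (j-1-q)*C
//                       + (p > i+1 ? WM(i+1,p-1) : INF)
//   WM(i,j) = min(WM(i,j-1)+C,
//                 min_p V(p,j)+B+min((p-i)*C, WM(i,p-1)))
//   W(j)    = min(W(j-1), min_i W(i-1)+V(i,j))

static inline int pairType(int a, int b) {
    if (a == 1 && b == 4) return 1;
    if (a == 4 && b == 1) return 2;
    if (a == 3 && b == 2) return 3;
    if (a == 2 && b == 3) return 4;
    if (a == 3 && b == 4) return 5;
    if (a == 4 && b == 3) return 6;
    return 0;
}

// [[Rcpp::export(name = ".foldFill")]]
List foldFill(IntegerVector s, LogicalVector forceUnpaired,
              NumericMatrix stackG, NumericVector hairpinG,
              NumericVector bulgeG, NumericVector internalG,
              double multiA, double multiB, double multiC,
              int minHairpin, int maxInternal) {
    const double INF = 1e9;
    int n = s.size();
    NumericMatrix V(n + 1, n + 1), WM(n + 1, n + 1);
    NumericVector W(n + 1);
    for (int i = 0; i <= n; ++i)
        for (int j = 0; j <= n; ++j) { V(i, j) = INF; WM(i, j) = INF; }

    for (int span = minHairpin + 1; span < n; ++span) {
        for (int i = 1; i + span <= n; ++i) {
            int j = i + span;
            // ---- V(i,j)
            int pt = pairType(s[i - 1], s[j - 1]);
            if (pt != 0 && !forceUnpaired[i - 1] && !forceUnpaired[j - 1]) {
                int L = j - i - 1;
                double best = (L >= minHairpin && L < hairpinG.size())
                                  ? hairpinG[L] : INF;
                // interior loops (stack / bulge / internal)
                for (int p = i + 1; p < j; ++p) {
                    int l1 = p - i - 1;
                    if (l1 > maxInternal) break;
                    for (int q = j - 1; q > p; --q) {
                        int l2 = j - q - 1;
                        if (l1 + l2 > maxInternal) break;
                        if (V(p, q) >= INF) continue;
                        double e;
                        int pt2 = pairType(s[p - 1], s[q - 1]);
                        if (l1 == 0 && l2 == 0)
                            e = stackG(pt, pt2) + V(p, q);
                        else if (l1 == 0 || l2 == 0)
                            e = bulgeG[l1 + l2] + V(p, q);
                        else
                            e = internalG[l1 + l2] + V(p, q);
                        if (e < best) best = e;
                    }
                }
                // multiloop: split form A + B + min_k WM(i+1,k)+WM(k+1,j-1)
                // (same minimum as the canonical rightmost-branch form the
                // enumerator uses)
                for (int k = i + 2; k <= j - 3; ++k) {
                    if (WM(i + 1, k) >= INF || WM(k + 1, j - 1) >= INF)
                        continue;
                    double e = multiA + multiB + WM(i + 1, k) +
                               WM(k + 1, j - 1);
                    if (e < best) best = e;
                }
                V(i, j) = best;
            }
            // ---- WM(i,j)
            double best = INF;
            if (j - 1 >= i && WM(i, j - 1) < INF)
                best = WM(i, j - 1) + multiC;
            for (int p = i; p < j; ++p) {
                if (V(p, j) >= INF) continue;
                double left = multiC * (p - i);
                if (p - 1 >= i && WM(i, p - 1) < INF &&
                    WM(i, p - 1) < left)
                    left = WM(i, p - 1);
                double e = V(p, j) + multiB + left;
                if (e < best) best = e;
            }
            WM(i, j) = best;
        }
    }
    W[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
        W[j] = W[j - 1];
        for (int i = 1; i <= j; ++i)
            if (V(i, j) < INF && W[i - 1] + V(i, j) < W[j])
                W[j] = W[i - 1] + V(i, j);
    }
    return List::create(_["V"] = V, _["WM"] = WM, _["W"] = W,
                        _["mfe"] = W[n]);
}
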