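#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inside/outside charts for the stem-constrained grammar
//   (1) X -> a        (2) X -> aX      (3) X -> aHb   (4) X -> aHbX
//   (5) H -> aHb      (6) H -> aYb     (7) Y -> aXb
// All arithmetic is in log space so charts stay finite for long sequences
// (probabilities of individual derivations underflow doubles near n ~ 340).
//
// Span bounds implied by the rules: Y spans >= 3, H spans >= 5, a
// pair-emitting expansion of X spans >= 7 (rule 4 as a whole spans >= 8).
//
// x is 0-based integer-coded (A=0, C=1, G=2, U=3); matrices are n x n with
// entry (i, j) holding the value for the 1-based span (i+1, j+1).

static inline double lse(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  return (a > b) ? a + log1p(exp(b - a)) : b + log1p(exp(a - b));
}

// [[Rcpp::export]]
List scfg_inside_cpp(IntegerVector x, NumericVector lp, NumericVector lu,
                     NumericMatrix lpi) {
  const int n = x.size();
  NumericMatrix aX(n, n), aH(n, n), aY(n, n);
  std::fill(aX.begin(), aX.end(), R_NegInf);
  std::fill(aH.begin(), aH.end(), R_NegInf);
  std::fill(aY.begin(), aY.end(), R_NegInf);

  for (int i = 0; i < n; ++i) aX(i, i) = lp[0] + lu[x[i]];

  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      const double pij = lpi(x[i], x[j]);

      if (len >= 3 && pij != R_NegInf)
        aY(i, j) = lp[6] + pij + aX(i + 1, j - 1);

      if (len >= 5 && pij != R_NegInf) {
        double v = lp[5] + pij + aY(i + 1, j - 1);           // rule 6
        if (len >= 7)
          v = lse(v, lp[4] + pij + aH(i + 1, j - 1));        // rule 5
        aH(i, j) = v;
      }

      double v = lp[1] + lu[x[i]] + aX(i + 1, j);            // rule 2
      if (len >= 7 && pij != R_NegInf)
        v = lse(v, lp[2] + pij + aH(i + 1, j - 1));          // rule 3
      if (len >= 8) {                                        // rule 4
        for (int k = i + 6; k <= j - 1; ++k) {
          const double pik = lpi(x[i], x[k]);
          if (pik == R_NegInf) continue;
          const double h = aH(i + 1, k - 1);
          if (h == R_NegInf) continue;
          v = lse(v, lp[3] + pik + h + aX(k + 1, j));
        }
      }
      aX(i, j) = v;
    }
  }

  return List::create(_["alphaX"] = aX, _["alphaH"] = aH, _["alphaY"] = aY,
                      _["logZ"] = aX(0, n - 1));
}

// [[Rcpp::export]]
List scfg_outside_cpp(IntegerVector x, NumericVector lp, NumericVector lu,
                      NumericMatrix lpi, NumericMatrix aX, NumericMatrix aH,
                      NumericMatrix aY) {
  const int n = x.size();
  NumericMatrix bX(n, n), bH(n, n), bY(n, n);
  std::fill(bX.begin(), bX.end(), R_NegInf);
  std::fill(bH.begin(), bH.end(), R_NegInf);
  std::fill(bY.begin(), bY.end(), R_NegInf);
  bX(0, n - 1) = 0.0;

  for (int len = n; len >= 2; --len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      const double pij = lpi(x[i], x[j]);

      const double oX = bX(i, j);
      if (oX != R_NegInf) {
        bX(i + 1, j) = lse(bX(i + 1, j), lp[1] + lu[x[i]] + oX);   // rule 2
        if (len >= 7 && pij != R_NegInf)                           // rule 3
          bH(i + 1, j - 1) = lse(bH(i + 1, j - 1), lp[2] + pij + oX);
        if (len >= 8) {                                            // rule 4
          for (int k = i + 6; k <= j - 1; ++k) {
            const double pik = lpi(x[i], x[k]);
            if (pik == R_NegInf) continue;
            const double h = aH(i + 1, k - 1);
            if (h == R_NegInf) continue;
            bH(i + 1, k - 1) =
                lse(bH(i + 1, k - 1), lp[3] + pik + aX(k + 1, j) + oX);
            bX(k + 1, j) = lse(bX(k + 1, j), lp[3] + pik + h + oX);
          }
        }
      }

      const double oH = bH(i, j);
      if (len >= 5 && pij != R_NegInf && oH != R_NegInf) {
        if (len >= 7)                                              // rule 5
          bH(i + 1, j - 1) = lse(bH(i + 1, j - 1), lp[4] + pij + oH);
        bY(i + 1, j - 1) = lse(bY(i + 1, j - 1), lp[5] + pij + oH);// rule 6
      }

      const double oY = bY(i, j);
      if (len >= 3 && pij != R_NegInf && oY != R_NegInf)           // rule 7
        bX(i + 1, j - 1) = lse(bX(i + 1, j - 1), lp[6] + pij + oY);
    }
  }

  return List::create(_["betaX"] = bX, _["betaH"] = bH, _["betaY"] = bY);
}

// Base-pair probabilities: for each pair-emitting rule S -> aRbT the pair
// (i, j) contributes ruleprob * pi(x_i, x_j) * gamma(R, S, T, i, j) where
// gamma = sum_{j < k <= n} alpha(R, i+1, j-1) beta(S, i, k) alpha(T, j+1, k);
// for rules without a trailing T the sum collapses to k = j.  Everything is
// normalized by the total inside probability alpha(X, 1, n).

// [[Rcpp::export]]
NumericMatrix scfg_pairprob_cpp(IntegerVector x, NumericVector lp,
                                NumericMatrix lpi, NumericMatrix aX,
                                NumericMatrix aH, NumericMatrix aY,
                                NumericMatrix bX, NumericMatrix bH,
                                NumericMatrix bY, double logZ) {
  const int n = x.size();
  NumericMatrix P(n, n);
  if (logZ == R_NegInf) return P;

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double pij = lpi(x[i], x[j]);
      if (pij == R_NegInf) continue;
      const int len = j - i + 1;
      double acc = R_NegInf;

      if (len >= 7) {                                   // rule 3: X -> aHb
        const double h = aH(i + 1, j - 1);
        if (h != R_NegInf)
          acc = lse(acc, lp[2] + pij + h + bX(i, j));
      }
      if (len >= 7) {                                   // rule 5: H -> aHb
        const double h = aH(i + 1, j - 1);
        if (h != R_NegInf)
          acc = lse(acc, lp[4] + pij + h + bH(i, j));
      }
      if (len >= 5) {                                   // rule 6: H -> aYb
        const double y = aY(i + 1, j - 1);
        if (y != R_NegInf)
          acc = lse(acc, lp[5] + pij + y + bH(i, j));
      }
      if (len >= 3)                                     // rule 7: Y -> aXb
        acc = lse(acc, lp[6] + pij + aX(i + 1, j - 1) + bY(i, j));
      if (len >= 7) {                                   // rule 4: X -> aHbX
        const double h = aH(i + 1, j - 1);
        if (h != R_NegInf) {
          for (int k = j + 1; k < n; ++k) {
            const double o = bX(i, k);
            if (o == R_NegInf) continue;
            acc = lse(acc, lp[3] + pij + h + o + aX(j + 1, k));
          }
        }
      }

      if (acc != R_NegInf) P(i, j) = exp(acc - logZ);
    }
  }
  return P;
}
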