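#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// HKY85 transition probabilities, closed form (TN93 specialization).
// State order A, C, G, T. Q is scaled so the expected rate is 1 subst/site,
// hence t is in expected substitutions per site. Row-major P[i*4+j] = P(i->j).
static inline void hky_pmat(double t, double kappa, const double *pi,
                            double *P) {
  const double piA = pi[0], piC = pi[1], piG = pi[2], piT = pi[3];
  const double piR = piA + piG, piY = piC + piT;
  const double beta =
      1.0 / (2.0 * kappa * (piA * piG + piC * piT) + 2.0 * piR * piY);
  const double e2 = std::exp(-beta * t);
  const double eR = std::exp(-beta * t * (piR * kappa + piY));
  const double eY = std::exp(-beta * t * (piY * kappa + piR));

  P[0 * 4 + 0] = piA + piA * piY / piR * e2 + piG / piR * eR;
  P[0 * 4 + 2] = piG + piG * piY / piR * e2 - piG / piR * eR;
  P[0 * 4 + 1] = piC * (1.0 - e2);
  P[0 * 4 + 3] = piT * (1.0 - e2);

  P[2 * 4 + 2] = piG + piG * piY / piR * e2 + piA / piR * eR;
  P[2 * 4 + 0] = piA + piA * piY / piR * e2 - piA / piR * eR;
  P[2 * 4 + 1] = piC * (1.0 - e2);
  P[2 * 4 + 3] = piT * (1.0 - e2);

  P[1 * 4 + 1] = piC + piC * piR / piY * e2 + piT / piY * eY;
  P[1 * 4 + 3] = piT + piT * piR / piY * e2 - piT / piY * eY;
  P[1 * 4 + 0] = piA * (1.0 - e2);
  P[1 * 4 + 2] = piG * (1.0 - e2);

  P[3 * 4 + 3] = piT + piT * piR / piY * e2 + piC / piY * eY;
  P[3 * 4 + 1] = piC + piC * piR / piY * e2 - piC / piY * eY;
  P[3 * 4 + 0] = piA * (1.0 - e2);
  P[3 * 4 + 2] = piG * (1.0 - e2);
}

// [[Rcpp::export]]
NumericMatrix hky_transition_matrix_cpp(double t, double kappa,
                                        NumericVector pi) {
  double buf[16];
  hky_pmat(t, kappa, REAL(pi), buf);
  NumericMatrix P(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) P(i, j) = buf[i * 4 + j];
  return P;
}

// Felsenstein pruning log-likelihood under HKY + discrete-gamma.
//
// edge        : (parent, child) rows in postorder (children before parents,
//               ape 1-based node numbering, root = edge(last, 0))
// lengths     : branch length per edge row, expected substitutions/site
// n_tip       : number of tips; tip nodes are 1..n_tip
// tip_states  : n_pattern x n_tip integer matrix, 0=A 1=C 2=G 3=T 4=missing
// weights     : pattern multiplicities
// rates       : relative rate of each gamma category (mean 1); equal category
//               probabilities; length 1 with rate 1 means rate homogeneity
//
// Missing states contribute a partial likelihood of 1 for every state.
// [[Rcpp::export]]
double hky_pruning_loglik_cpp(IntegerMatrix edge, NumericVector lengths,
                              int n_tip, IntegerMatrix tip_states,
                              NumericVector weights, double kappa,
                              NumericVector pi, NumericVector rates) {
  const int n_pat = tip_states.nrow();
  const int n_edge = edge.nrow();
  int n_node = n_tip;
  for (int e = 0; e < n_edge; ++e) {
    if (edge(e, 0) > n_node) n_node = edge(e, 0);
    if (edge(e, 1) > n_node) n_node = edge(e, 1);
  }
  const int root = edge(n_edge - 1, 0);
  const int n_cat = rates.size();

  std::vector<double> site(n_pat, 0.0);
  std::vector<double> part((size_t)(n_node + 1) * 4 * n_pat);
  std::vector<char> seen((size_t)n_node + 1);
  double Pm[16];

  for (int cat = 0; cat < n_cat; ++cat) {
    std::fill(seen.begin(), seen.end(), 0);
    for (int e = 0; e < n_edge; ++e) {
      const int p = edge(e, 0), c = edge(e, 1);
      hky_pmat(lengths[e] * rates[cat], kappa, REAL(pi), Pm);
      double *Lp = &part[(size_t)p * 4 * n_pat];
      if (!seen[p]) {
        std::fill(Lp, Lp + 4 * n_pat, 1.0);
        seen[p] = 1;
      }
      if (c <= n_tip) {
        for (int s = 0; s < n_pat; ++s) {
          const int st = tip_states(s, c - 1);
          if (st < 4) {
            for (int a = 0; a < 4; ++a) Lp[a * n_pat + s] *= Pm[a * 4 + st];
          }
        }
      } else {
        const double *Lc = &part[(size_t)c * 4 * n_pat];
        for (int s = 0; s < n_pat; ++s) {
          for (int a = 0; a < 4; ++a) {
            const double v = Pm[a * 4 + 0] * Lc[0 * n_pat + s] +
                             Pm[a * 4 + 1] * Lc[1 * n_pat + s] +
                             Pm[a * 4 + 2] * Lc[2 * n_pat + s] +
                             Pm[a * 4 + 3] * Lc[3 * n_pat + s];
            Lp[a * n_pat + s] *= v;
          }
        }
      }
    }
    const double *Lr = &part[(size_t)root * 4 * n_pat];
    for (int s = 0; s < n_pat; ++s) {
      site[s] += pi[0] * Lr[0 * n_pat + s] + pi[1] * Lr[1 * n_pat + s] +
                 pi[2] * Lr[2 * n_pat + s] + pi[3] * Lr[3 * n_pat + s];
    }
  }

  double logL = 0.0;
  const double invcat = 1.0 / n_cat;
  for (int s = 0; s < n_pat; ++s) {
    const double v = site[s] * invcat;
    if (!(v > 0.0) || !std::isfinite(v)) return R_NegInf;
    logL += weights[s] * std::log(v);
  }
  return logL;
}
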